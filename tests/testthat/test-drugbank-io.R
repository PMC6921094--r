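test_that("parser extracts cards with derived target counts", {
  xml <- catalog_frag(
    drug_frag(
      name = "Triplex", id = "DB0001",
      targets = c(
        target_frag(name = "T1", known = "yes", action = "inhibitor",
                    gene = "ACE"),
        target_frag(name = "T2", known = "no", action = NA, gene = "REN"),
        target_frag(name = "T3", known = "unknown", action = NA, gene = "AGT")
      )
    )
  )
  cat1 <- parse_drugbank_xml(xml)
  expect_equal(nrow(cat1$cards), 1L)
  expect_equal(cat1$cards$drug_id, "DB0001")
  expect_equal(cat1$cards$n_targets, 3L)
  expect_equal(cat1$cards$n_known_action_targets, 1L)
  expect_equal(sum(cat1$targets$known_action), 1L)
})

test_that("empty catalog parses to an empty card list", {
  cat1 <- parse_drugbank_xml("<drugbank></drugbank>")
  expect_equal(nrow(cat1$cards), 0L)
  expect_equal(nrow(cat1$targets), 0L)
})

test_that("malformed XML raises a parse error", {
  expect_error(parse_drugbank_xml("<drugbank><drug>"), "malformed")
})

test_that("drugs missing name or type are rejected, parsing continues", {
  xml <- catalog_frag(
    drug_frag(name = "Keepol"),
    drug_frag(name = NA),
    drug_frag(name = "Typeless", type = NA),
    drug_frag(name = "Alienol", type = "gene therapy")
  )
  cat1 <- parse_drugbank_xml(xml)
  expect_equal(nrow(cat1$cards), 1L)
  expect_equal(cat1$cards$name, "Keepol")
  expect_equal(nrow(cat1$rejects), 3L)
  expect_setequal(cat1$rejects$reason,
                  c("missing-name", "missing-or-invalid-type"))
})

test_that("empty-string and literal NULL fields are normalized to absent", {
  xml <- catalog_frag(
    drug_frag(name = "Nullol",
              targets = target_frag(gene = "NULL", organism = ""))
  )
  cat1 <- parse_drugbank_xml(xml)
  expect_true(is.na(cat1$targets$gene_symbol))
  expect_true(is.na(cat1$targets$organism))
})

test_that("status labels are lower-cased and comma-split", {
  xml <- catalog_frag(
    drug_frag(name = "Statol", groups = "Approved, Investigational")
  )
  cat1 <- parse_drugbank_xml(xml)
  expect_setequal(cat1$cards$status_labels[[1]],
                  c("approved", "investigational"))
})

test_that("unparseable marketing dates become absent with a warning", {
  xml <- catalog_frag(
    drug_frag(name = "Datol",
              products = c(product_frag(date = "not-a-date"),
                           product_frag(date = "1999-12-31")))
  )
  expect_warning(cat1 <- parse_drugbank_xml(xml), "ISO-8601")
  expect_equal(sum(is.na(cat1$products$marketing_start_date)), 1L)
})

test_that("parsing the same bytes twice yields identical catalogs", {
  xml <- random_catalog_xml(25, seed = 7)
  expect_identical(parse_drugbank_xml(xml), parse_drugbank_xml(xml))
})

test_that("duplicate enzyme listings collapse to unique entries", {
  xml <- catalog_frag(
    drug_frag(name = "Enzol",
              targets = target_frag(enzymes = c("CYP3A4", "CYP3A4", "CYP2D6")))
  )
  cat1 <- parse_drugbank_xml(xml)
  expect_equal(sort(cat1$targets$enzymes[[1]]), c("CYP2D6", "CYP3A4"))
})

test_that("marketing details report the earliest date per drug and country", {
  xml <- catalog_frag(
    drug_frag(name = "Oldol",
              products = c(product_frag(date = "2002-01-01"),
                           product_frag(date = "1985-05-27"))),
    drug_frag(name = "Bareol")
  )
  cat1 <- parse_drugbank_xml(xml)
  m <- extract_marketing_details(cat1, c("  oldol ", "Bareol"))
  expect_equal(m$earliest_marketing_date[m$name == "  oldol "],
               as.Date("1985-05-27"))
  expect_true(is.na(m$earliest_marketing_date[m$name == "Bareol"]))
})

test_that("unmatched marketing names yield absent rows and a warning", {
  cat1 <- parse_drugbank_xml(catalog_frag(drug_frag(name = "Onlyol")))
  expect_warning(m <- extract_marketing_details(cat1, "Ghostol"), "Ghostol")
  expect_equal(nrow(m), 1L)
  expect_true(is.na(m$country) && is.na(m$earliest_marketing_date))
  expect_error(extract_marketing_details(cat1, character()), "at least one")
})

test_that("per-drug earliest dates match a brute-force scan of the raw XML", {
  set.seed(31)
  drugs <- vapply(seq_len(50), function(i) {
    k <- sample(0:4, 1)
    prods <- if (k > 0) {
      vapply(seq_len(k), function(j) {
        product_frag(country = sample(c("United States", "Canada"), 1),
                     date = format(as.Date("1970-01-01") +
                                     sample.int(17000, 1), "%Y-%m-%d"))
      }, character(1))
    } else {
      character(0)
    }
    drug_frag(name = sprintf("Marketol %02d", i), products = prods)
  }, character(1))
  xml <- catalog_frag(drugs)
  cat1 <- parse_drugbank_xml(xml)
  names <- sprintf("Marketol %02d", 1:50)
  got <- suppressWarnings(extract_marketing_details(cat1, names))

  doc <- xml2::read_xml(xml)
  for (nm in names) {
    node <- xml2::xml_find_first(
      doc, sprintf("/drugbank/drug[name='%s']", nm))
    dates <- as.Date(xml2::xml_text(
      xml2::xml_find_all(node, ".//product/started-marketing-on")))
    rows <- got[got$name == nm, ]
    if (length(dates) == 0) {
      expect_true(all(is.na(rows$earliest_marketing_date)))
    } else {
      expect_equal(min(rows$earliest_marketing_date, na.rm = TRUE),
                   min(dates))
    }
  }
})

test_that("cards table writes one row per card and round-trips scalars", {
  xml <- catalog_frag(
    drug_frag(name = "Aol", targets = target_frag(gene = "G1")),
    drug_frag(name = "Bol", targets = target_frag(gene = NA)),
    drug_frag(name = "Col", type = "biotech")
  )
  cat1 <- parse_drugbank_xml(xml)
  path <- tempfile(fileext = ".tsv")
  write_cards_table(cat1, path)
  back <- utils::read.delim(path, na.strings = "")
  expect_equal(nrow(back), 3L)
  expect_equal(back$name, cat1$cards$name)
  expect_equal(back$type, cat1$cards$drug_type)
  expect_equal(back$n_targets, cat1$cards$n_targets)
  expect_equal(back$n_known_action_targets, cat1$cards$n_known_action_targets)
  # absent gene symbol is an empty cell, not a "NULL" placeholder
  expect_true(is.na(back$gene_symbols[back$name == "Bol"]))
  expect_error(write_cards_table(cat1, file.path(tempfile(), "no", "x.tsv")),
               "cannot write")
})
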