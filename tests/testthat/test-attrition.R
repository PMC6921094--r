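small_catalog <- function(...) parse_drugbank_xml(catalog_frag(...))

test_that("type filter retains small molecules and excludes biologics", {
  cat1 <- small_catalog(
    drug_frag(name = "S1"), drug_frag(name = "B1", type = "biotech"),
    drug_frag(name = "S2"), drug_frag(name = "B2", type = "biotech"),
    drug_frag(name = "B3", type = "biotech")
  )
  r <- filter_small_molecules(cat1)
  expect_equal(r$retained$cards$name, c("S1", "S2"))
  expect_equal(r$stage$n_in, 5L)
  expect_equal(r$stage$n_out, 2L)
  expect_equal(nrow(r$stage$exclusions), 3L)

  all_bio <- small_catalog(drug_frag(name = "B", type = "biotech"))
  expect_equal(filter_small_molecules(all_bio)$stage$n_out, 0L)

  empty <- parse_drugbank_xml("<drugbank/>")
  r0 <- filter_small_molecules(empty)
  expect_equal(c(r0$stage$n_in, r0$stage$n_out), c(0L, 0L))
})

test_that("approval filter requires an allowlisted label and veto dominates", {
  cat1 <- small_catalog(
    drug_frag(name = "Ok", groups = "approved"),
    drug_frag(name = "Pulled", groups = c("approved", "withdrawn")),
    drug_frag(name = "Trial", groups = "investigational"),
    drug_frag(name = "Street", groups = c("approved", "illicit"))
  )
  r <- filter_approved(cat1)
  expect_equal(r$retained$cards$name, "Ok")
  excl <- r$stage$exclusions
  expect_equal(excl$reason[match(c("Pulled", "Trial", "Street"),
                                 cat1$cards$name[match(excl$drug_id,
                                                       cat1$cards$drug_id)])],
               c("vetoed-status", "not-approved", "vetoed-status"))
})

test_that("known-action filter keys on known-action count, not total targets", {
  cat1 <- small_catalog(
    drug_frag(name = "Selective",
              targets = c(target_frag(known = "yes"),
                          target_frag(name = "U1", known = "unknown",
                                      action = NA),
                          target_frag(name = "U2", known = "no",
                                      action = NA))),
    drug_frag(name = "Dual",
              targets = c(target_frag(known = "yes"),
                          target_frag(name = "T2", known = "yes",
                                      action = "activator"))),
    drug_frag(name = "Blind", targets = target_frag(known = "no",
                                                    action = NA))
  )
  r <- filter_single_known_action(cat1)
  expect_equal(r$retained$cards$name, "Selective")
  expect_equal(r$retained$cards$n_targets, 3L)
})

test_that("exclusions assign distinct reasons with fixed precedence", {
  cfg <- attrition_config(excluded_drug_names = "badol")
  cat1 <- small_catalog(
    drug_frag(name = "Goodol",
              targets = target_frag(gene = "ACE")),
    drug_frag(name = "Bugkiller",
              targets = target_frag(organism = "Staphylococcus aureus")),
    drug_frag(name = "Badol", targets = target_frag(gene = "TOP1")),
    drug_frag(name = "Gapol", targets = target_frag(gene = NA))
  )
  r <- apply_exclusions(cat1, cfg)
  expect_equal(r$retained$cards$name, "Goodol")
  reasons <- r$stage$exclusions$reason[
    match(c("Bugkiller", "Badol", "Gapol"),
          cat1$cards$name[match(r$stage$exclusions$drug_id,
                                cat1$cards$drug_id)])]
  expect_equal(reasons, c("nonhuman-target", "blocklisted", "missing-field"))
})

test_that("exclusions refuse cards that skipped the known-action filter", {
  cat1 <- small_catalog(
    drug_frag(name = "Dual",
              targets = c(target_frag(), target_frag(name = "T2",
                                                     known = "yes",
                                                     action = "agonist")))
  )
  expect_error(apply_exclusions(cat1), "exactly one known-action")
})

test_that("consolidation groups same-class drugs into one pair", {
  cat1 <- small_catalog(
    drug_frag(name = "Aceol", targets = target_frag(gene = "ace")),
    drug_frag(name = "Acezil", targets = target_frag(gene = " ACE ")),
    drug_frag(name = "Blockol",
              targets = target_frag(gene = "ACE", action = "Antagonist"))
  )
  pairs <- consolidate_pairs(cat1)
  expect_equal(nrow(pairs), 2L)
  inh <- pairs[pairs$action == "inhibitor", ]
  expect_equal(inh$gene_symbol, "ACE")
  expect_equal(sort(inh$member_names[[1]]), c("Aceol", "Acezil"))
  # actions are normalized but never merged across distinct words
  expect_true("antagonist" %in% pairs$action)
})

test_that("consolidation is a partition of the input drugs and idempotent", {
  xml <- random_catalog_xml(60, seed = 11)
  fr <- run_funnel(parse_drugbank_xml(xml))
  pairs <- fr$pairs
  ids <- unlist(pairs$member_drug_ids)
  expect_equal(sort(ids), sort(fr$cards$cards$drug_id))  # union == input
  expect_equal(anyDuplicated(ids), 0L)                   # pairwise disjoint
  expect_equal(sum(pairs$n_members), nrow(fr$cards$cards))
  # pair keys unique and sorted
  key <- paste(pairs$gene_symbol, pairs$action)
  expect_equal(anyDuplicated(key), 0L)
  expect_equal(key, sort(key))
  # re-consolidating the member expansion changes nothing
  again <- consolidate_pairs(fr$cards)
  expect_identical(pairs, again)
})

test_that("one-target-total rate matches a brute-force recount", {
  set.seed(5)
  drugs <- vapply(seq_len(40), function(i) {
    extra <- sample(0:2, 1)
    tg <- c(target_frag(gene = sprintf("G%02d", i)),
            if (extra > 0) {
              vapply(seq_len(extra), function(k) {
                target_frag(name = sprintf("U%d", k), known = "unknown",
                            action = NA)
              }, character(1))
            })
    drug_frag(name = sprintf("Rateol %02d", i), targets = tg)
  }, character(1))
  cat1 <- parse_drugbank_xml(catalog_frag(drugs))
  # oracle: count <targets> children directly in the XML
  doc <- xml2::read_xml(catalog_frag(drugs))
  n_single <- sum(vapply(xml2::xml_find_all(doc, "/drugbank/drug"),
                         function(d) {
                           length(xml2::xml_find_all(d, "./targets/target")) == 1L
                         }, logical(1)))
  expect_equal(one_target_total_rate(cat1),
               floor(100 * n_single / 40 * 100 + 0.5) / 100)

  all_single <- small_catalog(drug_frag(name = "One",
                                        targets = target_frag()))
  expect_equal(one_target_total_rate(all_single), 100)
  expect_error(one_target_total_rate(parse_drugbank_xml("<drugbank/>")),
               "undefined")
})

test_that("funnel stages telescope and match a per-record predicate oracle", {
  for (seed in c(3, 17)) {
    xml <- random_catalog_xml(20, seed = seed)
    cfg <- attrition_config(excluded_drug_names = "randomol 001")
    fr <- run_funnel(parse_drugbank_xml(xml), cfg)
    st <- fr$report$stages
    # telescoping: each stage consumes the previous stage's survivors
    expect_equal(st$n_in[-1], st$n_out[-nrow(st)])
    expect_equal(st$n_out + st$n_excluded, st$n_in)
    expect_equal(unname(oracle_funnel_counts(xml, cfg)), st$n_out)
  }
})

test_that("record-wise type and status filters commute", {
  xml <- random_catalog_xml(40, seed = 23)
  cat1 <- parse_drugbank_xml(xml)
  cfg <- attrition_config()
  ts <- filter_approved(filter_small_molecules(cat1)$retained, cfg)$retained
  st <- filter_small_molecules(filter_approved(cat1, cfg)$retained)$retained
  expect_identical(ts$cards, st$cards)
})

test_that("every stage returns a subset of its input, order preserved", {
  cat1 <- parse_drugbank_xml(random_catalog_xml(30, seed = 9))
  for (res in list(filter_small_molecules(cat1),
                   filter_approved(cat1),
                   filter_single_known_action(cat1))) {
    ids <- res$retained$cards$drug_id
    expect_true(all(ids %in% cat1$cards$drug_id))
    expect_equal(ids, cat1$cards$drug_id[cat1$cards$drug_id %in% ids])
  }
})

test_that("an empty catalog flows through the funnel as all zeros", {
  fr <- run_funnel(parse_drugbank_xml("<drugbank/>"))
  expect_true(all(fr$report$stages$n_in == 0))
  expect_true(all(fr$report$stages$n_out == 0))
  expect_equal(nrow(fr$pairs), 0L)
})
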