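roles_fixture <- function() {
  utils::read.delim(extdata("example_roles.tsv"), stringsAsFactors = FALSE)
}
hotspots_fixture <- function() {
  utils::read.delim(extdata("example_hotspots.tsv"), stringsAsFactors = FALSE)
}
annotations_fixture <- function() {
  utils::read.delim(extdata("example_annotations.tsv"),
                    stringsAsFactors = FALSE, na.strings = "")
}

test_that("gene roles map through the table and absent genes are discarded", {
  roles <- roles_fixture()
  expect_equal(classify_role("ESR1", roles), "oncogene")
  expect_equal(classify_role("TP53", roles), "both")
  expect_equal(classify_role("NOT_A_GENE", roles), "none")
  expect_error(classify_role("X", rbind(roles, roles[1, ])), "one role")
})

test_that("truncating and hotspot patterns are recognized and mutually exclusive", {
  expect_true(is_truncating("Nonsense_Mutation"))
  expect_true(is_truncating("Frame_Shift_Ins"))
  expect_false(is_truncating("Missense_Mutation"))
  expect_false(is_truncating("Splice_Region"))
  expect_true(is_truncating("Splice_Region", include_splice_region = TRUE))
  hs <- hotspots_fixture()
  rec <- make_records(3, protein_change = c("p.D538G", "p.E380Q", "p.Q538*"),
                      classification = c("Missense_Mutation",
                                         "Missense_Mutation",
                                         "Nonsense_Mutation"))
  got <- is_hotspot(rec, hs)
  expect_equal(got, c(TRUE, FALSE, FALSE))  # truncating never hotspot
  # mutual exclusivity over arbitrary records
  expect_false(any(got & is_truncating(rec$variant_classification)))
  # unparseable protein change -> FALSE, not an error
  rec2 <- make_records(1, protein_change = "not-hgvsp")
  expect_false(is_hotspot(rec2, hs))
})

test_that("functional scores follow the scoring table", {
  ann <- annotations_fixture()
  # oncogene missense rated high by all three tools: 3 x 2 = 6
  expect_equal(func_score("ESR1 p.D538G", "hotspot", ann), 6)
  expect_equal(func_score("ESR1 p.D538G", "hotspot", ann, is_hotspot = TRUE),
               7)
  # mixed ratings: high 2 + medium 2 + low 1 = 5 (+1 hotspot)
  expect_equal(func_score("ESR1 p.Y537S", "hotspot", ann, is_hotspot = TRUE),
               6)
  # no annotations at all
  expect_equal(func_score("NOVEL p.A1V", "hotspot", NULL), 0)
  expect_equal(func_score("NOVEL p.A1V", "hotspot", NULL, is_hotspot = TRUE), 1)
  # TSG truncation: base 4 + strong 2 / weak 1 / none 0
  expect_equal(func_score("CDH1 Trunc", "truncating", ann), 6)
  expect_equal(func_score("TP53 Trunc", "truncating", ann), 5)
  expect_equal(func_score("NF1 Trunc", "truncating", ann), 4)
  expect_equal(func_score("NF1 Trunc", "truncating", NULL), 4)
})

driver_sim_data <- function(seed = 501) {
  cfg <- sim_config(
    seed = seed,
    cohorts = data.frame(label = c("A", "B"), n_mbc = 1000, n_pbc = 1000,
                         panel_id = "P1", stringsAsFactors = FALSE),
    genes = data.frame(
      gene = c("ESR1", "CDH1"), baseline = c(0.04, 0.04),
      mbc_log_or = c(log(4), log(3)),
      hotspot_fraction = c(0.9, 0), truncating_fraction = c(0, 0.95),
      stringsAsFactors = FALSE),
    tropism = data.frame(gene = "ESR1", site_set = "liver", log_or = log(3),
                         stringsAsFactors = FALSE)
  )
  sim_to_data(generate(cfg))
}

test_that("driver calling collapses keys, applies eligibility and runs the tests", {
  d <- driver_sim_data()
  plan <- analysis_plan(genes = c("ESR1", "CDH1"))
  calls <- suppressWarnings(call_driver_mutations(
    d, roles_fixture(), hotspots_fixture(), annotations_fixture(),
    plan, genes = c("ESR1", "CDH1")))
  expect_s3_class(calls, "driver_calls")
  # hotspot missense collapsed by amino-acid change
  esr1 <- calls[calls$variant_key == "ESR1 p.D538G", ]
  expect_equal(nrow(esr1), 1)
  expect_equal(esr1$pattern, "hotspot")
  expect_true(esr1$eligible)
  expect_gt(esr1$or, 1)
  expect_lt(esr1$q, 0.05)
  # truncating variants aggregated under a single Trunc key
  cdh1 <- calls[calls$gene == "CDH1", ]
  expect_equal(cdh1$variant_key, "CDH1 Trunc")
  expect_equal(cdh1$pattern, "truncating")
  expect_true(cdh1$eligible)   # func 6, many carriers
  # every eligible call satisfies the score threshold
  expect_true(all(calls$func_score[calls$eligible] >= 5))
  # site preference: the ESR1 hotspot prefers the liver
  pref <- attr(calls, "site_preference")
  liver <- pref[pref$feature == "ESR1 p.D538G" & pref$site_set == "liver", ]
  expect_gt(liver$estimate, 0)
  expect_lt(liver$q, 0.05)
})

test_that("carrier thresholds and degenerate knowledge tables behave", {
  # one carrier: ineligible regardless of score
  cl <- make_clinical(6, tumor_type = rep(c("metastasis", "primary"), 3))
  rec <- make_records(1, sample_id = "S001")
  d <- mbc_data(rec, cl, data.frame(panel_id = "P1", gene = "ESR1",
                                    stringsAsFactors = FALSE))
  plan <- analysis_plan(genes = "ESR1")
  calls <- suppressWarnings(call_driver_mutations(
    d, roles_fixture(), hotspots_fixture(), annotations_fixture(),
    plan, genes = "ESR1"))
  expect_equal(calls$carriers, 1)
  expect_false(calls$eligible)
  # laxer threshold reading (>= 2): still one carrier, still ineligible
  calls2 <- suppressWarnings(call_driver_mutations(
    d, roles_fixture(), hotspots_fixture(), annotations_fixture(),
    plan, genes = "ESR1", carrier_min = 1))
  expect_false(calls2$eligible)
  # empty hotspot table: no oncogene keys at all
  empty_hs <- data.frame(gene = character(), protein_position = integer())
  d2 <- driver_sim_data(502)
  calls3 <- suppressWarnings(call_driver_mutations(
    d2, roles_fixture(), empty_hs, NULL, plan,
    genes = c("ESR1", "CDH1")))
  expect_false(any(calls3$pattern == "hotspot"))
  # TSG truncation without evidence scores the base 4 and stays ineligible
  expect_true(all(calls3$func_score[calls3$pattern == "truncating"] == 4))
  expect_false(any(calls3$eligible))
})
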