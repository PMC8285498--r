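test_that("carrier status is sample-level and key-specific", {
  rec <- rbind(
    make_records(2, sample_id = c("S001", "S001"), pos = 1:2),  # two ESR1 hits
    make_records(1, sample_id = "S002", protein_change = "p.E380Q", pos = 3),
    make_records(1, sample_id = "S003", classification = "Nonsense_Mutation",
                 protein_change = "p.Q120*", pos = 4)
  )
  g <- carrier_key("ESR1")
  expect_true(carrier_status(rec, "S001", g))
  expect_false(carrier_status(rec, "S999", g))
  v <- carrier_key("ESR1", protein_change = "p.D538G")
  expect_true(carrier_status(rec, "S001", v))
  expect_false(carrier_status(rec, "S002", v))
  tr <- carrier_key("ESR1", protein_change = "Trunc")
  expect_true(carrier_status(rec, "S003", tr))
  expect_false(carrier_status(rec, "S001", tr))
  expect_error(carrier_key("ESR1", "amplification", "p.D538G"),
               "only valid for snv_indel")
})

test_that("contingency collapsing reproduces the engineered liver-vs-other margins", {
  fix <- fixture_from_counts(163, 420, 161, 1416, gene = "ESR1",
                             site = "liver")
  d <- mbc_data(fix$mutations, fix$clinical, fix$panels)
  tab <- build_contingency(d$mutations, d$clinical, carrier_key("ESR1"),
                           "site_vs_other_sites",
                           grouping = list(site_set = "liver"),
                           panels = d$panels)
  expect_equal(unname(collapse_contingency(tab)), c(163, 420, 161, 1416))
  # conservation: stratum total equals eligible samples of that cohort
  expect_equal(sum(tab$a + tab$b + tab$c + tab$d), nrow(fix$clinical))
})

test_that("contingency construction is order-invariant and one-cell-per-sample", {
  sim <- generate(std_sim_config(301, log(2)))
  d <- sim_to_data(sim)
  key <- carrier_key("G1")
  t1 <- build_contingency(d$mutations, d$clinical, key, "mbc_vs_pbc",
                          panels = d$panels)
  shuffled <- d$mutations[sample.int(nrow(d$mutations)), ]
  t2 <- build_contingency(shuffled, d$clinical, key, "mbc_vs_pbc",
                          panels = d$panels)
  expect_equal(as.data.frame(t1), as.data.frame(t2))
  per_cohort <- table(d$clinical$cohort)
  expect_equal(t1$a + t1$b + t1$c + t1$d,
               as.vector(per_cohort[t1$cohort]))
})

test_that("site cases partition the distant metastatic samples", {
  sim <- generate(std_sim_config(302, log(2)))
  d <- sim_to_data(sim)
  distant <- d$clinical[d$clinical$tumor_type == "metastasis" &
                          !is.na(d$clinical$site_set), ]
  sites <- unique(distant$site_set)
  case_sum <- 0
  for (s in sites) {
    tab <- build_contingency(d$mutations, d$clinical, carrier_key("G1"),
                             "site_vs_other_sites",
                             grouping = list(site_set = s),
                             panels = d$panels)
    case_sum <- case_sum + sum(tab$a + tab$b)
  }
  expect_equal(case_sum, nrow(distant))
})

test_that("cohorts without an arm or without CNA data contribute no stratum", {
  cl <- rbind(make_clinical(4, rep("metastasis", 4), cohort = "A"),
              transform(make_clinical(4, rep(c("metastasis", "primary"),
                                             each = 2), cohort = "B"),
                        sample_id = sprintf("B%03d", 1:4),
                        patient_id = sprintf("B%03d", 1:4)))
  rec <- make_records(2, sample_id = c("S001", "B001"),
                      cohort = c("A", "B"))
  tab <- build_contingency(rec, cl, carrier_key("ESR1"), "mbc_vs_pbc")
  expect_equal(tab$cohort, "B")   # cohort A has no PBC arm
  # all samples one group -> untestable
  tab2 <- build_contingency(rec, cl[cl$tumor_type == "metastasis", ],
                            carrier_key("ESR1"), "mbc_vs_pbc")
  expect_true(attr(tab2, "untestable"))
  # amplification key restricted to cohorts present in the CNA table
  cna <- data.frame(sample_id = "B001", cohort = "B", gene = "ESR1",
                    level = 2, stringsAsFactors = FALSE)
  tab3 <- build_contingency(cna, cl, carrier_key("ESR1", "amplification"),
                            "mbc_vs_pbc")
  expect_equal(tab3$cohort, "B")
})

test_that("multi-site patient table records concordant and discordant pairs", {
  cl <- make_clinical(5, tumor_type = rep("metastasis", 5),
                      biopsy_site = c("Liver", "Bone", "Liver", "Ovary", "Lung"))
  cl$patient_id <- c("PA", "PA", "PB", "PB", "PC")  # PC: single site
  cl <- classify_site_set(cl)
  rec <- make_records(1, sample_id = "S001")        # PA liver carrier only
  tab <- multi_site_table(rec, cl, genes = "ESR1")
  expect_setequal(unique(tab$patient_id), c("PA", "PB"))
  ps <- attr(tab, "pair_summary")
  expect_equal(ps$discordant, 1)   # PA: liver+ vs bone-
  expect_equal(ps$concordant, 1)   # PB: both wild-type
  # no qualifying mutations anywhere -> all-false rows
  tab2 <- multi_site_table(rec[0, ], cl, genes = "ESR1")
  expect_true(all(!tab2$carrier))
  # no multi-site patients -> empty table
  tab3 <- multi_site_table(rec, cl[cl$patient_id == "PC", ], genes = "ESR1")
  expect_equal(nrow(tab3), 0)
})
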