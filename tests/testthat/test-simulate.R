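test_that("generation is deterministic: same seed gives byte-identical files", {
  cfg <- std_sim_config(88, log(2))
  d1 <- tempfile(); d2 <- tempfile()
  generate(cfg, out_dir = d1)
  generate(cfg, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("genes off a cohort's panel emit no records in that cohort", {
  cfg <- sim_config(
    seed = 5,
    cohorts = data.frame(label = c("A", "B"), n_mbc = 200, n_pbc = 200,
                         panel_id = c("P1", "P2"), stringsAsFactors = FALSE),
    genes = data.frame(gene = c("ON", "OFF"), baseline = 0.2,
                       mbc_log_or = 0, stringsAsFactors = FALSE),
    panels = data.frame(panel_id = c("P1", "P1", "P2"),
                        gene = c("ON", "OFF", "ON"), stringsAsFactors = FALSE),
    noise = list(silent_rate = 0, lowdepth_rate = 0, lowvaf_rate = 0,
                 duplicate_rate = 0)
  )
  sim <- generate(cfg)
  expect_equal(sum(sim$mutations$gene == "OFF" & sim$mutations$cohort == "B"), 0)
  expect_gt(sum(sim$mutations$gene == "OFF" & sim$mutations$cohort == "A"), 0)
  expect_gt(sum(sim$mutations$gene == "ON" & sim$mutations$cohort == "B"), 0)
})

test_that("QC removes exactly the injected noise records", {
  cfg <- std_sim_config(91, log(2))
  sim <- generate(cfg)
  nc <- sim$truth$noise_counts
  expect_gt(sum(nc), 0)
  out <- filter_variants(sim$mutations, qc_config())
  s <- attr(out, "qc_summary")
  counts <- setNames(s$count, s$reason)
  expect_equal(unname(counts["duplicate"]), unname(nc["duplicate"]))
  expect_equal(unname(counts["low_depth"]), unname(nc["low_depth"]))
  expect_equal(unname(counts["low_vaf"]), unname(nc["low_vaf"]))
  expect_equal(unname(counts["class_not_allowlisted"]), unname(nc["silent"]))
  expect_true(all(out$injected_noise == "signal"))
})

test_that("ground-truth manifest agrees with the emitted files", {
  cfg <- sim_config(
    seed = 12,
    cohorts = data.frame(label = "A", n_mbc = 300, n_pbc = 300,
                         panel_id = "P1", stringsAsFactors = FALSE),
    genes = data.frame(gene = c("G1", "G2"), baseline = c(0.1, 0.05),
                       mbc_log_or = c(log(2), 0), stringsAsFactors = FALSE),
    noise = list(silent_rate = 0, lowdepth_rate = 0, lowvaf_rate = 0,
                 duplicate_rate = 0)
  )
  sim <- generate(cfg)
  for (g in c("G1", "G2")) {
    from_files <- sort(unique(sim$mutations$sample_id[sim$mutations$gene == g]))
    from_truth <- sort(rownames(sim$truth$carrier_status)[sim$truth$carrier_status[, g]])
    expect_equal(from_files, from_truth)
  }
})

test_that("empirical carrier frequency converges to the logistic model", {
  baseline <- 0.1; lor <- log(2)
  cfg <- sim_config(
    seed = 1,
    cohorts = data.frame(label = "BIG", n_mbc = 50000, n_pbc = 50000,
                         panel_id = "P1", stringsAsFactors = FALSE),
    genes = data.frame(gene = "G1", baseline = baseline, mbc_log_or = lor,
                       stringsAsFactors = FALSE),
    noise = list(silent_rate = 0, lowdepth_rate = 0, lowvaf_rate = 0,
                 duplicate_rate = 0)
  )
  sim <- generate(cfg)
  is_mbc <- sim$clinical$tumor_type == "metastasis"
  carrier <- sim$truth$carrier_status[, "G1"]
  p_pbc <- mean(carrier[!is_mbc])
  p_mbc <- mean(carrier[is_mbc])
  p_mbc_true <- plogis(qlogis(baseline) + lor)
  se_pbc <- sqrt(baseline * (1 - baseline) / 50000)
  se_mbc <- sqrt(p_mbc_true * (1 - p_mbc_true) / 50000)
  expect_lt(abs(p_pbc - baseline), 3 * se_pbc)
  expect_lt(abs(p_mbc - p_mbc_true), 3 * se_mbc)
})

test_that("count fixtures reproduce exact contingencies and handle degeneracy", {
  fix <- fixture_from_counts(163, 420, 161, 1416, gene = "ESR1")
  d <- mbc_data(fix$mutations, fix$clinical, fix$panels)
  tab <- build_contingency(d$mutations, d$clinical, carrier_key("ESR1"),
                           "mbc_vs_pbc", panels = d$panels)
  expect_equal(unname(collapse_contingency(tab)), c(163, 420, 161, 1416))
  # zero carriers anywhere -> untestable downstream
  fix0 <- fixture_from_counts(0, 5, 0, 5)
  d0 <- mbc_data(fix0$mutations, fix0$clinical, fix0$panels)
  t0 <- build_contingency(d0$mutations, d0$clinical, carrier_key("GENE1"),
                          "mbc_vs_pbc", panels = d0$panels)
  expect_true(attr(t0, "untestable"))
  expect_true(or_meta(t0)$untestable)
  # degenerate margins survive without crashing
  fix1 <- fixture_from_counts(1, 0, 0, 1)
  d1 <- mbc_data(fix1$mutations, fix1$clinical, fix1$panels)
  t1 <- build_contingency(d1$mutations, d1$clinical, carrier_key("GENE1"),
                          "mbc_vs_pbc", panels = d1$panels)
  expect_s3_class(or_meta(t1), "or_meta")
})

test_that("invalid configurations fail before generation", {
  expect_error(sim_config(site_probs = c(liver = 0.5)), "sum")
  expect_error(sim_config(genes = data.frame(gene = "X", baseline = 1.4,
                                             mbc_log_or = 0)))
})
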