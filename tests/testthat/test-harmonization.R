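test_that("sample selection drops males, multi-site patients and hotspot panels", {
  cl <- make_clinical(6, tumor_type = c(rep("metastasis", 4), "primary", "primary"))
  cl$sex[1] <- "male"
  cl$patient_id[2] <- cl$patient_id[3] <- "PMULTI"
  cl$biopsy_site[2] <- "Liver"; cl$biopsy_site[3] <- "Bone"
  cl$panel_id[4] <- "PHOT"
  panels <- data.frame(panel_id = c("P1", "PHOT"), gene = "ESR1",
                       full_exonic = c(TRUE, FALSE), stringsAsFactors = FALSE)
  kept <- select_samples(cl, panels)
  log <- attr(kept, "exclusion_log")
  expect_setequal(kept$sample_id, c("S005", "S006"))
  expect_equal(log$reason[log$sample_id == "S001"], "male")
  expect_setequal(log$reason[log$sample_id %in% c("S002", "S003")],
                  "multiple metastatic sites")
  expect_equal(log$reason[log$sample_id == "S004"], "hotspot-only panel")
  # multi_site mode keeps exactly the multi-site metastatic patients
  multi <- select_samples(cl, panels, mode = "multi_site")
  expect_setequal(multi$sample_id, c("S002", "S003"))
})

test_that("variant QC filters in fixed order with exact accounting", {
  rec <- rbind(
    make_records(4, depth = c(9, 10, 200, 200), vaf = c(0.2, 0.2, 0.005, 0.01),
                 pos = 1:4),
    make_records(2, sample_id = c("S900", "S900"), pos = c(7, 7)),  # duplicate
    make_records(1, sample_id = "S901", classification = "Silent", pos = 9),
    make_records(1, sample_id = "S902", classification = "Splice_Region", pos = 10)
  )
  out <- filter_variants(rec, qc_config())
  s <- attr(out, "qc_summary")
  counts <- setNames(s$count, s$reason)
  expect_equal(unname(counts["duplicate"]), 1)
  expect_equal(unname(counts["low_depth"]), 1)     # depth 9 only
  expect_equal(unname(counts["low_vaf"]), 1)       # vaf 0.005 only
  expect_equal(unname(counts["class_not_allowlisted"]), 1)  # Silent only
  expect_equal(sum(s$count), nrow(rec))            # conservation
  # boundary: depth 10 and vaf 0.01 are kept (strict inequality)
  expect_true(any(out$depth == 10, na.rm = TRUE))
  expect_true(any(out$vaf == 0.01, na.rm = TRUE))
  expect_true("Splice_Region" %in% out$variant_classification)
  # idempotence and order stability (data content, not audit attributes)
  out2 <- filter_variants(out, qc_config())
  strip <- function(d) data.frame(unclass(as.data.frame(d)),
                                  stringsAsFactors = FALSE)
  expect_equal(strip(out2), strip(out))
})

test_that("missing depth/VAF never triggers removal", {
  rec <- make_records(3, depth = NA_real_, vaf = NA_real_)
  out <- filter_variants(rec, qc_config())
  expect_equal(nrow(out), 3)
})

test_that("outlier rule flags hypermutated samples by cohort-wise Tukey fence", {
  counts <- c(2, 3, 3, 4, 50)
  rec <- do.call(rbind, lapply(seq_along(counts), function(i) {
    make_records(counts[i], sample_id = rep(sprintf("S%03d", i), counts[i]),
                 pos = seq_len(counts[i]) + i * 100)
  }))
  out <- flag_outlier_samples(rec, qc_config())   # Q3=4, IQR=1, fence 7
  expect_equal(out, "S005")
  # all-equal counts: nothing flagged
  rec2 <- do.call(rbind, lapply(1:5, function(i) {
    make_records(3, sample_id = rep(sprintf("T%03d", i), 3),
                 pos = 1:3 + i * 10)
  }))
  expect_length(flag_outlier_samples(rec2, qc_config()), 0)
  # k = Inf disables the rule
  expect_length(flag_outlier_samples(rec, qc_config(outlier_k = Inf)), 0)
  # tiny cohort: skipped with warning
  rec3 <- make_records(3, sample_id = c("U1", "U1", "U2"))
  expect_warning(flag_outlier_samples(rec3, qc_config()), "<4 samples")
})

test_that("concurrent gene selection applies the panel-fraction threshold", {
  panels <- do.call(rbind, lapply(1:11, function(i) {
    genes <- c("ALWAYS",
               if (i <= 7) "SEVEN",
               if (i <= 6) "SIX")
    data.frame(panel_id = paste0("P", i), gene = genes,
               stringsAsFactors = FALSE)
  }))
  got <- select_concurrent_genes(panels, 7 / 11)
  expect_true("SEVEN" %in% got)       # 7 of 11 kept
  expect_false("SIX" %in% got)        # 6 of 11 dropped
  expect_true("ALWAYS" %in% got)
  # monotone: raising the fraction never adds genes
  fr <- seq(0.1, 1, by = 0.1)
  sets <- lapply(fr, function(f) select_concurrent_genes(panels, f))
  for (i in seq_along(sets)[-1]) {
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  }
  expect_error(select_concurrent_genes(panels[0, ]), "no panels")
})

test_that("CNA filter keeps only high-level calls", {
  cna <- data.frame(sample_id = paste0("S", 1:5), cohort = "A",
                    gene = "ERBB2", level = c(2, -2, -1.5, -1, 1),
                    stringsAsFactors = FALSE)
  out <- filter_cna(cna, qc_config())
  expect_setequal(out$level, c(2, -2))
  expect_equal(attr(out, "qc_summary")$count,
               c(3, 2))
})

test_that("site-set classification partitions metastatic samples", {
  cl <- make_clinical(6, tumor_type = c(rep("metastasis", 5), "primary"),
                      biopsy_site = c("Liver", "Regional lymph nodes",
                                      "Axillary lymph node", "Ipsilateral breast",
                                      "", "Breast"))
  expect_warning(classify_site_set(cl), "unmatched")
  got <- suppressWarnings(classify_site_set(cl))
  expect_equal(got$site_class[1], "distant")
  expect_equal(got$site_set[1], "liver")
  expect_equal(got$site_class[2], "local")       # regional LN = local relapse
  expect_true(is.na(got$site_set[2]))
  expect_equal(got$site_set[3], "lymph_nodes")   # distant lymph node
  expect_equal(got$site_class[4], "local")
  expect_equal(got$site_set[5], "other_distant") # empty -> fallback
  expect_true(is.na(got$site_class[6]))          # primary not classified
  # partition: exactly one of local/distant, distant implies one specific set
  met <- got[got$tumor_type == "metastasis", ]
  expect_true(all(met$site_class %in% c("local", "distant")))
  expect_true(all(is.na(met$site_set[met$site_class == "local"])))
  expect_true(all(!is.na(met$site_set[met$site_class == "distant"])))
})

test_that("subtype classification handles HER2-positive-only membership", {
  cl <- make_clinical(4, tumor_type = "metastasis",
                      hr = c("pos", "neg", NA, "neg"),
                      her2 = c("neg", "neg", "pos", "pos"))
  got <- classify_subtype(cl)
  expect_equal(got$receptor_subtype[1], "HR+/HER2-")
  expect_equal(got$receptor_subtype[2], "Triple-negative")
  expect_true(is.na(got$receptor_subtype[3]))
  # HER2-positive-only sample belongs to both HER2+ subgroups
  expect_true(got$st_hr_pos_her2_pos[3])
  expect_true(got$st_hr_neg_her2_pos[3])
  expect_equal(got$receptor_subtype[4], "HR-/HER2+")
})
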