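# Orchestration of the three analyses: pan-metastasis enrichment,
# metastatic-site-specific enrichment with the dual-criterion organotropism
# call, and treatment-status contrasts.

#' Assemble a harmonized analysis dataset
#'
#' Bundles QC-filtered mutation records, eligible clinical samples, panel
#' definitions and (optionally) filtered CNA records, resolving site sets
#' and subtypes on the clinical table. This is the input container for the
#' `run_*` analyses.
#'
#' @param mutations QC-filtered mutation records (see [apply_qc()]).
#' @param clinical Eligible sample table (see [select_samples()]).
#' @param panels Panel definition table.
#' @param cna Optional filtered CNA records (see [filter_cna()]).
#' @param site_map Site matcher table (see [default_site_set_map()]).
#' @return A list of class `"mbc_data"`.
#' @export
mbc_data <- function(mutations, clinical, panels, cna = NULL,
                     site_map = default_site_set_map()) {
  clinical <- classify_site_set(clinical, site_map)
  clinical <- classify_subtype(clinical)
  structure(list(mutations = mutations, clinical = clinical,
                 panels = panels, cna = cna),
            class = "mbc_data")
}

#' @export
print.mbc_data <- function(x, ...) {
  cat(sprintf("Harmonized dataset: %d samples (%d MBC / %d PBC), %d cohorts, %d mutation records\n",
              nrow(x$clinical),
              sum(x$clinical$tumor_type == "metastasis"),
              sum(x$clinical$tumor_type == "primary"),
              length(unique(x$clinical$cohort)), nrow(x$mutations)))
  invisible(x)
}

#' Analysis plan
#'
#' Collects the knobs of the enrichment analyses: the gene set, mutation
#' types, site sets, thresholds and cohort subsets.
#'
#' @param genes Character vector of genes to test (normally from
#'   [select_concurrent_genes()]).
#' @param mutation_types Subset of `c("snv_indel", "amplification",
#'   "deletion")`.
#' @param site_sets Specific distant site sets to test (default the 11
#'   named organ sets; the `other_distant` catch-all is excluded from
#'   per-site testing).
#' @param q_threshold Significance threshold on q-values (default 0.05).
#' @param min_site_n Minimum metastatic sample count for a site set to be
#'   tested (default 20).
#' @param site_cohorts Optional cohort subset used for site-vs-other-site
#'   comparisons (cohorts with per-sample site resolution); NULL = all
#'   cohorts that have at least two distinct metastatic site sets.
#' @param stage2_all_genes Test all genes at stage 2 instead of only
#'   stage-1-significant genes (default FALSE).
#' @param het_alpha Heterogeneity q-value threshold for the random-effects
#'   switch.
#' @return A list of class `"analysis_plan"`.
#' @export
analysis_plan <- function(genes, mutation_types = "snv_indel",
                          site_sets = setdiff(specific_site_sets,
                                              "other_distant"),
                          q_threshold = 0.05, min_site_n = 20,
                          site_cohorts = NULL, stage2_all_genes = FALSE,
                          het_alpha = 0.05) {
  stopifnot(q_threshold > 0, q_threshold < 1, length(genes) > 0)
  structure(list(genes = genes, mutation_types = mutation_types,
                 site_sets = site_sets, q_threshold = q_threshold,
                 min_site_n = min_site_n, site_cohorts = site_cohorts,
                 stage2_all_genes = stage2_all_genes,
                 het_alpha = het_alpha),
            class = "analysis_plan")
}

# records table for a mutation type (snv_indel -> mutations, else cna)
records_for_type <- function(data, type) {
  if (type == "snv_indel") data$mutations else {
    if (is.null(data$cna)) NULL else data$cna
  }
}

# grouped logistic fit from a stratified contingency: outcome = case
# membership, predictor = carrier, cohort as covariate
contingency_logistic <- function(tab) {
  if (nrow(tab) == 0) return(NULL)
  rows_carrier <- data.frame(cohort = tab$cohort, carrier = 1,
                             success = tab$a, failure = tab$c)
  rows_noncar <- data.frame(cohort = tab$cohort, carrier = 0,
                            success = tab$b, failure = tab$d)
  g <- rbind(rows_carrier, rows_noncar)
  g <- g[g$success + g$failure > 0, , drop = FALSE]
  if (length(unique(g$carrier[g$success + g$failure > 0])) < 2) return(NULL)
  covs <- if (length(unique(g$cohort)) > 1) data.frame(cohort = g$cohort) else NULL
  logistic_fit(cbind(g$success, g$failure), g$carrier, covariates = covs)
}

regression_row <- function(fit, feature, comparison, family) {
  if (is.null(fit)) {
    return(data.frame(feature = feature, comparison = comparison,
                      family = family, term = "carrier", estimate = NA_real_,
                      se = NA_real_, or = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, p = NA_real_, q = NA_real_,
                      converged = FALSE, separation_flag = FALSE,
                      stringsAsFactors = FALSE))
  }
  ce <- fit$carrier
  data.frame(feature = feature, comparison = comparison, family = family,
             term = "carrier", estimate = ce$log_or, se = ce$se, or = ce$or,
             ci_low = ce$ci_low, ci_high = ce$ci_high,
             p = if (fit$separation_flag) NA_real_ else ce$p, q = NA_real_,
             converged = fit$converged,
             separation_flag = fit$separation_flag,
             stringsAsFactors = FALSE)
}

#' Pan-metastasis enrichment analysis
#'
#' For each gene and mutation type, compares carrier frequency between all
#' MBC and all PBC samples: cohort-stratified odds-ratio meta-analysis
#' (with FDR-gated fixed/random model switching) validated by
#' cohort-adjusted logistic regression. FDR is applied within one family
#' per mutation type (meta-analysis p-values and logistic p-values each
#' form a family). A gene is reported MBC-enriched when both q-values fall
#' below the plan threshold.
#'
#' @param data An [mbc_data()].
#' @param plan An [analysis_plan()].
#' @return List of class `"pan_metastasis_result"`: `meta` (meta_family
#'   rows per mutation type), `logistic` (regression rows), `enriched`
#'   (data frame `feature, mutation_type, direction`).
#' @export
run_pan_metastasis <- function(data, plan) {
  meta_all <- list(); logi_all <- list()
  for (type in plan$mutation_types) {
    recs <- records_for_type(data, type)
    if (is.null(recs)) next
    tabs <- lapply(plan$genes, function(g) {
      build_contingency(recs, data$clinical,
                        carrier_key(g, mutation_type = type),
                        "mbc_vs_pbc", panels = data$panels)
    })
    names(tabs) <- plan$genes
    fam <- meta_family(tabs, het_alpha = plan$het_alpha)
    fam$comparison <- "mbc_vs_pbc"
    fam$family <- paste0("pan_", type)
    fam$mutation_type <- type
    meta_all[[type]] <- fam
    lrows <- do.call(rbind, lapply(plan$genes, function(g) {
      regression_row(contingency_logistic(tabs[[g]]), g, "mbc_vs_pbc",
                     paste0("pan_", type, "_logistic"))
    }))
    ok <- !is.na(lrows$p)
    lrows$q[ok] <- bh_fdr(lrows$p[ok])
    lrows$mutation_type <- type
    logi_all[[type]] <- lrows
  }
  meta <- rbind_list(meta_all)
  logistic <- rbind_list(logi_all)
  enriched <- NULL
  if (!is.null(meta)) {
    both <- merge(meta[, c("feature", "mutation_type", "q", "log_or")],
                  logistic[, c("feature", "mutation_type", "q")],
                  by = c("feature", "mutation_type"),
                  suffixes = c("_meta", "_logistic"))
    hit <- !is.na(both$q_meta) & both$q_meta < plan$q_threshold &
      !is.na(both$q_logistic) & both$q_logistic < plan$q_threshold
    enriched <- data.frame(
      feature = both$feature[hit], mutation_type = both$mutation_type[hit],
      direction = ifelse(both$log_or[hit] > 0, "enriched", "depleted"),
      stringsAsFactors = FALSE)
    enriched <- enriched[order(enriched$feature), , drop = FALSE]
    rownames(enriched) <- NULL
  }
  structure(list(meta = meta, logistic = logistic, enriched = enriched),
            class = "pan_metastasis_result")
}

#' @export
print.pan_metastasis_result <- function(x, ...) {
  cat("Pan-metastasis enrichment analysis\n")
  cat(sprintf("  %d features tested; %d MBC-enriched (both q < threshold)\n",
              if (is.null(x$meta)) 0L else nrow(x$meta),
              if (is.null(x$enriched)) 0L else sum(x$enriched$direction == "enriched")))
  if (!is.null(x$enriched) && nrow(x$enriched)) {
    print(x$enriched, row.names = FALSE)
  }
  invisible(x)
}

# cohorts with >= 2 distinct metastatic site sets (site-resolvable)
site_resolvable_cohorts <- function(clinical) {
  met <- clinical[clinical$tumor_type == "metastasis" &
                    !is.na(clinical$site_set), ]
  n <- tapply(met$site_set, met$cohort, function(x) length(unique(x)))
  names(n)[!is.na(n) & n >= 2]
}

#' Metastatic-site-specific analysis with dual-criterion organotropism calls
#'
#' Stage 1 tests every (gene, site set) for enrichment of the site's MBC
#' samples against PBC (meta-analysis plus confirmatory cohort-adjusted
#' logistic regression; FDR over the whole gene x site family). Stage 2
#' tests, for stage-1-significant genes, the site against all other
#' metastatic sites by cohort-adjusted logistic regression on the
#' site-resolvable cohort subset (FDR within the stage-2 family). An
#' organotropism call is emitted when both q-values pass the threshold;
#' its direction comes from the sign of the stage-2 log-OR. Genes depleted
#' in MBC at stage 1 are reported but never called organotropic.
#'
#' @param data An [mbc_data()].
#' @param plan An [analysis_plan()].
#' @return List of class `"site_specific_result"`: `stage1` (meta rows per
#'   gene x site), `stage1_logistic`, `stage2` (regression rows), `calls`
#'   (data frame of organotropism calls), `sites_tested`.
#' @export
run_site_specific <- function(data, plan) {
  met <- data$clinical[data$clinical$tumor_type == "metastasis", ]
  site_n <- table(met$site_set[!is.na(met$site_set)])
  sites <- intersect(plan$site_sets, names(site_n)[site_n >= plan$min_site_n])
  skipped <- setdiff(plan$site_sets, sites)
  if (length(skipped)) {
    warning("site set(s) below minimum sample count skipped: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  if (!length(sites)) stop("no site set reaches the minimum sample count")
  grid <- expand.grid(gene = plan$genes, site = sites,
                      stringsAsFactors = FALSE)
  tabs <- lapply(seq_len(nrow(grid)), function(i) {
    build_contingency(data$mutations, data$clinical,
                      carrier_key(grid$gene[i]), "mbc_vs_pbc",
                      grouping = list(site_set = grid$site[i]),
                      panels = data$panels)
  })
  names(tabs) <- paste(grid$gene, grid$site, sep = "|")
  stage1 <- meta_family(tabs, het_alpha = plan$het_alpha)
  stage1$gene <- grid$gene
  stage1$site_set <- grid$site
  stage1$comparison <- "site_vs_pbc"
  stage1$family <- "site_stage1"
  s1_logistic <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    regression_row(contingency_logistic(tabs[[i]]),
                   names(tabs)[i], "site_vs_pbc", "site_stage1_logistic")
  }))
  ok <- !is.na(s1_logistic$p)
  s1_logistic$q[ok] <- bh_fdr(s1_logistic$p[ok])

  pass1 <- !is.na(stage1$q) & stage1$q < plan$q_threshold
  stage2_idx <- if (plan$stage2_all_genes) seq_len(nrow(grid)) else which(pass1)
  cohorts2 <- plan$site_cohorts
  if (is.null(cohorts2)) cohorts2 <- site_resolvable_cohorts(data$clinical)
  stage2 <- NULL
  if (length(stage2_idx)) {
    s2_tabs <- lapply(stage2_idx, function(i) {
      build_contingency(data$mutations, data$clinical,
                        carrier_key(grid$gene[i]), "site_vs_other_sites",
                        grouping = list(site_set = grid$site[i],
                                        cohorts = cohorts2),
                        panels = data$panels)
    })
    stage2 <- do.call(rbind, lapply(seq_along(stage2_idx), function(j) {
      i <- stage2_idx[j]
      row <- regression_row(contingency_logistic(s2_tabs[[j]]),
                            paste(grid$gene[i], grid$site[i], sep = "|"),
                            "site_vs_other_sites", "site_stage2")
      row$gene <- grid$gene[i]; row$site_set <- grid$site[i]
      row
    }))
    ok2 <- !is.na(stage2$p)
    stage2$q[ok2] <- bh_fdr(stage2$p[ok2])
  }

  calls <- data.frame(gene = character(), site_set = character(),
                      direction = character(), vs_pbc_or = numeric(),
                      vs_pbc_q = numeric(), vs_other_or = numeric(),
                      vs_other_q = numeric(), subtype_robust = logical(),
                      stringsAsFactors = FALSE)
  if (!is.null(stage2)) {
    for (j in seq_len(nrow(stage2))) {
      i1 <- which(stage1$gene == stage2$gene[j] &
                    stage1$site_set == stage2$site_set[j])
      if (!length(i1)) next
      ok_s1 <- !is.na(stage1$q[i1]) && stage1$q[i1] < plan$q_threshold &&
        stage1$log_or[i1] > 0   # depleted-in-MBC genes are never called
      ok_s2 <- !is.na(stage2$q[j]) && stage2$q[j] < plan$q_threshold
      if (ok_s1 && ok_s2) {
        calls <- rbind(calls, data.frame(
          gene = stage2$gene[j], site_set = stage2$site_set[j],
          direction = ifelse(stage2$estimate[j] > 0, "enriched", "depleted"),
          vs_pbc_or = stage1$or[i1], vs_pbc_q = stage1$q[i1],
          vs_other_or = stage2$or[j], vs_other_q = stage2$q[j],
          subtype_robust = NA, stringsAsFactors = FALSE))
      }
    }
  }
  rownames(calls) <- NULL
  structure(list(stage1 = stage1, stage1_logistic = s1_logistic,
                 stage2 = stage2, calls = calls, sites_tested = sites,
                 site_cohorts = cohorts2),
            class = "site_specific_result")
}

#' @export
print.site_specific_result <- function(x, ...) {
  cat(sprintf("Site-specific analysis: %d site sets tested, %d organotropism call(s)\n",
              length(x$sites_tested), nrow(x$calls)))
  if (nrow(x$calls)) print(x$calls, row.names = FALSE, digits = 3)
  invisible(x)
}

# stage-2 refit with an extra subtype covariate, grouped by cohort x
# carrier x covariate level
stage2_refit <- function(data, gene, site, cohorts, covariate) {
  met <- data$clinical[data$clinical$tumor_type == "metastasis" &
                         !is.na(data$clinical$site_set) &
                         data$clinical$cohort %in% cohorts, , drop = FALSE]
  cov_val <- met[[covariate]]
  met <- met[!is.na(cov_val), , drop = FALSE]
  if (nrow(met) == 0) return(NULL)
  carriers <- carrier_ids(data$mutations, carrier_key(gene))
  y <- as.numeric(met$site_set == site)
  carrier <- as.numeric(met$sample_id %in% carriers)
  covs <- data.frame(cov = met[[covariate]], stringsAsFactors = FALSE)
  if (length(unique(met$cohort)) > 1) covs$cohort <- met$cohort
  dropped_cov <- length(unique(covs$cov)) < 2
  fit <- logistic_fit(y, carrier, covariates = covs)
  fit$covariate_dropped <- dropped_cov
  fit
}

#' Subtype-adjusted confirmation of organotropism calls
#'
#' Refits each call's stage-2 site-vs-other regression twice, adding the
#' histology subtype and (separately) the receptor subtype as covariates.
#' A call is subtype-robust when the carrier term stays below the q
#' threshold in both refits (FDR within each refit family). Also reports
#' the two-sided Fisher's exact association between ILC histology and
#' carrier status among metastatic samples (the lobular-confounding
#' check for ovary/peritoneum-style calls).
#'
#' @param data An [mbc_data()].
#' @param site_result A [run_site_specific()] result.
#' @param plan The [analysis_plan()].
#' @return `site_result` with `calls$subtype_robust` filled in and a
#'   `subtype_refits` data frame attached (per call and covariate:
#'   estimate, p, q, covariate_dropped, plus `ilc_fisher_p`).
#' @export
run_subtype_adjusted <- function(data, site_result, plan) {
  calls <- site_result$calls
  if (nrow(calls) == 0) {
    site_result$subtype_refits <- data.frame()
    return(site_result)
  }
  refits <- list()
  for (covariate in c("histology", "receptor_subtype")) {
    rows <- do.call(rbind, lapply(seq_len(nrow(calls)), function(j) {
      fit <- stage2_refit(data, calls$gene[j], calls$site_set[j],
                          site_result$site_cohorts, covariate)
      if (is.null(fit)) {
        return(data.frame(gene = calls$gene[j], site_set = calls$site_set[j],
                          covariate = covariate, estimate = NA_real_,
                          p = NA_real_, q = NA_real_,
                          covariate_dropped = NA, stringsAsFactors = FALSE))
      }
      data.frame(gene = calls$gene[j], site_set = calls$site_set[j],
                 covariate = covariate, estimate = fit$carrier$log_or,
                 p = if (fit$separation_flag) NA_real_ else fit$carrier$p,
                 q = NA_real_, covariate_dropped = fit$covariate_dropped,
                 stringsAsFactors = FALSE)
    }))
    ok <- !is.na(rows$p)
    rows$q[ok] <- bh_fdr(rows$p[ok])
    refits[[covariate]] <- rows
  }
  refit_tab <- rbind_list(refits)
  # ILC association check per call (metastatic samples, site-resolvable)
  met <- data$clinical[data$clinical$tumor_type == "metastasis" &
                         data$clinical$cohort %in% site_result$site_cohorts &
                         !is.na(data$clinical$histology), , drop = FALSE]
  ilc_p <- vapply(seq_len(nrow(calls)), function(j) {
    carriers <- carrier_ids(data$mutations, carrier_key(calls$gene[j]))
    carr <- met$sample_id %in% carriers
    ilc <- met$histology == "ILC"
    fisher_exact_2x2(sum(carr & ilc), sum(!carr & ilc),
                     sum(carr & !ilc), sum(!carr & !ilc))
  }, numeric(1))
  for (j in seq_len(nrow(calls))) {
    qs <- refit_tab$q[refit_tab$gene == calls$gene[j] &
                        refit_tab$site_set == calls$site_set[j]]
    if (all(is.na(qs))) {
      calls$subtype_robust[j] <- NA
    } else {
      calls$subtype_robust[j] <- all(!is.na(qs) & qs < plan$q_threshold)
    }
  }
  calls$ilc_fisher_p <- ilc_p
  site_result$calls <- calls
  site_result$subtype_refits <- refit_tab
  site_result
}

#' Treatment-status contrasts for enriched genes
#'
#' Compares carrier frequency per gene between treatment-naive PBC and (i)
#' treatment-naive de novo MBC and (ii) post-treatment MBC, by
#' cohort-adjusted logistic regression (FDR within each contrast family).
#' Classifies each gene as `metastasis_associated` (significant in the de
#' novo contrast — enrichment precedes any treatment) or
#' `treatment_associated` (significant only post-treatment — consistent
#' with treatment selection).
#'
#' @param data An [mbc_data()].
#' @param plan An [analysis_plan()] (its `genes` are typically the
#'   MBC-enriched set).
#' @return List of class `"treatment_result"`: `contrasts` (regression
#'   rows per gene and contrast), `classification` (gene ->
#'   metastasis_associated / treatment_associated / neither).
#' @export
run_treatment_contrasts <- function(data, plan) {
  specs <- list(
    denovo = list(case = "denovo_metastasis", control = "naive_primary"),
    post = list(case = "post_treatment_metastasis", control = "naive_primary")
  )
  out <- list()
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    rows <- do.call(rbind, lapply(plan$genes, function(g) {
      tab <- build_contingency(data$mutations, data$clinical,
                               carrier_key(g), "treatment_contrast",
                               grouping = list(case_status = sp$case,
                                               control_status = sp$control),
                               panels = data$panels)
      row <- regression_row(contingency_logistic(tab), g,
                            paste0("treatment_", nm),
                            paste0("treatment_", nm))
      row$gene <- g
      row
    }))
    ok <- !is.na(rows$p)
    rows$q[ok] <- bh_fdr(rows$p[ok])
    out[[nm]] <- rows
  }
  contrasts <- rbind_list(out)
  sig <- function(nm, g) {
    r <- out[[nm]]
    any(r$gene == g & !is.na(r$q) & r$q < plan$q_threshold & r$estimate > 0)
  }
  classification <- data.frame(
    gene = plan$genes,
    class = vapply(plan$genes, function(g) {
      if (sig("denovo", g)) "metastasis_associated"
      else if (sig("post", g)) "treatment_associated"
      else "neither"
    }, character(1)),
    stringsAsFactors = FALSE
  )
  rownames(classification) <- NULL
  structure(list(contrasts = contrasts, classification = classification),
            class = "treatment_result")
}

#' @export
print.treatment_result <- function(x, ...) {
  cat("Treatment-status contrasts\n")
  print(x$classification, row.names = FALSE)
  invisible(x)
}
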