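# Sample eligibility, variant/CNA QC, outlier exclusion, panel-intersection
# gene selection, and site/subtype classification.

#' QC configuration
#'
#' Bundles the tunable quality-control thresholds. Defaults follow the
#' analysis conventions of multi-cohort panel studies: strict-inequality
#' depth and VAF cutoffs (a record at exactly the threshold is kept), a
#' functional-consequence allowlist, a cohort-wise Tukey outlier rule, the
#' panel-concurrence fraction, and the high-level CNA call set.
#'
#' @param min_depth Minimum sequencing depth; records with depth <
#'   `min_depth` are removed (missing depth passes). Default 10.
#' @param min_vaf Minimum variant allele frequency; records with vaf <
#'   `min_vaf` are removed (missing vaf passes). Default 0.01.
#' @param variant_class_allowlist Retained `Variant_Classification` values.
#' @param outlier_rule `"iqr"` (count > Q3 + k * IQR within cohort) or
#'   `"fixed"` (count > cutoff).
#' @param outlier_k Multiplier k for the IQR rule. Default 3.
#' @param outlier_cutoff Absolute cutoff for the fixed rule.
#' @param panel_min_fraction Minimum fraction of panels that must target a
#'   gene for it to enter the concurrent gene set. Default 7/11.
#' @param cna_keep_levels CNA call levels retained by [filter_cna()].
#'   Default c(-2, 2) (deep deletion, high-level amplification).
#' @return A list of class `"qc_config"`.
#' @export
qc_config <- function(min_depth = 10, min_vaf = 0.01,
                      variant_class_allowlist = c(
                        "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del",
                        "In_Frame_Ins", "Missense_Mutation",
                        "Nonsense_Mutation", "Nonstop_Mutation",
                        "Splice_Region", "Splice_Site",
                        "Translation_Start_Site"),
                      outlier_rule = c("iqr", "fixed"), outlier_k = 3,
                      outlier_cutoff = Inf, panel_min_fraction = 7 / 11,
                      cna_keep_levels = c(-2, 2)) {
  outlier_rule <- match.arg(outlier_rule)
  stopifnot(min_vaf >= 0, min_vaf <= 1, length(variant_class_allowlist) > 0,
            panel_min_fraction > 0, panel_min_fraction <= 1)
  structure(list(min_depth = min_depth, min_vaf = min_vaf,
                 variant_class_allowlist = variant_class_allowlist,
                 outlier_rule = outlier_rule, outlier_k = outlier_k,
                 outlier_cutoff = outlier_cutoff,
                 panel_min_fraction = panel_min_fraction,
                 cna_keep_levels = cna_keep_levels),
            class = "qc_config")
}

#' Select eligible samples
#'
#' Applies the cohort sample-eligibility rules. In `single_site` mode
#' (default) the analysis set excludes male samples, samples of patients
#' biopsied at more than one metastatic site (to avoid redundant counting),
#' and samples sequenced on hotspot-only panels (`full_exonic = FALSE`).
#' In `multi_site` mode exactly the patients with samples from two or more
#' metastatic sites are kept (the multi-region comparison set).
#'
#' @param samples Clinical sample data frame (see [read_clinical()]).
#' @param panels Panel definition data frame (see [read_panels()]); used to
#'   resolve `full_exonic`. Optional — when NULL all panels are assumed
#'   full-exonic.
#' @param mode `"single_site"` or `"multi_site"`.
#' @return The eligible subset of `samples`, with attribute
#'   `"exclusion_log"` (data frame `sample_id, reason`).
#' @export
select_samples <- function(samples, panels = NULL,
                           mode = c("single_site", "multi_site")) {
  mode <- match.arg(mode)
  reason <- rep(NA_character_, nrow(samples))
  met <- samples$tumor_type == "metastasis"
  # distinct metastatic biopsy sites per patient
  met_sites <- unique(samples[met, c("patient_id", "biopsy_site")])
  n_sites <- table(met_sites$patient_id)
  multi <- names(n_sites)[n_sites >= 2]
  if (mode == "single_site") {
    is_male <- !is.na(samples$sex) & samples$sex == "male"
    reason[is_male] <- "male"
    multi_hit <- is.na(reason) & samples$patient_id %in% multi & met
    reason[multi_hit] <- "multiple metastatic sites"
    if (!is.null(panels) && "full_exonic" %in% names(panels)) {
      fe <- tapply(panels$full_exonic, panels$panel_id, function(x) all(x))
      hotspot_panel <- is.na(reason) &
        samples$panel_id %in% names(fe)[!fe]
      reason[hotspot_panel] <- "hotspot-only panel"
      unresolved <- is.na(reason) & !(samples$panel_id %in% names(fe))
      reason[unresolved] <- "unresolvable panel_id"
    }
  } else {
    reason[!(samples$patient_id %in% multi & met)] <- "not a multi-site metastatic sample"
  }
  keep <- is.na(reason)
  out <- samples[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusion_log") <- data.frame(
    sample_id = samples$sample_id[!keep], reason = reason[!keep],
    stringsAsFactors = FALSE)
  out
}

#' Filter variant records by QC rules
#'
#' Removes, in this fixed order (so removal counts are reproducible):
#' within-sample duplicates (same sample, chrom, positions, alleles; first
#' occurrence kept), records with depth below `min_depth`, records with VAF
#' below `min_vaf`, and records whose classification is outside the
#' functional allowlist. Missing depth or VAF never triggers removal —
#' several cohorts lack those fields. Retained records keep their input
#' order, making the operation idempotent.
#'
#' @param records Mutation record data frame.
#' @param config A [qc_config()].
#' @return Retained records, with attribute `"qc_summary"`: data frame
#'   `step, reason, count` whose counts plus the retained count equal the
#'   input count.
#' @export
filter_variants <- function(records, config = qc_config()) {
  n0 <- nrow(records)
  key <- paste(records$sample_id, records$chrom, records$pos_start,
               records$pos_end, records$ref_allele, records$alt_allele,
               sep = "\r")
  dup <- duplicated(key)
  r1 <- records[!dup, , drop = FALSE]
  low_depth <- !is.na(r1$depth) & r1$depth < config$min_depth
  r2 <- r1[!low_depth, , drop = FALSE]
  low_vaf <- !is.na(r2$vaf) & r2$vaf < config$min_vaf
  r3 <- r2[!low_vaf, , drop = FALSE]
  bad_class <- !(r3$variant_classification %in% config$variant_class_allowlist)
  out <- r3[!bad_class, , drop = FALSE]
  rownames(out) <- NULL
  summary <- data.frame(
    step = "filter_variants",
    reason = c("duplicate", "low_depth", "low_vaf", "class_not_allowlisted",
               "retained"),
    count = c(sum(dup), sum(low_depth), sum(low_vaf), sum(bad_class),
              nrow(out)),
    stringsAsFactors = FALSE
  )
  stopifnot(sum(summary$count) == n0)
  attr(out, "qc_summary") <- summary
  out
}

#' Flag hypermutated outlier samples
#'
#' Within each cohort, computes per-sample variant counts over the samples
#' carrying at least one retained variant and flags samples whose count
#' exceeds Q3 + k * IQR (quartiles by linear interpolation,
#' `stats::quantile` type 7; the IQR is floored at 1 mutation because the
#' counts are integers and a degenerate zero spread would otherwise flag
#' any sample above Q3), or a fixed cutoff under the `"fixed"` rule.
#' Samples with zero retained variants are outside the count distribution
#' (they cannot be hypermutated). Cohorts with fewer than four counted
#' samples are skipped with a warning (quartiles would be meaningless).
#'
#' @param records Mutation record data frame (after [filter_variants()]).
#' @param config A [qc_config()].
#' @return Character vector of outlier sample ids.
#' @export
flag_outlier_samples <- function(records, config = qc_config()) {
  counts <- as.data.frame(table(sample_id = records$sample_id),
                          stringsAsFactors = FALSE)
  names(counts)[2] <- "n"
  cohort_of <- records$cohort[match(counts$sample_id, records$sample_id)]
  counts$cohort <- cohort_of
  out <- character(0)
  for (ch in unique(counts$cohort)) {
    x <- counts[counts$cohort == ch, ]
    if (nrow(x) < 4) {
      warning("cohort ", ch, " has <4 samples; outlier rule skipped",
              call. = FALSE)
      next
    }
    bound <- if (config$outlier_rule == "iqr") {
      qs <- stats::quantile(x$n, c(0.25, 0.75), type = 7, names = FALSE)
      # counts are integers: floor the spread at one mutation so a
      # degenerate IQR of 0 (half the cohort at the same count) cannot
      # declare every sample above Q3 hypermutated
      qs[2] + config$outlier_k * max(qs[2] - qs[1], 1)
    } else {
      config$outlier_cutoff
    }
    out <- c(out, x$sample_id[x$n > bound])
  }
  sort(out)
}

#' Select genes concurrently targeted by enough panels
#'
#' Returns the genes present in at least `ceiling(min_fraction * n_panels)`
#' of the panels, in deterministic sorted order. Raising `min_fraction`
#' never adds genes.
#'
#' @param panels Panel definition data frame (`panel_id, gene`).
#' @param min_fraction Minimum fraction of panels (default 7/11).
#' @return Sorted character vector of gene symbols.
#' @export
select_concurrent_genes <- function(panels, min_fraction = 7 / 11) {
  if (is.null(panels) || nrow(panels) == 0) stop("no panels supplied")
  n_panels <- length(unique(panels$panel_id))
  # epsilon guards exact fractions against floating error (7/11 * 11 == 7)
  threshold <- ceiling(min_fraction * n_panels - 1e-8)
  tab <- table(unique(panels[, c("panel_id", "gene")])$gene)
  sort(names(tab)[tab >= threshold])
}

#' Filter CNA records to high-level calls
#'
#' Keeps only calls whose level is in `cna_keep_levels` (default deep
#' deletion -2 and high-level amplification +2); single-copy gains/losses
#' and the -1.5 intermediate level are removed.
#'
#' @param cna_records CNA record data frame (see [read_cna()]).
#' @param config A [qc_config()].
#' @return Retained records with attribute `"qc_summary"`.
#' @export
filter_cna <- function(cna_records, config = qc_config()) {
  keep <- cna_records$level %in% config$cna_keep_levels
  out <- cna_records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "qc_summary") <- data.frame(
    step = "filter_cna", reason = c("low_level_call", "retained"),
    count = c(sum(!keep), sum(keep)), stringsAsFactors = FALSE)
  out
}

#' Default metastatic-site-set matchers
#'
#' Ordered, case-insensitive regular-expression matchers resolving free-text
#' biopsy-site labels to the 15 metastatic site sets: `pan` (all),
#' `local` vs `distant`, and 12 specific distant sets (11 named organs plus
#' the `other_distant` catch-all). Local-recurrence matchers come first so
#' that e.g. "Regional lymph nodes" resolves to local recurrence, not the
#' distant lymph-node set.
#'
#' @return Data frame `pattern, site_set` (site_set `"local"` for
#'   local-recurrence matchers).
#' @export
default_site_set_map <- function() {
  data.frame(
    pattern = c(
      "local recurrence|ipsilateral breast|contralateral breast|regional lymph",
      "liver", "lymph", "bone", "chest wall|thorax|thoracic|rib",
      "skin", "lung", "soft", "pleura", "brain|cerebr|cns",
      "ovary|ovarian", "periton"
    ),
    site_set = c("local", "liver", "lymph_nodes", "bone",
                 "chest_wall_thorax", "skin", "lung", "soft", "pleura",
                 "brain", "ovary", "peritoneum"),
    stringsAsFactors = FALSE
  )
}

specific_site_sets <- c("liver", "lymph_nodes", "bone", "chest_wall_thorax",
                        "skin", "lung", "soft", "pleura", "brain", "ovary",
                        "peritoneum", "other_distant")

#' Classify metastatic samples into site sets
#'
#' Maps each metastatic sample's biopsy-site label to its site-set labels:
#' every metastatic sample is `pan`, then either `local` (local-recurrence
#' matchers) or `distant` plus exactly one specific distant set. Unmatched
#' or empty labels fall back to `other_distant` with a warning.
#'
#' @param samples Clinical data frame (metastatic rows are classified;
#'   primary rows get NA).
#' @param site_map Matcher table as in [default_site_set_map()].
#' @return `samples` with added columns `site_class` (`"local"`/
#'   `"distant"`) and `site_set` (specific set, NA for local).
#' @export
classify_site_set <- function(samples, site_map = default_site_set_map()) {
  met <- samples$tumor_type == "metastasis"
  site <- rep(NA_character_, nrow(samples))
  labels <- tolower(samples$biopsy_site)
  unmatched_any <- FALSE
  for (i in seq_len(nrow(site_map))) {
    hit <- met & is.na(site) & grepl(site_map$pattern[i], labels,
                                     ignore.case = TRUE)
    site[hit] <- site_map$site_set[i]
  }
  fallback <- met & is.na(site)
  if (any(fallback)) {
    warning(sum(fallback),
            " metastatic sample(s) with unmatched biopsy site -> other_distant",
            call. = FALSE)
    site[fallback] <- "other_distant"
  }
  samples$site_class <- ifelse(!met, NA_character_,
                               ifelse(site == "local", "local", "distant"))
  samples$site_set <- ifelse(!met | site == "local", NA_character_, site)
  samples
}

#' Receptor and histology subtype classification
#'
#' Derives the receptor subtype from (hr_status, her2_status) and keeps the
#' histology subtype. A sample annotated only as HER2-positive (HR status
#' missing) cannot be placed in a single receptor subtype and is a member
#' of both HER2-positive subtypes, so membership is returned as logical
#' columns rather than one factor: `st_hr_pos_her2_neg, st_hr_pos_her2_pos,
#' st_hr_neg_her2_pos, st_triple_neg`. The single-label column
#' `receptor_subtype` is NA for such samples (and for samples with missing
#' status).
#'
#' @param samples Clinical data frame.
#' @return `samples` with the membership columns and `receptor_subtype`
#'   added.
#' @export
classify_subtype <- function(samples) {
  hr <- samples$hr_status
  her2 <- samples$her2_status
  lab <- rep(NA_character_, nrow(samples))
  lab[!is.na(hr) & !is.na(her2) & hr == "pos" & her2 == "neg"] <- "HR+/HER2-"
  lab[!is.na(hr) & !is.na(her2) & hr == "pos" & her2 == "pos"] <- "HR+/HER2+"
  lab[!is.na(hr) & !is.na(her2) & hr == "neg" & her2 == "pos"] <- "HR-/HER2+"
  lab[!is.na(hr) & !is.na(her2) & hr == "neg" & her2 == "neg"] <- "Triple-negative"
  her2_only <- is.na(hr) & !is.na(her2) & her2 == "pos"
  samples$receptor_subtype <- lab
  samples$st_hr_pos_her2_neg <- !is.na(lab) & lab == "HR+/HER2-"
  samples$st_hr_pos_her2_pos <- (!is.na(lab) & lab == "HR+/HER2+") | her2_only
  samples$st_hr_neg_her2_pos <- (!is.na(lab) & lab == "HR-/HER2+") | her2_only
  samples$st_triple_neg <- !is.na(lab) & lab == "Triple-negative"
  samples
}

#' Apply the full variant QC cascade
#'
#' Runs [filter_variants()] then [flag_outlier_samples()] and removes all
#' variants of flagged samples, returning the retained records plus a
#' combined accounting summary (per-reason removal counts + retained =
#' input).
#'
#' @param records Mutation record data frame.
#' @param config A [qc_config()].
#' @return Retained records with attributes `"qc_summary"` and
#'   `"outlier_samples"`.
#' @export
apply_qc <- function(records, config = qc_config()) {
  n0 <- nrow(records)
  r1 <- filter_variants(records, config)
  s1 <- attr(r1, "qc_summary")
  outliers <- flag_outlier_samples(r1, config)
  in_outlier <- r1$sample_id %in% outliers
  out <- r1[!in_outlier, , drop = FALSE]
  rownames(out) <- NULL
  summary <- rbind(
    s1[s1$reason != "retained", ],
    data.frame(step = "apply_qc", reason = c("outlier_sample", "retained"),
               count = c(sum(in_outlier), nrow(out)),
               stringsAsFactors = FALSE)
  )
  rownames(summary) <- NULL
  stopifnot(sum(summary$count) == n0)
  attr(out, "qc_summary") <- summary
  attr(out, "outlier_samples") <- outliers
  out
}
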