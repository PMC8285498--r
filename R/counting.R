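# Carrier-status resolution and construction of cohort-stratified 2x2
# carrier tables for every comparison the analyses perform.

# rbind a list of data frames; NULL for an empty list (avoids the
# rbind(make.row.names=) footgun on empty input)
rbind_list <- function(x) {
  x <- Filter(Negate(is.null), x)
  if (length(x) == 0) return(NULL)
  do.call(rbind, c(x, list(make.row.names = FALSE)))
}

#' Construct a carrier key
#'
#' A carrier key identifies the feature being counted: a gene (any
#' allow-listed SNV/Indel, or a CNA direction) or a specific variant (a
#' protein change such as `"p.D538G"`, or the pooled truncating class
#' `"Trunc"`). Variant keys are only valid for SNV/Indel counting.
#'
#' @param feature Gene symbol.
#' @param mutation_type `"snv_indel"`, `"amplification"`, or `"deletion"`.
#' @param protein_change Optional HGVSp-short protein change or `"Trunc"`.
#' @return A list of class `"carrier_key"`.
#' @export
carrier_key <- function(feature, mutation_type = c("snv_indel",
                                                   "amplification",
                                                   "deletion"),
                        protein_change = NULL) {
  mutation_type <- match.arg(mutation_type)
  if (!is.null(protein_change) && mutation_type != "snv_indel") {
    stop("variant keys are only valid for snv_indel")
  }
  structure(list(feature = feature, mutation_type = mutation_type,
                 protein_change = protein_change),
            class = "carrier_key")
}

#' @export
format.carrier_key <- function(x, ...) {
  base <- if (x$mutation_type == "snv_indel") x$feature else
    paste0(x$feature, ":", x$mutation_type)
  if (!is.null(x$protein_change)) paste(base, x$protein_change) else base
}

#' @export
print.carrier_key <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

# classifications counted as truncating under the default pattern rules
truncating_classes <- function(include_splice_region = FALSE) {
  cls <- c("Nonsense_Mutation", "Splice_Site", "Frame_Shift_Del",
           "Frame_Shift_Ins")
  if (include_splice_region) cls <- c(cls, "Splice_Region")
  cls
}

# which sample ids carry the keyed alteration (records already QC-filtered;
# for CNA keys pass the filtered CNA table)
carrier_ids <- function(records, key) {
  if (key$mutation_type == "snv_indel") {
    hit <- records$gene == key$feature
    if (!is.null(key$protein_change)) {
      if (identical(key$protein_change, "Trunc")) {
        hit <- hit & records$variant_classification %in% truncating_classes()
      } else {
        hit <- hit & records$protein_change == key$protein_change
      }
    }
  } else {
    lvl <- if (key$mutation_type == "amplification") 2 else -2
    hit <- records$gene == key$feature & records$level == lvl
  }
  unique(records$sample_id[hit])
}

#' Carrier status of one sample for a keyed feature
#'
#' TRUE iff the sample has at least one qualifying record for the key:
#' any allow-listed SNV/Indel in the gene, a +2/-2 CNA call, a matching
#' protein change, or a truncating-class record for `"Trunc"` keys.
#' Carrier status is binary at the sample level; within-sample multiplicity
#' is ignored.
#'
#' @param records QC-filtered mutation (or CNA) record data frame.
#' @param sample_id Sample identifier.
#' @param key A [carrier_key()].
#' @return Logical scalar.
#' @export
carrier_status <- function(records, sample_id, key) {
  sample_id %in% carrier_ids(records, key)
}

# resolve each sample to "case"/"control"/NA for a named comparison
resolve_groups <- function(samples, comparison, grouping = list()) {
  grp <- rep(NA_character_, nrow(samples))
  if (comparison == "mbc_vs_pbc") {
    grp[samples$tumor_type == "metastasis"] <- "case"
    grp[samples$tumor_type == "primary"] <- "control"
    if (!is.null(grouping$site_set)) {
      # one site set vs PBC: cases restricted to that set
      in_site <- samples$tumor_type == "metastasis" &
        !is.na(samples$site_set) & samples$site_set == grouping$site_set
      grp[samples$tumor_type == "metastasis" & !in_site] <- NA_character_
    }
  } else if (comparison == "site_vs_other_sites") {
    if (is.null(grouping$site_set)) stop("site_vs_other_sites needs grouping$site_set")
    met <- samples$tumor_type == "metastasis" & !is.na(samples$site_set)
    grp[met & samples$site_set == grouping$site_set] <- "case"
    grp[met & samples$site_set != grouping$site_set] <- "control"
  } else if (comparison == "treatment_contrast") {
    if (is.null(grouping$case_status) || is.null(grouping$control_status)) {
      stop("treatment_contrast needs grouping$case_status and grouping$control_status")
    }
    grp[!is.na(samples$treatment_status) &
          samples$treatment_status == grouping$case_status] <- "case"
    grp[!is.na(samples$treatment_status) &
          samples$treatment_status == grouping$control_status] <- "control"
  } else {
    stop("unknown comparison: ", comparison)
  }
  if (!is.null(grouping$cohorts)) {
    grp[!(samples$cohort %in% grouping$cohorts)] <- NA_character_
  }
  grp
}

#' Build a cohort-stratified 2x2 carrier table
#'
#' Resolves each eligible sample to case/control for the requested
#' comparison, restricts to samples assessable for the keyed feature (the
#' gene must be on the sample's panel; CNA keys additionally require the
#' cohort to have CNA data), and tabulates carriers per cohort. One stratum
#' is emitted per cohort contributing at least one case and one control
#' sample; strata are sorted by cohort label, and each sample lands in
#' exactly one cell.
#'
#' @param records QC-filtered mutation records (or filtered CNA records for
#'   amplification/deletion keys).
#' @param samples Eligible clinical data frame (after [select_samples()];
#'   with `site_set` columns from [classify_site_set()] where the
#'   comparison needs them).
#' @param key A [carrier_key()].
#' @param comparison `"mbc_vs_pbc"`, `"site_vs_other_sites"`, or
#'   `"treatment_contrast"`.
#' @param grouping List of comparison arguments: `site_set`,
#'   `case_status`/`control_status` (treatment levels), `cohorts` (cohort
#'   subset restriction).
#' @param panels Optional panel table; when given, samples whose panel does
#'   not target the gene are excluded (not counted as non-carriers).
#' @return Data frame of class `"stratified_contingency"` with columns
#'   `cohort, a, b, c, d` and attributes `"feature"`, `"comparison"`,
#'   `"untestable"`.
#' @export
build_contingency <- function(records, samples, key, comparison,
                              grouping = list(), panels = NULL) {
  grp <- resolve_groups(samples, comparison, grouping)
  assessable <- rep(TRUE, nrow(samples))
  if (!is.null(panels)) {
    on_panel <- unique(panels$panel_id[panels$gene == key$feature])
    assessable <- samples$panel_id %in% on_panel
  }
  if (key$mutation_type != "snv_indel") {
    cna_cohorts <- unique(records$cohort)
    assessable <- assessable & samples$cohort %in% cna_cohorts
  }
  use <- !is.na(grp) & assessable
  carriers <- carrier_ids(records, key)
  is_carrier <- samples$sample_id %in% carriers
  cohorts <- sort(unique(samples$cohort[use]))
  rows <- lapply(cohorts, function(ch) {
    i <- use & samples$cohort == ch
    data.frame(cohort = ch,
               a = sum(i & grp == "case" & is_carrier),
               b = sum(i & grp == "case" & !is_carrier),
               c = sum(i & grp == "control" & is_carrier),
               d = sum(i & grp == "control" & !is_carrier),
               stringsAsFactors = FALSE)
  })
  tab <- rbind_list(rows)
  if (is.null(tab)) tab <- data.frame(cohort = character(), a = integer(),
                                      b = integer(), c = integer(),
                                      d = integer(), stringsAsFactors = FALSE)
  # a stratum needs both arms; both-zero-carrier strata are retained (they
  # are dropped from pooling downstream, but reported)
  tab <- tab[(tab$a + tab$b) > 0 & (tab$c + tab$d) > 0, , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab,
            feature = carrier_key_label(key),
            comparison = comparison,
            untestable = nrow(tab) == 0 || all(tab$a + tab$c == 0),
            class = c("stratified_contingency", "data.frame"))
}

carrier_key_label <- function(key) format(key)

#' Collapse a stratified contingency over cohorts
#'
#' @param contingency A [build_contingency()] result.
#' @return Named numeric vector `a, b, c, d` of pooled cell totals.
#' @export
collapse_contingency <- function(contingency) {
  c(a = sum(contingency$a), b = sum(contingency$b),
    c = sum(contingency$c), d = sum(contingency$d))
}

#' Per-patient carrier table for multi-site patients
#'
#' For patients with metastatic samples from two or more sites, tabulates
#' carrier status per gene at each biopsied site, and summarizes concordant
#' and discordant site pairs per gene.
#'
#' @param records QC-filtered mutation records.
#' @param samples Clinical data frame in multi-site selection mode (see
#'   [select_samples()]), with `site_set` resolved.
#' @param genes Character vector of genes to tabulate.
#' @return Data frame `patient_id, site_set, sample_id, gene, carrier` with
#'   attribute `"pair_summary"` (per gene: concordant / discordant site-pair
#'   counts). Zero multi-site patients yield an empty table.
#' @export
multi_site_table <- function(records, samples, genes) {
  met <- samples[samples$tumor_type == "metastasis" &
                   !is.na(samples$site_set), , drop = FALSE]
  n_sites <- tapply(met$site_set, met$patient_id,
                    function(x) length(unique(x)))
  keep_pat <- names(n_sites)[n_sites >= 2]
  met <- met[met$patient_id %in% keep_pat, , drop = FALSE]
  if (nrow(met) == 0 || length(genes) == 0) {
    out <- data.frame(patient_id = character(), site_set = character(),
                      sample_id = character(), gene = character(),
                      carrier = logical(), stringsAsFactors = FALSE)
    attr(out, "pair_summary") <- data.frame(
      gene = character(), concordant = integer(), discordant = integer(),
      stringsAsFactors = FALSE)
    return(out)
  }
  rows <- expand.grid(sample_id = met$sample_id, gene = genes,
                      stringsAsFactors = FALSE)
  rows$patient_id <- met$patient_id[match(rows$sample_id, met$sample_id)]
  rows$site_set <- met$site_set[match(rows$sample_id, met$sample_id)]
  rows$carrier <- mapply(function(s, g) {
    any(records$sample_id == s & records$gene == g)
  }, rows$sample_id, rows$gene)
  out <- rows[, c("patient_id", "site_set", "sample_id", "gene", "carrier")]
  out <- out[order(out$patient_id, out$gene, out$site_set), ]
  rownames(out) <- NULL
  pair_summary <- do.call(rbind, lapply(genes, function(g) {
    gg <- out[out$gene == g, ]
    conc <- 0L; disc <- 0L
    for (p in unique(gg$patient_id)) {
      st <- gg$carrier[gg$patient_id == p]
      if (length(st) < 2) next
      pairs <- utils::combn(st, 2)
      conc <- conc + sum(pairs[1, ] == pairs[2, ])
      disc <- disc + sum(pairs[1, ] != pairs[2, ])
    }
    data.frame(gene = g, concordant = conc, discordant = disc,
               stringsAsFactors = FALSE)
  }))
  attr(out, "pair_summary") <- pair_summary
  out
}
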