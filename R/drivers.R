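# Knowledge-guided candidate-driver-mutation calling: gene role
# classification (oncogene / tumor suppressor), hotspot and truncation
# pattern matching, integer functional-impact scoring with the >= 5
# eligibility threshold, and per-variant enrichment / site-preference
# tests.

#' Classify a gene's cancer role
#'
#' Looks a gene up in a role table (e.g. derived from a cancer gene
#' census). Genes absent from the table get role `"none"` and are
#' discarded from driver analysis.
#'
#' @param gene Gene symbol(s).
#' @param role_table Data frame `gene, role` with role in
#'   `c("oncogene", "tsg", "both")`.
#' @return Character vector of roles (`"none"` when unannotated).
#' @export
classify_role <- function(gene, role_table) {
  stopifnot(all(c("gene", "role") %in% names(role_table)))
  if (anyDuplicated(role_table$gene)) stop("one role per gene required")
  role <- role_table$role[match(gene, role_table$gene)]
  role[is.na(role)] <- "none"
  role
}

#' Is a variant classification truncating?
#'
#' Truncating means nonsense, splice-site, or frameshift
#' insertion/deletion. Splice-region variants are not counted by default
#' (they pass QC but do not satisfy the tumor-suppressor truncation
#' pattern); set `include_splice_region = TRUE` to widen the definition.
#'
#' @param variant_classification MAF classification string(s).
#' @param include_splice_region Count `Splice_Region` as truncating?
#' @return Logical vector.
#' @export
is_truncating <- function(variant_classification,
                          include_splice_region = FALSE) {
  variant_classification %in% truncating_classes(include_splice_region)
}

# parse the protein position out of an HGVSp-short string (p.D538G,
# p.Q120*, p.E545_K550del ...); NA when unparseable
parse_protein_position <- function(protein_change) {
  m <- regmatches(protein_change,
                  regexpr("^p\\.[A-Za-z*]{1,3}([0-9]+)", protein_change))
  pos <- rep(NA_integer_, length(protein_change))
  has <- lengths(regmatches(protein_change,
                            gregexpr("^p\\.[A-Za-z*]{1,3}[0-9]+",
                                     protein_change))) > 0
  pos[has] <- as.integer(sub("^p\\.[A-Za-z*]{1,3}", "",
                             regmatches(protein_change,
                                        regexpr("^p\\.[A-Za-z*]{1,3}[0-9]+",
                                                protein_change))))
  pos
}

#' Is a record a hotspot mutation?
#'
#' TRUE when the protein position parsed from the record's HGVSp-short
#' protein change matches a hotspot entry for the gene. Matching is by
#' position only (any substitution at a recurrent position counts).
#' Truncating records never match (hotspot and truncating patterns are
#' mutually exclusive); unparseable protein changes return FALSE.
#'
#' @param records Mutation record data frame (columns `gene,
#'   protein_change, variant_classification`).
#' @param hotspot_table Data frame `gene, protein_position`.
#' @return Logical vector, one per record.
#' @export
is_hotspot <- function(records, hotspot_table) {
  stopifnot(all(c("gene", "protein_position") %in% names(hotspot_table)))
  pos <- parse_protein_position(records$protein_change)
  key <- paste(records$gene, pos)
  hs <- paste(hotspot_table$gene, hotspot_table$protein_position)
  out <- !is.na(pos) & key %in% hs &
    !is_truncating(records$variant_classification)
  out
}

#' Functional-impact score of a candidate driver mutation
#'
#' Integer eligibility score. For oncogene missense variants the score
#' sums per-tool points from three functional annotation tools
#' (high/medium impact = 2, low = 1, neutral or missing = 0 per tool) plus
#' 1 if the variant lies at a hotspot position. For tumor-suppressor
#' truncating variants the truncation itself scores 4, plus literature
#' evidence points (strong = 2, weak = 1, none = 0). The eligibility
#' threshold used downstream is score >= 5. All points are overridable.
#'
#' @param variant_key Variant key string (`"GENE p.X123Y"` or
#'   `"GENE Trunc"`).
#' @param pattern `"hotspot"` (oncogene missense) or `"truncating"`
#'   (tumor-suppressor truncation).
#' @param annotations Data frame `variant_key, tool, impact` with impact in
#'   `c("high", "medium", "low", "neutral")` for missense tools, and/or
#'   `variant_key, tsg_evidence` rows with evidence in
#'   `c("strong", "weak", "none")`. May be empty.
#' @param is_hotspot Logical: does the variant lie at a hotspot position?
#'   (+1 for the hotspot pattern.)
#' @param points Named list of point values (defaults as described).
#' @return Non-negative integer score.
#' @export
func_score <- function(variant_key, pattern, annotations,
                       is_hotspot = FALSE,
                       points = list(high = 2, medium = 2, low = 1,
                                     neutral = 0, hotspot_bonus = 1,
                                     truncation_base = 4, strong = 2,
                                     weak = 1, none = 0)) {
  if (pattern == "truncating") {
    score <- points$truncation_base
    if (!is.null(annotations) && nrow(annotations) &&
        "tsg_evidence" %in% names(annotations)) {
      ev <- annotations$tsg_evidence[annotations$variant_key == variant_key]
      ev <- ev[!is.na(ev)]
      if (length(ev)) {
        score <- score + max(vapply(ev, function(e) {
          as.numeric(points[[e]] %||% 0)
        }, numeric(1)))
      }
    }
    return(as.integer(score))
  }
  score <- 0
  if (!is.null(annotations) && nrow(annotations) &&
      all(c("tool", "impact") %in% names(annotations))) {
    ann <- annotations[annotations$variant_key == variant_key &
                         !is.na(annotations$impact), , drop = FALSE]
    if (nrow(ann)) {
      score <- sum(vapply(ann$impact, function(im) {
        as.numeric(points[[im]] %||% 0)
      }, numeric(1)))
    }
  }
  if (is_hotspot) score <- score + points$hotspot_bonus
  as.integer(score)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Call candidate driver mutations
#'
#' Applies the pattern-based driver strategy to the MBC-enriched gene set:
#' oncogenes contribute hotspot missense variants collapsed by amino-acid
#' change, tumor suppressors contribute truncating variants collapsed per
#' gene under the `"Trunc"` key, and dual-role genes contribute both
#' patterns. Each variant key is scored ([func_score()]); eligible keys
#' (score >= 5 and more than `carrier_min` MBC carriers) are tested for
#' MBC-vs-PBC enrichment by stratified meta-analysis and for
#' site preference by cohort-adjusted logistic regression per site set,
#' with FDR within the candidate family.
#'
#' @param data An [mbc_data()].
#' @param role_table Data frame `gene, role`.
#' @param hotspots Data frame `gene, protein_position`.
#' @param annotations Functional annotation table (see [func_score()]); may
#'   be NULL.
#' @param plan An [analysis_plan()].
#' @param genes Genes to evaluate (normally the stage-1 MBC-enriched
#'   list).
#' @param carrier_min Carrier-count threshold: keys need strictly more than
#'   this many MBC carriers (default 2, i.e. at least 3; set 1 for the
#'   laxer >= 2 reading).
#' @return Data frame of class `"driver_calls"`: one row per variant key
#'   with `variant_key, gene, role, pattern, func_score, carriers,
#'   eligible, or, ci_low, ci_high, p, q` (enrichment vs PBC for eligible
#'   keys) and attribute `"site_preference"` (regression rows per eligible
#'   key x site).
#' @export
call_driver_mutations <- function(data, role_table, hotspots,
                                  annotations = NULL, plan, genes,
                                  carrier_min = 2) {
  roles <- classify_role(genes, role_table)
  keep <- roles != "none"
  genes <- genes[keep]; roles <- roles[keep]
  mbc_ids <- data$clinical$sample_id[data$clinical$tumor_type == "metastasis"]
  recs <- data$mutations
  rows <- list()
  for (i in seq_along(genes)) {
    g <- genes[i]; role <- roles[i]
    grecs <- recs[recs$gene == g, , drop = FALSE]
    if (role %in% c("oncogene", "both")) {
      hot <- is_hotspot(grecs, hotspots) &
        grecs$variant_classification == "Missense_Mutation"
      for (pc in unique(grecs$protein_change[hot])) {
        key <- paste(g, pc)
        carriers <- unique(grecs$sample_id[hot & grecs$protein_change == pc &
                                             grecs$sample_id %in% mbc_ids])
        rows[[key]] <- data.frame(
          variant_key = key, gene = g, role = role, pattern = "hotspot",
          func_score = func_score(key, "hotspot", annotations,
                                  is_hotspot = TRUE),
          carriers = length(carriers), protein_change = pc,
          stringsAsFactors = FALSE)
      }
    }
    if (role %in% c("tsg", "both")) {
      tr <- is_truncating(grecs$variant_classification)
      if (any(tr)) {
        key <- paste(g, "Trunc")
        carriers <- unique(grecs$sample_id[tr & grecs$sample_id %in% mbc_ids])
        rows[[key]] <- data.frame(
          variant_key = key, gene = g, role = role, pattern = "truncating",
          func_score = func_score(key, "truncating", annotations),
          carriers = length(carriers), protein_change = "Trunc",
          stringsAsFactors = FALSE)
      }
    }
  }
  calls <- rbind_list(rows)
  if (is.null(calls)) {
    calls <- data.frame(variant_key = character(), gene = character(),
                        role = character(), pattern = character(),
                        func_score = integer(), carriers = integer(),
                        protein_change = character(),
                        stringsAsFactors = FALSE)
  }
  calls$eligible <- calls$func_score >= 5 & calls$carriers > carrier_min
  calls$or <- NA_real_; calls$ci_low <- NA_real_; calls$ci_high <- NA_real_
  calls$p <- NA_real_; calls$q <- NA_real_
  site_pref <- list()
  for (j in which(calls$eligible)) {
    key <- carrier_key(calls$gene[j],
                       protein_change = calls$protein_change[j])
    tab <- build_contingency(data$mutations, data$clinical, key,
                             "mbc_vs_pbc", panels = data$panels)
    fit <- or_meta(tab)
    if (!fit$untestable) {
      calls$or[j] <- fit$pooled$or
      calls$ci_low[j] <- fit$pooled$ci_low
      calls$ci_high[j] <- fit$pooled$ci_high
      calls$p[j] <- fit$pooled$p
    }
    for (s in plan$site_sets) {
      stab <- build_contingency(data$mutations, data$clinical, key,
                                "site_vs_other_sites",
                                grouping = list(site_set = s,
                                                cohorts = plan$site_cohorts %||%
                                                  site_resolvable_cohorts(data$clinical)),
                                panels = data$panels)
      if (attr(stab, "untestable")) next
      row <- regression_row(contingency_logistic(stab),
                            calls$variant_key[j], "site_vs_other_sites",
                            "driver_site_preference")
      row$site_set <- s
      site_pref[[paste(calls$variant_key[j], s)]] <- row
    }
  }
  ok <- calls$eligible & !is.na(calls$p)
  calls$q[ok] <- bh_fdr(calls$p[ok])
  pref <- rbind_list(site_pref)
  if (!is.null(pref)) {
    okp <- !is.na(pref$p)
    pref$q[okp] <- bh_fdr(pref$p[okp])
  }
  calls$protein_change <- NULL
  attr(calls, "site_preference") <- pref
  class(calls) <- c("driver_calls", "data.frame")
  calls
}

#' @export
print.driver_calls <- function(x, ...) {
  cat(sprintf("Candidate driver mutations: %d pattern-matched key(s), %d eligible\n",
              nrow(x), sum(x$eligible)))
  if (nrow(x)) {
    print(as.data.frame(x)[, c("variant_key", "role", "pattern",
                               "func_score", "carriers", "eligible", "or",
                               "q")],
          row.names = FALSE, digits = 3)
  }
  invisible(x)
}
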