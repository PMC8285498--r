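# Readers and writers for the tab-delimited tables the pipeline consumes:
# MAF-style mutation tables, gene-level CNA tables (long or matrix), clinical
# sample tables, panel definitions, gene-symbol alias tables, and the TSV
# reports the analyses emit. All readers normalize dialect differences up
# front so downstream code sees one canonical schema.

# Closed MAF Variant_Classification vocabulary accepted at parse time.
maf_classifications <- c(
  "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
  "Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
  "Splice_Region", "Splice_Site", "Translation_Start_Site",
  "5'Flank", "3'Flank", "5'UTR", "3'UTR", "Intron", "Silent", "RNA", "IGR",
  "Targeted_Region", "De_novo_Start_InFrame", "De_novo_Start_OutOfFrame"
)

#' Column-map presets for mutation tables
#'
#' Returns a named list mapping canonical field names to the column names
#' used by a source dialect. `"maf"` is the standard MAF layout; the preset
#' can be modified or replaced per cohort.
#'
#' @param preset Currently `"maf"`.
#' @return Named list: canonical field -> source column name.
#' @export
column_map_preset <- function(preset = "maf") {
  switch(preset,
    maf = list(
      sample_id = "Tumor_Sample_Barcode", gene = "Hugo_Symbol",
      chrom = "Chromosome", pos_start = "Start_Position",
      pos_end = "End_Position", ref_allele = "Reference_Allele",
      alt_allele = "Tumor_Seq_Allele2",
      variant_classification = "Variant_Classification",
      protein_change = "HGVSp_Short", depth = "t_depth",
      alt_count = "t_alt_count", vaf = "vaf"
    ),
    stop("unknown column-map preset: ", preset)
  )
}

# strip leading chr, uppercase X/Y/MT
normalize_chrom <- function(x) {
  x <- sub("^chr", "", as.character(x), ignore.case = TRUE)
  toupper(x)
}

#' Read a somatic mutation table
#'
#' Parses a tab-delimited MAF-style mutation table into the canonical
#' mutation schema. Parsing is total: every input row becomes either one
#' mutation record or one logged rejection with a reason code, so
#' `nrow(records) + nrow(rejections)` equals the input row count.
#'
#' Chromosome labels are normalized (leading `"chr"` stripped, X/Y/MT
#' uppercased). VAF is taken from a `vaf` column when present, otherwise
#' computed as `t_alt_count / t_depth` when both are available; missing
#' depth/VAF stay missing (never 0). Row order is preserved.
#'
#' @param path Tab-delimited file with a header row.
#' @param cohort_label Cohort label attached to every record.
#' @param column_map Named list resolving canonical fields to source
#'   columns (see [column_map_preset()]).
#' @param normalize Optional function applied to the parsed record data
#'   frame before validation (hook for cohort-specific representation
#'   fixes, e.g. indel coordinate conventions); default identity.
#' @return A data frame of mutation records with columns `sample_id,
#'   cohort, gene, chrom, pos_start, pos_end, ref_allele, alt_allele,
#'   variant_classification, protein_change, depth, vaf`, with attributes
#'   `"rejections"` (data frame `row, reason`) and `"n_input"`.
#' @export
read_mutations <- function(path, cohort_label,
                           column_map = column_map_preset("maf"),
                           normalize = identity) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "#")
  required <- c("sample_id", "gene", "chrom", "pos_start", "pos_end",
                "ref_allele", "alt_allele", "variant_classification")
  for (f in required) {
    col <- column_map[[f]]
    if (is.null(col) || !(col %in% names(raw))) {
      stop("missing required column for field '", f, "': ",
           if (is.null(col)) "<unmapped>" else col)
    }
  }
  get_opt <- function(f) {
    col <- column_map[[f]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else rep(NA, nrow(raw))
  }
  rec <- data.frame(
    sample_id = as.character(raw[[column_map$sample_id]]),
    cohort = cohort_label,
    gene = as.character(raw[[column_map$gene]]),
    chrom = normalize_chrom(raw[[column_map$chrom]]),
    pos_start = suppressWarnings(as.numeric(raw[[column_map$pos_start]])),
    pos_end = suppressWarnings(as.numeric(raw[[column_map$pos_end]])),
    ref_allele = toupper(trimws(as.character(raw[[column_map$ref_allele]]))),
    alt_allele = toupper(trimws(as.character(raw[[column_map$alt_allele]]))),
    variant_classification = as.character(raw[[column_map$variant_classification]]),
    protein_change = as.character(get_opt("protein_change")),
    depth = suppressWarnings(as.numeric(get_opt("depth"))),
    vaf = suppressWarnings(as.numeric(get_opt("vaf"))),
    stringsAsFactors = FALSE
  )
  alt_count <- suppressWarnings(as.numeric(get_opt("alt_count")))
  no_vaf <- is.na(rec$vaf) & !is.na(alt_count) & !is.na(rec$depth) & rec$depth > 0
  rec$vaf[no_vaf] <- alt_count[no_vaf] / rec$depth[no_vaf]
  rec$protein_change[is.na(rec$protein_change)] <- ""
  rec <- normalize(rec)

  reason <- rep(NA_character_, nrow(rec))
  empty_allele <- function(x) is.na(x) | x == "" | x == "."
  bad <- empty_allele(rec$ref_allele) & empty_allele(rec$alt_allele)
  reason[bad] <- "no reference allele, alternative allele"
  bad_coord <- is.na(reason) &
    (is.na(rec$pos_start) | is.na(rec$pos_end) | rec$pos_start > rec$pos_end |
       rec$pos_start < 1)
  reason[bad_coord] <- "bad coordinate"
  bad_class <- is.na(reason) &
    !(rec$variant_classification %in% maf_classifications)
  reason[bad_class] <- "unknown classification"
  same_allele <- is.na(reason) & !empty_allele(rec$ref_allele) &
    !empty_allele(rec$alt_allele) & rec$ref_allele == rec$alt_allele
  reason[same_allele] <- "reference equals alternative allele"
  bad_vaf <- is.na(reason) & !is.na(rec$vaf) & (rec$vaf < 0 | rec$vaf > 1)
  reason[bad_vaf] <- "vaf outside [0,1]"

  keep <- is.na(reason)
  rejections <- data.frame(row = which(!keep), reason = reason[!keep],
                           stringsAsFactors = FALSE)
  out <- rec[keep, , drop = FALSE]
  rownames(out) <- NULL
  # MAF uses "-" for pure insertions/deletions; empty on one side only is
  # normalized to that convention
  out$ref_allele[out$ref_allele %in% c("", ".")] <- "-"
  out$alt_allele[out$alt_allele %in% c("", ".")] <- "-"
  attr(out, "rejections") <- rejections
  attr(out, "n_input") <- nrow(rec)
  out
}

#' Rewrite gene symbols to current HGNC names
#'
#' Applies an alias table (old symbol -> HGNC symbol) to the `gene` column
#' of a record table. Symbols already canonical are untouched; symbols in
#' neither the canonical set nor the alias table are kept and flagged. The
#' operation is idempotent provided the alias table maps into canonical
#' symbols.
#'
#' @param records Data frame with a `gene` column (mutation or CNA records).
#' @param alias_table Data frame with columns `old_symbol, hgnc_symbol`, or
#'   a named character vector `old -> new`.
#' @param canonical Optional character vector of recognized HGNC symbols;
#'   when supplied, genes in neither set gain an `unrecognized_symbol` flag
#'   column.
#' @return `records` with rewritten symbols; attribute `"rename_log"` is a
#'   data frame `old, new, count`.
#' @export
harmonize_symbols <- function(records, alias_table, canonical = NULL) {
  if (is.data.frame(alias_table)) {
    map <- stats::setNames(as.character(alias_table$hgnc_symbol),
                           as.character(alias_table$old_symbol))
  } else {
    map <- alias_table
  }
  if (anyDuplicated(names(map))) stop("alias table is not functional")
  old <- records$gene
  hit <- old %in% names(map)
  records$gene[hit] <- unname(map[old[hit]])
  if (any(hit)) {
    log_tab <- as.data.frame(table(old = old[hit]), stringsAsFactors = FALSE)
    rename_log <- data.frame(old = log_tab$old,
                             new = unname(map[log_tab$old]),
                             count = log_tab$Freq, stringsAsFactors = FALSE)
  } else {
    rename_log <- data.frame(old = character(), new = character(),
                             count = integer(), stringsAsFactors = FALSE)
  }
  if (!is.null(canonical)) {
    records$unrecognized_symbol <- !(records$gene %in% canonical)
  }
  attr(records, "rename_log") <- rename_log
  records
}

# WTSI-style CNA labels -> integer levels
cna_label_levels <- c(AMP = 2, HOM_DEL = -2)
cna_valid_levels <- c(-2, -1.5, -1, 1, 2)

#' Read a gene-level copy-number table
#'
#' Accepts either a long table (`sample_id, gene, level` columns, extra
#' columns ignored) or a cBioPortal-style matrix (first column gene
#' symbols, remaining columns one per sample). Zero levels mean "no
#' alteration" and are dropped; label calls `AMP`/`HOM_DEL` are mapped to
#' +2/-2; levels outside \{-2, -1.5, -1, 1, 2\} are rejected with a reason.
#' Intermediate levels (-1.5, -1, 1) are retained here and filtered later
#' by [filter_cna()], keeping the reader lossless.
#'
#' @param path Tab-delimited CNA table.
#' @param cohort_label Cohort label attached to every record.
#' @return Data frame `sample_id, cohort, gene, level` with attributes
#'   `"rejections"` and `"n_input"` (non-zero entries considered).
#' @export
read_cna <- function(path, cohort_label) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  long_cols <- c("sample_id", "gene", "level")
  if (all(long_cols %in% names(raw))) {
    rec <- data.frame(sample_id = as.character(raw$sample_id),
                      gene = as.character(raw$gene),
                      level_raw = as.character(raw$level),
                      stringsAsFactors = FALSE)
  } else {
    gene_col <- if ("Hugo_Symbol" %in% names(raw)) "Hugo_Symbol" else names(raw)[1]
    samples <- setdiff(names(raw), gene_col)
    rec <- data.frame(
      sample_id = rep(samples, each = nrow(raw)),
      gene = rep(as.character(raw[[gene_col]]), times = length(samples)),
      level_raw = as.character(unlist(raw[samples], use.names = FALSE)),
      stringsAsFactors = FALSE
    )
  }
  lev <- suppressWarnings(as.numeric(rec$level_raw))
  is_label <- rec$level_raw %in% names(cna_label_levels)
  lev[is_label] <- cna_label_levels[rec$level_raw[is_label]]
  nonzero <- !is.na(lev) & lev != 0 | is.na(lev)
  rec <- rec[nonzero, , drop = FALSE]; lev <- lev[nonzero]
  ok <- !is.na(lev) & lev %in% cna_valid_levels
  rejections <- data.frame(
    row = which(!ok),
    reason = ifelse(is.na(lev[!ok]), "unparseable level", "level outside closed set"),
    stringsAsFactors = FALSE
  )
  out <- data.frame(sample_id = rec$sample_id[ok], cohort = cohort_label,
                    gene = rec$gene[ok], level = lev[ok],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "rejections") <- rejections
  attr(out, "n_input") <- nrow(rec)
  out
}

# default label translations applied by read_clinical; cohort vocab_maps
# are merged over these
default_vocab_map <- function() {
  list(
    tumor_type = c("Metastasis" = "metastasis", "metastasis" = "metastasis",
                   "Primary" = "primary", "primary" = "primary"),
    histology = c("Breast Invasive Ductal Carcinoma" = "IDC", "IDC" = "IDC",
                  "Breast Invasive Lobular Carcinoma" = "ILC", "ILC" = "ILC",
                  "Ductal" = "IDC", "Lobular" = "ILC", "Other" = "Other",
                  "Others" = "Other"),
    receptor = c("Positive" = "pos", "positive" = "pos", "pos" = "pos",
                 "Negative" = "neg", "negative" = "neg", "neg" = "neg"),
    sex = c("Female" = "female", "female" = "female",
            "Male" = "male", "male" = "male"),
    treatment_status = c(
      "naive_primary" = "naive_primary",
      "denovo_metastasis" = "denovo_metastasis",
      "post_treatment_metastasis" = "post_treatment_metastasis"
    )
  )
}

map_vocab <- function(x, map, field, warn = TRUE) {
  x <- as.character(x)
  out <- rep(NA_character_, length(x))
  known <- !is.na(x) & x %in% names(map)
  out[known] <- unname(map[x[known]])
  unmapped <- !is.na(x) & x != "" & !known
  if (warn && any(unmapped)) {
    warning(sum(unmapped), " unmapped ", field, " label(s) set to NA: ",
            paste(utils::head(unique(x[unmapped]), 5), collapse = ", "),
            call. = FALSE)
  }
  out
}

#' Read a clinical sample table
#'
#' Parses a tab-delimited clinical table into the canonical sample schema,
#' enforcing controlled vocabularies for tumor type, histology, receptor
#' status, sex, and treatment status. Unmapped labels become NA with a
#' warning; biopsy-site strings are preserved verbatim (site sets are
#' resolved later by [classify_site_set()]).
#'
#' @param path Tab-delimited clinical table with columns `sample_id,
#'   patient_id, tumor_type, panel_id` and optionally `biopsy_site, sex,
#'   histology, hr_status, her2_status, treatment_status, age`.
#' @param cohort_label Cohort label attached to every sample.
#' @param vocab_map Named list of label translations merged over the
#'   defaults (elements `tumor_type, histology, receptor, sex,
#'   treatment_status`, each a named character vector source -> canonical).
#' @return Data frame of sample records (one row per sample).
#' @export
read_clinical <- function(path, cohort_label, vocab_map = list()) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  vm <- utils::modifyList(default_vocab_map(), vocab_map)
  need <- c("sample_id", "tumor_type", "panel_id")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing required clinical column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(raw$sample_id)) {
    stop("duplicate sample_id in clinical table: ",
         paste(utils::head(unique(raw$sample_id[duplicated(raw$sample_id)]), 3),
               collapse = ", "))
  }
  opt <- function(col, default = NA) {
    if (col %in% names(raw)) raw[[col]] else rep(default, nrow(raw))
  }
  tumor_type <- map_vocab(raw$tumor_type, vm$tumor_type, "tumor_type")
  if (anyNA(tumor_type)) stop("tumor_type must resolve to primary/metastasis for every sample")
  out <- data.frame(
    sample_id = as.character(raw$sample_id),
    patient_id = as.character(opt("patient_id", NA_character_)),
    cohort = cohort_label,
    tumor_type = tumor_type,
    biopsy_site = as.character(opt("biopsy_site", "")),
    sex = map_vocab(opt("sex"), vm$sex, "sex", warn = FALSE),
    histology = map_vocab(opt("histology"), vm$histology, "histology"),
    hr_status = map_vocab(opt("hr_status"), vm$receptor, "hr_status"),
    her2_status = map_vocab(opt("her2_status"), vm$receptor, "her2_status"),
    treatment_status = map_vocab(opt("treatment_status"), vm$treatment_status,
                                 "treatment_status", warn = FALSE),
    age = suppressWarnings(as.numeric(opt("age"))),
    panel_id = as.character(raw$panel_id),
    stringsAsFactors = FALSE
  )
  out$patient_id[is.na(out$patient_id) | out$patient_id == ""] <- out$sample_id[is.na(out$patient_id) | out$patient_id == ""]
  out$biopsy_site[is.na(out$biopsy_site)] <- ""
  out
}

#' Read panel definitions
#'
#' @param path Tab-delimited table with columns `panel_id, gene` (one row
#'   per panel-gene pair) and optionally `full_exonic` (logical; default
#'   TRUE).
#' @return Data frame `panel_id, gene, full_exonic`.
#' @export
read_panels <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("panel_id", "gene") %in% names(raw)))
  fe <- if ("full_exonic" %in% names(raw)) as.logical(raw$full_exonic) else TRUE
  out <- data.frame(panel_id = as.character(raw$panel_id),
                    gene = as.character(raw$gene),
                    full_exonic = fe, stringsAsFactors = FALSE)
  if (any(!nzchar(out$gene))) stop("panel table contains empty gene symbols")
  out
}

#' Read a gene-symbol alias table
#'
#' @param path Tab-delimited table with columns `old_symbol, hgnc_symbol`.
#' @return Data frame with those two columns.
#' @export
read_alias <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("old_symbol", "hgnc_symbol") %in% names(raw)))
  if (anyDuplicated(raw$old_symbol)) stop("alias table is not functional")
  raw[, c("old_symbol", "hgnc_symbol")]
}

# fixed column orders per report kind; keep writers/readers in lockstep
report_columns <- list(
  meta = c("feature", "comparison", "family", "k", "model", "log_or", "se",
           "or", "ci_low", "ci_high", "p", "q", "q_stat", "i2", "tau2",
           "het_p", "het_q", "untestable"),
  regression = c("feature", "comparison", "family", "term", "estimate", "se",
                 "or", "ci_low", "ci_high", "p", "q", "converged",
                 "separation_flag"),
  organotropism = c("gene", "site_set", "direction", "vs_pbc_or", "vs_pbc_q",
                    "vs_other_or", "vs_other_q", "subtype_robust"),
  driver = c("variant_key", "gene", "role", "pattern", "func_score",
             "carriers", "eligible", "or", "ci_low", "ci_high", "p", "q"),
  contingency = c("feature", "comparison", "cohort", "a", "b", "c", "d"),
  qc_summary = c("step", "reason", "count")
)

#' Write an analysis report as TSV
#'
#' Writes a result table with a fixed, documented column order per report
#' kind and fixed float precision, so identical results yield byte-identical
#' files. Missing columns are filled with NA; extra columns are dropped.
#' Files round-trip through [read_report()].
#'
#' @param results Data frame (possibly zero rows) of a known result kind.
#' @param path Output file path.
#' @param kind One of `"meta"`, `"regression"`, `"organotropism"`,
#'   `"driver"`, `"contingency"`, `"qc_summary"`.
#' @param digits Significant digits for numeric columns (default 10).
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, kind, digits = 10) {
  if (!kind %in% names(report_columns)) stop("unknown report kind: ", kind)
  cols <- report_columns[[kind]]
  results <- as.data.frame(results)
  for (col in setdiff(cols, names(results))) results[[col]] <- NA
  out <- results[, cols, drop = FALSE]
  for (col in cols) {
    if (is.numeric(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), "NA",
                           formatC(out[[col]], digits = digits, format = "g"))
    }
  }
  con <- file(path, open = "wb")  # binary mode: fixed \n line endings
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(out)) {
    lines <- do.call(paste, c(lapply(out, as.character), sep = "\t"))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read back a TSV report written by [write_report()]
#'
#' @param path Report file path.
#' @param kind Report kind (as in [write_report()]).
#' @return Data frame with the kind's canonical columns.
#' @export
read_report <- function(path, kind) {
  if (!kind %in% names(report_columns)) stop("unknown report kind: ", kind)
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(identical(names(out), report_columns[[kind]]))
  out
}
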