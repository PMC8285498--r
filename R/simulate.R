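# Multi-cohort MBC/PBC data generator with known ground truth. Carrier
# status is simulated at the sample x gene level through the same logistic
# model the analyses fit (baseline log-odds + metastasis shift + site
# tropism + optional histology confounding), then dressed as MAF-style
# variant records with configurable noise (silent records, low-depth /
# low-VAF records, within-sample duplicates, hypermutated outlier samples)
# and per-panel gene masking.

#' Simulation configuration
#'
#' Defines the cohort structure, per-gene effect sizes, site and subtype
#' distributions, and noise rates of a synthetic multi-cohort dataset.
#'
#' @param seed Integer seed; the generator is fully deterministic given the
#'   config. Default 2021.
#' @param cohorts Data frame with columns `label, n_mbc, n_pbc, panel_id`
#'   and optionally `has_cna, has_depth_vaf` (logical, default TRUE).
#' @param genes Data frame with columns `gene, baseline, mbc_log_or` and
#'   optionally `role` (`"oncogene"`, `"tsg"`, `"both"`, `"none"`),
#'   `hotspot_fraction` (probability a carrier variant is a hotspot
#'   missense), `truncating_fraction` (probability it is truncating),
#'   `amp_baseline, amp_log_or` (CNA amplification model),
#'   `hist_ilc_log_or` (log-odds shift for ILC-histology samples — the
#'   confounding hook), and `post_only_log_or` (extra shift applied only to
#'   post-treatment metastatic samples — the treatment-selection hook).
#' @param tropism Optional data frame `gene, site_set, log_or` of per-site
#'   tropism shifts applied to metastatic samples at that site.
#' @param panels Data frame `panel_id, gene` (default: every cohort's panel
#'   targets every configured gene).
#' @param site_probs Named probability vector over metastatic sites
#'   (specific distant sets and/or `"local"`); must sum to 1.
#' @param hist_probs Named probability vector over histologies
#'   (`IDC, ILC, Other`).
#' @param hist_site_log_or Optional data frame `histology, site_set,
#'   log_or`: multinomial log-weight shifts tilting site assignment by
#'   histology (the ILC -> ovary style confounder).
#' @param receptor_probs Named probability vector over receptor subtypes
#'   (`HR+/HER2-, HR+/HER2+, HR-/HER2+, TN`).
#' @param treatment Named list `p_naive_pbc` (fraction of PBC annotated
#'   treatment-naive), `p_denovo`, `p_post` (fractions of MBC annotated de
#'   novo / post-treatment; remainder NA).
#' @param noise Named list: `silent_rate` (extra Silent records per
#'   retained record), `lowdepth_rate`, `lowvaf_rate`, `duplicate_rate`,
#'   `outlier_rate` (fraction of samples turned into hypermutated
#'   outliers), `depth_size, depth_mu` (negative-binomial depth, shifted by
#'   +10), `vaf_shape1, vaf_shape2` (Beta VAF). Defaults give each QC
#'   filter ~2\% work.
#' @param hotspot_positions Named list gene -> integer protein positions
#'   used for hotspot missense variants (default position 538).
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 2021,
                       cohorts = data.frame(
                         label = c("A", "B", "C", "D"),
                         n_mbc = 500, n_pbc = 500,
                         panel_id = "P1", stringsAsFactors = FALSE),
                       genes = data.frame(
                         gene = "GENE1", baseline = 0.05, mbc_log_or = 0,
                         stringsAsFactors = FALSE),
                       tropism = NULL,
                       panels = NULL,
                       site_probs = c(liver = 0.25, bone = 0.20,
                                      lymph_nodes = 0.12, lung = 0.10,
                                      chest_wall_thorax = 0.06, skin = 0.05,
                                      soft = 0.04, pleura = 0.04,
                                      brain = 0.04, ovary = 0.03,
                                      peritoneum = 0.03, local = 0.04),
                       hist_probs = c(IDC = 0.72, ILC = 0.13, Other = 0.15),
                       hist_site_log_or = NULL,
                       receptor_probs = c(`HR+/HER2-` = 0.65,
                                          `HR+/HER2+` = 0.10,
                                          `HR-/HER2+` = 0.05, TN = 0.20),
                       treatment = list(p_naive_pbc = 0.6, p_denovo = 0.1,
                                        p_post = 0.6),
                       noise = list(),
                       hotspot_positions = list()) {
  stopifnot(abs(sum(site_probs) - 1) < 1e-8,
            all(genes$baseline >= 0 & genes$baseline <= 1))
  if (!"has_cna" %in% names(cohorts)) cohorts$has_cna <- TRUE
  if (!"has_depth_vaf" %in% names(cohorts)) cohorts$has_depth_vaf <- TRUE
  if (!"role" %in% names(genes)) genes$role <- "none"
  if (!"hotspot_fraction" %in% names(genes)) genes$hotspot_fraction <- 0
  if (!"truncating_fraction" %in% names(genes)) genes$truncating_fraction <- 0
  if (!"hist_ilc_log_or" %in% names(genes)) genes$hist_ilc_log_or <- 0
  if (!"post_only_log_or" %in% names(genes)) genes$post_only_log_or <- 0
  if (!"amp_baseline" %in% names(genes)) genes$amp_baseline <- 0
  if (!"amp_log_or" %in% names(genes)) genes$amp_log_or <- 0
  if (is.null(panels)) {
    panels <- expand.grid(panel_id = unique(cohorts$panel_id),
                          gene = genes$gene, stringsAsFactors = FALSE)
  }
  noise_defaults <- list(silent_rate = 0.02, lowdepth_rate = 0.02,
                         lowvaf_rate = 0.02, duplicate_rate = 0.02,
                         outlier_rate = 0, depth_size = 4, depth_mu = 190,
                         vaf_shape1 = 2, vaf_shape2 = 6)
  noise <- utils::modifyList(noise_defaults, noise)
  structure(list(seed = seed, cohorts = cohorts, genes = genes,
                 tropism = tropism, panels = panels,
                 site_probs = site_probs, hist_probs = hist_probs,
                 hist_site_log_or = hist_site_log_or,
                 receptor_probs = receptor_probs, treatment = treatment,
                 noise = noise, hotspot_positions = hotspot_positions),
            class = "sim_config")
}

#' Generate a synthetic multi-cohort dataset
#'
#' Draws per-sample carrier status for each configured gene from the
#' logistic model \eqn{logit P = logit(baseline) + mbc\_log\_or \cdot
#' [MBC] + tropism\_log\_or \cdot [site] + hist\_ilc\_log\_or \cdot [ILC]},
#' masks genes off a cohort's panel, emits one MAF-style mutation record
#' per carrier (hotspot missense, truncating, or generic missense per the
#' configured fractions), injects noise records (silent, low-depth,
#' low-VAF, duplicates, hypermutated outlier samples) with bookkeeping,
#' and simulates gene-level CNA amplification calls for CNA-bearing
#' cohorts.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, the tables are also
#'   written as tab-delimited files in the standard dialects
#'   (`mutations.maf`, `clinical.tsv`, `cna.tsv`, `panels.tsv`) plus a
#'   `truth.json`-style manifest (`truth.tsv` per-gene effects).
#' @return A list of class `"mbc_sim"`: `mutations`, `clinical`, `cna`,
#'   `panels` data frames and `truth` (list with `gene_effects`,
#'   `carrier_status` sample x gene logical matrix, and per-noise-class
#'   injected record counts).
#' @export
generate <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  co <- config$cohorts
  ge <- config$genes
  n_tot <- sum(co$n_mbc + co$n_pbc)

  clinical <- data.frame(
    sample_id = sprintf("S%05d", seq_len(n_tot)),
    patient_id = sprintf("PT%05d", seq_len(n_tot)),
    cohort = rep(co$label, times = co$n_mbc + co$n_pbc),
    tumor_type = unlist(lapply(seq_len(nrow(co)), function(i) {
      rep(c("metastasis", "primary"), times = c(co$n_mbc[i], co$n_pbc[i]))
    })),
    panel_id = rep(co$panel_id, times = co$n_mbc + co$n_pbc),
    sex = "female",
    stringsAsFactors = FALSE
  )
  is_mbc <- clinical$tumor_type == "metastasis"

  # histology, receptor
  clinical$histology <- sample(names(config$hist_probs), n_tot, TRUE,
                               prob = config$hist_probs)
  rec <- sample(names(config$receptor_probs), n_tot, TRUE,
                prob = config$receptor_probs)
  clinical$hr_status <- ifelse(rec %in% c("HR+/HER2-", "HR+/HER2+"), "pos", "neg")
  clinical$her2_status <- ifelse(rec %in% c("HR+/HER2+", "HR-/HER2+"), "pos", "neg")

  # metastatic site assignment, optionally tilted by histology
  site <- rep(NA_character_, n_tot)
  sites <- names(config$site_probs)
  if (is.null(config$hist_site_log_or)) {
    site[is_mbc] <- sample(sites, sum(is_mbc), TRUE, prob = config$site_probs)
  } else {
    for (h in unique(clinical$histology[is_mbc])) {
      w <- log(config$site_probs)
      tilt <- config$hist_site_log_or
      hit <- tilt[tilt$histology == h, , drop = FALSE]
      if (nrow(hit)) {
        idx <- match(hit$site_set, sites)
        w[idx[!is.na(idx)]] <- w[idx[!is.na(idx)]] + hit$log_or[!is.na(idx)]
      }
      p <- exp(w - max(w)); p <- p / sum(p)
      sel <- is_mbc & clinical$histology == h
      site[sel] <- sample(sites, sum(sel), TRUE, prob = p)
    }
  }
  site_label <- c(liver = "Liver", bone = "Bone", lymph_nodes = "Lymph nodes",
                  lung = "Lung", chest_wall_thorax = "Chest wall",
                  skin = "Skin", soft = "Soft tissue", pleura = "Pleura",
                  brain = "Brain", ovary = "Ovary", peritoneum = "Peritoneum",
                  local = "Local recurrence",
                  other_distant = "Distant organ")
  clinical$biopsy_site <- ifelse(is_mbc, unname(site_label[site]), "Breast")
  clinical$biopsy_site[is_mbc & is.na(clinical$biopsy_site)] <- "Distant organ"

  # treatment status
  tr <- config$treatment
  clinical$treatment_status <- NA_character_
  pbc_naive <- !is_mbc & stats::runif(n_tot) < tr$p_naive_pbc
  clinical$treatment_status[pbc_naive] <- "naive_primary"
  u <- stats::runif(n_tot)
  clinical$treatment_status[is_mbc & u < tr$p_denovo] <- "denovo_metastasis"
  clinical$treatment_status[is_mbc & u >= tr$p_denovo &
                              u < tr$p_denovo + tr$p_post] <- "post_treatment_metastasis"

  # carrier status per sample x gene from the logistic model
  on_panel <- function(g) {
    panel_ids <- unique(config$panels$panel_id[config$panels$gene == g])
    clinical$panel_id %in% panel_ids
  }
  carrier <- matrix(FALSE, n_tot, nrow(ge),
                    dimnames = list(clinical$sample_id, ge$gene))
  for (j in seq_len(nrow(ge))) {
    eta <- stats::qlogis(ge$baseline[j]) + ge$mbc_log_or[j] * is_mbc
    if (!is.null(config$tropism)) {
      tj <- config$tropism[config$tropism$gene == ge$gene[j], , drop = FALSE]
      for (r in seq_len(nrow(tj))) {
        hit <- is_mbc & !is.na(site) & site == tj$site_set[r]
        eta[hit] <- eta[hit] + tj$log_or[r]
      }
    }
    if (ge$hist_ilc_log_or[j] != 0) {
      eta <- eta + ge$hist_ilc_log_or[j] * (clinical$histology == "ILC")
    }
    if (ge$post_only_log_or[j] != 0) {
      post <- !is.na(clinical$treatment_status) &
        clinical$treatment_status == "post_treatment_metastasis"
      eta <- eta + ge$post_only_log_or[j] * post
    }
    carrier[, j] <- stats::runif(n_tot) < stats::plogis(eta)
  }

  # emit one mutation record per carrier for on-panel genes
  mut_list <- vector("list", nrow(ge))
  for (j in seq_len(nrow(ge))) {
    idx <- which(carrier[, j] & on_panel(ge$gene[j]))
    if (!length(idx)) next
    u <- stats::runif(length(idx))
    cls <- ifelse(u < ge$hotspot_fraction[j], "Missense_Mutation",
                  ifelse(u < ge$hotspot_fraction[j] + ge$truncating_fraction[j],
                         sample(truncating_classes(), length(idx), TRUE),
                         "Missense_Mutation"))
    hot <- u < ge$hotspot_fraction[j]
    pc <- character(length(idx))
    pos <- config$hotspot_positions[[ge$gene[j]]]
    if (is.null(pos)) pos <- 538L
    pc[hot] <- paste0("p.D", pos[1], "G")
    trunc <- cls %in% truncating_classes()
    pc[trunc] <- paste0("p.Q", 120 + (seq_len(sum(trunc)) %% 7), "*")
    other <- !hot & !trunc
    pc[other] <- paste0("p.A", 100 + (seq_len(sum(other)) %% 50), "V")
    mut_list[[j]] <- data.frame(
      sample_id = clinical$sample_id[idx],
      cohort = clinical$cohort[idx],
      gene = ge$gene[j],
      chrom = as.character(1 + (j %% 22)),
      pos_start = 1e6 * j + seq_along(idx),
      pos_end = 1e6 * j + seq_along(idx),
      ref_allele = "A", alt_allele = "G",
      variant_classification = cls,
      protein_change = pc,
      stringsAsFactors = FALSE
    )
  }
  mutations <- rbind_list(mut_list)
  if (is.null(mutations)) {
    mutations <- data.frame(sample_id = character(), cohort = character(),
                            gene = character(), chrom = character(),
                            pos_start = numeric(), pos_end = numeric(),
                            ref_allele = character(), alt_allele = character(),
                            variant_classification = character(),
                            protein_change = character(),
                            stringsAsFactors = FALSE)
  }

  # depth / VAF (cohorts without the fields get NA)
  nz <- config$noise
  n_mut <- nrow(mutations)
  has_dv <- co$has_depth_vaf[match(mutations$cohort, co$label)]
  depth <- 10 + stats::rnbinom(n_mut, size = nz$depth_size, mu = nz$depth_mu)
  vaf <- stats::rbeta(n_mut, nz$vaf_shape1, nz$vaf_shape2)
  vaf <- pmax(vaf, 0.011)  # signal records always pass the VAF filter
  mutations$depth <- ifelse(has_dv, depth, NA_real_)
  mutations$vaf <- ifelse(has_dv, vaf, NA_real_)
  mutations$injected_noise <- "signal"

  add_noise <- function(base, n, classification, depth, vaf, tag, offset) {
    if (n == 0 || nrow(base) == 0) return(NULL)
    pick <- sample.int(nrow(base), n, replace = TRUE)
    out <- base[pick, , drop = FALSE]
    # fresh positions per noise class so classes never alias each other
    out$pos_start <- offset + seq_len(n)
    out$pos_end <- out$pos_start
    if (!is.null(classification)) out$variant_classification <- classification
    out$protein_change <- ""
    hd <- co$has_depth_vaf[match(out$cohort, co$label)]
    out$depth <- ifelse(hd, depth, NA_real_)
    out$vaf <- ifelse(hd, vaf, NA_real_)
    out$injected_noise <- tag
    out
  }
  noise_counts <- c(silent = 0L, low_depth = 0L, low_vaf = 0L,
                    duplicate = 0L, outlier = 0L)
  noise_rows <- list()
  if (n_mut > 0) {
    n_sil <- stats::rbinom(1, n_mut, nz$silent_rate)
    noise_rows$silent <- add_noise(mutations, n_sil, "Silent", 100, 0.3,
                                   "silent", 4e8)
    # low-depth/low-VAF records only make sense in cohorts carrying the fields
    base_dv <- mutations[has_dv, , drop = FALSE]
    n_ld <- stats::rbinom(1, nrow(base_dv), nz$lowdepth_rate)
    noise_rows$low_depth <- add_noise(base_dv, n_ld, NULL, 5, 0.3,
                                      "low_depth", 5e8)
    n_lv <- stats::rbinom(1, nrow(base_dv), nz$lowvaf_rate)
    noise_rows$low_vaf <- add_noise(base_dv, n_lv, NULL, 100, 0.005,
                                    "low_vaf", 6e8)
    # duplicates: exact copies of existing records
    n_dup <- stats::rbinom(1, n_mut, nz$duplicate_rate)
    if (n_dup > 0) {
      pick <- sample.int(n_mut, n_dup, replace = TRUE)
      dup <- mutations[pick, , drop = FALSE]
      dup$injected_noise <- "duplicate"
      noise_rows$duplicate <- dup
    }
    # hypermutated outlier samples: many extra records in one sample
    if (nz$outlier_rate > 0) {
      n_out <- stats::rbinom(1, n_tot, nz$outlier_rate)
      if (n_out > 0) {
        osamp <- sample(clinical$sample_id, n_out)
        orows <- lapply(osamp, function(s) {
          k <- 40L
          i <- match(s, clinical$sample_id)
          data.frame(
            sample_id = s, cohort = clinical$cohort[i],
            gene = sample(ge$gene, k, TRUE),
            chrom = "1", pos_start = 9e7 + seq_len(k),
            pos_end = 9e7 + seq_len(k),
            ref_allele = "C", alt_allele = "T",
            variant_classification = "Missense_Mutation",
            protein_change = "",
            depth = ifelse(co$has_depth_vaf[match(clinical$cohort[i], co$label)], 100, NA_real_),
            vaf = ifelse(co$has_depth_vaf[match(clinical$cohort[i], co$label)], 0.3, NA_real_),
            injected_noise = "outlier",
            stringsAsFactors = FALSE)
        })
        noise_rows$outlier <- do.call(rbind, orows)
      }
    }
    for (tag in names(noise_rows)) {
      if (!is.null(noise_rows[[tag]])) {
        noise_counts[tag] <- nrow(noise_rows[[tag]])
      }
    }
    mutations <- do.call(rbind, c(list(mutations),
                                  Filter(Negate(is.null), noise_rows),
                                  list(make.row.names = FALSE)))
  }
  rownames(mutations) <- NULL

  # gene-level CNA amplification calls for CNA-bearing cohorts
  cna <- data.frame(sample_id = character(), cohort = character(),
                    gene = character(), level = numeric(),
                    stringsAsFactors = FALSE)
  amp_genes <- which(ge$amp_baseline > 0)
  if (length(amp_genes)) {
    has_cna_sample <- co$has_cna[match(clinical$cohort, co$label)]
    cna_list <- lapply(amp_genes, function(j) {
      eta <- stats::qlogis(ge$amp_baseline[j]) + ge$amp_log_or[j] * is_mbc
      hit <- has_cna_sample & stats::runif(n_tot) < stats::plogis(eta) &
        on_panel(ge$gene[j])
      if (!any(hit)) return(NULL)
      data.frame(sample_id = clinical$sample_id[hit],
                 cohort = clinical$cohort[hit],
                 gene = ge$gene[j], level = 2, stringsAsFactors = FALSE)
    })
    cna_list <- Filter(Negate(is.null), cna_list)
    if (length(cna_list)) cna <- rbind_list(cna_list)
  }

  truth <- list(
    gene_effects = ge[, c("gene", "baseline", "mbc_log_or")],
    tropism = config$tropism,
    carrier_status = carrier,
    site = site,
    noise_counts = noise_counts
  )
  out <- structure(list(mutations = mutations, clinical = clinical,
                        cna = cna, panels = config$panels, truth = truth,
                        config = config),
                   class = "mbc_sim")
  if (!is.null(out_dir)) write_dataset(out, out_dir)
  out
}

#' @export
print.mbc_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic multi-cohort dataset: %d cohorts, %d samples (%d MBC / %d PBC),\n  %d mutation records (%d injected noise), %d CNA calls, %d genes\n",
    nrow(x$config$cohorts), nrow(x$clinical),
    sum(x$clinical$tumor_type == "metastasis"),
    sum(x$clinical$tumor_type == "primary"),
    nrow(x$mutations), sum(x$truth$noise_counts), nrow(x$cna),
    nrow(x$config$genes)))
  invisible(x)
}

#' Write a synthetic dataset as tab-delimited files
#'
#' Emits `mutations.maf` (standard MAF column names), `clinical.tsv`,
#' `cna.tsv` (long format), `panels.tsv`, and `truth.tsv` into `dir`. The
#' files round-trip through the package readers.
#'
#' @param sim An [generate()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- sim$mutations
  maf <- data.frame(
    Hugo_Symbol = m$gene, Chromosome = m$chrom,
    Start_Position = m$pos_start, End_Position = m$pos_end,
    Reference_Allele = m$ref_allele, Tumor_Seq_Allele2 = m$alt_allele,
    Variant_Classification = m$variant_classification,
    HGVSp_Short = m$protein_change,
    t_depth = m$depth,
    t_alt_count = ifelse(is.na(m$depth) | is.na(m$vaf), NA,
                         round(m$depth * m$vaf)),
    Tumor_Sample_Barcode = m$sample_id,
    stringsAsFactors = FALSE
  )
  utils::write.table(maf, file.path(dir, "mutations.maf"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cl <- sim$clinical
  utils::write.table(cl, file.path(dir, "clinical.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$cna, file.path(dir, "cna.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$panels, file.path(dir, "panels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$gene_effects, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Minimal dataset reproducing an exact 2x2 contingency
#'
#' Builds a one-cohort dataset with exactly `a` carriers and `b`
#' non-carriers in the case group and `c` carriers / `d` non-carriers in
#' the control group, so that [build_contingency()] on the output returns
#' exactly `(a, b, c, d)`. Used to replay printed contingency tables
#' through the counting and meta-analysis machinery.
#'
#' @param a,b,c,d Non-negative cell counts.
#' @param gene Gene symbol for the carrier records.
#' @param site Optional specific metastatic site for the case samples; when
#'   given, cases are metastatic samples at `site` and controls are
#'   metastatic samples spread over other sites (the site-vs-other layout).
#'   When NULL, cases are metastatic and controls primary (MBC-vs-PBC
#'   layout).
#' @param cohort Cohort label (default `"FIX"`).
#' @return An `"mbc_sim"`-like list with `mutations`, `clinical`, `panels`.
#' @export
fixture_from_counts <- function(a, b, c, d, gene = "GENE1", site = NULL,
                                cohort = "FIX") {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  n <- a + b + c + d
  ids <- sprintf("F%05d", seq_len(max(n, 1)))[seq_len(n)]
  grp <- rep(c("case", "case", "control", "control"),
             times = c(a, b, c, d))
  is_carrier <- rep(c(TRUE, FALSE, TRUE, FALSE), times = c(a, b, c, d))
  if (is.null(site)) {
    tumor_type <- ifelse(grp == "case", "metastasis", "primary")
    biopsy <- ifelse(grp == "case", "Liver", "Breast")
  } else {
    tumor_type <- rep("metastasis", n)
    site_label <- c(liver = "Liver", bone = "Bone",
                    lymph_nodes = "Lymph nodes", lung = "Lung",
                    chest_wall_thorax = "Chest wall", skin = "Skin",
                    soft = "Soft tissue", pleura = "Pleura", brain = "Brain",
                    ovary = "Ovary", peritoneum = "Peritoneum")
    others <- setdiff(names(site_label), site)
    biopsy <- ifelse(grp == "case", unname(site_label[site]),
                     unname(site_label[rep_len(others, n)]))
  }
  clinical <- data.frame(
    sample_id = ids, patient_id = ids, cohort = cohort,
    tumor_type = tumor_type, biopsy_site = biopsy, sex = "female",
    histology = "IDC", hr_status = "pos", her2_status = "neg",
    treatment_status = NA_character_, age = 55, panel_id = "PFIX",
    stringsAsFactors = FALSE
  )
  k <- sum(is_carrier)
  mutations <- data.frame(
    sample_id = ids[is_carrier], cohort = rep(cohort, k),
    gene = rep(gene, k), chrom = rep("6", k),
    pos_start = 152000000 + seq_len(k), pos_end = 152000000 + seq_len(k),
    ref_allele = rep("A", k), alt_allele = rep("G", k),
    variant_classification = rep("Missense_Mutation", k),
    protein_change = rep("p.D538G", k), depth = rep(NA_real_, k),
    vaf = rep(NA_real_, k), stringsAsFactors = FALSE
  )
  panels <- data.frame(panel_id = "PFIX", gene = gene,
                       stringsAsFactors = FALSE)
  list(mutations = mutations, clinical = clinical, panels = panels)
}
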