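# Shared fixture builders for the test suite. Everything is generated in
# code; the only files touched are the small bundled examples under
# inst/extdata and per-test tempfiles.

extdata <- function(name) {
  system.file("extdata", name, package = "mbcenrich", mustWork = TRUE)
}

# one-gene four-cohort simulation in the standard study dimensions
# (4 cohorts x 500 MBC + 500 PBC, baseline carrier probability 5%)
std_sim_config <- function(seed, mbc_log_or = 0, gene = "G1", ...) {
  sim_config(
    seed = seed,
    cohorts = data.frame(label = c("A", "B", "C", "D"), n_mbc = 500,
                         n_pbc = 500, panel_id = "P1",
                         stringsAsFactors = FALSE),
    genes = data.frame(gene = gene, baseline = 0.05,
                       mbc_log_or = mbc_log_or, stringsAsFactors = FALSE),
    ...
  )
}

# harmonized dataset from a simulation output
sim_to_data <- function(sim, qc = qc_config()) {
  records <- suppressWarnings(apply_qc(sim$mutations, qc))
  eligible <- select_samples(sim$clinical, sim$panels)
  suppressWarnings(mbc_data(records, eligible, sim$panels,
                            cna = if (nrow(sim$cna)) filter_cna(sim$cna, qc) else NULL))
}

# pooled fixed-effects log-OR for one gene straight from a simulation
sim_fixed_estimate <- function(seed, mbc_log_or) {
  sim <- generate(std_sim_config(seed, mbc_log_or))
  d <- sim_to_data(sim)
  tab <- build_contingency(d$mutations, d$clinical, carrier_key("G1"),
                           "mbc_vs_pbc", panels = d$panels)
  or_meta(tab)$fixed
}

# a small in-memory mutation record table (already canonical schema)
make_records <- function(n = 6, sample_id = sprintf("S%03d", seq_len(n)),
                         cohort = "A", gene = "ESR1", depth = NA_real_,
                         vaf = NA_real_,
                         classification = "Missense_Mutation",
                         protein_change = "p.D538G",
                         pos = seq_len(n)) {
  data.frame(
    sample_id = sample_id, cohort = cohort, gene = gene, chrom = "6",
    pos_start = 152e6 + pos, pos_end = 152e6 + pos,
    ref_allele = "A", alt_allele = "G",
    variant_classification = classification,
    protein_change = protein_change, depth = depth, vaf = vaf,
    stringsAsFactors = FALSE
  )
}

# minimal clinical table
make_clinical <- function(n, tumor_type, cohort = "A",
                          biopsy_site = ifelse(tumor_type == "metastasis",
                                               "Liver", "Breast"),
                          sex = "female", histology = "IDC",
                          hr = "pos", her2 = "neg",
                          treatment = NA_character_, panel_id = "P1") {
  data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    patient_id = sprintf("P%03d", seq_len(n)),
    cohort = cohort, tumor_type = tumor_type, biopsy_site = biopsy_site,
    sex = sex, histology = histology, hr_status = hr, her2_status = her2,
    treatment_status = treatment, age = 55, panel_id = panel_id,
    stringsAsFactors = FALSE
  )
}
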