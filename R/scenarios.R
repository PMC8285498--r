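#' Constructed organotropism validation scenarios
#'
#' Three fixed simulation configurations that probe the dual-criterion
#' organotropism caller end to end:
#'
#' \describe{
#'   \item{`"tropism"`}{one gene enriched in MBC (log-OR ln 4) with a
#'     genuine liver tropism (site log-OR ln 3), independent of subtype —
#'     the caller should emit a liver call that survives subtype
#'     adjustment.}
#'   \item{`"enrichment"`}{the same MBC enrichment but uniform across
#'     sites — stage 2 should fail everywhere and no call be emitted.}
#'   \item{`"confounded"`}{no direct site effect; the gene is driven by
#'     ILC histology (log-OR ln 8) and ILC samples are preferentially
#'     biopsied in the ovary — the crude site test fires but the
#'     histology-adjusted refit should not, yielding a call with
#'     `subtype_robust = FALSE`.}
#' }
#'
#' Each scenario uses two cohorts of 1500 MBC + 1500 PBC samples and a 5\%
#' baseline carrier probability.
#'
#' @param which `"tropism"`, `"enrichment"`, or `"confounded"`.
#' @param seed Simulation seed (default 2021).
#' @return A [sim_config()].
#' @export
scenario_config <- function(which, seed = 2021) {
  cohorts <- data.frame(label = c("A", "B"), n_mbc = 1500, n_pbc = 1500,
                        panel_id = "P1", stringsAsFactors = FALSE)
  switch(which,
    tropism = sim_config(
      seed = seed, cohorts = cohorts,
      genes = data.frame(gene = "TRG", baseline = 0.05,
                         mbc_log_or = log(4), stringsAsFactors = FALSE),
      tropism = data.frame(gene = "TRG", site_set = "liver",
                           log_or = log(3), stringsAsFactors = FALSE)
    ),
    enrichment = sim_config(
      seed = seed, cohorts = cohorts,
      genes = data.frame(gene = "ENR", baseline = 0.05,
                         mbc_log_or = log(4), stringsAsFactors = FALSE)
    ),
    confounded = sim_config(
      seed = seed, cohorts = cohorts,
      genes = data.frame(gene = "CFG", baseline = 0.05,
                         mbc_log_or = log(4), hist_ilc_log_or = log(8),
                         stringsAsFactors = FALSE),
      hist_site_log_or = data.frame(histology = "ILC", site_set = "ovary",
                                    log_or = log(25),
                                    stringsAsFactors = FALSE)
    ),
    stop("unknown scenario: ", which)
  )
}
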