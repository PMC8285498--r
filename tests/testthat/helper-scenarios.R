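# Run one of the packaged organotropism validation scenarios end to end:
# generate -> QC -> site-specific stages -> subtype adjustment.
run_scenario <- function(which, seed = 2021) {
  cfg <- scenario_config(which, seed)
  sim <- generate(cfg)
  d <- sim_to_data(sim)
  plan <- analysis_plan(genes = cfg$genes$gene)
  ss <- suppressWarnings(run_site_specific(d, plan))
  suppressWarnings(run_subtype_adjusted(d, ss, plan))
}
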