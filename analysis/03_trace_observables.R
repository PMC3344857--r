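#!/usr/bin/env Rscript
# Observable pipeline on trace data: read per-nucleus stacks (synthetic
# stand-ins from 02, or reconstructed microscopy traces dropped into the
# same layout), then compute per-nucleus end-to-end, center-of-mass,
# entanglement and effective-persistence-length statistics.

source(file.path("analysis", "00_common.R"))

stack_dir <- file.path(RESULTS_DIR, "synthetic_traces")
if (!dir.exists(stack_dir))
  stop("no trace stacks at ", stack_dir, "; run 02_synthetic_nuclei.R ",
       "first (or point stack_dir at experimental data)")

datasets <- read_sc_stacks(stack_dir)
message("read ", length(datasets), " nuclei")

rows <- lapply(datasets, function(ds) {
  st <- ensemble_stats(ds, resample_n = 60L)
  lp <- effective_persistence_length(ds)
  data.frame(nucleus_id = ds$nucleus_id, n_traces = length(ds$traces),
             mean_sq_ree_um2 = st$mean_sq_ree,
             mean_sq_dcm_um2 = st$mean_sq_dcm,
             macn_intra = st$macn_intra, macn_inter = st$macn_inter,
             effective_lp_um = lp$l_p, lp_censored = lp$censored)
})
per_nucleus <- do.call(rbind, c(rows, make.row.names = FALSE))
write.csv(per_nucleus, file.path(RESULTS_DIR, "trace_observables.csv"),
          row.names = FALSE)

pooled <- ensemble_stats(datasets, resample_n = 60L)
message("pooled over nuclei:")
print(pooled)
print(per_nucleus)
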