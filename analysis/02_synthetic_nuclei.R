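#!/usr/bin/env Rscript
# Generate synthetic nucleus datasets emulating reconstructed SC traces
# (19 backbones of ~12 um mean contour, endpoints on the nuclear envelope,
# localization noise) and write them in the per-nucleus stack layout so
# the downstream scripts exercise the same I/O path as experimental data.

source(file.path("analysis", "00_common.R"))

n_nuclei <- 9L   # one dataset per imaged nucleus
out <- file.path(RESULTS_DIR, "synthetic_traces")
datasets <- lapply(seq_len(n_nuclei), function(i)
  generate_nucleus(synthetic_nucleus_config(seed = 1000L + i),
                   nucleus_id = sprintf("Stack%02d", i)))
write_traces(datasets, out)

summaries <- do.call(rbind, lapply(datasets, trace_summary))
write.csv(summaries, file.path(RESULTS_DIR, "synthetic_trace_summary.csv"),
          row.names = FALSE)

message(sprintf("wrote %d nuclei (%d traces, mean contour %.2f um) to %s",
                n_nuclei, nrow(summaries), mean(summaries$contour), out))
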