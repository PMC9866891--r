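#!/usr/bin/env Rscript
# Stage 1 — synthesize the study inputs.
#
# Builds the 43-compound labeled calibration benchmark (five homologous
# PFAS series, PPARalpha-like generating model, sigma = 0.35 kcal/mol) and
# an unlabeled screening panel (extended homologous series plus randomized
# decoys), and writes both under results/.

suppressMessages(library(pfasscreen))
library(readr)

SEED <- 101
dir.create("results", showWarnings = FALSE)

bench <- make_benchmark(seed = SEED)
truth <- attr(bench, "truth")
write_csv(bench, "results/benchmark.csv")
jsonlite::write_json(
  list(intercept = truth$intercept,
       coefficients = as.list(truth$coefficients),
       sigma = truth$sigma, seed = truth$seed),
  "results/benchmark_truth.json", auto_unbox = TRUE, digits = NA)

message(sprintf("benchmark: %d compounds across groups %s",
                nrow(bench), paste(sort(unique(bench$group)), collapse = " ")))
message(sprintf("endpoint range: %.2f to %.2f kcal/mol",
                min(bench$bs), max(bench$bs)))

panel <- dplyr::bind_rows(
  homologous_series("C", 0:11),
  homologous_series("S", 1:10),
  homologous_series("P", 1:10),
  homologous_series("F", 1:11, m = 2),
  homologous_series("Y", 1:10),
  decoy_structures(15, seed = SEED)
)
write_csv(panel, "results/screening_panel.csv")
message(sprintf("screening panel: %d compounds (%d decoys)",
                nrow(panel), sum(panel$group == "decoy")))
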