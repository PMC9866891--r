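#!/usr/bin/env Rscript
# Stage 2 — topological descriptors.
#
# Computes X%, ICR, PW2, TPC (plus the auxiliary pool) for the screening
# panel, reports any parse rejects, and prints the descriptor trend along
# the PFCA homologous series — the structural signal the receptor models
# read.

suppressMessages(library(pfasscreen))
library(readr)

panel <- read_compound_csv("results/screening_panel.csv")
tbl <- descriptor_table(panel)
rej <- descriptor_rejects(tbl)

write_csv(tbl, "results/panel_descriptors.csv")
if (nrow(rej) > 0) write_csv(rej, "results/panel_rejects.csv")
message(sprintf("descriptors for %d compounds (%d rejected)",
                nrow(tbl), nrow(rej)))

pfca <- tbl[tbl$group == "C", c("id", "x_percent", "icr", "pw2", "tpc")]
message("PFCA homologous series (descriptors rise with chain length):")
for (i in seq_len(nrow(pfca))) {
  message(sprintf("  %-4s X%% = %5.2f  ICR = %.3f  PW2 = %.3f  TPC = %.2f",
                  pfca$id[i], pfca$x_percent[i], pfca$icr[i],
                  pfca$pw2[i], pfca$tpc[i]))
}
stopifnot(all(diff(pfca$x_percent) > 0),
          all(diff(pfca$icr) > 0),
          all(diff(pfca$tpc) > 0))
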