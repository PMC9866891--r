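#!/usr/bin/env Rscript
# Stage 4 — applicability domain.
#
# Williams-plot data (standardized residuals vs leverage) for the labeled
# training and validation sets, and Insubria-graph data (leverage vs
# predicted score) for the unlabeled screening panel. Short-chain TFA-like
# members are expected to exceed h* against the longer-chain bulk.

suppressMessages(library(pfasscreen))
library(readr)

bench <- read_compound_csv("results/benchmark.csv")
model <- read_model("results/model.json")
split <- split_one_to_z(bench, 3)

h_star <- critical_leverage(model$n_train, model$p)
message(sprintf("h* = 3(p+1)/n = %.3f for n = %d, p = %d",
                h_star, model$n_train, model$p))

train_pred <- predict(model, split$training)
rmse_c <- sqrt(mean((split$training$bs - train_pred)^2))
val_pred <- predict(model, split$validation)
rmse_ext <- sqrt(mean((split$validation$bs - val_pred)^2))

williams <- dplyr::bind_rows(
  dplyr::mutate(assess_domain(model, split$training, split$training,
                              rmse = rmse_c), set = "training"),
  dplyr::mutate(assess_domain(model, split$training, split$validation,
                              rmse = rmse_ext), set = "validation")
)
write_csv(williams, "results/williams.csv")
message(sprintf("Williams: %d/%d labeled compounds in-domain",
                sum(williams$in_domain), nrow(williams)))
flagged <- williams[!williams$in_domain, ]
for (i in seq_len(nrow(flagged))) {
  message(sprintf("  flagged %-4s (%s): h = %.3f, z = %+.2f",
                  flagged$id[i], flagged$reason[i], flagged$h[i],
                  flagged$z[i]))
}

panel <- read_compound_csv("results/panel_descriptors.csv")
insubria <- assess_domain(model, split$training, panel)
insubria$group <- panel$group
write_csv(insubria, "results/insubria.csv")
message(sprintf("Insubria: %d/%d screening compounds in-domain",
                sum(insubria$in_domain), nrow(insubria)))
print(table(insubria$group, insubria$reason))
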