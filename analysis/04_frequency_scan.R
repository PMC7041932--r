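#!/usr/bin/env Rscript
# Frequency decoding: conformation AUCs of the calmodulin-only model across
# spike frequencies (the C lobe's TR window peaking near 20 Hz), and the
# BCM-like curve of the full model (CaMKII minus CaN activated areas) with
# and without neurogranin.
suppressPackageStartupMessages(library(hemicam))
dir.create("results", showWarnings = FALSE)

## calmodulin-only conformation AUCs
net_cam <- build_network(config = model_config(
  with_camkii = FALSE, with_can = FALSE, with_ng = FALSE, phospho = FALSE))
eq_cam <- suppressWarnings(equilibrate(net_cam))
freqs <- c(3, 10, 20, 30, 50)
aucs <- t(vapply(freqs, function(f)
  conformation_auc(simulate_protocol(net_cam, eq_cam, spike_protocol(f))),
  numeric(4)))
auc_df <- data.frame(freq = freqs, aucs)
write.csv(auc_df, "results/conformation_auc.csv", row.names = FALSE)
print(auc_df)
message(sprintf("TR-conformation AUC is maximal at %g Hz",
                freqs[which.max(auc_df$TR)]))

## BCM-like curves, with and without neurogranin
scan_freqs <- c(0.5, 1, 2, 5, 10, 20, 50, 100)
for (ng in c(TRUE, FALSE)) {
  net <- build_network(config = model_config(with_ng = ng))
  eq <- suppressWarnings(equilibrate(net))
  curve <- bcm_curve(net, scan_freqs, eq)
  lab <- if (ng) "with_ng" else "no_ng"
  write.csv(curve, sprintf("results/bcm_%s.csv", lab), row.names = FALSE)
  th <- theta_m(curve)
  message(sprintf("BCM %s: theta_m = %s Hz", lab,
                  if (is.na(th)) attr(th, "reason") else sprintf("%.2f", th)))
  print(curve)
}
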