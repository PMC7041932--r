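#!/usr/bin/env Rscript
# Parameter recovery on synthetic data: single-constant fits on noise-free
# titrations and the cC-LC identifiability analysis (their log-estimates are
# strongly anticorrelated across noisy replicate fits: the steady-state
# curves constrain a product-like combination, not the pair).
suppressPackageStartupMessages(library(hemicam))
dir.create("results", showWarnings = FALSE)
set.seed(42)

fits <- list(
  KNT = list(data = synth_config(kind = "locked_titration", lobe = "N",
                                 conf = "T", sd = 0, seed = 1,
                                 ca_total = 10^seq(-6, -2.5, length.out = 12)),
             spec = list(KNT = list(start = 3e-5, lower = 1e-6, upper = 1e-3)),
             truth = 9.38e-5),
  Kd_Ng_TT = list(data = synth_config(condition = protocol_condition("Ng"),
                                      sd = 0, seed = 1,
                                      ca_total = 10^seq(-7, -3.5,
                                                        length.out = 10)),
                  spec = list(Kd_Ng_TT = list(start = 4e-6, lower = 1e-8,
                                              upper = 1e-4)),
                  truth = 1.2e-6),
  Kd_CaMKII_RR = list(data = synth_config(
    condition = protocol_condition("CaMKII"), sd = 0, seed = 1,
    ca_total = 10^seq(-7.5, -4, length.out = 10)),
    spec = list(Kd_CaMKII_RR = list(start = 1e-6, lower = 1e-9,
                                    upper = 1e-5)),
    truth = 1.1 / 2.87e6))

rec <- do.call(rbind, lapply(names(fits), function(nm) {
  f <- fit_least_squares(gen_titration(fits[[nm]]$data), fits[[nm]]$spec)
  data.frame(parameter = nm, truth = fits[[nm]]$truth,
             estimate = unname(f$estimates[1]),
             rel_error = abs(unname(f$estimates[1]) / fits[[nm]]$truth - 1))
}))
write.csv(rec, "results/fit_recovery.csv", row.names = FALSE)
print(rec)

ests <- t(vapply(1:12, function(s) {
  d <- gen_titration(synth_config(condition = protocol_condition("none"),
                                  sd = 0.02, seed = 900 + s,
                                  ca_total = 10^seq(-7.5, -3.5,
                                                    length.out = 15)))
  f <- fit_least_squares(d, list(cC = list(start = 2e-5, lower = 1e-7,
                                           upper = 1.1e-3),
                                 LC = list(start = 5e5, lower = 1e3,
                                           upper = 1e8)))
  log10(f$estimates)
}, numeric(2)))
colnames(ests) <- c("log10_cC", "log10_LC")
write.csv(as.data.frame(ests), "results/cc_lc_replicates.csv",
          row.names = FALSE)
lmfit <- lm(log10_LC ~ log10_cC, data = as.data.frame(ests))
message(sprintf("cC-LC replicate fits: correlation %.3f, slope %.2f",
                cor(ests[, 1], ests[, 2]), coef(lmfit)[2]))
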