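#!/usr/bin/env Rscript
# Calibration of the calcium spike: a single 8 ms, 1926-ion injection into
# the fully buffered, equilibrated model, and short trains at 1/5/10 Hz.
suppressPackageStartupMessages(library(hemicam))
dir.create("results", showWarnings = FALSE)

net <- build_network()
eq <- suppressWarnings(equilibrate(net))
message(sprintf("equilibrated basal free Ca: %.4g M", eq$state[["Ca"]]))

sim <- simulate_protocol(net, eq, spike_protocol(10, n_spikes = 1, record = 2),
                         spike_points = 17)
cal <- spike_calibration(sim)
message(sprintf("single spike: peak %.3g M, half-life %.1f ms",
                cal$peak, 1000 * cal$half_life))

traces <- do.call(rbind, lapply(c(1, 5, 10), function(f) {
  s <- simulate_protocol(net, eq, spike_protocol(f, n_spikes = 10, record = 12))
  data.frame(freq = f, time = s$time, ca = s$y[, "Ca"])
}))
write.csv(traces, "results/spike_trains_ca.csv", row.names = FALSE)
write.csv(data.frame(peak = cal$peak, basal = cal$basal,
                     half_life = cal$half_life),
          "results/spike_calibration.csv", row.names = FALSE)
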