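#!/usr/bin/env Rscript
# High-frequency stimulation: one continuous 300-spike 100 Hz train versus
# three 100-spike bursts separated by 10 min, and the fate of the
# phosphorylated CaMKII pool after stimulation ends.
suppressPackageStartupMessages(library(hemicam))
dir.create("results", showWarnings = FALSE)

net <- build_network()
eq <- suppressWarnings(equilibrate(net))
sp <- net$species
pcols <- sp$id[(sp$type == "cam" & sp$partner == "CaMKIIp") |
                 sp$id == "CaMKIIp"]
avog_vol <- 6.02214076e23 * net$config$volume

runs <- list(continuous = spike_protocol(100),
             bursts = spike_protocol(100, 100, n_bursts = 3))
rows <- lapply(names(runs), function(nm) {
  sim <- simulate_protocol(net, eq, runs[[nm]])
  tr <- activity_traces(sim)
  ph <- rowSums(sim$y[, pcols, drop = FALSE])
  late <- sim$time > max(sim$time) - 200
  write.csv(data.frame(time = sim$time, camkii = tr$camkii, can = tr$can,
                       ng = tr$ng, phospho_monomers = ph * avog_vol),
            sprintf("results/trace_100hz_%s.csv", nm), row.names = FALSE)
  data.frame(protocol = nm,
             area_camkii = activated_area(tr, "camkii"),
             area_can = activated_area(tr, "can"),
             phospho_plateau_monomers = mean(ph[late]) * avog_vol)
})
cmp <- do.call(rbind, rows)
write.csv(cmp, "results/burst_comparison.csv", row.names = FALSE)
print(cmp)
gain <- 100 * (cmp$area_camkii[2] - cmp$area_camkii[1]) / cmp$area_camkii[1]
message(sprintf("burst vs continuous CaMKII area: %+.1f%%", gain))
message(sprintf("sustained phospho pool (continuous): %.0f monomers",
                cmp$phospho_plateau_monomers[1]))
message("note: with the ring-combinatoric coefficient the phosphorylation")
message("layer is bistable and a 100 Hz train locks it on; see the methods")
message("vignette for the analysis of this regime")
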