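# shared fixtures: networks are cheap to build, equilibria are cached, and
# the heavy spike-train simulations used by several acceptance checks are
# memoized so each is run once per session.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

full_network <- function() cached("full_net", build_network())

full_equilibrium <- function()
  cached("full_eq", suppressWarnings(equilibrate(full_network())))

cam_only_network <- function() cached("cam_net", build_network(
  config = model_config(with_camkii = FALSE, with_can = FALSE,
                        with_ng = FALSE, phospho = FALSE)))

cam_only_equilibrium <- function()
  cached("cam_eq", suppressWarnings(equilibrate(cam_only_network())))

sim_100hz_continuous <- function() cached("sim100", simulate_protocol(
  full_network(), full_equilibrium(), spike_protocol(100)))

sim_100hz_bursts <- function() cached("sim100b", simulate_protocol(
  full_network(), full_equilibrium(),
  spike_protocol(100, 100, n_bursts = 3)))

cam_only_network_closed <- function() cached("cam_net_closed", build_network(
  config = model_config(with_camkii = FALSE, with_can = FALSE,
                        with_ng = FALSE, phospho = FALSE,
                        calcium_dynamics = FALSE)))

AVOG_VOL <- 6.02214076e23 * 1e-15
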