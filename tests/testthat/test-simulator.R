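# Spike protocols, equilibration and trajectory integration.

test_that("spike influx rate converts ions to a molar zero-order rate", {
  pr <- spike_protocol(10)
  expect_equal(spike_influx_rate(pr), 1926 / (6.02214076e23 * 1e-15 * 0.008))
  expect_equal(spike_influx_rate(pr), 4.0e-4, tolerance = 1e-3)
  expect_equal(spike_influx_rate(spike_protocol(10, ions = 0)), 0)
  expect_equal(spike_influx_rate(spike_protocol(10, ions = 2 * 1926)),
               2 * spike_influx_rate(pr))
})

test_that("protocol validation rejects overlapping spikes", {
  expect_error(spike_protocol(200, width = 0.008), "overlap")
  expect_error(spike_protocol(10, width = 0), "width > 0")
  pr <- spike_protocol(100, 100, n_bursts = 3, gap = 600)
  expect_length(pr$onsets, 300)
  # burst onsets: second burst starts one block-duration plus a gap later
  expect_equal(pr$onsets[101] - pr$onsets[1], (99 / 100 + 0.008) + 600)
})

test_that("equilibration with zero duration returns the initial state", {
  net <- cam_only_network()
  eq0 <- equilibrate(net, duration = 0)
  expect_identical(eq0$state, initial_state(net))
})

test_that("a zero-spike protocol leaves the trajectory flat", {
  net <- cam_only_network()
  eq <- cam_only_equilibrium()
  sim <- simulate_protocol(net, eq, spike_protocol(1, n_spikes = 0,
                                                   record = 50))
  drift <- apply(sim$y, 2, function(v) max(abs(v - v[1])))
  expect_lt(max(drift / pmax(abs(sim$y[1, ]), 1e-12)), 1e-5)
})

test_that("protein totals are conserved along a stimulated trajectory", {
  err <- conservation_error(sim_100hz_continuous())
  expect_lt(max(err), 1e-5)
  expect_named(err, c("CaM", "CaMKII", "CaN", "Ng"))
})

test_that("total calcium is bookkept across influx, pump and leak", {
  # closed system: total calcium is exactly conserved
  net <- cam_only_network_closed()
  y0 <- initial_state(net)
  y0[["Ca"]] <- 1e-5
  eq <- suppressWarnings(equilibrate(net, duration = 100, state = y0))
  species_totals <- hemicam:::species_composition(net)[, "Ca"]
  expect_lt(abs(sum(eq$state * species_totals) / 1e-5 - 1), 1e-6)
})

test_that("identical spike trains deliver identical total calcium at any frequency", {
  # fixed ions/spike: cumulative influx = n * ions / (N_A V), frequency-free
  for (f in c(0.5, 5, 50)) {
    pr <- spike_protocol(f, n_spikes = 300)
    influx_total <- spike_influx_rate(pr) * pr$width * pr$n_spikes
    expect_equal(influx_total, 300 * 1926 / (6.02214076e23 * 1e-15),
                 tolerance = 1e-12)
  }
})

test_that("activated areas are stable under solver tolerance refinement", {
  net <- cam_only_network()
  eq <- cam_only_equilibrium()
  pr <- spike_protocol(10, n_spikes = 20, record = 60)
  auc1 <- conformation_auc(simulate_protocol(net, eq, pr))
  auc2 <- conformation_auc(simulate_protocol(net, eq, pr,
                                             rtol = 1e-9, atol = 1e-15))
  expect_equal(auc1[["TR"]], auc2[["TR"]], tolerance = 1e-3)
})

test_that("stored-grid refinement leaves activated areas unchanged", {
  net <- full_network()
  eq <- full_equilibrium()
  pr <- spike_protocol(20, n_spikes = 20, record = 60)
  a1 <- activated_area(activity_traces(simulate_protocol(net, eq, pr)),
                       "camkii")
  a2 <- activated_area(activity_traces(
    simulate_protocol(net, eq, pr, spike_points = 18, inter_dt = 0.005,
                      tail_dt = 0.5)), "camkii")
  expect_equal(a1, a2, tolerance = 1e-3)
})
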