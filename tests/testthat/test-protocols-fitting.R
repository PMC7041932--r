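# Titration and chelation protocols, least-squares parameter recovery.

ti_grid <- 10^seq(-8, -3.5, length.out = 10)

test_that("partner-free titration coincides with the closed-form saturation", {
  p <- cam_params()
  ti <- cached("ti_none",
               simulate_titration(p, partner_params(),
                                  protocol_condition("none"), ti_grid, "C"))
  expect_true(all(diff(ti$ca_free) > 0))
  expect_true(all(diff(ti$sat) >= 0))
  expect_equal(ti$sat, mwc_saturation(p, "C", ti$ca_free), tolerance = 1e-5)
})

test_that("partners shift the apparent calcium affinity in opposite directions", {
  p <- cam_params(); pp <- partner_params()
  half <- function(d) stats::approx(d$sat, log10(d$ca_free), xout = 0.5)$y
  ti0 <- cached("ti_none",
                simulate_titration(p, pp, protocol_condition("none"),
                                   ti_grid, "C"))
  ti_ng <- cached("ti_ng",
                  simulate_titration(p, pp, protocol_condition("Ng"),
                                     ti_grid, "C"))
  ti_kk <- simulate_titration(p, pp, protocol_condition("CaMKII"),
                              ti_grid, "C")
  # the closed-state binder hinders calcium binding, open-state binders help
  expect_gt(half(ti_ng), half(ti0))
  expect_lt(half(ti_kk), half(ti0))
})

test_that("neurogranin speeds up calcium release from the C lobe", {
  p <- cam_params(); pp <- partner_params()
  times <- seq(0, 0.6, by = 0.004)
  ch0 <- simulate_chelation(p, pp, protocol_condition("none", CaM = 10e-6),
                            times = times)
  chN <- simulate_chelation(p, pp,
                            protocol_condition("Ng", CaM = 10e-6,
                                               partner_conc = 50e-6),
                            times = times)
  expect_lt(half_decay_time(chN), half_decay_time(ch0))
  # no chelator -> flat signal
  flat <- simulate_chelation(p, pp, protocol_condition("none", CaM = 10e-6),
                             chelator = chelator_spec("EGTA", conc = 0),
                             times = seq(0, 0.5, by = 0.05))
  expect_lt(max(abs(flat$signal - flat$signal[1])), 1e-6)
})

test_that("single-parameter fits recover generating values on noise-free data", {
  # closed-N-lobe titration anchors the T-state calcium affinity
  d_knt <- gen_titration(synth_config(kind = "locked_titration", lobe = "N",
                                      conf = "T", sd = 0, seed = 3,
                                      ca_total = 10^seq(-6, -2.5,
                                                        length.out = 12)))
  f <- fit_least_squares(d_knt, list(KNT = list(start = 3e-5, lower = 1e-6,
                                                upper = 1e-3)))
  expect_true(f$converged)
  expect_equal(f$estimates[["KNT"]], 9.38e-5, tolerance = 1e-3)

  # neurogranin affinity from the shifted C-lobe curve (network forward model)
  d_ng <- gen_titration(synth_config(condition = protocol_condition("Ng"),
                                     sd = 0, seed = 3,
                                     ca_total = 10^seq(-7, -3.5,
                                                       length.out = 10)))
  f2 <- fit_least_squares(d_ng, list(Kd_Ng_TT = list(start = 4e-6,
                                                     lower = 1e-8,
                                                     upper = 1e-4)))
  expect_equal(f2$estimates[["Kd_Ng_TT"]], 1.2e-6, tolerance = 1e-3)

  # CaMKII affinity from the left-shifted curve
  d_kk <- gen_titration(synth_config(condition = protocol_condition("CaMKII"),
                                     sd = 0, seed = 3,
                                     ca_total = 10^seq(-7.5, -4,
                                                       length.out = 10)))
  f3 <- fit_least_squares(d_kk, list(Kd_CaMKII_RR = list(start = 1e-6,
                                                         lower = 1e-9,
                                                         upper = 1e-5)))
  expect_equal(f3$estimates[["Kd_CaMKII_RR"]], 1.1 / 2.87e6, tolerance = 1e-3)
})

test_that("cC and LC are strongly anticorrelated across replicate fits", {
  ests <- vapply(1:10, function(s) {
    d <- gen_titration(synth_config(condition = protocol_condition("none"),
                                    sd = 0.02, seed = 500 + s,
                                    ca_total = 10^seq(-7.5, -3.5,
                                                      length.out = 15)))
    f <- fit_least_squares(d, list(cC = list(start = 2e-5, lower = 1e-7,
                                             upper = 1.1e-3),
                                   LC = list(start = 5e5, lower = 1e3,
                                             upper = 1e8)))
    log10(f$estimates)
  }, numeric(2))
  expect_lt(stats::cor(ests[1, ], ests[2, ]), -0.9)
})

test_that("a fit with all parameters fixed reports the forward residual", {
  d <- gen_titration(synth_config(kind = "locked_titration", lobe = "N",
                                  conf = "T", sd = 0.05, seed = 11,
                                  ca_total = 10^seq(-6, -3, length.out = 8)))
  f <- fit_least_squares(d, list())
  direct <- sqrt(sum((d$sat - forward_predict(cam_params(), partner_params(),
                                              d))^2))
  expect_equal(f$residual_norm, direct)
})
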