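# The allosteric parameterization and its closed-form oracles.

test_that("rate table reproduces the reference transition rates", {
  p <- cam_params()
  rtC <- build_rate_table(p, "C")
  rtN <- build_rate_table(p, "N")
  # one bound ion on the C lobe: symmetric sqrt(c) split of the shift
  expect_equal(rtC$k_TtoR[2], 4.47e7, tolerance = 1e-3)
  expect_equal(rtC$k_RtoT[2], 4.38e8, tolerance = 1e-3)
  # N lobe at zero calcium
  expect_equal(rtN$k_TtoR[1], 316227)
  expect_equal(rtN$k_RtoT[1], 316227 * 299)
  # off-rates follow kon * K * c, not the rounded printed value
  expect_equal(rtC$koff_R, 1.22e8 * 9.38e-5 * 5e-5)
  expect_equal(rtC$koff_R, 0.57218, tolerance = 1e-6)
})

test_that("rate table satisfies the thermodynamic invariants exactly", {
  p <- cam_params()
  for (lobe in c("N", "C")) {
    rt <- build_rate_table(p, lobe)
    # equilibrium shift: each bound ion multiplies K_open by 1/c
    ratio <- rt$k_TtoR / rt$k_RtoT
    expect_equal(ratio[1], 1 / rt$L)
    expect_equal(ratio[2] / ratio[1], 1 / rt$c)
    expect_equal(ratio[3] / ratio[2], 1 / rt$c)
    expect_equal(rt$koff_R, rt$koff_T * rt$c)
    # detailed balance around each bind-open-unbind-close cycle
    for (n in 1:2) {
      fwd <- rt$kon * rt$k_TtoR[n + 1] * rt$koff_R * rt$k_RtoT[n]
      bwd <- rt$koff_T * rt$k_RtoT[n + 1] * rt$kon * rt$k_TtoR[n]
      expect_equal(fwd, bwd)
    }
  }
})

test_that("parameter validation names the offending field", {
  expect_error(cam_params(LN = -1), "LN")
  expect_error(cam_params(cC = 1.5), "cC")
  expect_error(cam_params(bogus = 1), "unknown field")
  expect_error(partner_params(koff_CaN_Ca = c(1, 2, 3)), "koff_CaN_Ca")
  expect_error(partner_params(koff_CaMKIIp_RR = 20), "tighter")
})

test_that("closed-form open fraction has the right limits and shape", {
  p <- cam_params()
  expect_equal(mwc_open_fraction(p, "N", 0), 1 / (1 + 299))
  expect_equal(mwc_open_fraction(p, "C", 0), 1 / (1 + 195865))
  expect_gt(mwc_open_fraction(p, "C", 1), 0.999)
  ca <- 10^seq(-9, -2, length.out = 50)
  for (lobe in c("N", "C")) {
    f <- mwc_open_fraction(p, lobe, ca)
    expect_true(all(f >= 0 & f <= 1))
    expect_true(all(diff(f) >= 0))
  }
  expect_error(mwc_open_fraction(p, "N", -1e-9), ">= 0")
})

test_that("closed-form saturation has the right limits and shape", {
  p <- cam_params()
  expect_equal(mwc_saturation(p, "C", 0), 0)
  expect_equal(mwc_saturation(p, "N", 0), 0)
  expect_gt(mwc_saturation(p, "C", 1), 0.9999)
  ca <- 10^seq(-9, -2, length.out = 50)
  s <- mwc_saturation(p, "C", ca)
  expect_true(all(diff(s) >= 0))
  expect_true(all(s >= 0 & s <= 1))
})

test_that("partner-free network steady states match the closed forms", {
  p <- cam_params()
  net <- cam_only_network_closed()
  sp <- net$species
  cam <- sp$type == "cam"
  y0 <- initial_state(net)
  for (ca in 10^seq(-7.5, -3, length.out = 10)) {
    y <- y0
    y[["Ca"]] <- ca
    eq <- suppressWarnings(equilibrate(net, duration = 20000, state = y,
                                       rtol = 1e-10, atol = 1e-18))
    s <- eq$state
    free <- s[["Ca"]]
    openC <- sum(s[sp$id[cam & sp$confC == "R"]]) / net$config$CaM
    satC <- sum(s[sp$id[cam]] * sp$nC[cam]) / (2 * net$config$CaM)
    expect_equal(openC, mwc_open_fraction(p, "C", free), tolerance = 1e-6)
    expect_equal(satC, mwc_saturation(p, "C", free), tolerance = 1e-6)
    openN <- sum(s[sp$id[cam & sp$confN == "R"]]) / net$config$CaM
    satN <- sum(s[sp$id[cam]] * sp$nN[cam]) / (2 * net$config$CaM)
    expect_equal(openN, mwc_open_fraction(p, "N", free), tolerance = 1e-6)
    expect_equal(satN, mwc_saturation(p, "N", free), tolerance = 1e-6)
  }
})
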