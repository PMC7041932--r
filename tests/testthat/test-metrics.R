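# Activity traces, activated areas, conformation AUCs, BCM machinery.

fake_trace <- function(time, camkii, basal = 0) {
  tr <- data.frame(time = time, camkii = camkii)
  attr(tr, "basal") <- c(camkii = basal)
  class(tr) <- c("activity_trace", "data.frame")
  tr
}

test_that("activated area integrates excursions above basal", {
  # rectangular excursion of +0.5 /s lasting 100 s -> area 50
  tr <- fake_trace(time = c(0, 10, 10, 110, 110, 200),
                   camkii = c(0.1, 0.1, 0.6, 0.6, 0.1, 0.1), basal = 0.1)
  expect_equal(activated_area(tr, "camkii"), 50)
  # flat trace at basal -> 0
  flat <- fake_trace(seq(0, 100, 10), rep(0.3, 11), basal = 0.3)
  expect_equal(activated_area(flat, "camkii"), 0)
  # negative deviations are clipped by default, kept when clip = FALSE
  dip <- fake_trace(c(0, 50, 100), c(0.3, 0.1, 0.3), basal = 0.3)
  expect_equal(activated_area(dip, "camkii"), 0)
  expect_equal(activated_area(dip, "camkii", clip = FALSE), -10)
  expect_error(activated_area(tr, "can"), "can")
})

test_that("activity traces report fractions scaled by the catalytic constants", {
  sim <- sim_100hz_continuous()
  tr <- activity_traces(sim)
  expect_true(all(tr$camkii >= 0 & tr$camkii <= 2))
  expect_true(all(tr$can >= 0 & tr$can <= 0.5))
  expect_true(all(tr$ng >= 0 & tr$ng <= 1))
  basal <- attr(tr, "basal")
  expect_equal(tr$camkii[1], basal[["camkii"]], tolerance = 1e-6)
  # catalytic constants rescale linearly
  tr2 <- activity_traces(sim, kcat_camkii = 4)
  expect_equal(tr2$camkii, 2 * tr$camkii)
})

test_that("conformation AUCs obey the sum rule and classify bound species", {
  sim <- sim_100hz_continuous()
  auc <- conformation_auc(sim)
  expect_named(auc, c("RR", "RT", "TR", "TT"))
  # the four class fractions always sum to one, so the AUCs sum to zero
  expect_lt(abs(sum(auc)) / max(abs(auc)), 1e-6)
  # class fractions partition the calmodulin pool at every stored time
  # (compared within the trajectory: equilibration carries a ~1e-5 solver
  # offset against the nominal total)
  sp <- sim$network$species
  cam_ids <- sp$id[sp$type == "cam"]
  tot <- rowSums(sim$y[, cam_ids])
  expect_lt(max(tot) / min(tot) - 1, 1e-5)
  expect_equal(mean(tot), sim$network$config$CaM, tolerance = 1e-3)
})

test_that("BCM curve is the area difference and theta_m interpolates the crossing", {
  curve <- data.frame(freq = c(1, 5, 10, 30),
                      area_camkii = c(1, 2, 8, 30),
                      area_can = c(4, 6, 6, 5))
  curve$bcm <- curve$area_camkii - curve$area_can
  th <- theta_m(curve)
  expect_gt(th, 5); expect_lt(th, 10)
  # log-linear interpolation between 5 and 10 Hz where bcm goes -4 -> +2
  expect_equal(th, exp(log(5) + 4 / 6 * (log(10) - log(5))))
  # antisymmetry: swapping the areas flips the sign of the curve
  swapped <- transform(curve, bcm = area_can - area_camkii)
  expect_equal(swapped$bcm, -curve$bcm)
  flat <- data.frame(freq = c(1, 10), bcm = c(1, 2))
  expect_true(is.na(theta_m(flat)))
  expect_match(attr(theta_m(flat), "reason"), "sign change")
})

test_that("basal calcineurin activity is lower in the presence of neurogranin", {
  eq_ng <- full_equilibrium()
  net_ko <- build_network(config = model_config(with_ng = FALSE))
  eq_ko <- suppressWarnings(equilibrate(net_ko))
  bound_can <- function(net, st) {
    sp <- net$species
    sum(st[sp$id[sp$type == "cam" & sp$partner == "CaN"]]) / net$config$CaN
  }
  with_ng <- bound_can(full_network(), eq_ng$state)
  without <- bound_can(net_ko, eq_ko$state)
  expect_lt(with_ng, without)
})
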