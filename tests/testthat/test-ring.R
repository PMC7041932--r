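# CaMKII hexamer-ring combinatorics and the polynomial surrogate.

test_that("single-ring neighbour probability matches brute-force enumeration", {
  # independent oracle: place k actives in all C(6, k) position sets on a
  # 6-ring, average over active monomers the indicator of >= 1 active
  # neighbour
  brute <- function(k) {
    if (k == 0) return(0)
    sets <- utils::combn(6, k)
    mean(apply(sets, 2, function(pos) {
      act <- logical(6); act[pos] <- TRUE
      nb <- vapply(pos, function(i)
        act[(i %% 6) + 1] || act[((i - 2) %% 6) + 1], logical(1))
      mean(nb)
    }))
  }
  for (k in 0:6)
    expect_equal(ring_neighbor_prob_exact(k), brute(k), info = paste("k =", k))
  expect_equal(ring_neighbor_prob_exact(2), 0.4)
  expect_equal(ring_neighbor_prob_exact(1), 0)
  expect_equal(ring_neighbor_prob_exact(6), 1)
  expect_error(ring_neighbor_prob_exact(7), "0..6")
})

test_that("Monte-Carlo curve agrees with the hypergeometric expectation", {
  n <- 60
  reps <- 400
  curve <- build_neighbor_curve(n, n_reps = reps, seed = 99,
                                grid = seq(0, 1, by = 0.05))
  expected <- neighbor_prob_expected(curve$frac, n)
  interior <- curve$se > 0
  expect_true(all(abs(curve$prob - expected)[interior] <=
                    3 * curve$se[interior] + 1e-12))
  expect_equal(curve$prob[1], 0)
  expect_equal(curve$prob[nrow(curve)], 1)
  # reproducibility under the recorded seed
  again <- build_neighbor_curve(n, n_reps = reps, seed = 99,
                                grid = seq(0, 1, by = 0.05))
  expect_identical(curve$prob, again$prob)
  expect_error(build_neighbor_curve(100), "multiple of 6")
})

test_that("large systems approach the independent-labelling limit", {
  for (p in c(0.1, 0.5, 0.9))
    expect_equal(neighbor_prob_expected(p, 48174), 1 - (1 - p)^2,
                 tolerance = 1e-3)
})

test_that("degree-5 surrogate fits the expectation curve tightly", {
  curve <- neighbor_curve_expected(48174)
  sur <- fit_surrogate(curve)
  expect_lt(sur$max_residual, 0.02)
  expect_equal(eval_surrogate(sur, 1), 1, tolerance = 0.02)
  expect_lt(eval_surrogate(sur, 0), 0.01)
  mid <- eval_surrogate(sur, 0.5)
  expect_equal(mid, neighbor_prob_expected(0.5, 48174), tolerance = 0.02)
  # evaluations are clamped
  expect_warning(v <- eval_surrogate(sur, 1.2), "clamp")
  expect_lte(v, 1)
  # degenerate inputs
  zero <- fit_surrogate(data.frame(frac = seq(0, 1, 0.1), prob = 0))
  expect_equal(zero$coef, rep(0, 6))
  expect_error(fit_surrogate(data.frame(frac = 1, prob = 1)), "degenerate")
})

test_that("autophosphorylation multiplier has the stated limits", {
  sur <- default_surrogate()
  expect_lt(autophos_coefficient(0, sur), 0.01)
  expect_equal(autophos_coefficient(1, sur), 1, tolerance = 0.02)
  expect_equal(autophos_coefficient(0.5, sur),
               neighbor_prob_expected(0.5, 48174), tolerance = 0.02)
})

test_that("dephosphorylation flux follows Michaelis-Menten", {
  expect_equal(dephos_flux(0, 1e-5), 0)
  expect_equal(dephos_flux(1e-6, 2e-5), 0.8 * 1e-6 * 0.5)
  # saturation limit
  expect_equal(dephos_flux(1e-6, 1), 0.8 * 1e-6, tolerance = 1e-4)
  expect_error(dephos_flux(-1, 1e-5), ">= 0")
})
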