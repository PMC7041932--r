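#' Probability that an active monomer in a six-membered ring has an active
#' neighbour
#'
#' CaMKII subunits trans-autophosphorylate within hexamer rings: an active
#' (calmodulin-bound and/or phosphorylated) monomer can only be
#' phosphorylated if at least one of its two ring neighbours is also active.
#' For a ring carrying `k` active monomers with the other `k - 1` actives
#' placed uniformly among the 5 remaining positions, the probability that
#' the focal active monomer has at least one active neighbour is
#' `1 - choose(6 - k, 2) / choose(5, 2)`; by convention the value at
#' `k = 0` is 0 (there is no active monomer to phosphorylate).
#'
#' @param k number of active monomers in the hexamer, 0..6 (vectorized).
#' @return probability in \[0, 1\].
#' @examples
#' ring_neighbor_prob_exact(2)  # 0.4
#' @export
ring_neighbor_prob_exact <- function(k) {
  if (any(k != round(k)) || any(k < 0) || any(k > 6))
    stop("k must be an integer in 0..6")
  ifelse(k == 0, 0, 1 - choose(6 - k, 2) / choose(5, 2))
}

#' Exact expected neighbour probability under random placement
#'
#' For `m` active monomers distributed uniformly at random over
#' `n_monomers` positions partitioned into rings of six, the five ringmates
#' of a focal active monomer are a uniform 5-subset of the other
#' `n_monomers - 1` positions carrying `m - 1` actives. The expected
#' probability that the focal active monomer has an active neighbour is
#' therefore a hypergeometric average of [ring_neighbor_prob_exact()]. This
#' is the quantity the Monte-Carlo construction of [build_neighbor_curve()]
#' estimates; as `n_monomers` grows it tends to the independent-labelling
#' limit `1 - (1 - p)^2`.
#'
#' @param frac active fraction in \[0, 1\] (vectorized); the active count is
#'   `round(frac * n_monomers)`.
#' @param n_monomers total number of monomers (a multiple of 6).
#' @return expected neighbour probability in \[0, 1\].
#' @export
neighbor_prob_expected <- function(frac, n_monomers) {
  check_monomers(n_monomers)
  if (any(frac < 0 | frac > 1)) stop("active fraction must be in [0, 1]")
  vapply(frac, function(f) {
    m <- round(f * n_monomers)
    if (m == 0) return(0)
    j <- 0:5  # active ringmates of the focal active monomer
    w <- stats::dhyper(j, m - 1, n_monomers - m, 5)
    sum(w * ring_neighbor_prob_exact(j + 1))
  }, numeric(1))
}

#' Monte-Carlo neighbour-probability curve over active fractions
#'
#' Reproduces the stochastic construction of the autophosphorylation
#' coefficient: for each active fraction on a 1% grid, the corresponding
#' number of active monomers is distributed uniformly at random over the
#' rings `n_reps` times; each replicate tallies hexamer types (0..6 actives)
#' and weights monomers by [ring_neighbor_prob_exact()] for their ring type.
#' The mean over replicates is the curve value.
#'
#' @param n_monomers total monomers, divisible by 6.
#' @param n_reps independent random placements per grid point (>= 1).
#' @param seed integer seed; recorded in the result.
#' @param grid active-fraction grid (default 0 to 1 in 0.01 steps).
#' @return data.frame of class `neighbor_curve` with columns `frac`, `prob`,
#'   `se` (Monte-Carlo standard error), and attributes `n_monomers`,
#'   `n_reps`, `seed`.
#' @export
build_neighbor_curve <- function(n_monomers, n_reps = 1000, seed = 1234,
                                 grid = seq(0, 1, by = 0.01)) {
  check_monomers(n_monomers)
  if (n_reps < 1) stop("n_reps must be >= 1")
  n_rings <- n_monomers / 6
  ring_w <- ring_neighbor_prob_exact(0:6)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  est <- t(vapply(grid, function(f) {
    m <- round(f * n_monomers)
    if (m == 0) return(c(0, 0))
    if (m == n_monomers) return(c(1, 0))
    vals <- vapply(seq_len(n_reps), function(r) {
      pos <- sample.int(n_monomers, m)
      per_ring <- tabulate((pos - 1L) %/% 6L + 1L, nbins = n_rings)
      # mean neighbour probability over the m active monomers
      sum(per_ring * ring_w[per_ring + 1L]) / m
    }, numeric(1))
    c(mean(vals), stats::sd(vals) / sqrt(n_reps))
  }, numeric(2)))
  out <- data.frame(frac = grid, prob = est[, 1], se = est[, 2])
  attr(out, "n_monomers") <- n_monomers
  attr(out, "n_reps") <- n_reps
  attr(out, "seed") <- seed
  class(out) <- c("neighbor_curve", "data.frame")
  out
}

#' Exact expectation curve on the standard grid
#'
#' Deterministic counterpart of [build_neighbor_curve()]: the hypergeometric
#' expectation at every grid point. Used to build the default polynomial
#' surrogate without Monte-Carlo noise.
#'
#' @inheritParams build_neighbor_curve
#' @return data.frame of class `neighbor_curve` (with `se = 0`).
#' @export
neighbor_curve_expected <- function(n_monomers, grid = seq(0, 1, by = 0.01)) {
  check_monomers(n_monomers)
  out <- data.frame(frac = grid,
                    prob = neighbor_prob_expected(grid, n_monomers),
                    se = 0)
  attr(out, "n_monomers") <- n_monomers
  attr(out, "n_reps") <- 0
  class(out) <- c("neighbor_curve", "data.frame")
  out
}

#' Degree-5 polynomial surrogate of a neighbour-probability curve
#'
#' Least-squares polynomial of degree 5 fitted to a neighbour curve; the
#' surrogate is what the ODE rate law evaluates (cheaply, continuously) to
#' modulate the CaMKII autophosphorylation rate. Evaluations are clamped to
#' \[0, 1\].
#'
#' @param curve a `neighbor_curve` data.frame (columns `frac`, `prob`).
#' @return list of class `poly_surrogate` with `coef` (c0..c5, ascending
#'   powers) and `max_residual` on the fitting grid.
#' @export
fit_surrogate <- function(curve) {
  if (!all(c("frac", "prob") %in% names(curve)) || nrow(curve) < 6)
    stop("degenerate curve: need columns frac, prob and >= 6 points")
  if (all(curve$prob == 0)) {
    out <- list(coef = rep(0, 6), max_residual = 0)
    class(out) <- "poly_surrogate"
    return(out)
  }
  fit <- stats::lm(prob ~ frac + I(frac^2) + I(frac^3) + I(frac^4) + I(frac^5),
                   data = curve)
  cf <- unname(stats::coef(fit))
  out <- list(coef = cf,
              max_residual = max(abs(stats::resid(fit))))
  class(out) <- "poly_surrogate"
  out
}

#' Evaluate a polynomial surrogate (clamped to \[0, 1\])
#'
#' @param surrogate a `poly_surrogate`.
#' @param frac active fraction(s); values outside \[0, 1\] are clamped with
#'   a warning.
#' @export
eval_surrogate <- function(surrogate, frac) {
  stopifnot(inherits(surrogate, "poly_surrogate"))
  if (any(frac < 0 | frac > 1)) {
    warning("active fraction outside [0, 1]; clamping")
    frac <- pmin(pmax(frac, 0), 1)
  }
  v <- outer(frac, 0:5, `^`) %*% surrogate$coef
  pmin(pmax(as.vector(v), 0), 1)
}

#' Autophosphorylation rate multiplier at a given active fraction
#'
#' The dimensionless coefficient that scales the 6.3 /s base
#' trans-autophosphorylation rate of calmodulin-bound, non-phosphorylated
#' CaMKII monomers: the (surrogate) probability that an active monomer has
#' an active ring neighbour, evaluated at the current active fraction
#' (phosphorylated and/or calmodulin-bound monomers over total monomers).
#'
#' @param active_fraction current active fraction in \[0, 1\].
#' @param surrogate a `poly_surrogate`; default from [default_surrogate()].
#' @export
autophos_coefficient <- function(active_fraction,
                                 surrogate = default_surrogate()) {
  eval_surrogate(surrogate, active_fraction)
}

#' Default surrogate at a given monomer count
#'
#' Polynomial surrogate fitted to the exact hypergeometric expectation curve
#' at the system's monomer count (results cached per count).
#'
#' @param n_monomers monomer count; non-multiples of 6 are rounded to the
#'   nearest multiple (the ring partition needs complete hexamers).
#' @export
default_surrogate <- function(n_monomers = 48174) {
  n6 <- max(6L, as.integer(round(n_monomers / 6)) * 6L)
  key <- as.character(n6)
  if (is.null(.surrogate_cache[[key]]))
    .surrogate_cache[[key]] <- fit_surrogate(neighbor_curve_expected(n6))
  .surrogate_cache[[key]]
}

.surrogate_cache <- new.env(parent = emptyenv())

#' CaN-mediated dephosphorylation flux (Michaelis-Menten)
#'
#' Henry-Michaelis-Menten dephosphorylation of the pooled
#' phospho-CaMKII monomer concentration with total active (calmodulin-bound)
#' CaN as the enzyme: `v = kcat * E * S / (Km + S)`.
#'
#' @param active_CaN active calcineurin concentration (M).
#' @param CaMKIIp_total total phosphorylated monomer concentration (M).
#' @param kcat,Km catalytic constants (/s, M).
#' @return flux in M/s.
#' @export
dephos_flux <- function(active_CaN, CaMKIIp_total,
                        kcat = 0.8, Km = 2e-5) {
  if (any(active_CaN < 0) || any(CaMKIIp_total < 0))
    stop("concentrations must be >= 0")
  kcat * active_CaN * CaMKIIp_total / (Km + CaMKIIp_total)
}

check_monomers <- function(n_monomers) {
  if (length(n_monomers) != 1 || n_monomers < 6 || n_monomers %% 6 != 0)
    stop("n_monomers must be a positive multiple of 6")
  invisible(n_monomers)
}
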