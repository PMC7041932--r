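#' Transition and calcium dissociation rates of one calmodulin lobe
#'
#' Expands the lobe's allosteric constants into the six conformational
#' transition rates (per calcium occupancy n = 0, 1, 2) and the two
#' conformation-specific calcium off-rates. The split of the equilibrium
#' shift between the two directions is symmetric in sqrt(c):
#' `k_TtoR[n] = k0 * c^(-n/2)` and `k_RtoT[n] = k0 * L * c^(n/2)`, so that
#' `k_TtoR[n]/k_RtoT[n] = (1/L) * c^(-n)` — each bound ion multiplies the
#' open/closed equilibrium constant by 1/c while both directed rates move.
#' Off-rates follow from the conformation-independent `kon`:
#' `koff_T = kon * K_T`, `koff_R = koff_T * c`. These choices close every
#' bind-open-unbind-close thermodynamic cycle exactly (detailed balance).
#'
#' @param params a [cam_params()] object.
#' @param lobe `"N"` or `"C"`.
#' @return list of class `rate_table` with elements `k_TtoR`, `k_RtoT`
#'   (length-3 vectors for n = 0, 1, 2, in /s), `koff_T`, `koff_R` (/s),
#'   `kon` (/M/s), and the underlying `L`, `c`, `K_T`, `K_R`.
#' @examples
#' rt <- build_rate_table(cam_params(), "C")
#' rt$k_TtoR[2]  # ~4.47e7 /s at one bound ion
#' @export
build_rate_table <- function(params, lobe = c("N", "C")) {
  stopifnot(inherits(params, "cam_params"))
  lobe <- match.arg(lobe)
  L <- if (lobe == "N") params$LN else params$LC
  cc <- if (lobe == "N") params$cN else params$cC
  KT <- if (lobe == "N") params$KNT else params$KCT
  kon <- if (lobe == "N") params$kon_N else params$kon_C
  k0 <- if (lobe == "N") params$k0_N else params$k0_C
  n <- 0:2
  rt <- list(
    lobe = lobe,
    k_TtoR = k0 * cc^(-n / 2),
    k_RtoT = k0 * L * cc^(n / 2),
    koff_T = kon * KT,
    koff_R = kon * KT * cc,
    kon = kon,
    L = L, c = cc, K_T = KT, K_R = KT * cc
  )
  class(rt) <- "rate_table"
  rt
}

#' Closed-form open fraction of a lobe at fixed free calcium
#'
#' Two-state concerted closed form for a lobe with two identical calcium
#' sites: `fR = (1 + x_R)^2 / (L (1 + x_T)^2 + (1 + x_R)^2)` with
#' `x_S = Ca / K_S`. Serves as the analytic oracle for the steady state of
#' the generated partner-free reaction network.
#'
#' @param params a [cam_params()] object.
#' @param lobe `"N"` or `"C"`.
#' @param ca free calcium concentration (M), vectorized.
#' @return open-state fraction in \[0, 1\].
#' @export
mwc_open_fraction <- function(params, lobe = c("N", "C"), ca) {
  rt <- build_rate_table(params, lobe)
  if (any(ca < 0)) stop("free calcium concentration must be >= 0")
  xr <- ca / rt$K_R
  xt <- ca / rt$K_T
  (1 + xr)^2 / (rt$L * (1 + xt)^2 + (1 + xr)^2)
}

#' Closed-form fractional calcium saturation of a lobe
#'
#' Fraction of the lobe's two sites occupied at fixed free calcium under the
#' same two-state scheme as [mwc_open_fraction()]:
#' `Y = (x_R (1 + x_R) + L x_T (1 + x_T)) / ((1 + x_R)^2 + L (1 + x_T)^2)`.
#'
#' @inheritParams mwc_open_fraction
#' @return site saturation in \[0, 1\]; 0 at `ca = 0`.
#' @export
mwc_saturation <- function(params, lobe = c("N", "C"), ca) {
  rt <- build_rate_table(params, lobe)
  if (any(ca < 0)) stop("free calcium concentration must be >= 0")
  xr <- ca / rt$K_R
  xt <- ca / rt$K_T
  (xr * (1 + xr) + rt$L * xt * (1 + xt)) / ((1 + xr)^2 + rt$L * (1 + xt)^2)
}

#' Saturation of a conformation-locked lobe
#'
#' Simple one-site-class binding curve `x/(1+x)` with `x = Ca/K` for a lobe
#' held in a single conformation (e.g. the disulfide-crosslinked closed
#' N-lobe used when anchoring `KNT`).
#'
#' @inheritParams mwc_open_fraction
#' @param conf `"T"` or `"R"`, the conformation the lobe is locked in.
#' @export
locked_lobe_saturation <- function(params, lobe = c("N", "C"),
                                   conf = c("T", "R"), ca) {
  rt <- build_rate_table(params, lobe)
  conf <- match.arg(conf)
  if (any(ca < 0)) stop("free calcium concentration must be >= 0")
  K <- if (conf == "T") rt$K_T else rt$K_R
  x <- ca / K
  x / (1 + x)
}
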