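# Trajectory-derived plasticity metrics: activity traces, activated areas,
# conformation AUCs, BCM-like frequency-response curves.

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Enzyme activity traces of a simulated trajectory
#'
#' CaMKII activity is the fraction of monomers bound to calmodulin and/or
#' phosphorylated, times its catalytic constant towards GluR1; calcineurin
#' activity is the fraction bound to calmodulin times its catalytic
#' constant; neurogranin "activity" is its calmodulin-bound fraction
#' (dimensionless). Basal values are taken at the pre-stimulus equilibrium
#' the simulation started from.
#'
#' @param sim a `sim_output`.
#' @param kcat_camkii,kcat_can catalytic constants towards GluR1 (/s);
#'   defaults from the network's partner parameters.
#' @return data.frame of class `activity_trace` with columns `time`,
#'   `camkii`, `can`, `ng` and attribute `basal` (named vector).
#' @export
activity_traces <- function(sim, kcat_camkii = NULL, kcat_can = NULL) {
  net <- sim$network
  cfg <- net$config
  kcat_camkii <- kcat_camkii %||% net$partners$kcat_CaMKII_GluR1
  kcat_can <- kcat_can %||% net$partners$kcat_CaN_GluR1
  sp <- net$species
  need <- function(ok, what)
    if (!any(ok)) stop("missing species for trace: ", what)
  frac_of <- function(cols, total, y) {
    if (total <= 0) return(rep(0, NROW(y)))
    if (is.matrix(y)) rowSums(y[, cols, drop = FALSE]) / total
    else sum(y[cols]) / total
  }
  out <- data.frame(time = sim$time)
  basal <- c()
  if (cfg$with_camkii) {
    cols <- sp$id[(sp$type == "cam" &
                     sp$partner %in% c("CaMKII", "CaMKIIp")) |
                    sp$id == "CaMKIIp"]
    need(cols %in% colnames(sim$y), "CaMKII")
    out$camkii <- frac_of(cols, cfg$CaMKII, sim$y) * kcat_camkii
    basal["camkii"] <- frac_of(cols, cfg$CaMKII, sim$basal_state) * kcat_camkii
  }
  if (cfg$with_can) {
    cols <- sp$id[sp$type == "cam" & sp$partner == "CaN"]
    need(cols %in% colnames(sim$y), "CaN")
    out$can <- frac_of(cols, cfg$CaN, sim$y) * kcat_can
    basal["can"] <- frac_of(cols, cfg$CaN, sim$basal_state) * kcat_can
  }
  if (cfg$with_ng) {
    cols <- sp$id[sp$type == "cam" & sp$partner == "Ng"]
    out$ng <- frac_of(cols, cfg$Ng, sim$y)
    basal["ng"] <- frac_of(cols, cfg$Ng, sim$basal_state)
  }
  attr(out, "basal") <- basal
  class(out) <- c("activity_trace", "data.frame")
  out
}

#' Activated area of an enzyme activity trace
#'
#' Trapezoidal time integral of the activity excursion above its basal
#' value. Positive deviations only by default (activation above basal);
#' `clip = FALSE` integrates the signed deviation instead.
#'
#' @param trace an `activity_trace`.
#' @param component `"camkii"`, `"can"` or `"ng"`.
#' @param clip integrate only positive deviations (default TRUE).
#' @return area in (1/s) * s.
#' @export
activated_area <- function(trace, component = c("camkii", "can", "ng"),
                           clip = TRUE) {
  component <- match.arg(component)
  if (is.null(trace[[component]]))
    stop("trace does not contain component: ", component)
  v <- trace[[component]] - attr(trace, "basal")[[component]]
  if (clip) v <- pmax(v, 0)
  trapz(trace$time, v)
}

#' Signed AUCs of the four calmodulin conformation classes
#'
#' Classifies every calmodulin species into RR/RT/TR/TT by lobe conformation
#' (first letter: N lobe; partner-bound species count with their locked
#' conformations: RR-binders as RR, neurogranin-bound by the N-lobe state
#' with a closed C lobe) and integrates the class fraction minus its basal
#' value over the trajectory. The four class fractions sum to one at all
#' times, so the four AUCs sum to zero.
#'
#' @param sim a `sim_output`.
#' @return named numeric vector of signed AUCs (s) for RR, RT, TR, TT.
#' @export
conformation_auc <- function(sim) {
  net <- sim$network
  sp <- net$species
  cam <- sp$type == "cam"
  cls <- paste0(sp$confN[cam], sp$confC[cam])
  ids <- sp$id[cam]
  out <- c(RR = 0, RT = 0, TR = 0, TT = 0)
  for (g in names(out)) {
    cols <- ids[cls == g]
    f <- rowSums(sim$y[, cols, drop = FALSE]) / net$config$CaM
    f0 <- sum(sim$basal_state[cols]) / net$config$CaM
    out[g] <- trapz(sim$time, f - f0)
  }
  out
}

#' BCM-like frequency-response curve
#'
#' For each spike frequency, runs a full protocol from the supplied
#' equilibrium and computes the activated areas of CaMKII and calcineurin;
#' the BCM value is their difference (CaMKII minus CaN), negative in the
#' LTD-dominated regime and positive in the LTP-dominated one.
#'
#' @param network a `reaction_network`.
#' @param frequencies spike frequencies to scan (Hz).
#' @param equilibrium an `equilibrium` (computed once if missing).
#' @param n_spikes,record passed to [spike_protocol()].
#' @param ... further arguments to [simulate_protocol()].
#' @return data.frame of class `bcm_curve`: `freq`, `area_camkii`,
#'   `area_can`, `bcm`.
#' @export
bcm_curve <- function(network, frequencies, equilibrium = NULL,
                      n_spikes = 300, record = 3000, ...) {
  eq <- equilibrium %||% equilibrate(network)
  rows <- lapply(frequencies, function(f) {
    sim <- simulate_protocol(network, eq,
                             spike_protocol(f, n_spikes, record = record), ...)
    tr <- activity_traces(sim)
    a_k <- activated_area(tr, "camkii")
    a_n <- activated_area(tr, "can")
    data.frame(freq = f, area_camkii = a_k, area_can = a_n, bcm = a_k - a_n)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("bcm_curve", "data.frame")
  out
}

#' Crossover frequency of a BCM curve
#'
#' The LTD-to-LTP transition frequency: log-linear interpolation of the
#' first sign change from negative to positive BCM along increasing
#' frequency.
#'
#' @param curve a `bcm_curve` (or data.frame with `freq`, `bcm`).
#' @return frequency in Hz, or `NA` with a `reason` attribute when the
#'   curve has no negative-to-positive sign change.
#' @export
theta_m <- function(curve) {
  o <- order(curve$freq)
  f <- curve$freq[o]; b <- curve$bcm[o]
  for (i in seq_len(length(f) - 1)) {
    if (b[i] < 0 && b[i + 1] >= 0) {
      if (b[i + 1] == 0) return(f[i + 1])
      lf <- log(f[i]) + (0 - b[i]) * (log(f[i + 1]) - log(f[i])) /
        (b[i + 1] - b[i])
      return(exp(lf))
    }
  }
  out <- NA_real_
  attr(out, "reason") <- "no negative-to-positive sign change in scan"
  out
}
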