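# Bridging the generated network to the compiled right-hand side, plus a
# pure-R reference implementation of the identical rate laws used by the
# test suite to cross-check the compiled path.

pack_network <- function(network, influx = 0) {
  sp <- network$species
  rr <- network$reactions
  s <- network$special
  as0 <- function(x) as.integer((x %||% integer(0)) - 1L)
  list(ns = nrow(sp),
       r1 = as0(rr$r1),
       r2 = as.integer(ifelse(rr$r2 > 0, rr$r2 - 1L, -1L)),
       p1 = as.integer(ifelse(rr$p1 > 0, rr$p1 - 1L, -1L)),
       p2 = as.integer(ifelse(rr$p2 > 0, rr$p2 - 1L, -1L)),
       k = as.numeric(rr$k),
       ica = as.integer(s$ica - 1L),
       leak = as.numeric(s$leak),
       pump_vmax = as.numeric(s$pump_Vmax),
       pump_km = as.numeric(s$pump_Km),
       influx = as.numeric(influx),
       k_autop = as.numeric(s$k_autop %||% 0),
       auto_src = as0(s$auto_src),
       auto_dst = as0(s$auto_dst),
       active_idx = as0(s$active_idx),
       total_monomer = as.numeric(s$total_monomer %||% 1),
       poly = as.numeric(s$poly %||% rep(0, 6)),
       kcat_dep = as.numeric(s$kcat_dep %||% 0),
       km_dep = as.numeric(s$Km_dep %||% 1),
       enz_idx = as0(s$enz_idx),
       dep_src = as0(s$dep_src),
       dep_dst = as0(s$dep_dst))
}

use_network <- function(network, influx = 0) {
  invisible(.Call("hc_set_network", pack_network(network, influx),
                  PACKAGE = "hemicam"))
}

set_influx <- function(rate) {
  invisible(.Call("hc_set_influx", as.numeric(rate), PACKAGE = "hemicam"))
}

compiled_rhs <- function(y) {
  .Call("hc_rhs", as.numeric(y), PACKAGE = "hemicam")
}

#' Reference evaluation of the network's time derivative
#'
#' Pure-R implementation of exactly the rate laws the compiled solver core
#' integrates: mass action with up to two reactants, the calcium
#' leak/pump/influx terms, the surrogate-modulated autophosphorylation and
#' the pooled Michaelis-Menten dephosphorylation. Kept independent of the C
#' code so the two can be checked against each other.
#'
#' @param network a `reaction_network`.
#' @param y named or unnamed state vector (M), in species order.
#' @param influx current zero-order spike influx (M/s).
#' @return derivative vector (M/s).
#' @export
network_rhs <- function(network, y, influx = 0) {
  rr <- network$reactions
  s <- network$special
  yc <- as.numeric(y)
  ydot <- numeric(nrow(network$species))
  y2 <- ifelse(rr$r2 > 0, yc[pmax(rr$r2, 1)], 1)
  rates <- rr$k * yc[rr$r1] * y2
  for (j in seq_along(rates)) {
    ydot[rr$r1[j]] <- ydot[rr$r1[j]] - rates[j]
    if (rr$r2[j] > 0) ydot[rr$r2[j]] <- ydot[rr$r2[j]] - rates[j]
    if (rr$p1[j] > 0) ydot[rr$p1[j]] <- ydot[rr$p1[j]] + rates[j]
    if (rr$p2[j] > 0) ydot[rr$p2[j]] <- ydot[rr$p2[j]] + rates[j]
  }
  ca <- yc[s$ica]
  ydot[s$ica] <- ydot[s$ica] + s$leak + influx -
    s$pump_Vmax * ca / (s$pump_Km + ca)
  if (!is.null(s$k_autop) && s$k_autop > 0) {
    frac <- sum(yc[s$active_idx]) / s$total_monomer
    coef <- min(max(sum(s$poly * frac^(0:5)), 0), 1)
    fl <- s$k_autop * coef * yc[s$auto_src]
    for (i in seq_along(fl)) {
      ydot[s$auto_src[i]] <- ydot[s$auto_src[i]] - fl[i]
      ydot[s$auto_dst[i]] <- ydot[s$auto_dst[i]] + fl[i]
    }
  }
  if (!is.null(s$kcat_dep) && s$kcat_dep > 0) {
    E <- sum(yc[s$enz_idx])
    S <- sum(yc[s$dep_src])
    fl <- s$kcat_dep * E * yc[s$dep_src] / (s$Km_dep + S)
    for (i in seq_along(fl)) {
      ydot[s$dep_src[i]] <- ydot[s$dep_src[i]] - fl[i]
      ydot[s$dep_dst[i]] <- ydot[s$dep_dst[i]] + fl[i]
    }
  }
  ydot
}
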