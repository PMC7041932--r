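# Stiff integration of the generated network under spike-train protocols.

#' Calcium spike-train stimulation protocol
#'
#' Describes a train of square calcium injections: each spike delivers a
#' fixed number of ions as a zero-order influx over a fixed window. A
#' continuous train places spike k at `k / freq`; a burst structure groups
#' spikes into blocks separated by silent gaps.
#'
#' @param freq spike frequency within a train/burst (Hz).
#' @param n_spikes number of spikes (total, or per burst when `n_bursts > 1`).
#' @param width injection window per spike (s).
#' @param ions calcium ions injected per spike.
#' @param n_bursts number of bursts (1 = continuous train).
#' @param gap silent interval between bursts (s).
#' @param record recording window (s): simulations run to at least this
#'   time and at least 60 s past the last spike.
#' @return object of class `spike_protocol` with the spike onset times.
#' @examples
#' spike_protocol(100)                      # 300 spikes at 100 Hz
#' spike_protocol(100, 100, n_bursts = 3)   # 3 x 100-spike bursts, 10 min apart
#' @export
spike_protocol <- function(freq, n_spikes = 300, width = 0.008, ions = 1926,
                           n_bursts = 1, gap = 600, record = 3000) {
  if (n_spikes < 0 || n_bursts < 1 || width <= 0 || ions < 0)
    stop("invalid protocol: counts must be positive, width > 0")
  if (n_spikes > 0 && freq <= 0) stop("invalid protocol: freq must be > 0")
  if (n_spikes > 1 && freq * width >= 1)
    stop("invalid protocol: freq * width >= 1, spikes would overlap")
  onsets <- numeric(0)
  if (n_spikes > 0) {
    block <- (seq_len(n_spikes) - 1) / freq
    block_dur <- (n_spikes - 1) / freq + width
    onsets <- unlist(lapply(seq_len(n_bursts) - 1,
                            function(b) b * (block_dur + gap) + block))
  }
  out <- list(freq = freq, n_spikes = n_spikes, width = width, ions = ions,
              n_bursts = n_bursts, gap = gap, record = record,
              onsets = onsets)
  class(out) <- "spike_protocol"
  out
}

#' Zero-order influx rate of one spike
#'
#' Converts ions-per-spike into the molar zero-order rate active during the
#' injection window: `ions / (N_A * volume * width)`.
#'
#' @param protocol a [spike_protocol()].
#' @param volume compartment volume (L).
#' @return rate in M/s.
#' @examples
#' spike_influx_rate(spike_protocol(10))  # ~4.0e-4 M/s
#' @export
spike_influx_rate <- function(protocol, volume = 1e-15) {
  if (protocol$width <= 0) stop("invalid protocol: zero spike width")
  protocol$ions / (AVOGADRO * volume * protocol$width)
}

# BDF (vode, mf = 22) rather than lsoda: the network's fast conformational
# modes (~6e10 /s) defeat lsoda's stiff/non-stiff switching heuristic mid
# spike train, while plain BDF integrates it robustly. When the stepper
# stalls (MXSTEP) the driver re-initializes from the last accepted state; a
# fresh BDF start with a new step-size estimate routinely clears the sticky
# point.
ode_times <- function(y, times, rtol, atol, maxsteps = 100000,
                      max_restarts = 10) {
  tend <- times[length(times)]
  done <- NULL
  remaining <- times
  for (attempt in seq_len(max_restarts + 1)) {
    out <- suppressWarnings(
      deSolve::vode(y = y, times = remaining, func = "hc_derivs",
                    parms = numeric(0), dllname = "hemicam",
                    initfunc = "hc_initmod", mf = 22,
                    rtol = rtol, atol = atol, maxsteps = maxsteps))
    treach <- out[nrow(out), 1]
    if (abs(treach - tend) <= 1e-9 + 1e-9 * abs(tend))
      return(if (is.null(done)) out else rbind(done, out[-1, , drop = FALSE]))
    # stalled: keep completed rows, restart from the last accepted state
    y <- pmax(as.numeric(out[nrow(out), -1]), 0)
    done <- if (is.null(done)) out else rbind(done, out[-1, , drop = FALSE])
    remaining <- c(treach, remaining[remaining > treach])
  }
  stop(sprintf("solver failure: integration stopped at t = %.6g (target %.6g)",
               done[nrow(done), 1], tend))
}

#' Equilibrate a network to its pre-stimulus steady state
#'
#' Integrates the network without spikes for `duration` seconds (default
#' 5000 s) and returns the end state. The maximum relative time-derivative
#' at the end state is reported; a value above `tol` triggers a warning.
#'
#' @param network a `reaction_network`.
#' @param duration equilibration time (s).
#' @param state optional starting state (defaults to the built initial
#'   amounts).
#' @param rtol,atol solver tolerances.
#' @param tol convergence threshold on max |dy/dt| / max(|y|, floor). The
#'   default tolerates the residual relaxation of the sub-picomolar basal
#'   phospho-CaMKII pool, whose intrinsic timescale (1/koff ~ 3 h) exceeds
#'   any practical equilibration window.
#' @return list of class `equilibrium` with `state`, `deriv_norm`,
#'   `converged`.
#' @export
equilibrate <- function(network, duration = 5000, state = NULL,
                        rtol = 1e-8, atol = 1e-14, tol = 1e-4) {
  y0 <- state %||% initial_state(network)
  if (duration <= 0) {
    use_network(network, influx = 0)
    dy <- compiled_rhs(y0)
  } else {
    use_network(network, influx = 0)
    out <- ode_times(y0, c(0, duration / 10, duration), rtol, atol)
    yend <- out[nrow(out), -1]
    y0 <- stats::setNames(pmax(as.numeric(yend), 0), network$species$id)
    dy <- compiled_rhs(y0)
  }
  norm <- max(abs(dy) / pmax(abs(y0), 1e-12))
  if (duration > 0 && norm > tol)
    warning(sprintf("equilibration may be incomplete: derivative norm %.3g",
                    norm))
  res <- list(state = y0, deriv_norm = norm, converged = norm <= tol)
  class(res) <- "equilibrium"
  res
}

#' Simulate a spike-train protocol
#'
#' Integrates the network from an equilibrated state under the protocol's
#' event-gated zero-order influx. The solver restarts exactly at every
#' injection-window edge (the influx is constant within a segment, so the
#' stiff stepper never crosses a discontinuity). Output is stored on an
#' adaptive grid: dense inside and around spikes, coarser in long gaps and
#' along the post-train tail; metrics integrate on this stored grid.
#'
#' @param network a `reaction_network`.
#' @param state a state vector or an `equilibrium` object.
#' @param protocol a [spike_protocol()].
#' @param rtol,atol solver tolerances (the network is very stiff: lobe
#'   transition rates reach ~6e10 /s).
#' @param spike_points stored points per injection window.
#' @param inter_dt target output spacing between spikes (s).
#' @param tail_dt output spacing along the post-train tail (s).
#' @return object of class `sim_output`: `time`, `y` (time x species
#'   matrix), `protocol`, `basal_state`, `network`.
#' @export
simulate_protocol <- function(network, state, protocol,
                              rtol = 1e-8, atol = 1e-14,
                              spike_points = 9, inter_dt = 0.02,
                              tail_dt = 1) {
  if (inherits(state, "equilibrium")) state <- state$state
  sp_rate <- spike_influx_rate(protocol, network$config$volume)
  onsets <- protocol$onsets
  train_end <- if (length(onsets)) max(onsets) + protocol$width else 0
  t_end <- max(protocol$record, train_end + 60)

  # segment table: (t0, t1, influx)
  seg <- data.frame(t0 = numeric(0), t1 = numeric(0), influx = numeric(0))
  cur <- 0
  for (on in onsets) {
    if (on > cur) seg <- rbind(seg, data.frame(t0 = cur, t1 = on, influx = 0))
    seg <- rbind(seg, data.frame(t0 = on, t1 = on + protocol$width,
                                 influx = sp_rate))
    cur <- on + protocol$width
  }
  if (t_end > cur) seg <- rbind(seg, data.frame(t0 = cur, t1 = t_end, influx = 0))

  use_network(network, influx = 0)
  y <- as.numeric(state)
  times_out <- list(); states_out <- list()
  times_out[[1]] <- 0
  states_out[[1]] <- y
  for (i in seq_len(nrow(seg))) {
    dt <- seg$t1[i] - seg$t0[i]
    if (seg$influx[i] > 0) {
      npts <- spike_points
    } else if (i == nrow(seg)) {
      # tail: dense for the first 10 s, then tail_dt
      npts <- NA
    } else {
      npts <- min(max(ceiling(dt / inter_dt), 4), 40)
    }
    if (is.na(npts)) {
      brk <- min(seg$t0[i] + 10, seg$t1[i])
      tt <- unique(c(seq(seg$t0[i], brk, length.out = 201),
                     if (seg$t1[i] > brk)
                       seq(brk, seg$t1[i],
                           length.out = max(2, ceiling((seg$t1[i] - brk) / tail_dt)))))
    } else {
      tt <- seq(seg$t0[i], seg$t1[i], length.out = npts + 1)
    }
    set_influx(seg$influx[i])
    out <- ode_times(y, tt, rtol, atol)
    y <- as.numeric(out[nrow(out), -1])
    times_out[[i + 1]] <- out[-1, 1]
    states_out[[i + 1]] <- out[-1, -1, drop = FALSE]
  }
  set_influx(0)
  tvec <- unlist(times_out)
  ymat <- do.call(rbind, states_out)
  colnames(ymat) <- network$species$id
  neg <- min(ymat)
  if (neg < -1e-7)
    stop("negative concentration beyond tolerance: ", neg)
  ymat[ymat < 0] <- 0
  res <- list(time = tvec, y = ymat, protocol = protocol,
              basal_state = stats::setNames(as.numeric(state),
                                            network$species$id),
              network = network)
  class(res) <- "sim_output"
  res
}

#' @export
print.sim_output <- function(x, ...) {
  cat("sim_output:", length(x$time), "stored points over",
      round(max(x$time), 3), "s;", ncol(x$y), "species\n")
  invisible(x)
}

#' Peak and half-life of the free-calcium transient after a single spike
#'
#' @param sim a `sim_output` from a single-spike protocol.
#' @return list with `peak` (M), `basal` (M), `half_life` (s).
#' @export
spike_calibration <- function(sim) {
  ca <- sim$y[, "Ca"]
  basal <- sim$basal_state[["Ca"]]
  ipk <- which.max(ca)
  peak <- ca[ipk]
  target <- basal + (peak - basal) / 2
  after <- seq(ipk, length(ca))
  below <- after[which(ca[after] <= target)[1]]
  half <- if (is.na(below) || below == ipk) NA_real_ else {
    # linear interpolation between the bracketing stored points
    i1 <- below - 1; i2 <- below
    tfrac <- (ca[i1] - target) / (ca[i1] - ca[i2])
    sim$time[i1] + tfrac * (sim$time[i2] - sim$time[i1]) - sim$time[ipk]
  }
  list(peak = peak, basal = basal, half_life = half)
}

#' Conservation drift of the protein totals along a trajectory
#'
#' Total calmodulin, CaMKII (including phospho), calcineurin and neurogranin
#' are conserved by the reaction set; calcium is conserved only in closed
#' systems (no leak/pump/influx). Returns the maximum relative drift of each
#' applicable total over the stored trajectory.
#'
#' @param sim a `sim_output`.
#' @return named numeric vector of max |total(t)/total(0) - 1|.
#' @export
conservation_error <- function(sim) {
  net <- sim$network
  comp <- species_composition(net)
  groups <- c("CaM", "CaMKII", "CaN", "Ng")
  if (!net$config$calcium_dynamics) groups <- c(groups, "Ca")
  out <- c()
  for (g in groups) {
    w <- comp[, g]
    if (all(w == 0)) next
    tot <- as.numeric(sim$y %*% w)
    out[g] <- max(abs(tot / tot[1] - 1))
  }
  out
}
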