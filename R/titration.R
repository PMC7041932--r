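# Steady-state calcium titration and stopped-flow chelation protocols.
#
# Titrations scan a grid of *total* calcium in a closed system (no
# leak/pump/influx), equilibrate, and report lobe saturation against the
# resulting *free* calcium — the x-axis the fluorescence experiments report.
# Chelation protocols equilibrate a premix and then add an excess of a fast
# calcium chelator at t = 0, following the decay of lobe saturation (EGTA
# protocol) or the rise of chelator-bound calcium (quin-2 protocol).

#' Describe a titration/chelation condition
#'
#' @param partner `"none"`, `"Ng"`, `"CaMKII"`, `"CaMKIIp"` or `"CaN"`.
#' @param CaM total calmodulin (M).
#' @param partner_conc total partner concentration (M).
#' @return list of class `protocol_condition`.
#' @export
protocol_condition <- function(partner = c("none", "Ng", "CaMKII",
                                           "CaMKIIp", "CaN"),
                               CaM = 5e-6, partner_conc = 50e-6) {
  partner <- match.arg(partner)
  out <- list(partner = partner, CaM = CaM, partner_conc = partner_conc)
  class(out) <- "protocol_condition"
  out
}

#' Chelator kinetics presets
#'
#' The published protocols state chelator identity and concentration but not
#' kinetics; these literature-typical defaults (EGTA: slow association, Kd
#' 70 nM; quin-2: fast association, Kd 60 nM) are package assumptions and
#' can be overridden.
#'
#' @param name `"EGTA"` or `"quin2"`.
#' @param conc chelator concentration mixed in at t = 0 (M); defaults to
#'   the protocol-typical value (10 mM EGTA, 150 uM quin-2).
#' @param kon,Kd association rate (/M/s) and dissociation constant (M).
#' @export
chelator_spec <- function(name = c("EGTA", "quin2"), conc = NULL,
                          kon = NULL, Kd = NULL) {
  name <- match.arg(name)
  def <- switch(name,
                EGTA = list(conc = 1e-2, kon = 1.5e6, Kd = 70e-9),
                quin2 = list(conc = 150e-6, kon = 5e8, Kd = 60e-9))
  list(name = name, conc = conc %||% def$conc, kon = kon %||% def$kon,
       Kd = Kd %||% def$Kd)
}

titration_network <- function(params, partners, condition) {
  p <- condition$partner
  cfg <- model_config(
    CaM = condition$CaM,
    CaMKII = if (p %in% c("CaMKII", "CaMKIIp")) condition$partner_conc else 0,
    CaN = if (p == "CaN") condition$partner_conc else 0,
    Ng = if (p == "Ng") condition$partner_conc else 0,
    Ca = 0,
    with_camkii = p %in% c("CaMKII", "CaMKIIp"),
    with_can = p == "CaN",
    with_ng = p == "Ng",
    phospho = FALSE,
    calcium_dynamics = FALSE)
  build_network(params, partners, cfg)
}

lobe_saturation_of <- function(net, y, lobe = c("C", "N", "CaM")) {
  lobe <- match.arg(lobe)
  sp <- net$species
  cam <- sp$type == "cam"
  tot <- net$config$CaM
  nca <- switch(lobe,
                C = sp$nC[cam],
                N = sp$nN[cam],
                CaM = sp$nN[cam] + sp$nC[cam])
  sites <- if (lobe == "CaM") 4 else 2
  if (is.matrix(y)) as.numeric(y[, sp$id[cam], drop = FALSE] %*% nca) / (sites * tot)
  else sum(y[sp$id[cam]] * nca) / (sites * tot)
}

#' Steady-state calcium titration curve
#'
#' Scans a grid of total calcium, equilibrates the closed system at each
#' point, and reports lobe saturation against the steady-state free
#' calcium.
#'
#' @param params a [cam_params()].
#' @param partners a [partner_params()].
#' @param condition a [protocol_condition()].
#' @param ca_total total-calcium grid (M).
#' @param lobe `"C"`, `"N"` or `"CaM"` (whole-protein saturation).
#' @param equil_time equilibration time per grid point (s).
#' @return data.frame of class `titration_dataset` with columns `ca_total`,
#'   `ca_free`, `sat` and a logical `equilibrated` flag per point.
#' @export
simulate_titration <- function(params = cam_params(),
                               partners = partner_params(),
                               condition = protocol_condition(),
                               ca_total = 10^seq(-7.5, -3, length.out = 15),
                               lobe = "C", equil_time = 2000) {
  net <- titration_network(params, partners, condition)
  y0 <- initial_state(net)
  if (condition$partner == "CaMKIIp") {
    y0[["CaMKIIp"]] <- y0[["CaMKII"]]
    y0[["CaMKII"]] <- 0
  }
  rows <- lapply(ca_total, function(ca) {
    y <- y0
    y[["Ca"]] <- ca
    eq <- suppressWarnings(equilibrate(net, duration = equil_time, state = y))
    data.frame(ca_total = ca, ca_free = eq$state[["Ca"]],
               sat = lobe_saturation_of(net, eq$state, lobe),
               equilibrated = eq$converged)
  })
  out <- do.call(rbind, rows)
  attr(out, "condition") <- condition
  attr(out, "lobe") <- lobe
  class(out) <- c("titration_dataset", "data.frame")
  out
}

#' Stopped-flow chelation timecourse
#'
#' Equilibrates a premix of calmodulin, calcium and (optionally) a partner,
#' then adds the chelator instantaneously at t = 0 and follows the decay.
#'
#' @param params,partners,condition as in [simulate_titration()].
#' @param chelator a [chelator_spec()].
#' @param ca_total premixed total calcium (M).
#' @param times output time grid (s).
#' @param observable `"c_lobe_sat"` (EGTA protocol: C-lobe saturation) or
#'   `"chel_ca"` (quin-2 protocol: chelator-bound calcium normalized to the
#'   total calcium in the system).
#' @return data.frame of class `chelation_dataset` with `time`, `signal`.
#' @export
simulate_chelation <- function(params = cam_params(),
                               partners = partner_params(),
                               condition = protocol_condition(
                                 partner = "none", CaM = 10e-6),
                               chelator = chelator_spec("EGTA"),
                               ca_total = 100e-6,
                               times = c(seq(0, 1, by = 0.02),
                                         seq(1.1, 30, by = 0.1)),
                               observable = c("c_lobe_sat", "chel_ca")) {
  observable <- match.arg(observable)
  p <- condition$partner
  cfg <- model_config(
    CaM = condition$CaM,
    CaMKII = if (p %in% c("CaMKII", "CaMKIIp")) condition$partner_conc else 0,
    CaN = if (p == "CaN") condition$partner_conc else 0,
    Ng = if (p == "Ng") condition$partner_conc else 0,
    Ca = ca_total,
    with_camkii = p %in% c("CaMKII", "CaMKIIp"),
    with_can = p == "CaN",
    with_ng = p == "Ng",
    phospho = FALSE, calcium_dynamics = FALSE,
    chelator = chelator)
  net <- build_network(params, partners, cfg)
  y0 <- initial_state(net)
  if (p == "CaMKIIp") { y0[["CaMKIIp"]] <- y0[["CaMKII"]]; y0[["CaMKII"]] <- 0 }
  eq <- suppressWarnings(equilibrate(net, duration = 2000, state = y0))
  y <- eq$state
  if (chelator$conc > 0 &&
      chelator$Kd > ca_total * 0.1 && chelator$conc < ca_total)
    warning("chelator too weak for the premixed calcium: decay may be incomplete")
  y[["Chel"]] <- chelator$conc
  use_network(net, influx = 0)
  out <- ode_times(y, times, rtol = 1e-8, atol = 1e-14)
  ymat <- out[, -1, drop = FALSE]
  colnames(ymat) <- net$species$id
  signal <- if (observable == "c_lobe_sat") {
    lobe_saturation_of(net, ymat, "C")
  } else {
    ymat[, "ChelCa"] / ca_total
  }
  res <- data.frame(time = out[, 1], signal = signal)
  attr(res, "condition") <- condition
  attr(res, "chelator") <- chelator
  attr(res, "observable") <- observable
  class(res) <- c("chelation_dataset", "data.frame")
  res
}

#' Time to half-decay of a chelation signal
#' @param dataset a `chelation_dataset`.
#' @export
half_decay_time <- function(dataset) {
  s <- dataset$signal
  target <- s[1] / 2
  i <- which(s <= target)[1]
  if (is.na(i) || i == 1) return(NA_real_)
  tf <- (s[i - 1] - target) / (s[i - 1] - s[i])
  dataset$time[i - 1] + tf * (dataset$time[i] - dataset$time[i - 1])
}
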