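# Reaction-network generation from the allosteric parameterization.
#
# Species bookkeeping: each calmodulin conformer is one species, identified
# by per-lobe conformation (T/R) and per-lobe calcium occupancy (0..2), plus
# the bound partner if any. The two sites within a lobe are identical and
# lumped into occupancy counts with statistical factors (2*kon for 0->1,
# 2*koff for 2->1), which is exact for identical per-site affinities.

AVOGADRO <- 6.02214076e23

cam_id <- function(confN, nN, confC, nC, partner = "none") {
  base <- sprintf("CaM_%s%d%s%d", confN, nN, confC, nC)
  if (partner == "none") base else paste(base, partner, sep = "_")
}

#' Enumerate the species of the model
#'
#' Builds the full species table for a configuration: all calmodulin
#' conformers (free and partner-bound, subject to the conformational binding
#' rules), the five calcium-loading intermediates of calcineurin's B
#' subunit, the free partners, free calcium, and an optional chelator pair.
#'
#' Binding rules: CaMKII, phospho-CaMKII and (fully calcium-loaded)
#' calcineurin bind calmodulin with both lobes open (RR) and hold them open
#' while bound; neurogranin binds calmodulin whose C lobe is closed (N lobe
#' free, so RT and TT) and holds the C lobe closed.
#'
#' @param config a [model_config()].
#' @return data.frame with columns `id`, `type` (cam/can_ca/free/ca/chel),
#'   `partner`, `confN`, `nN`, `confC`, `nC`, `can_k`, `init` (M).
#' @examples
#' nrow(enumerate_species(model_config()))            # 90
#' nrow(enumerate_species(model_config(
#'   with_camkii = FALSE, with_can = FALSE, with_ng = FALSE,
#'   phospho = FALSE)))                               # 37
#' @export
enumerate_species <- function(config) {
  stopifnot(inherits(config, "model_config"))
  rows <- list()
  add <- function(id, type, init = 0, partner = NA, confN = NA, nN = NA,
                  confC = NA, nC = NA, can_k = NA) {
    rows[[length(rows) + 1]] <<- data.frame(
      id = id, type = type, partner = partner, confN = confN, nN = nN,
      confC = confC, nC = nC, can_k = can_k, init = init,
      stringsAsFactors = FALSE)
  }
  # free calmodulin conformers; everything starts in the closed apo state
  for (confN in c("T", "R")) for (nN in 0:2)
    for (confC in c("T", "R")) for (nC in 0:2)
      add(cam_id(confN, nN, confC, nC), "cam",
          init = if (confN == "T" && nN == 0 && confC == "T" && nC == 0)
            config$CaM else 0,
          partner = "none", confN = confN, nN = nN, confC = confC, nC = nC)
  # RR-binders lock both lobes open
  rr_partners <- c(if (config$with_camkii) c("CaMKII", "CaMKIIp"),
                   if (config$with_can) "CaN")
  for (p in rr_partners)
    for (nN in 0:2) for (nC in 0:2)
      add(cam_id("R", nN, "R", nC, p), "cam", partner = p,
          confN = "R", nN = nN, confC = "R", nC = nC)
  # neurogranin holds the C lobe closed; the N lobe stays free
  if (config$with_ng)
    for (confN in c("T", "R")) for (nN in 0:2) for (nC in 0:2)
      add(cam_id(confN, nN, "T", nC, "Ng"), "cam", partner = "Ng",
          confN = confN, nN = nN, confC = "T", nC = nC)
  # calcineurin B-subunit loading intermediates (CaN_Ca0 is free CaN)
  if (config$with_can)
    for (k in 0:4)
      add(sprintf("CaN_Ca%d", k), "can_ca",
          init = if (k == 0) config$CaN else 0, can_k = k)
  if (config$with_camkii) {
    add("CaMKII", "free", init = config$CaMKII)
    add("CaMKIIp", "free")
  }
  if (config$with_ng) add("Ng", "free", init = config$Ng)
  add("Ca", "ca", init = config$Ca)
  if (!is.null(config$chelator)) {
    add("Chel", "chel", init = 0)
    add("ChelCa", "chel", init = 0)
  }
  sp <- do.call(rbind, rows)
  stopifnot(!anyDuplicated(sp$id), all(sp$init >= 0))
  rownames(sp) <- NULL
  sp
}

#' Build the full reaction network
#'
#' Compiles the allosteric and partner parameters plus a configuration into
#' the enumerated mass-action network: calcium binding/unbinding on every
#' lobe of every species (with statistical factors and conformation-specific
#' off-rates), T/R transitions for every lobe not conformation-locked by a
#' bound partner, conformation-selective partner association (same Kd at
#' every calcium occupancy), sequential calcium loading of calcineurin's B
#' subunit, the calcium leak/pump/spike-influx subsystem, and the CaMKII
#' phosphorylation layer (ring-surrogate-modulated autophosphorylation and
#' pooled Michaelis-Menten dephosphorylation by active calcineurin).
#'
#' @param params a [cam_params()].
#' @param partners a [partner_params()].
#' @param config a [model_config()].
#' @return object of class `reaction_network`: list with `species`,
#'   `reactions` (mass-action table), `special` (non-mass-action fluxes and
#'   the phosphorylation wiring) and the inputs.
#' @export
build_network <- function(params = cam_params(),
                          partners = partner_params(),
                          config = model_config()) {
  stopifnot(inherits(params, "cam_params"),
            inherits(partners, "partner_params"))
  sp <- enumerate_species(config)
  idx <- function(id) {
    i <- match(id, sp$id)
    if (any(is.na(i))) stop("internal: unknown species ", id[is.na(i)][1])
    i
  }
  rtN <- build_rate_table(params, "N")
  rtC <- build_rate_table(params, "C")

  rx <- list()
  add_rx <- function(kind, k, r1, r2 = 0L, p1 = 0L, p2 = 0L) {
    rx[[length(rx) + 1]] <<- data.frame(kind = kind, k = k,
                                        r1 = r1, r2 = r2, p1 = p1, p2 = p2,
                                        stringsAsFactors = FALSE)
  }
  ica <- idx("Ca")
  cam <- sp[sp$type == "cam", ]

  lock_state <- function(partner) switch(partner,
    none = c(N = FALSE, C = FALSE),
    CaMKII = , CaMKIIp = , CaN = c(N = TRUE, C = TRUE),
    Ng = c(N = FALSE, C = TRUE))

  for (i in seq_len(nrow(cam))) {
    s <- cam[i, ]
    si <- idx(s$id)
    locked <- lock_state(s$partner)
    for (lobe in c("N", "C")) {
      rt <- if (lobe == "N") rtN else rtC
      conf <- if (lobe == "N") s$confN else s$confC
      n <- if (lobe == "N") s$nN else s$nC
      koff <- if (conf == "T") rt$koff_T else rt$koff_R
      # calcium binding (n -> n+1) and release generated from the lower state
      if (n < 2) {
        up <- s
        if (lobe == "N") up$nN <- n + 1 else up$nC <- n + 1
        ui <- idx(cam_id(up$confN, up$nN, up$confC, up$nC, up$partner))
        add_rx("ca_bind", (2 - n) * rt$kon, r1 = si, r2 = ica, p1 = ui)
        add_rx("ca_unbind", (n + 1) * koff, r1 = ui, p1 = si, p2 = ica)
      }
      # conformational transition for unlocked lobes, generated from T side
      if (!locked[[lobe]] && conf == "T") {
        op <- s
        if (lobe == "N") op$confN <- "R" else op$confC <- "R"
        oi <- idx(cam_id(op$confN, op$nN, op$confC, op$nC, op$partner))
        add_rx("conf_open", rt$k_TtoR[n + 1], r1 = si, p1 = oi)
        add_rx("conf_close", rt$k_RtoT[n + 1], r1 = oi, p1 = si)
      }
    }
  }

  # partner association/dissociation (same Kd at every calcium occupancy)
  bind_partner <- function(partner, free_id, kon, koff_fun) {
    tgt <- if (partner == "Ng") cam[cam$partner == "none" & cam$confC == "T", ]
           else cam[cam$partner == "none" & cam$confN == "R" & cam$confC == "R", ]
    for (i in seq_len(nrow(tgt))) {
      s <- tgt[i, ]
      ci <- idx(cam_id(s$confN, s$nN, s$confC, s$nC, partner))
      add_rx("partner_on", kon, r1 = idx(s$id), r2 = idx(free_id), p1 = ci)
      add_rx("partner_off", koff_fun(s), r1 = ci, p1 = idx(s$id),
             p2 = idx(free_id))
    }
  }
  if (config$with_camkii) {
    bind_partner("CaMKII", "CaMKII", partners$kon_CaMKII_RR,
                 function(s) partners$koff_CaMKII_RR)
    bind_partner("CaMKIIp", "CaMKIIp", partners$kon_CaMKIIp_RR,
                 function(s) partners$koff_CaMKIIp_RR)
  }
  if (config$with_can) {
    bind_partner("CaN", "CaN_Ca4", partners$kon_CaN_RR,
                 function(s) partners$Kd_CaN_RR * partners$kon_CaN_RR)
    for (k in 0:3)
      add_rx("can_load", partners$kon_CaN_Ca,
             r1 = idx(sprintf("CaN_Ca%d", k)), r2 = ica,
             p1 = idx(sprintf("CaN_Ca%d", k + 1)))
    for (k in 1:4)
      add_rx("can_unload", partners$koff_CaN_Ca[k],
             r1 = idx(sprintf("CaN_Ca%d", k)),
             p1 = idx(sprintf("CaN_Ca%d", k - 1)), p2 = ica)
  }
  if (config$with_ng)
    bind_partner("Ng", "Ng", partners$kon_Ng,
                 function(s) partners$kon_Ng * partners$Kd_Ng_TT *
                   (if (s$confN == "R") params$e else 1))
  if (!is.null(config$chelator)) {
    ch <- config$chelator
    add_rx("chel_on", ch$kon, r1 = idx("Chel"), r2 = ica, p1 = idx("ChelCa"))
    add_rx("chel_off", ch$kon * ch$Kd, r1 = idx("ChelCa"),
           p1 = idx("Chel"), p2 = ica)
  }
  reactions <- do.call(rbind, rx)
  rownames(reactions) <- NULL

  # --- non-mass-action layer -------------------------------------------
  special <- list(ica = ica,
                  leak = if (config$calcium_dynamics) config$leak else 0,
                  pump_Vmax = if (config$calcium_dynamics) config$pump_Vmax else 0,
                  pump_Km = config$pump_Km,
                  influx = 0)
  if (config$phospho) {
    n_monomers <- round(config$CaMKII * AVOGADRO * config$volume)
    surro <- config$surrogate %||% default_surrogate(n_monomers)
    kcid <- function(p) vapply(0:8, function(j)
      cam_id("R", j %/% 3, "R", j %% 3, p), character(1))
    src <- idx(kcid("CaMKII"))
    dst <- idx(kcid("CaMKIIp"))
    special$k_autop <- partners$k_autop
    special$auto_src <- src
    special$auto_dst <- dst
    special$active_idx <- c(src, dst, idx("CaMKIIp"))
    special$total_monomer <- config$CaMKII
    special$poly <- surro$coef
    special$n_monomers <- n_monomers
    if (config$with_can) {
      special$kcat_dep <- partners$kcat_CaN_CaMKIIp
      special$Km_dep <- partners$Km_CaN_CaMKIIp
      special$enz_idx <- idx(kcid("CaN"))
      special$dep_src <- c(dst, idx("CaMKIIp"))
      special$dep_dst <- c(src, idx("CaMKII"))
    }
  }

  net <- list(species = sp, reactions = reactions, special = special,
              params = params, partners = partners, config = config)
  class(net) <- "reaction_network"
  check_mass_balance(net)
  net
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("reaction_network:", nrow(x$species), "species,",
      nrow(x$reactions), "mass-action reactions\n")
  cat("  partners:",
      paste(c("CaMKII", "CaN", "Ng")[c(x$config$with_camkii,
                                       x$config$with_can, x$config$with_ng)],
            collapse = ", "), "\n")
  invisible(x)
}

# Elemental composition per species: counts of calcium ions and of each
# protein unit. Used for the builder's mass-balance self-check and for the
# conservation groups the tests assert along trajectories.
species_composition <- function(net) {
  sp <- net$species
  comp <- matrix(0, nrow(sp), 6,
                 dimnames = list(sp$id,
                                 c("Ca", "CaM", "CaMKII", "CaN", "Ng", "Chel")))
  for (i in seq_len(nrow(sp))) {
    s <- sp[i, ]
    if (s$type == "cam") {
      comp[i, "CaM"] <- 1
      comp[i, "Ca"] <- s$nN + s$nC
      if (s$partner == "CaMKII" || s$partner == "CaMKIIp")
        comp[i, "CaMKII"] <- 1
      if (s$partner == "CaN") { comp[i, "CaN"] <- 1; comp[i, "Ca"] <- comp[i, "Ca"] + 4 }
      if (s$partner == "Ng") comp[i, "Ng"] <- 1
    } else if (s$type == "can_ca") {
      comp[i, "CaN"] <- 1; comp[i, "Ca"] <- s$can_k
    } else if (s$id == "CaMKII" || s$id == "CaMKIIp") {
      comp[i, "CaMKII"] <- 1
    } else if (s$id == "Ng") {
      comp[i, "Ng"] <- 1
    } else if (s$id == "Ca") {
      comp[i, "Ca"] <- 1
    } else if (s$id == "Chel") {
      comp[i, "Chel"] <- 1
    } else if (s$id == "ChelCa") {
      comp[i, "Chel"] <- 1; comp[i, "Ca"] <- 1
    }
  }
  comp
}

check_mass_balance <- function(net) {
  comp <- species_composition(net)
  rr <- net$reactions
  for (j in seq_len(nrow(rr))) {
    lhs <- comp[rr$r1[j], ] + (if (rr$r2[j] > 0) comp[rr$r2[j], ] else 0)
    rhs <- (if (rr$p1[j] > 0) comp[rr$p1[j], ] else 0) +
           (if (rr$p2[j] > 0) comp[rr$p2[j], ] else 0)
    if (any(lhs != rhs))
      stop("builder invariant violated: reaction ", j, " (", rr$kind[j],
           ") is not mass balanced")
  }
  invisible(TRUE)
}

#' Initial state vector of a network
#' @param network a `reaction_network`.
#' @export
initial_state <- function(network) {
  stats::setNames(network$species$init, network$species$id)
}

#' Thermodynamic self-check: detailed balance over conformational cycles
#'
#' Enumerates every bind-calcium / open / unbind-calcium / close four-cycle
#' in the calmodulin subgraph (including the N lobe of neurogranin-bound
#' species) and reports the maximum absolute log ratio of clockwise to
#' counterclockwise rate products. For an equilibrium subnetwork this must
#' vanish; the leak/pump/influx and phosphorylation layers are excluded by
#' construction (they are not part of any such cycle).
#'
#' @param network a `reaction_network`.
#' @return list with `max_log_ratio`, `n_cycles`, and the per-cycle table.
#' @export
validate_detailed_balance <- function(network) {
  rr <- network$reactions
  sp <- network$species
  key <- function(r1, r2, p1, p2) paste(r1, r2, p1, p2, sep = "|")
  kmap <- stats::setNames(rr$k, key(rr$r1, rr$r2, rr$p1, rr$p2))
  getk <- function(r1, r2 = 0, p1 = 0, p2 = 0) {
    v <- kmap[[key(r1, r2, p1, p2)]]
    if (is.null(v)) NA_real_ else v
  }
  ica <- network$special$ica
  cam <- sp[sp$type == "cam", ]
  logs <- c(); labs <- c()
  for (i in seq_len(nrow(cam))) {
    s <- cam[i, ]
    for (lobe in c("N", "C")) {
      conf <- if (lobe == "N") s$confN else s$confC
      n <- if (lobe == "N") s$nN else s$nC
      if (conf != "T" || n >= 2) next
      locked <- if (s$partner %in% c("CaMKII", "CaMKIIp", "CaN")) TRUE
                else if (s$partner == "Ng" && lobe == "C") TRUE else FALSE
      if (locked) next
      mk <- function(conf, nn) {
        x <- s
        if (lobe == "N") { x$confN <- conf; x$nN <- nn }
        else { x$confC <- conf; x$nC <- nn }
        match(cam_id(x$confN, x$nN, x$confC, x$nC, x$partner), sp$id)
      }
      A <- mk("T", n); B <- mk("T", n + 1); C <- mk("R", n + 1); D <- mk("R", n)
      fwd <- c(getk(A, ica, B), getk(B, 0, C), getk(C, 0, D, ica), getk(D, 0, A))
      bwd <- c(getk(B, 0, A, ica), getk(C, 0, B), getk(D, ica, C), getk(A, 0, D))
      if (any(is.na(fwd)) || any(is.na(bwd))) next
      logs <- c(logs, sum(log(fwd)) - sum(log(bwd)))
      labs <- c(labs, sprintf("%s:%s:n%d", s$id, lobe, n))
    }
  }
  list(max_log_ratio = if (length(logs)) max(abs(logs)) else 0,
       n_cycles = length(logs),
       cycles = data.frame(cycle = labs, log_ratio = logs))
}
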