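#' Allosteric parameters of the two calmodulin lobes
#'
#' Returns the thermodynamic and kinetic constants describing the
#' hemiconcerted two-state behaviour of calmodulin: each lobe (N, C)
#' switches between a closed (T) and an open (R) conformation, binding two
#' calcium ions with identical per-site affinities that depend on the
#' conformation only.
#'
#' The defaults are the model's reference parameter set. `L` is the
#' allosteric constant \[T\]/\[R\] of a lobe at zero calcium; `c = K_R/K_T`
#' is the ratio of open- to closed-state calcium dissociation constants
#' (c < 1: calcium favours the open state); `K_T` the per-site dissociation
#' constant of the closed lobe (M); `kon` the conformation-independent
#' per-site calcium association rate (/M/s); `k0` the T->R base transition
#' rate at zero calcium (/s); `e` the ratio of neurogranin affinities for
#' RT vs TT calmodulin (1: neurogranin is blind to the N-lobe state).
#'
#' @param ... named overrides of any default value.
#' @return A list of class `cam_params`.
#' @examples
#' p <- cam_params()
#' p$LC
#' @export
cam_params <- function(...) {
  p <- list(
    LN = 299, LC = 195865,
    cN = 0.01, cC = 5e-5,
    KNT = 9.38e-5, KCT = 9.38e-5,
    kon_N = 1.22e10, kon_C = 1.22e8,
    k0_N = 316227, k0_C = 316227,
    e = 1
  )
  p <- modify_named(p, list(...), "cam_params")
  class(p) <- "cam_params"
  validate_cam_params(p)
  p
}

#' Kinetic parameters of the calmodulin binding partners
#'
#' Association/dissociation constants of CaMKII, phospho-CaMKII (CaMKIIp),
#' calcineurin (CaN) and neurogranin (Ng) for their preferred calmodulin
#' conformation, the four sequential calcium loading steps of the CaN B
#' subunit, and the catalytic constants of the phosphorylation layer.
#' `Kd = koff/kon` throughout.
#'
#' @param ... named overrides of any default value.
#' @return A list of class `partner_params`.
#' @export
partner_params <- function(...) {
  p <- list(
    kon_CaMKII_RR = 2.87e6, koff_CaMKII_RR = 1.1,
    kon_CaMKIIp_RR = 3.85e7, koff_CaMKIIp_RR = 8.7e-5,
    kon_CaN_RR = 2.3e7, Kd_CaN_RR = 3.26e-9,
    kon_Ng = 1e14, Kd_Ng_TT = 1.2e-6,
    kon_CaN_Ca = 2e7,
    koff_CaN_Ca = c(0.0092, 0.0312, 0.352, 0.9),
    k_autop = 6.3,
    kcat_CaN_CaMKIIp = 0.8, Km_CaN_CaMKIIp = 2e-5,
    kcat_CaMKII_GluR1 = 2, kcat_CaN_GluR1 = 0.5
  )
  p <- modify_named(p, list(...), "partner_params")
  class(p) <- "partner_params"
  validate_partner_params(p)
  p
}

#' Model configuration: concentrations, partner presence, calcium handling
#'
#' @param CaM,CaMKII,CaN,Ng total protein concentrations (M).
#' @param Ca initial free calcium concentration (M).
#' @param with_camkii,with_can,with_ng logical; include the partner and its
#'   calmodulin-bound species. A knocked-out partner is removed from the
#'   species list entirely.
#' @param phospho logical; include CaMKII autophosphorylation and its
#'   CaN-mediated dephosphorylation.
#' @param calcium_dynamics logical; include the constant calcium leak, the
#'   Michaelis-Menten pump and the gateable spike influx. Turn off for
#'   closed-system titration/chelation protocols.
#' @param leak zero-order calcium influx (M/s).
#' @param pump_Vmax,pump_Km Michaelis-Menten calcium pump parameters (M/s, M).
#' @param volume compartment volume (L), used to convert ion counts.
#' @param chelator optional list(conc, kon, Kd) adding a single calcium
#'   chelator species (used by the chelation protocols).
#' @param surrogate polynomial surrogate for the ring neighbour probability
#'   (see [fit_surrogate()]); `NULL` uses the default built from the exact
#'   expectation curve at the monomer count implied by `CaMKII` and `volume`.
#' @return A list of class `model_config`.
#' @export
model_config <- function(CaM = 4e-5, CaMKII = 8e-5, CaN = 8e-6, Ng = 4e-5,
                         Ca = 8e-8,
                         with_camkii = TRUE, with_can = TRUE, with_ng = TRUE,
                         phospho = TRUE,
                         calcium_dynamics = TRUE,
                         leak = 3.85e-6, pump_Vmax = 1e-4, pump_Km = 2e-6,
                         volume = 1e-15,
                         chelator = NULL,
                         surrogate = NULL) {
  if (phospho && !with_camkii)
    stop("configuration error: phosphorylation requested with CaMKII absent")
  if (phospho && !with_can)
    message("note: phosphorylation with CaN absent: no dephosphorylation flux")
  cfg <- list(CaM = CaM, CaMKII = CaMKII, CaN = CaN, Ng = Ng, Ca = Ca,
              with_camkii = with_camkii, with_can = with_can, with_ng = with_ng,
              phospho = phospho, calcium_dynamics = calcium_dynamics,
              leak = leak, pump_Vmax = pump_Vmax, pump_Km = pump_Km,
              volume = volume, chelator = chelator, surrogate = surrogate)
  for (f in c("CaM", "CaMKII", "CaN", "Ng", "Ca", "leak", "pump_Vmax",
              "pump_Km", "volume"))
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 0 ||
        !is.finite(cfg[[f]]))
      stop("invalid configuration field: ", f)
  class(cfg) <- "model_config"
  cfg
}

#' Read a parameter configuration from a YAML file
#'
#' The file may carry three top-level keys, `allosteric`, `partners` and
#' `model`, each a mapping of the symbols accepted by [cam_params()],
#' [partner_params()] and [model_config()]. Missing keys fall back to the
#' defaults, so a file carrying only the constants being varied is valid.
#'
#' @param path path to a YAML file.
#' @return list with elements `params`, `partners`, `config`.
#' @export
read_model_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  al <- doc$allosteric %||% list()
  pa <- doc$partners %||% list()
  mo <- doc$model %||% list()
  if (!is.null(pa$koff_CaN_Ca)) pa$koff_CaN_Ca <- as.numeric(pa$koff_CaN_Ca)
  list(params = do.call(cam_params, al),
       partners = do.call(partner_params, pa),
       config = do.call(model_config, mo))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

modify_named <- function(base, overrides, what) {
  if (length(overrides) == 0) return(base)
  nm <- names(overrides)
  if (is.null(nm) || any(nm == ""))
    stop(what, ": overrides must be named")
  unknown <- setdiff(nm, names(base))
  if (length(unknown))
    stop(what, ": unknown field(s): ", paste(unknown, collapse = ", "))
  # store as double: YAML/JSON configs may deliver integers, and products
  # like k0 * L overflow integer arithmetic
  base[nm] <- lapply(overrides, function(v)
    if (is.numeric(v)) as.numeric(v) else v)
  base
}

validate_cam_params <- function(p) {
  pos <- c("LN", "LC", "cN", "cC", "KNT", "KCT", "kon_N", "kon_C",
           "k0_N", "k0_C", "e")
  for (f in pos) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop("invalid allosteric parameter: ", f, " must be a positive number")
  }
  if (p$cN > 1) stop("invalid allosteric parameter: cN must satisfy 0 < cN <= 1")
  if (p$cC > 1) stop("invalid allosteric parameter: cC must satisfy 0 < cC <= 1")
  invisible(p)
}

validate_partner_params <- function(p) {
  for (f in setdiff(names(p), "koff_CaN_Ca")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0)
      stop("invalid partner parameter: ", f)
  }
  k <- p$koff_CaN_Ca
  if (!is.numeric(k) || length(k) != 4 || any(!is.finite(k)) || any(k <= 0))
    stop("invalid partner parameter: koff_CaN_Ca must be 4 positive rates")
  if (any(diff(k) <= 0))
    stop("invalid partner parameter: koff_CaN_Ca must increase with occupancy")
  kd_k <- p$koff_CaMKII_RR / p$kon_CaMKII_RR
  kd_p <- p$koff_CaMKIIp_RR / p$kon_CaMKIIp_RR
  if (kd_p >= kd_k)
    stop("invalid partner parameters: phospho-CaMKII must bind CaM tighter ",
         "than CaMKII (Kd_CaMKIIp_RR < Kd_CaMKII_RR)")
  invisible(p)
}
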