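# Least-squares parameter recovery on titration/chelation datasets.
#
# The estimation protocols are staged forward fits: a dataset (synthetic
# here; fluorescence-derived in the laboratory) is compared against the
# forward-simulated curve under candidate parameters, and a bounded
# Levenberg-Marquardt search on log10-parameters minimizes the summed
# squared residuals. Correlated parameter pairs (notably cC and LC, which
# the steady-state curves constrain only through a product-like combination)
# surface either through the local correlation matrix at the optimum or
# across replicate fits.

#' Forward-predict the observable of a dataset under candidate parameters
#'
#' Dispatches on the dataset `kind`: partner-free titrations use the
#' analytic two-state equilibrium (free calcium solved from total-calcium
#' conservation), partner titrations re-equilibrate the reaction network,
#' locked-lobe titrations use the single-conformation binding curve, and
#' chelation datasets re-run the stopped-flow protocol.
#'
#' @param params,partners candidate parameter objects.
#' @param dataset a dataset carrying attributes `kind`, `condition`, `lobe`
#'   (as produced by [simulate_titration()], [gen_titration()], etc.).
#' @return predicted observable at the dataset's design points.
#' @export
forward_predict <- function(params, partners, dataset) {
  kind <- attr(dataset, "kind") %||% "titration"
  cond <- attr(dataset, "condition")
  lobe <- attr(dataset, "lobe") %||% "C"
  if (kind == "locked_titration") {
    conf <- attr(dataset, "conf") %||% "T"
    return(locked_lobe_saturation(params, lobe, conf, dataset$ca_free))
  }
  if (kind == "chelation") {
    pred <- simulate_chelation(params, partners, cond,
                               chelator = attr(dataset, "chelator"),
                               ca_total = attr(dataset, "ca_total"),
                               times = dataset$time,
                               observable = attr(dataset, "observable"))
    return(pred$signal)
  }
  if (cond$partner == "none") {
    # closed system without partners: free calcium from conservation
    vapply(dataset$ca_total, function(catot) {
      bound <- function(free)
        2 * cond$CaM * (mwc_saturation(params, "N", free) +
                        mwc_saturation(params, "C", free))
      free <- stats::uniroot(function(x) x + bound(x) - catot,
                             lower = 0, upper = catot,
                             tol = 1e-3 * .Machine$double.eps^0.5 * catot +
                               1e-18)$root
      switch(lobe,
             C = mwc_saturation(params, "C", free),
             N = mwc_saturation(params, "N", free),
             CaM = (mwc_saturation(params, "N", free) +
                    mwc_saturation(params, "C", free)) / 2)
    }, numeric(1))
  } else {
    pred <- simulate_titration(params, partners, cond,
                               ca_total = dataset$ca_total, lobe = lobe)
    pred$sat
  }
}

set_fit_param <- function(params, partners, name, value) {
  if (name %in% names(unclass(params))) {
    params[[name]] <- value
  } else if (name == "Kd_CaMKII_RR") {
    partners$koff_CaMKII_RR <- value * partners$kon_CaMKII_RR
  } else if (name == "Kd_CaMKIIp_RR") {
    partners$koff_CaMKIIp_RR <- value * partners$kon_CaMKIIp_RR
  } else if (name %in% names(unclass(partners))) {
    partners[[name]] <- value
  } else {
    stop("unknown fit parameter: ", name)
  }
  list(params = params, partners = partners)
}

#' Fit parameters to datasets by bounded least squares
#'
#' @param datasets a single dataset or a list of datasets (titration,
#'   locked-lobe titration or chelation; see [forward_predict()]).
#' @param fit named list describing the free parameters: each element
#'   `list(start =, lower =, upper =)` (linear scale; the search runs on
#'   log10). Parameter names address [cam_params()] or [partner_params()]
#'   fields, plus the virtual `Kd_CaMKII_RR` / `Kd_CaMKIIp_RR` (dissociation
#'   constants adjusted through the off-rate at fixed on-rate).
#' @param params,partners fixed baseline parameter objects.
#' @param control passed to [minpack.lm::nls.lm.control()]. The default
#'   `epsfcn` widens the finite-difference Jacobian step to ~1e-3 on the
#'   log10 scale so that it is not swamped by ODE solver noise when the
#'   forward model re-equilibrates the network.
#' @return object of class `fit_result`: `estimates` (linear scale),
#'   `residual_norm`, `converged`, `message`, `correlation` (local
#'   correlation matrix of the log-estimates, when computable).
#' @export
fit_least_squares <- function(datasets, fit,
                              params = cam_params(),
                              partners = partner_params(),
                              control = minpack.lm::nls.lm.control(
                                maxiter = 100, epsfcn = 1e-6)) {
  if (inherits(datasets, "data.frame")) datasets <- list(datasets)
  if (length(fit) == 0) {
    # all parameters fixed: report the forward residual directly
    r <- unlist(lapply(datasets, function(d)
      observed_of(d) - forward_predict(params, partners, d)))
    return(structure(list(estimates = numeric(0),
                          residual_norm = sqrt(sum(r^2)),
                          converged = TRUE, message = "no free parameters",
                          correlation = NULL),
                     class = "fit_result"))
  }
  nm <- names(fit)
  start <- log10(vapply(fit, function(f) f$start, numeric(1)))
  lower <- log10(vapply(fit, function(f) f$lower, numeric(1)))
  upper <- log10(vapply(fit, function(f) f$upper, numeric(1)))
  resid_fun <- function(logp) {
    pa <- params; pp <- partners
    for (i in seq_along(nm)) {
      upd <- set_fit_param(pa, pp, nm[i], 10^logp[i])
      pa <- upd$params; pp <- upd$partners
    }
    unlist(lapply(datasets, function(d)
      observed_of(d) - forward_predict(pa, pp, d)))
  }
  ans <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                            fn = resid_fun, control = control)
  est <- stats::setNames(10^ans$par, nm)
  corr <- NULL
  if (length(nm) >= 2) {
    corr <- tryCatch(stats::cov2cor(solve(ans$hessian)),
                     error = function(e) NULL)
    if (!is.null(corr)) dimnames(corr) <- list(nm, nm)
  }
  converged <- ans$info %in% 1:4
  out <- list(estimates = est,
              residual_norm = sqrt(ans$deviance),
              converged = converged,
              message = if (converged) ans$message
                        else paste0("non-convergence: ", ans$message,
                                    " (final residual ",
                                    signif(sqrt(ans$deviance), 4), ")"),
              correlation = corr,
              nls = ans)
  class(out) <- "fit_result"
  out
}

observed_of <- function(dataset) {
  if (!is.null(dataset$sat)) dataset$sat else dataset$signal
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result:", if (x$converged) "converged" else "NOT converged", "\n")
  if (length(x$estimates)) {
    cat("  estimates:\n")
    for (n in names(x$estimates))
      cat(sprintf("    %-18s %.6g\n", n, x$estimates[[n]]))
  }
  cat(sprintf("  residual norm: %.4g\n", x$residual_norm))
  invisible(x)
}
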