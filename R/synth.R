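# Synthetic dataset generation for exercising the fitting machinery: the
# noise-free forward curves of the model's own protocols plus additive
# Gaussian noise on the observable scale, truncated to [0, 1].

#' Configuration for synthetic dataset generation
#'
#' @param params,partners generating ("true") parameter objects.
#' @param condition a [protocol_condition()].
#' @param kind `"titration"`, `"locked_titration"` or `"chelation"`.
#' @param sd Gaussian noise standard deviation on the observable scale.
#' @param seed integer seed, recorded in every emitted dataset.
#' @param lobe observed lobe for titrations (`"C"`, `"N"`, `"CaM"`).
#' @param conf locked conformation for `locked_titration`.
#' @param ca_total total-calcium grid for titrations (M); for
#'   `locked_titration` this is the free-calcium grid.
#' @param chelator,ca_premix,times,observable chelation protocol settings
#'   (see [simulate_chelation()]).
#' @return list of class `synth_config`.
#' @export
synth_config <- function(params = cam_params(), partners = partner_params(),
                         condition = protocol_condition(),
                         kind = c("titration", "locked_titration",
                                  "chelation"),
                         sd = 0.02, seed = 1,
                         lobe = "C", conf = "T",
                         ca_total = 10^seq(-7.5, -3, length.out = 15),
                         chelator = chelator_spec("EGTA"),
                         ca_premix = 100e-6,
                         times = c(seq(0, 1, by = 0.02), seq(1.1, 30, by = 0.1)),
                         observable = "c_lobe_sat") {
  kind <- match.arg(kind)
  if (sd < 0) stop("noise sd must be >= 0")
  out <- as.list(environment())
  class(out) <- "synth_config"
  out
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic titration dataset
#'
#' Forward-simulates the configured titration (or locked-lobe curve) under
#' the generating parameters and adds i.i.d. Gaussian noise truncated to
#' \[0, 1\]. Identical seeds give identical datasets.
#'
#' @param config a [synth_config()].
#' @return `titration_dataset` with attributes `kind`, `sd`, `seed`.
#' @export
gen_titration <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$kind == "locked_titration") {
    base <- data.frame(ca_free = config$ca_total)
    base$sat <- locked_lobe_saturation(config$params, config$lobe,
                                       config$conf, base$ca_free)
    attr(base, "conf") <- config$conf
  } else {
    base <- simulate_titration(config$params, config$partners,
                               config$condition, ca_total = config$ca_total,
                               lobe = config$lobe)
  }
  base$sat <- with_seed(config$seed,
                        pmin(pmax(base$sat + stats::rnorm(nrow(base),
                                                          sd = config$sd),
                                  0), 1))
  attr(base, "kind") <- config$kind
  attr(base, "condition") <- config$condition
  attr(base, "lobe") <- config$lobe
  attr(base, "sd") <- config$sd
  attr(base, "seed") <- config$seed
  class(base) <- c("titration_dataset", "data.frame")
  base
}

#' Generate a synthetic chelation dataset
#'
#' @param config a [synth_config()] with `kind = "chelation"`.
#' @return `chelation_dataset` with attributes `kind`, `sd`, `seed`.
#' @export
gen_chelation <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  base <- simulate_chelation(config$params, config$partners,
                             config$condition, chelator = config$chelator,
                             ca_total = config$ca_premix,
                             times = config$times,
                             observable = config$observable)
  base$signal <- with_seed(config$seed,
                           pmin(pmax(base$signal +
                                       stats::rnorm(nrow(base),
                                                    sd = config$sd), 0), 1))
  attr(base, "kind") <- "chelation"
  attr(base, "ca_total") <- config$ca_premix
  attr(base, "sd") <- config$sd
  attr(base, "seed") <- config$seed
  base
}
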