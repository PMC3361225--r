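#' Define a simulation scenario for mock omics data
#'
#' A scenario bundles every generative parameter of the two-class Gaussian
#' measurement model: each feature is drawn as `N(0, bio_variance)` in
#' controls and `N(gamma, bio_variance)` in cases (`gamma = 0` for
#' non-marker features), and every performed measurement receives additive
#' technical noise `N(0, tech_variance)`. Values are on the natural-log
#' scale throughout, as is conventional for expression-like data.
#'
#' @param label Scenario name; the presets are `"human"` and `"animal"`
#'   (see [scenario_preset()]), anything else is a custom scenario.
#' @param n_features Number of features (e.g. genes, metabolites) per sample.
#' @param n_per_class Number of individual samples per class in a training
#'   set; generated training sets are balanced, `2 * n_per_class` in total.
#' @param bio_variance Biological (between-subject) variance of each feature.
#' @param tech_variance Technical (measurement) variance, added once per
#'   performed measurement. Default `0.2^2`.
#' @param n_markers Number of marker features whose case-class mean is
#'   shifted by a nonzero effect size.
#' @param gamma_low,gamma_high Bounds of the uniform distribution the marker
#'   effect sizes are drawn from.
#'
#' @return A `scenario_config` object (a validated list of the above fields).
#' @seealso [scenario_preset()], [simulate_individuals()]
#' @examples
#' scenario_config(label = "toy", n_features = 50, n_per_class = 10,
#'                 bio_variance = 0.2, n_markers = 5)
#' @export
scenario_config <- function(label = "custom",
                            n_features = 1000,
                            n_per_class = 90,
                            bio_variance = 0.2,
                            tech_variance = 0.04,
                            n_markers = 10,
                            gamma_low = 0.3,
                            gamma_high = 0.4) {
  cfg <- structure(
    list(
      label = as.character(label)[1],
      n_features = as.integer(n_features),
      n_per_class = as.integer(n_per_class),
      bio_variance = as.numeric(bio_variance),
      tech_variance = as.numeric(tech_variance),
      n_markers = as.integer(n_markers),
      gamma_low = as.numeric(gamma_low),
      gamma_high = as.numeric(gamma_high)
    ),
    class = "scenario_config"
  )
  validate_scenario_config(cfg)
  cfg
}

#' Preset scenarios mimicking human and animal study designs
#'
#' Two presets capture typical data characteristics: `"human"` studies run
#' with more subjects but higher biological variability (90 samples/class,
#' variance 0.2); `"animal"` experiments (e.g. inbred mice or rats) are
#' smaller but more homogeneous (30 samples/class, variance 0.1). Both use
#' 1000 features and technical variance `0.2^2`. Any field can be
#' overridden, e.g. to explore an animal-variance design at human sample
#' size.
#'
#' @param name `"human"` or `"animal"`.
#' @param ... Field overrides passed to [scenario_config()].
#' @return A `scenario_config`.
#' @examples
#' scenario_preset("animal")
#' scenario_preset("animal", n_per_class = 90)  # animal variance, human n
#' @export
scenario_preset <- function(name = c("human", "animal"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    human  = list(label = "human",  n_features = 1000L,
                  n_per_class = 90L, bio_variance = 0.2),
    animal = list(label = "animal", n_features = 1000L,
                  n_per_class = 30L, bio_variance = 0.1)
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(formals(scenario_config)))
  if (length(bad) > 0) {
    rlang::abort(
      paste0("Unknown scenario field(s): ", paste(bad, collapse = ", ")),
      class = "poolsim_error_config"
    )
  }
  do.call(scenario_config, utils::modifyList(base, overrides))
}

validate_scenario_config <- function(cfg) {
  fail <- function(msg) rlang::abort(msg, class = "poolsim_error_config")
  if (is.na(cfg$n_features) || cfg$n_features < 1L) {
    fail("`n_features` must be a positive integer")
  }
  if (is.na(cfg$n_per_class) || cfg$n_per_class < 1L) {
    fail("`n_per_class` must be a positive integer")
  }
  if (!is.finite(cfg$bio_variance) || cfg$bio_variance <= 0) {
    fail("`bio_variance` must be > 0")
  }
  if (!is.finite(cfg$tech_variance) || cfg$tech_variance < 0) {
    fail("`tech_variance` must be >= 0")
  }
  if (is.na(cfg$n_markers) || cfg$n_markers < 0L ||
      cfg$n_markers > cfg$n_features) {
    fail("`n_markers` must satisfy 0 <= n_markers <= n_features")
  }
  if (!is.finite(cfg$gamma_low) || !is.finite(cfg$gamma_high) ||
      cfg$gamma_low < 0 || cfg$gamma_low > cfg$gamma_high) {
    fail("effect-size bounds must satisfy 0 <= gamma_low <= gamma_high")
  }
  invisible(cfg)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "<scenario_config> %s: %d features, %d/class, bio var %.3g, tech var %.3g, %d markers, gamma ~ U(%.3g, %.3g)\n",
    x$label, x$n_features, x$n_per_class, x$bio_variance, x$tech_variance,
    x$n_markers, x$gamma_low, x$gamma_high
  ))
  invisible(x)
}
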