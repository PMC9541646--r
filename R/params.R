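#' Variance components of a dynamic species abundance distribution GLMM
#'
#' Container for the parameters of the intercept-only Poisson lognormal mixed
#' model on the linear-predictor (log abundance) scale. The random-effect
#' structure distinguishes among-species heterogeneity (`sigma2_h`),
#' within-species environmental variation correlated across sampling units
#' (`sigma2_e`), common environmental variation shared by all species
#' (`sigma2_c`), observation-level overdispersion (`sigma2_o`) and
#' uncorrelated sampling-unit noise (`sigma2_u`). Correlation across units
#' decays exponentially with the time lag (rate `gamma`, temporal models) or
#' with distance in km (rate `alpha`, spatial models); the common-environment
#' term may carry its own decay rate (`gamma_c` / `alpha_c`), defaulting to
#' the species-specific one.
#'
#' @param beta0 Intercept: expected log count. Confounded with the sampling
#'   intensity \eqn{\nu} as \eqn{\tilde\beta_0 = \ln\nu + \beta_0}.
#' @param sigma2_h Among-species variance (species heterogeneity), >= 0.
#' @param sigma2_e Within-species (species-by-unit) environmental variance, >= 0.
#' @param sigma2_c Common-environment (among-unit) variance, >= 0.
#' @param sigma2_o Observation-level (overdispersion) variance, >= 0.
#' @param sigma2_u Uncorrelated sampling-unit variance, >= 0.
#' @param gamma,gamma_c Temporal decay rates (> 0, per unit time). `gamma_c`
#'   defaults to `gamma`.
#' @param alpha,alpha_c Spatial decay rates (> 0, per km) used in place of
#'   `gamma`, `gamma_c` for spatial models. `alpha_c` defaults to `alpha`.
#' @return An object of class `variance_components`.
#' @seealso [to_population_params()], [variance_proportions()],
#'   [similarity_relative()], [similarity_mean()]
#' @export
#' @examples
#' vc <- variance_components(beta0 = 2, sigma2_h = 0.64, sigma2_e = 0.36,
#'                           gamma = 0.17)
#' similarity_relative(vc, u = 1 / 0.17)
variance_components <- function(beta0 = 0,
                                sigma2_h = 0, sigma2_e = 0, sigma2_c = 0,
                                sigma2_o = 0, sigma2_u = 0,
                                gamma = NULL, gamma_c = NULL,
                                alpha = NULL, alpha_c = NULL) {
  vars <- c(sigma2_h = sigma2_h, sigma2_e = sigma2_e, sigma2_c = sigma2_c,
            sigma2_o = sigma2_o, sigma2_u = sigma2_u)
  if (any(!is.finite(vars)) || any(vars < 0))
    stop("variance components must be finite and >= 0")
  if (!is.null(gamma) && !is.null(alpha))
    stop("supply temporal rates (gamma) or spatial rates (alpha), not both")
  dimension <- if (!is.null(alpha)) "spatial" else "temporal"
  rate <- if (dimension == "spatial") alpha else gamma
  rate_c <- if (dimension == "spatial") {
    if (is.null(alpha_c)) alpha else alpha_c
  } else {
    if (is.null(gamma_c)) gamma else gamma_c
  }
  for (r in list(rate, rate_c))
    if (!is.null(r) && (!is.finite(r) || r <= 0))
      stop("decay rates must be finite and > 0")
  structure(list(beta0 = beta0,
                 sigma2_h = sigma2_h, sigma2_e = sigma2_e,
                 sigma2_c = sigma2_c, sigma2_o = sigma2_o,
                 sigma2_u = sigma2_u,
                 rate = rate, rate_c = rate_c,
                 dimension = dimension),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  rn <- if (x$dimension == "spatial") c("alpha", "alpha_c") else c("gamma", "gamma_c")
  cat("Variance components (", x$dimension, " model)\n", sep = "")
  cat(sprintf("  beta0    = %.4f\n", x$beta0))
  for (nm in c("sigma2_h", "sigma2_e", "sigma2_c", "sigma2_o", "sigma2_u"))
    if (x[[nm]] > 0) cat(sprintf("  %-8s = %.4f\n", nm, x[[nm]]))
  if (!is.null(x$rate))
    cat(sprintf("  %-8s = %.4f  (1/%s = %.2f)\n", rn[1], x$rate, rn[1], 1 / x$rate))
  if (!is.null(x$rate_c) && !identical(x$rate_c, x$rate))
    cat(sprintf("  %-8s = %.4f  (1/%s = %.2f)\n", rn[2], x$rate_c, rn[2], 1 / x$rate_c))
  invisible(x)
}

# decay rate accessors; error when the component needs a rate that is absent
vc_rate <- function(vc) {
  if (is.null(vc$rate)) stop("variance_components has no decay rate")
  vc$rate
}
vc_rate_c <- function(vc) {
  if (is.null(vc$rate_c)) vc_rate(vc) else vc$rate_c
}

#' Population-dynamic parameters of the Gompertz community model
#'
#' Parameters of the multispecies stochastic Gompertz (log-linear density
#' regulation) model on the population-dynamics scale: the mean and
#' among-species variance of the long-run growth rate, species-specific and
#' general (synchronizing) environmental variances, the strength of density
#' regulation and the mean log carrying capacity.
#'
#' @param mean_growth Mean growth rate across species (per unit time).
#' @param sigma2_r Among-species variance of the growth rate, >= 0.
#' @param sigma2_s Species-specific environmental variance (per unit time), >= 0.
#' @param sigma2_E General environmental variance (per unit time), >= 0.
#' @param gamma Strength of density regulation, > 0; `1/gamma` is the mean
#'   return time to equilibrium.
#' @param logK Mean log carrying capacity; equals `mean_growth / gamma` under
#'   Gompertz regulation (filled in when omitted).
#' @param nu Sampling intensity: the fraction of true abundance observed,
#'   in (0, 1].
#' @return An object of class `population_params`.
#' @export
population_params <- function(mean_growth = NULL, sigma2_r = 0, sigma2_s = 0,
                              sigma2_E = 0, gamma, logK = NULL, nu = 1) {
  if (!is.finite(gamma) || gamma <= 0) stop("gamma must be > 0")
  if (any(c(sigma2_r, sigma2_s, sigma2_E) < 0)) stop("variances must be >= 0")
  if (!is.finite(nu) || nu <= 0 || nu > 1) stop("nu must be in (0, 1]")
  if (is.null(mean_growth) && is.null(logK))
    stop("supply mean_growth or logK")
  if (is.null(mean_growth)) mean_growth <- gamma * logK
  if (is.null(logK)) logK <- mean_growth / gamma
  if (abs(logK * gamma - mean_growth) > 1e-8 * max(1, abs(mean_growth)))
    stop("inconsistent parameters: logK * gamma must equal mean_growth")
  structure(list(mean_growth = mean_growth, sigma2_r = sigma2_r,
                 sigma2_s = sigma2_s, sigma2_E = sigma2_E,
                 gamma = gamma, logK = logK, nu = nu),
            class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat("Population-dynamic parameters (Gompertz, log scale)\n")
  cat(sprintf("  mean growth rate  = %.4f\n", x$mean_growth))
  cat(sprintf("  sigma2_r          = %.5f\n", x$sigma2_r))
  cat(sprintf("  sigma2_s          = %.4f\n", x$sigma2_s))
  cat(sprintf("  sigma2_E          = %.4f\n", x$sigma2_E))
  cat(sprintf("  gamma             = %.4f  (return time %.2f)\n", x$gamma, 1 / x$gamma))
  cat(sprintf("  log K             = %.4f\n", x$logK))
  cat(sprintf("  nu                = %.3f\n", x$nu))
  invisible(x)
}

#' Transform GLMM variance components to population-dynamic parameters
#'
#' Applies the correspondence between the linear-predictor covariance of the
#' mixed model and the stationary covariance of log abundance under Gompertz
#' dynamics: \eqn{\sigma_r^2 = \gamma^2 \sigma_h^2},
#' \eqn{\sigma_s^2 = 2\gamma\sigma_e^2}, \eqn{\sigma_E^2 = 2\gamma_c\sigma_c^2}
#' (with \eqn{\gamma_c = \gamma} unless a separate common-environment rate was
#' estimated). The intercept is corrected for sampling intensity,
#' \eqn{\ln K = \beta_0 - \ln\nu}, and the mean growth rate is
#' \eqn{\bar r = \gamma \ln K}.
#'
#' @param vc A [variance_components()] object with a temporal decay rate.
#' @param nu Sampling intensity in (0, 1].
#' @return A [population_params()] object.
#' @export
to_population_params <- function(vc, nu = 1) {
  stopifnot(inherits(vc, "variance_components"))
  if (vc$dimension != "temporal")
    stop("population-dynamic transformation applies to temporal models")
  if (!is.finite(nu) || nu <= 0 || nu > 1) stop("nu must be in (0, 1]")
  g <- vc_rate(vc)
  gc <- vc_rate_c(vc)
  logK <- vc$beta0 - log(nu)
  population_params(mean_growth = g * logK,
                    sigma2_r = g^2 * vc$sigma2_h,
                    sigma2_s = 2 * g * vc$sigma2_e,
                    sigma2_E = 2 * gc * vc$sigma2_c,
                    gamma = g, logK = logK, nu = nu)
}

#' Transform population-dynamic parameters to GLMM variance components
#'
#' Inverse of [to_population_params()] (the observation-level and
#' sampling-unit variances, which have no population-dynamic counterpart, are
#' zero).
#'
#' @param p A [population_params()] object.
#' @param gamma_c Optional separate decay rate for the common-environment
#'   term; defaults to `p$gamma`.
#' @return A [variance_components()] object.
#' @export
to_variance_components <- function(p, gamma_c = NULL) {
  stopifnot(inherits(p, "population_params"))
  g <- p$gamma
  gc <- if (is.null(gamma_c)) g else gamma_c
  variance_components(beta0 = p$logK + log(p$nu),
                      sigma2_h = p$sigma2_r / g^2,
                      sigma2_e = p$sigma2_s / (2 * g),
                      sigma2_c = p$sigma2_E / (2 * gc),
                      gamma = g, gamma_c = gc)
}

# -- flat key-value serialization ------------------------------------------

vc_to_list <- function(vc, nu = NULL) {
  out <- list(beta0 = vc$beta0, sigma2_h = vc$sigma2_h,
              sigma2_e = vc$sigma2_e, sigma2_c = vc$sigma2_c,
              sigma2_o = vc$sigma2_o, sigma2_u = vc$sigma2_u)
  if (vc$dimension == "spatial") {
    out$alpha <- vc$rate; out$alpha_c <- vc$rate_c
  } else {
    out$gamma <- vc$rate; out$gamma_c <- vc$rate_c
  }
  if (!is.null(nu)) out$nu <- nu
  out[!vapply(out, is.null, logical(1))]
}

#' Read or write variance components as a flat key-value config file
#'
#' The on-disk representation is a flat YAML or JSON mapping with keys
#' `beta0`, `sigma2_h`, `sigma2_e`, `sigma2_c`, `sigma2_o`, `sigma2_u`,
#' `gamma`, `gamma_c`, `alpha`, `alpha_c` and optionally `nu`. The format is
#' chosen from the file extension (`.json` vs `.yml`/`.yaml`).
#'
#' @param vc A [variance_components()] object.
#' @param path File path ending in `.json`, `.yml` or `.yaml`.
#' @param nu Optional sampling intensity stored alongside the components.
#' @return `write_params` returns `path` invisibly; `read_params` returns a
#'   list with elements `vc` (a `variance_components`) and `nu` (or `NULL`).
#' @export
write_params <- function(vc, path, nu = NULL) {
  lst <- vc_to_list(vc, nu)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("beta0", "sigma2_h", "sigma2_e", "sigma2_c", "sigma2_o",
             "sigma2_u", "gamma", "gamma_c", "alpha", "alpha_c")
  args <- lst[intersect(names(lst), known)]
  vc <- do.call(variance_components, args)
  list(vc = vc, nu = lst$nu)
}
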