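#' Configuration of a multispecies Gompertz community simulation
#'
#' Describes the discrete-time stochastic Gompertz community: each species'
#' log abundance follows
#' \deqn{X_{i,t+1} = X_{i,t} + r_i - \gamma X_{i,t} + \eta_{i,t} + \epsilon_t}
#' with quenched growth-rate heterogeneity \eqn{r_i \sim N(\mu_r,\sigma_r^2)}
#' drawn once per species, species-specific environmental noise
#' \eqn{\eta_{i,t} \sim N(0,\sigma_s^2)} independent over species and time,
#' and common environmental noise \eqn{\epsilon_t \sim N(0,\sigma_E^2)}
#' shared by all species. Observed counts are Poisson samples at intensity
#' \eqn{\nu}: \eqn{y_{i,t} \sim \mathrm{Poisson}(\nu e^{X_{i,t}})}.
#'
#' @param n_species Number of species S.
#' @param n_steps Total simulated time steps (including burn-in).
#' @param burn_in Initial steps discarded before output.
#' @param gamma Strength of density regulation per step, in (0, 1) for a
#'   stable discrete map.
#' @param mu_r Mean growth rate per step; the stationary mean log abundance
#'   (log carrying capacity) is `mu_r / gamma`.
#' @param sigma2_r Among-species growth-rate variance, >= 0.
#' @param sigma2_s Species-specific environmental variance per step, >= 0.
#' @param sigma2_E Common environmental variance per step, >= 0.
#' @param nu Sampling intensity in (0, 1].
#' @param x0 Initial log abundance for all species; defaults to the
#'   carrying-capacity value `mu_r / gamma`.
#' @param seed Integer seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_species = 100, n_steps = 370, burn_in = 320,
                              gamma = 0.1, mu_r = 1,
                              sigma2_r = 0, sigma2_s = 0, sigma2_E = 0,
                              nu = 1, x0 = mu_r / gamma, seed = 1L) {
  stopifnot(n_species >= 1, n_steps >= 1)
  if (burn_in >= n_steps) stop("burn_in must be < n_steps")
  if (gamma <= 0 || gamma >= 1) stop("gamma must be in (0, 1)")
  if (any(c(sigma2_r, sigma2_s, sigma2_E) < 0)) stop("variances must be >= 0")
  if (nu <= 0 || nu > 1) stop("nu must be in (0, 1]")
  structure(list(n_species = as.integer(n_species),
                 n_steps = as.integer(n_steps),
                 burn_in = as.integer(burn_in),
                 gamma = gamma, mu_r = mu_r,
                 sigma2_r = sigma2_r, sigma2_s = sigma2_s,
                 sigma2_E = sigma2_E, nu = nu, x0 = x0,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a community under discrete Gompertz dynamics
#'
#' Runs the discrete map described in [simulation_config()], discards the
#' burn-in, and Poisson-samples observed counts. The update is an Euler step
#' with unit time increment; both noise terms are added once per step after
#' the deterministic density-regulation step.
#'
#' @param config A [simulation_config()].
#' @return An object of class `simulated_community` with elements
#'   `latent_logN` (S x T matrix of post-burn-in log abundances), `counts`
#'   (S x T integer matrix), `growth_rates` (length-S vector) and `config`.
#' @export
simulate_community <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  S <- config$n_species
  Tkeep <- config$n_steps - config$burn_in
  g <- config$gamma
  r <- rnorm(S, config$mu_r, sqrt(config$sigma2_r))
  X <- rep(config$x0, S)
  keep <- matrix(NA_real_, S, Tkeep)
  ss <- sqrt(config$sigma2_s); sE <- sqrt(config$sigma2_E)
  for (t in seq_len(config$n_steps)) {
    eps <- if (sE > 0) rnorm(1, 0, sE) else 0
    eta <- if (ss > 0) rnorm(S, 0, ss) else numeric(S)
    X <- (1 - g) * X + r + eta + eps
    if (any(!is.finite(X)) || any(X > 700))
      stop("latent log abundance overflowed at step ", t,
           " (max X = ", round(max(X), 1), "); check gamma and variances")
    if (t > config$burn_in) keep[, t - config$burn_in] <- X
  }
  counts <- matrix(rpois(S * Tkeep, config$nu * exp(keep)), S, Tkeep)
  structure(list(latent_logN = keep, counts = counts, growth_rates = r,
                 config = config),
            class = "simulated_community")
}

#' @export
print.simulated_community <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Simulated community: S = %d species, T = %d steps kept (burn-in %d)\n",
              cfg$n_species, ncol(x$latent_logN), cfg$burn_in))
  cat(sprintf("  gamma = %.3f, mu_r = %.3f, sigma2_r = %.4f, sigma2_s = %.4f, sigma2_E = %.4f, nu = %.3f\n",
              cfg$gamma, cfg$mu_r, cfg$sigma2_r, cfg$sigma2_s, cfg$sigma2_E, cfg$nu))
  cat(sprintf("  mean latent log abundance = %.3f, seed = %d\n",
              mean(x$latent_logN), cfg$seed))
  invisible(x)
}

#' Convert a simulated community to a long-format community table
#'
#' @param x A `simulated_community`.
#' @param location Location identifier assigned to all observations.
#' @return A [community_table()] with one row per species and time step.
#' @export
as_community_table <- function(x, location = "1") {
  stopifnot(inherits(x, "simulated_community"))
  S <- nrow(x$counts); Tn <- ncol(x$counts)
  community_table(species = rep(sprintf("sp%03d", seq_len(S)), times = Tn),
                  time = rep(seq_len(Tn), each = S),
                  location = location,
                  count = as.vector(x$counts))
}

#' Write a simulated community to CSV with a sidecar config file
#'
#' Writes the long-format counts via [write_community_csv()] and the full
#' simulation configuration (including the seed and package version) to a
#' YAML sidecar `<path>.config.yml`.
#'
#' @param x A `simulated_community`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(x, path) {
  stopifnot(inherits(x, "simulated_community"))
  write_community_csv(as_community_table(x), path)
  cfg <- unclass(x$config)
  cfg$package_version <- as.character(packageVersion("sadglmm"))
  yaml::write_yaml(cfg, paste0(path, ".config.yml"))
  invisible(path)
}

#' Factorial simulation-study design grid
#'
#' Enumerates the full factorial of the simulation study used to probe
#' estimation accuracy: strength of density regulation
#' \eqn{\gamma \in \{0.05, 0.1, 0.5\}} (an alternative set
#' \{0.01, 0.1, 0.5\} is available), within-species variance proportion
#' \eqn{\sigma_e^2 \in \{0.2, 0.4, 0.6, 0.8\}} with
#' \eqn{\sigma_h^2 = 1 - \sigma_e^2}, common-environment variance
#' \eqn{\sigma_c^2 \in \{0.01, 0.1\}}, and sampling intensity
#' \eqn{\nu \in \{0.01, 0.1, 0.5\}}. Each cell is converted to
#' simulator parameters via \eqn{\sigma_s^2 = 2\gamma\sigma_e^2},
#' \eqn{\sigma_r^2 = \gamma^2\sigma_h^2}, \eqn{\sigma_E^2 = 2\gamma\sigma_c^2}
#' and \eqn{\mu_r = 10\gamma} (log carrying capacity 10), with S = 100
#' species, 370 steps and 320 burn-in.
#'
#' @param gamma_set `"figure"` for \{0.05, 0.1, 0.5\} (default) or `"text"`
#'   for \{0.01, 0.1, 0.5\}.
#' @param seed Base seed; each cell gets `seed + cell index`.
#' @return A list of [simulation_config()] objects; each carries the
#'   generating GLMM-scale values as a `glmm_truth` attribute.
#' @export
simulation_study_grid <- function(gamma_set = c("figure", "text"), seed = 1L) {
  gamma_set <- match.arg(gamma_set)
  gammas <- if (gamma_set == "figure") c(0.05, 0.1, 0.5) else c(0.01, 0.1, 0.5)
  cells <- expand.grid(gamma = gammas,
                       sigma2_e = c(0.2, 0.4, 0.6, 0.8),
                       sigma2_c = c(0.01, 0.1),
                       nu = c(0.01, 0.1, 0.5),
                       KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(cells)), function(k) {
    cl <- cells[k, ]
    sigma2_h <- 1 - cl$sigma2_e
    cfg <- simulation_config(n_species = 100, n_steps = 370, burn_in = 320,
                             gamma = cl$gamma, mu_r = 10 * cl$gamma,
                             sigma2_r = cl$gamma^2 * sigma2_h,
                             sigma2_s = 2 * cl$gamma * cl$sigma2_e,
                             sigma2_E = 2 * cl$gamma * cl$sigma2_c,
                             nu = cl$nu, seed = seed + k)
    attr(cfg, "glmm_truth") <- c(sigma2_h = sigma2_h, sigma2_e = cl$sigma2_e,
                                 sigma2_c = cl$sigma2_c, gamma = cl$gamma,
                                 nu = cl$nu)
    cfg
  })
}
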