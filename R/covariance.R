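#' Exponentially decaying correlation kernel
#'
#' The single correlation family used throughout: temporal random effects
#' decay as an Ornstein-Uhlenbeck process, \eqn{\rho(u) = e^{-\gamma u}} for a
#' time lag `u`, and spatial random effects decay as
#' \eqn{\rho(d) = e^{-\alpha d}} for a distance `d` in km. `1/rate` is the
#' lag at which correlation has fallen to \eqn{e^{-1}}.
#'
#' @param kind `"temporal-OU"` or `"spatial-exponential"`.
#' @param rate Decay rate, > 0 (per unit time or per km).
#' @return An object of class `correlation_kernel`.
#' @export
correlation_kernel <- function(kind = c("temporal-OU", "spatial-exponential"),
                               rate) {
  kind <- match.arg(kind)
  if (!is.finite(rate) || rate <= 0) stop("rate must be finite and > 0")
  structure(list(kind = kind, rate = rate), class = "correlation_kernel")
}

#' Correlation matrix of an exponentially decaying kernel
#'
#' Evaluates \eqn{e^{-\mathrm{rate}\cdot d}} element-wise on a matrix of
#' pairwise lags or distances. For distinct points the result is symmetric
#' positive definite with unit diagonal; on a line (temporal lags) its
#' inverse is tridiagonal (the Markov property of the OU kernel).
#'
#' @param kernel A [correlation_kernel()], or a positive rate.
#' @param lags Symmetric nonnegative matrix of pairwise absolute lags or
#'   distances with zero diagonal, or a numeric vector of point coordinates
#'   (times or 1-d positions) from which pairwise lags are formed.
#' @return A symmetric correlation matrix.
#' @export
#' @examples
#' correlation_matrix(correlation_kernel("temporal-OU", 0.5), c(0, 1, 2))
correlation_matrix <- function(kernel, lags) {
  rate <- if (inherits(kernel, "correlation_kernel")) kernel$rate else kernel
  if (!is.finite(rate) || rate <= 0) stop("rate must be finite and > 0")
  if (!is.matrix(lags)) lags <- abs(outer(lags, lags, "-"))
  if (any(lags < 0)) stop("lags/distances must be nonnegative")
  if (any(abs(lags - t(lags)) > 1e-12)) stop("lag matrix must be symmetric")
  if (any(diag(lags) != 0)) stop("lag matrix must have zero diagonal")
  exp(-rate * lags)
}

# Tridiagonal precision (inverse correlation) of the OU kernel on sorted
# points t_1 < ... < t_T, via the Markov/AR(1) factorization: with
# r_k = exp(-rate * (t_{k+1} - t_k)),
#   Q[k,k]   = 1/(1 - r_{k-1}^2) + r_k^2/(1 - r_k^2)   (edge terms -> 1, 0)
#   Q[k,k+1] = -r_k/(1 - r_k^2)
# and log det(correlation) = sum(log(1 - r_k^2)). Valid for unequal spacing.
ou_precision <- function(times, rate) {
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  n <- length(times)
  if (n == 1L)
    return(list(i = 1L, j = 1L, x = 1, logdet_cor = 0, n = 1L))
  r <- exp(-rate * diff(times))
  s <- 1 - r^2
  d <- c(1, 1 / s) + c(r^2 / s, 0)
  o <- -r / s
  list(i = c(seq_len(n), seq_len(n - 1L), 2:n),
       j = c(seq_len(n), 2:n, seq_len(n - 1L)),
       x = c(d, o, o),
       logdet_cor = sum(log(s)),
       n = n)
}

# Dense precision of an arbitrary exponential-decay correlation (spatial
# layouts); returns the same triplet structure as ou_precision.
dense_precision <- function(distmat, rate) {
  R <- exp(-rate * distmat)
  ch <- tryCatch(chol(R), error = function(e)
    stop("correlation matrix is not positive definite"))
  Q <- chol2inv(ch)
  n <- nrow(Q)
  idx <- which(Q != 0, arr.ind = TRUE)
  list(i = idx[, 1], j = idx[, 2], x = Q[idx],
       logdet_cor = 2 * sum(log(diag(ch))), n = n)
}

#' Covariance of linear predictors under the mixed model
#'
#' The covariance between the linear predictors of two observations as a
#' function of their lag `u` (time, or distance for spatial components) and
#' whether they share species and replicate:
#' \deqn{\sigma_h^2+\sigma_e^2+\sigma_c^2+\sigma_o^2+\sigma_u^2} for the same
#' observation (same species and replicate at lag 0);
#' \deqn{\sigma_h^2+\sigma_e^2 e^{-\gamma u}+\sigma_c^2 e^{-\gamma_c u}} for
#' the same species otherwise; and
#' \deqn{\sigma_c^2 e^{-\gamma_c u}} for different species.
#'
#' @param vc A [variance_components()] object.
#' @param u Nonnegative lag (vectorized).
#' @param same_species,same_replicate Logical flags locating the pair.
#' @return Numeric covariance.
#' @export
linear_predictor_covariance <- function(vc, u, same_species = TRUE,
                                        same_replicate = FALSE) {
  stopifnot(inherits(vc, "variance_components"))
  if (any(u < 0)) stop("lag u must be >= 0")
  needs_rate <- (vc$sigma2_e > 0 || vc$sigma2_c > 0) &&
    !(length(u) == 1L && u == 0 && same_species && same_replicate)
  g <- if (needs_rate || !is.null(vc$rate)) vc_rate(vc) else 1
  gc <- if (needs_rate || !is.null(vc$rate)) vc_rate_c(vc) else 1
  common <- vc$sigma2_c * exp(-gc * u)
  out <- ifelse(same_species,
                vc$sigma2_h + vc$sigma2_e * exp(-g * u) + common,
                common)
  if (same_species && same_replicate)
    out <- ifelse(u == 0, out + vc$sigma2_o + vc$sigma2_u, out)
  out
}

#' Stationary variance of relative log abundance
#'
#' The variance of the species abundance distribution on the relative
#' log-abundance scale, \eqn{\sigma_s^2/2\gamma + \sigma_r^2/\gamma^2}: the
#' sum of the within-species environmental contribution and the
#' growth-rate-heterogeneity contribution.
#'
#' @param p A [population_params()] object.
#' @return Numeric variance.
#' @export
stationary_relative_variance <- function(p) {
  stopifnot(inherits(p, "population_params"))
  if (p$gamma <= 0) stop("gamma must be > 0")
  p$sigma2_s / (2 * p$gamma) + p$sigma2_r / p$gamma^2
}

#' Temporal covariance of log abundance under the Gompertz model
#'
#' The stationary autocovariance of a species' log abundance at lag `u`:
#' \deqn{\sigma_r^2/\gamma^2 + (\sigma_s^2/2\gamma)e^{-\gamma u}
#'   + (\sigma_E^2/2\gamma)e^{-\gamma u}.}
#' At lag 0 this is the stationary variance of log abundance; as
#' \eqn{u \to \infty} it decays to the growth-rate-heterogeneity floor
#' \eqn{\sigma_r^2/\gamma^2}.
#'
#' @param p A [population_params()] object.
#' @param u Nonnegative lag (vectorized).
#' @return Numeric covariance.
#' @export
log_abundance_covariance <- function(p, u) {
  stopifnot(inherits(p, "population_params"))
  if (any(u < 0)) stop("lag u must be >= 0")
  p$sigma2_r / p$gamma^2 +
    (p$sigma2_s + p$sigma2_E) / (2 * p$gamma) * exp(-p$gamma * u)
}

#' Partition variance into species-specific and general proportions
#'
#' Splits the estimated variance components into the two partitions that
#' govern community similarity: the species-specific partition
#' (heterogeneity \eqn{\sigma_h^2}, within-species environment
#' \eqn{\sigma_e^2}, overdispersion \eqn{\sigma_o^2}), which drives the
#' dynamics of relative log abundance, and the general partition
#' (common environment \eqn{\sigma_c^2}, uncorrelated sampling-unit noise
#' \eqn{\sigma_u^2}), which drives mean log abundance. Each partition is
#' normalized to proportions summing to 1.
#'
#' @param vc A [variance_components()] object.
#' @return A list with numeric vectors `species_specific` (named `sigma2_h`,
#'   `sigma2_e`, `sigma2_o`) and `general` (named `sigma2_c`, `sigma2_u`),
#'   plus the raw `total_species_specific` and `total_general` variances.
#' @export
variance_proportions <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  ss <- c(sigma2_h = vc$sigma2_h, sigma2_e = vc$sigma2_e, sigma2_o = vc$sigma2_o)
  ge <- c(sigma2_c = vc$sigma2_c, sigma2_u = vc$sigma2_u)
  if (sum(ss) <= 0) stop("all species-specific components are zero")
  out <- list(species_specific = ss / sum(ss),
              total_species_specific = sum(ss))
  if (sum(ge) > 0) {
    out$general <- ge / sum(ge)
    out$total_general <- sum(ge)
  } else {
    out$general <- ge * NA_real_
    out$total_general <- 0
  }
  out
}

#' Community similarity: correlation of relative log abundance
#'
#' The correlation between the community's relative log abundances at two
#' sampling units separated by lag `u` (years, or km for spatial models):
#' \deqn{\rho_x(u) = \frac{\sigma_e^2 e^{-\gamma u} + \sigma_h^2}
#'   {\sigma_e^2 + \sigma_h^2 + \sigma_o^2}.}
#' As `u` grows the similarity decays, at rate \eqn{\gamma}, towards the
#' floor set by species heterogeneity; observation-level variance lowers the
#' whole curve since it contributes variance but no covariance across units.
#'
#' @param vc A [variance_components()] object.
#' @param u Nonnegative lag (vectorized).
#' @return Correlation in (0, 1].
#' @export
similarity_relative <- function(vc, u) {
  stopifnot(inherits(vc, "variance_components"))
  if (any(u < 0)) stop("lag u must be >= 0")
  denom <- vc$sigma2_h + vc$sigma2_e + vc$sigma2_o
  if (denom <= 0) stop("sigma2_h + sigma2_e + sigma2_o must be > 0")
  g <- if (vc$sigma2_e > 0) vc_rate(vc) else 1
  (vc$sigma2_e * exp(-g * u) + vc$sigma2_h) / denom
}

#' Community similarity: correlation of mean log abundance
#'
#' The correlation between the community mean log abundance at two sampling
#' units separated by lag `v`:
#' \deqn{\rho_{\bar X}(v) = \frac{\sigma_c^2 e^{-\gamma_c v}}
#'   {\sigma_c^2 + \sigma_u^2}}
#' (decay rate \eqn{\alpha_c} per km for spatial models). Uncorrelated
#' sampling-unit noise \eqn{\sigma_u^2} lowers the curve uniformly.
#'
#' @param vc A [variance_components()] object.
#' @param v Nonnegative lag (vectorized).
#' @return Correlation in (0, 1].
#' @export
similarity_mean <- function(vc, v) {
  stopifnot(inherits(vc, "variance_components"))
  if (any(v < 0)) stop("lag v must be >= 0")
  denom <- vc$sigma2_c + vc$sigma2_u
  if (denom <= 0) stop("sigma2_c + sigma2_u must be > 0")
  gc <- if (vc$sigma2_c > 0) vc_rate_c(vc) else 1
  vc$sigma2_c * exp(-gc * v) / denom
}
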