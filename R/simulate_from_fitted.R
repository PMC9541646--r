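# draw a random-effect vector from the estimated covariance and return
# Poisson counts on the fitting design (shared by simulate_from_fitted and
# the bootstrap's lean loop)
draw_counts <- function(struct, theta, seed) {
  set.seed(seed)
  r <- theta_rates(theta, struct)
  b <- numeric(struct$q)
  for (bl in struct$blocks) {
    sigma <- exp(theta[[paste0("log_sd_", bl$code)]])
    if (bl$kind == "iid") {
      b[bl$offset + seq_len(bl$n_levels)] <- rnorm(bl$n_levels, 0, sigma)
    } else {
      rate <- if (bl$code == "c") r$rate_c else r$rate
      for (ch in bl$chunks) {
        z <- if (is.matrix(ch$coords)) {
          R <- exp(-rate * ch$coords)
          cR <- tryCatch(chol(R), error = function(e)
            stop("estimated spatial correlation is not positive definite"))
          as.vector(t(cR) %*% rnorm(ch$n))
        } else {
          # exact Markov recursion of the OU kernel on (unequal) spacings
          x <- numeric(ch$n)
          x[1] <- rnorm(1)
          if (ch$n > 1) {
            rho <- exp(-rate * diff(ch$coords))
            for (k in 2:ch$n)
              x[k] <- rho[k - 1] * x[k - 1] +
                sqrt(1 - rho[k - 1]^2) * rnorm(1)
          }
          x
        }
        b[bl$offset + ch$start - 1L + seq_len(ch$n)] <- sigma * z
      }
    }
  }
  eta <- theta[["beta0"]] + as.vector(struct$Z %*% b)
  if (any(eta > 500)) stop("simulated linear predictor overflows exp()")
  rpois(struct$N, exp(eta))
}

#' Simulate count data from a fitted model on its own design
#'
#' Draws the random-effect vector from its estimated distribution (iid
#' normal for uncorrelated blocks; exact Markov recursion on the chunk's
#' time points for temporal exponential kernels; Cholesky of the distance
#' kernel for spatial ones), forms the linear predictor on the same
#' (species, time, location, replicate) grid as the original data, and
#' samples Poisson counts. This is the data-generating step of the
#' parametric bootstrap.
#'
#' @param fit A fitted `sad_glmm`.
#' @param seed Integer seed.
#' @return A `community_table` with the same rows as the fitting data and
#'   newly simulated counts.
#' @export
simulate_from_fitted <- function(fit, seed = 1L) {
  stopifnot(inherits(fit, "sad_glmm"))
  if (!fit$converged) stop("fit did not converge; refusing to simulate")
  key <- fit$struct$data_key
  community_table(species = key$species, time = key$time,
                  location = key$location, replicate = key$replicate,
                  count = draw_counts(fit$struct, fit$theta, seed),
                  locations = attr(fit$data, "locations"))
}
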