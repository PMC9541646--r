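test_that("correlation_matrix evaluates the exponential kernel", {
  k <- correlation_kernel("temporal-OU", 0.5)
  R <- correlation_matrix(k, c(0, 1))
  expect_equal(R[1, 2], exp(-0.5), tolerance = 1e-12)
  expect_equal(diag(R), c(1, 1))

  expect_equal(correlation_matrix(k, 0), matrix(1, 1, 1))

  expect_error(correlation_matrix(correlation_kernel("temporal-OU", -1), 0:2))
  D <- abs(outer(0:2, 0:2, "-")); D[1, 2] <- D[2, 1] <- -1
  expect_error(correlation_matrix(k, D), "nonnegative")
})

test_that("the OU kernel on a line has a tridiagonal inverse", {
  R <- correlation_matrix(0.5, c(0, 1, 2))
  Rinv <- solve(R)
  expect_lt(abs(Rinv[1, 3]), 1e-10)

  R6 <- correlation_matrix(0.3, 0:5)
  Rinv6 <- solve(R6)
  off <- abs(Rinv6[abs(row(Rinv6) - col(Rinv6)) > 1] )
  expect_true(all(off < 1e-8))
})

test_that("correlation matrices are symmetric, unit-diagonal, positive definite", {
  set.seed(11)
  for (rate in c(0.05, 0.5, 3)) {
    pts <- sort(runif(50, 0, 20))
    R <- correlation_matrix(rate, pts)
    expect_equal(R, t(R))
    expect_equal(diag(R), rep(1, 50))
    expect_gt(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("analytic tridiagonal precision matches the dense inverse", {
  for (times in list(0:5, c(0, 0.7, 1.1, 4, 4.5, 9))) {
    rate <- 0.4
    P <- sadglmm:::ou_precision(times, rate)
    Q <- matrix(0, P$n, P$n)
    Q[cbind(P$i, P$j)] <- P$x
    R <- correlation_matrix(rate, times)
    expect_lt(max(abs(Q - solve(R))), 1e-8)
    expect_equal(P$logdet_cor, determinant(R)$modulus[[1]], tolerance = 1e-10)
  }
})

test_that("linear predictor covariance follows the three-case form", {
  vc <- variance_components(sigma2_h = 0.5, sigma2_e = 0.3, sigma2_c = 0.1,
                            sigma2_o = 0.1, gamma = 0.4)
  expect_equal(linear_predictor_covariance(vc, 0, TRUE, TRUE), 1.0)
  expect_equal(linear_predictor_covariance(vc, 0, FALSE), 0.1)
  expect_equal(linear_predictor_covariance(vc, 1e6, TRUE), 0.5,
               tolerance = 1e-12)
  # same species, general lag
  u <- 1.3
  expect_equal(linear_predictor_covariance(vc, u, TRUE),
               0.5 + 0.3 * exp(-0.4 * u) + 0.1 * exp(-0.4 * u))
  expect_error(linear_predictor_covariance(vc, -1), ">= 0")
})

test_that("stationary relative variance adds environmental and heterogeneity terms", {
  expect_equal(stationary_relative_variance(
    population_params(gamma = 0.1, sigma2_s = 0.16, sigma2_r = 0.002,
                      logK = 10)), 1.0)
  expect_equal(stationary_relative_variance(
    population_params(gamma = 0.1, logK = 10)), 0)
  expect_equal(stationary_relative_variance(
    population_params(gamma = 0.5, sigma2_s = 0.2, sigma2_r = 0.05,
                      logK = 2)), 0.4)
})

test_that("log-abundance covariance matches the mixed-model covariance under the mapping", {
  p <- population_params(gamma = 0.25, sigma2_r = 0.02, sigma2_s = 0.12,
                         sigma2_E = 0.04, logK = 5, nu = 0.3)
  # lag 0 is the stationary variance of log abundance
  expect_equal(log_abundance_covariance(p, 0),
               p$sigma2_r / p$gamma^2 + (p$sigma2_s + p$sigma2_E) / (2 * p$gamma))
  expect_equal(log_abundance_covariance(p, 1e9), p$sigma2_r / p$gamma^2)
  # identity with the linear-predictor covariance of the transformed components
  vc <- to_variance_components(p)
  for (u in c(0, 1, 5))
    expect_equal(log_abundance_covariance(p, u),
                 linear_predictor_covariance(vc, u, same_species = TRUE),
                 tolerance = 1e-14)
  # conservation: relative variance = same-species variance minus common part
  expect_equal(stationary_relative_variance(p),
               linear_predictor_covariance(vc, 0, TRUE, TRUE) - vc$sigma2_c,
               tolerance = 1e-14)
})

test_that("variance components and population parameters are a bijection", {
  vc <- variance_components(beta0 = 9.3, sigma2_h = 0.2, sigma2_e = 0.8,
                            sigma2_c = 0.05, gamma = 0.1, gamma_c = 0.3)
  p <- to_population_params(vc, nu = 0.5)
  expect_equal(p$sigma2_r, 0.002)
  expect_equal(p$sigma2_s, 0.16)
  expect_equal(p$sigma2_E, 2 * 0.3 * 0.05)
  expect_equal(p$logK, 9.3 - log(0.5))
  expect_equal(p$mean_growth, 0.1 * p$logK)
  back <- to_variance_components(p, gamma_c = 0.3)
  for (f in c("beta0", "sigma2_h", "sigma2_e", "sigma2_c", "rate", "rate_c"))
    expect_equal(back[[f]], vc[[f]], tolerance = 1e-12)
  expect_error(to_population_params(vc, nu = 0), "nu")
  expect_error(to_population_params(vc, nu = 1.2), "nu")
})

test_that("variance proportions normalize each partition", {
  vc <- variance_components(sigma2_h = 0.64 * 3, sigma2_e = 0.36 * 3,
                            sigma2_c = 3, sigma2_u = 1, gamma = 1)
  vp <- variance_proportions(vc)
  expect_equal(unname(vp$species_specific), c(0.64, 0.36, 0))
  expect_equal(unname(vp$general), c(0.75, 0.25))
  expect_equal(sum(vp$species_specific), 1, tolerance = 1e-12)
  expect_equal(sum(vp$general), 1, tolerance = 1e-12)
  # scale invariance
  vc10 <- variance_components(sigma2_h = 6.4 * 3, sigma2_e = 3.6 * 3,
                              sigma2_c = 30, sigma2_u = 10, gamma = 1)
  expect_equal(variance_proportions(vc10)$species_specific,
               vp$species_specific)
  expect_error(variance_proportions(variance_components(sigma2_c = 1)),
               "species-specific")
})

test_that("similarity of relative log abundance decays to the heterogeneity floor", {
  vc <- variance_components(sigma2_h = 0.64, sigma2_e = 0.36, gamma = 0.17)
  expect_equal(similarity_relative(vc, 0), 1)
  expect_equal(similarity_relative(vc, 1e9), 0.64, tolerance = 1e-12)
  expect_equal(similarity_relative(vc, 1 / 0.17),
               0.36 * exp(-1) + 0.64, tolerance = 1e-12)
  # observation variance lowers the whole curve
  vco <- variance_components(sigma2_h = 0.64, sigma2_e = 0.36, sigma2_o = 0.5,
                             gamma = 0.17)
  expect_lt(similarity_relative(vco, 0), 1)
  expect_equal(similarity_relative(vco, 0), 1 / 1.5)
})

test_that("similarity of mean log abundance decays at the common-environment rate", {
  vc <- variance_components(sigma2_c = 0.2, gamma = 1, gamma_c = 0.25)
  expect_equal(similarity_mean(vc, 0), 1)
  vc2 <- variance_components(sigma2_c = 0.2, sigma2_u = 0.2, gamma = 1)
  expect_equal(similarity_mean(vc2, 0), 0.5)
  expect_equal(similarity_mean(vc, 1 / 0.25), exp(-1), tolerance = 1e-12)
})

test_that("similarity functions are monotone non-increasing and bounded", {
  set.seed(4)
  for (rep in 1:5) {
    vc <- variance_components(sigma2_h = runif(1), sigma2_e = runif(1),
                              sigma2_c = runif(1), sigma2_o = runif(1, 0, 0.2),
                              sigma2_u = runif(1, 0, 0.2),
                              gamma = runif(1, 0.05, 2),
                              gamma_c = runif(1, 0.05, 2))
    u <- seq(0, 30, by = 0.5)
    for (f in list(similarity_relative, similarity_mean)) {
      v <- f(vc, u)
      expect_true(all(diff(v) <= 1e-14))
      expect_true(all(v > 0 & v <= 1))
    }
  }
})
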