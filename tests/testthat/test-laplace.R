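test_that("Laplace matches adaptive Gauss-Hermite quadrature on iid-intercept models", {
  set.seed(41)
  clusters <- rep(sprintf("c%d", 1:5), each = 4)       # 20 observations
  y <- rpois(20, exp(1 + rnorm(5, 0, 0.6)[rep(1:5, each = 4)]))
  tab <- iid_cluster_table(y, clusters)
  spec <- model_spec(effects = "among_species")
  grid <- expand.grid(beta0 = c(-0.5, 0.5, 1, 1.5),
                      sigma = c(0.2, 0.4, 0.7, 1, 1.5))
  worst <- 0
  for (k in seq_len(nrow(grid))) {
    vc <- variance_components(beta0 = grid$beta0[k],
                              sigma2_h = grid$sigma[k]^2)
    lap <- laplace_nll(tab, spec, vc)
    ora <- agh_nll(y, clusters, grid$beta0[k], grid$sigma[k])
    worst <- max(worst, abs(lap - ora))
  }
  expect_lt(worst, 0.05)
})

test_that("vanishing random-effect variance recovers the fixed-effect Poisson likelihood", {
  y <- c(2L, 5L, 1L, 4L, 3L, 6L)
  tab <- iid_cluster_table(y, rep(c("a", "b"), 3))
  beta0 <- log(mean(y))
  poisson_nll <- -sum(dpois(y, exp(beta0), log = TRUE))
  nll <- laplace_nll(tab, model_spec(effects = "among_species"),
                     variance_components(beta0 = beta0, sigma2_h = 1e-10))
  expect_equal(nll, poisson_nll, tolerance = 1e-5)
})

test_that("duplicated observations shift the likelihood as the oracle dictates", {
  y <- c(3L, 1L, 4L, 2L)
  cl <- c("a", "a", "b", "b")
  tab1 <- iid_cluster_table(y, cl)
  # duplicate every observation as a second replicate of the same events
  tab2 <- community_table(species = rep(cl, 2),
                          time = rep(c(1, 2, 1, 2), 2),
                          replicate = rep(c("r1", "r2"), each = 4),
                          count = rep(y, 2))
  spec <- model_spec(effects = "among_species")
  for (pars in list(c(0.5, 0.5), c(1, 0.8), c(0.2, 1.2))) {
    vc <- variance_components(beta0 = pars[1], sigma2_h = pars[2]^2)
    lap1 <- laplace_nll(tab1, spec, vc)
    lap2 <- laplace_nll(tab2, spec, vc)
    ora1 <- agh_nll(y, cl, pars[1], pars[2])
    ora2 <- agh_nll(rep(y, 2), rep(cl, 2), pars[1], pars[2])
    expect_equal(lap1 - lap2, ora1 - ora2, tolerance = 0.05)
  }
})

test_that("the full-structure likelihood agrees with an independent mixed-model fit", {
  skip_if_not_installed("glmmTMB")
  tab <- small_sim_table(S = 12, Tn = 10, gamma = 0.3, sigma2_e = 0.4,
                         sigma2_h = 0.5, sigma2_c = 0.1, seed = 3)
  fit <- fit_sad_glmm(tab, n_starts = 2)
  df <- as.data.frame(tab)
  df$tf <- glmmTMB::numFactor(df$time)
  df$one <- factor(1)
  df$species <- factor(df$species)
  g <- glmmTMB::glmmTMB(count ~ 1 + (1 | species) + ou(tf + 0 | species) +
                          ou(tf + 0 | one),
                        family = stats::poisson, data = df)
  expect_equal(fit$loglik, as.numeric(stats::logLik(g)), tolerance = 1e-4)
  vcg <- glmmTMB::VarCorr(g)$cond
  expect_equal(fit$estimates$sigma2_h, vcg$species[1, 1], tolerance = 1e-2)
  expect_equal(fit$estimates$sigma2_e, vcg$species.1[1, 1], tolerance = 1e-2)
  expect_equal(fit$estimates$rate,
               -log(attr(vcg$species.1, "correlation")[1, 2]),
               tolerance = 1e-2)
})

test_that("laplace_nll rejects inconsistent inputs", {
  tab <- toy_table()
  expect_error(
    laplace_nll(tab, model_spec(effects = "among_species"),
                variance_components(beta0 = 1)), # sigma2_h = 0
    "variance is 0")
  expect_error(nll_theta <- sadglmm:::nll_theta(
    c(beta0 = NaN), NULL, on_fail = "error"), "non-finite")
})

test_that("the analytic outer gradient matches finite differences", {
  tab <- small_sim_table(S = 8, Tn = 10, gamma = 0.25, sigma2_e = 0.4,
                         sigma2_h = 0.4, sigma2_c = 0.1, logK = 3, seed = 6)
  struct <- build_random_effects(tab, model_spec())
  nm <- sadglmm:::theta_map(struct)
  set.seed(2)
  for (rep in 1:3) {
    th <- setNames(c(runif(1, 1, 3), runif(3, -1.5, 0), runif(2, -1.5, 0.5)),
                   nm)
    objs <- sadglmm:::make_objectives(struct, nm,
                                      new.env(parent = emptyenv()))
    g_an <- objs$gr(th)
    h <- 1e-4
    g_fd <- vapply(seq_along(th), function(k) {
      e <- numeric(length(th)); e[k] <- h
      o <- sadglmm:::make_objectives(struct, nm,
                                     new.env(parent = emptyenv()))
      (o$fn(th + e) - o$fn(th - e)) / (2 * h)
    }, 0)
    expect_lt(max(abs(g_an - g_fd) / (abs(g_fd) + 1)), 1e-3)
  }
})
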