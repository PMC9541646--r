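test_that("the deterministic map sits at its fixed point", {
  cfg <- simulation_config(n_species = 5, n_steps = 30, burn_in = 10,
                           gamma = 0.2, mu_r = 1, nu = 1, seed = 1)
  sim <- simulate_community(cfg)
  expect_true(all(abs(sim$latent_logN - 5) < 1e-10))
})

test_that("simulation is bit-identical under the same seed", {
  cfg <- simulation_config(n_species = 12, n_steps = 40, burn_in = 20,
                           gamma = 0.3, mu_r = 0.9, sigma2_r = 0.01,
                           sigma2_s = 0.05, sigma2_E = 0.02, nu = 0.5,
                           seed = 99)
  s1 <- simulate_community(cfg)
  s2 <- simulate_community(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$latent_logN, s2$latent_logN)
  expect_identical(s1$growth_rates, s2$growth_rates)
})

test_that("common noise alone gives perfect synchrony", {
  cfg <- simulation_config(n_species = 8, n_steps = 60, burn_in = 20,
                           gamma = 0.2, mu_r = 0.6, sigma2_E = 0.1, seed = 5)
  sim <- simulate_community(cfg)
  spread <- apply(sim$latent_logN, 2, function(col) diff(range(col)))
  expect_true(all(spread < 1e-10))
})

test_that("stationary moments match the discrete closed forms", {
  g <- 0.1
  cfg <- simulation_config(n_species = 200, n_steps = 1100, burn_in = 100,
                           gamma = g, mu_r = 1, sigma2_r = g^2 * 0.8,
                           sigma2_s = 2 * g * 0.2, sigma2_E = 0.005,
                           nu = 1, seed = 21)
  sim <- simulate_community(cfg)
  X <- sim$latent_logN
  # grand mean at mu_r / gamma = 10, to Monte-Carlo accuracy
  sp_means <- rowMeans(X)
  se_mean <- sd(sp_means) / sqrt(nrow(X))
  expect_lt(abs(mean(X) - 10), 3 * se_mean + 0.02)
  # relative log abundance: variance = sigma2_s/(1-(1-g)^2) + sigma2_r/g^2
  x <- sweep(X, 2, colMeans(X))
  v_theory <- cfg$sigma2_s / (1 - (1 - g)^2) + cfg$sigma2_r / g^2
  v_per_sp <- rowMeans(x^2)
  se_v <- sd(v_per_sp) / sqrt(nrow(X))
  expect_lt(abs(mean(v_per_sp) - v_theory), 3 * se_v)
  # lag-u autocorrelation of the species-specific deviation is (1-g)^u
  dev <- sweep(x, 1, rowMeans(x))
  for (u in c(1, 3)) {
    ac <- mean(vapply(seq_len(nrow(dev)), function(i) {
      n <- ncol(dev)
      cor(dev[i, 1:(n - u)], dev[i, (1 + u):n])
    }, 0))
    expect_lt(abs(ac - (1 - g)^u), 0.03)
  }
})

test_that("counts are Poisson samples of the latent state", {
  cfg <- simulation_config(n_species = 400, n_steps = 60, burn_in = 10,
                           gamma = 0.5, mu_r = 1.5, nu = 0.8, seed = 3)
  sim <- simulate_community(cfg) # zero variances: constant latent state
  y <- as.vector(sim$counts)
  lambda <- 0.8 * exp(3)
  expect_lt(abs(mean(y) - lambda) / lambda, 0.01)
  expect_lt(abs(var(y) - lambda) / lambda, 0.05)
})

test_that("latent overflow aborts with the offending step", {
  cfg <- simulation_config(n_species = 2, n_steps = 10, burn_in = 5,
                           gamma = 0.5, mu_r = 400, nu = 1, seed = 1)
  expect_error(simulate_community(cfg), "step 1")
})

test_that("the factorial design grid applies the stated transformations", {
  grid <- simulation_study_grid()
  expect_length(grid, 3 * 4 * 2 * 3)
  tr <- t(vapply(grid, function(cfg) attr(cfg, "glmm_truth"), numeric(5)))
  # three sampling intensities x four sigma2_e levels x two sigma2_c per gamma
  for (g in c(0.05, 0.1, 0.5)) {
    sub <- tr[tr[, "gamma"] == g, ]
    expect_equal(sort(unique(sub[, "nu"])), c(0.01, 0.1, 0.5))
    expect_equal(sort(unique(sub[, "sigma2_e"])), c(0.2, 0.4, 0.6, 0.8))
    expect_equal(sort(unique(sub[, "sigma2_c"])), c(0.01, 0.1))
  }
  # the cell gamma=0.1, sigma2_e=0.2 has sigma2_s = 2*0.1*0.2
  k <- which(tr[, "gamma"] == 0.1 & tr[, "sigma2_e"] == 0.2 &
               tr[, "sigma2_c"] == 0.1 & tr[, "nu"] == 0.5)
  expect_equal(grid[[k[1]]]$sigma2_s, 0.04)
  expect_equal(grid[[k[1]]]$mu_r, 1)
  # sigma2_h + sigma2_e = 1 in every cell
  for (cfg in grid) {
    tru <- attr(cfg, "glmm_truth")
    expect_equal(cfg$sigma2_r / cfg$gamma^2 + tru[["sigma2_e"]], 1,
                 tolerance = 1e-12)
  }
  # alternative gamma set
  alt <- simulation_study_grid(gamma_set = "text")
  expect_equal(sort(unique(vapply(alt, function(cfg) cfg$gamma, 0))),
               c(0.01, 0.1, 0.5))
})

test_that("simulated communities export to tables and CSV with a config sidecar", {
  cfg <- simulation_config(n_species = 6, n_steps = 25, burn_in = 20,
                           gamma = 0.3, mu_r = 0.9, sigma2_s = 0.05, seed = 2)
  sim <- simulate_community(cfg)
  tab <- as_community_table(sim)
  expect_s3_class(tab, "community_table")
  expect_equal(nrow(tab), 6 * 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_simulation(sim, path)
  back <- read_community_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))
  side <- yaml::read_yaml(paste0(path, ".config.yml"))
  expect_equal(side$seed, 2L)
  expect_equal(side$gamma, 0.3)
})
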