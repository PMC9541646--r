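test_that("constant counts drive all variances to the boundary", {
  grid <- expand.grid(species = c("a", "b", "c"), time = 1:4,
                      replicate = c("r1", "r2"), stringsAsFactors = FALSE)
  tab <- community_table(grid$species, grid$time, replicate = grid$replicate,
                         count = rep(7L, nrow(grid)))
  fit <- suppressWarnings(
    fit_sad_glmm(tab, model_spec(effects = c("among_species",
                                             "observation_level")),
                 n_starts = 1))
  expect_true(all(fit$boundary))
  expect_equal(fit$estimates$beta0, log(7), tolerance = 1e-3)
  diag <- fit_diagnostics(fit)
  expect_true(all(c("among_species", "observation_level") %in%
                    diag$target[diag$check == "boundary"]))
})

test_that("moderate simulated data are recovered and flagged clean", {
  tab <- small_sim_table(S = 25, Tn = 15, gamma = 0.2, sigma2_e = 0.3,
                         sigma2_h = 0.6, sigma2_c = 0.05, logK = 4, seed = 9)
  fit <- fit_sad_glmm(tab, n_starts = 1)
  expect_true(fit$converged)
  expect_true(is.finite(fit$loglik))
  # single replicate: loose sanity bands only
  expect_gt(fit$estimates$sigma2_h, 0.2)
  expect_lt(fit$estimates$sigma2_h, 1.5)
  expect_gt(fit$estimates$sigma2_e, 0.05)
  # conditional modes are centered near zero
  expect_lt(abs(mean(fit$re_modes$among_species)), 0.5)
  expect_equal(length(fit$re_modes$among_species), 25)
})

test_that("few unit levels are flagged for correlated common effects", {
  tab <- small_sim_table(S = 20, Tn = 4, gamma = 0.2, sigma2_e = 0.3,
                         sigma2_h = 0.5, sigma2_c = 0.1, logK = 4, seed = 10)
  fit <- fit_sad_glmm(tab, n_starts = 1)
  diag <- fit_diagnostics(fit)
  expect_true("common_unit_correlated" %in%
                diag$target[diag$check == "few_levels"])
})

test_that("all-zero species are kept with a warning", {
  tab <- as.data.frame(small_sim_table(S = 6, Tn = 5, logK = 3, seed = 12))
  tab$count[tab$species == "sp001"] <- 0L
  tab <- sadglmm:::validate_community_table(tab)
  expect_warning(fit_sad_glmm(tab, model_spec(effects = c(
    "among_species", "species_by_unit_correlated")), n_starts = 1),
    "all-zero")
})

test_that("fit results serialize to JSON", {
  tab <- small_sim_table(S = 8, Tn = 6, logK = 3, seed = 13)
  fit <- fit_sad_glmm(tab, n_starts = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path, seed = 7)
  got <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(got$loglik, fit$loglik, tolerance = 1e-9)
  expect_equal(got$estimates$sigma2_h, fit$estimates$sigma2_h,
               tolerance = 1e-9)
  expect_equal(got$seed, 7)
  expect_equal(got$n_obs, nrow(tab))
})

test_that("spatial models fit with a distance kernel", {
  # simulate via the temporal machinery, then relabel times as locations on
  # a transect; the spatial fit should find comparable structure
  tab <- small_sim_table(S = 15, Tn = 8, gamma = 0.3, sigma2_e = 0.4,
                         sigma2_h = 0.4, sigma2_c = 0.05, logK = 4, seed = 22)
  sp_tab <- community_table(species = tab$species, time = 1,
                            location = sprintf("site%02d", tab$time),
                            count = tab$count)
  sites <- sort(unique(sp_tab$location))
  D <- abs(outer(seq_along(sites), seq_along(sites), "-")) * 2 # km spacing
  dimnames(D) <- list(sites, sites)
  fit <- fit_sad_glmm(sp_tab, model_spec("spatial", distances = D),
                      n_starts = 1)
  expect_true(fit$converged)
  expect_identical(fit$estimates$dimension, "spatial")
  expect_true(is.finite(fit$estimates$rate))
})
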