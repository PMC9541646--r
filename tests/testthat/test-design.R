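test_that("effect counts follow the Kronecker dimensions", {
  tab <- community_table(species = rep(c("A", "B"), each = 2),
                         time = rep(1:2, 2), location = "L1",
                         count = c(1, 2, 3, 4))
  struct <- build_random_effects(tab, model_spec())
  levels <- vapply(struct$blocks, `[[`, 0L, "n_levels")
  expect_equal(unname(levels[c("among_species", "species_by_unit_correlated",
                               "common_unit_correlated")]),
               c(2L, 4L, 2L))
  expect_equal(struct$q, 8L)
})

test_that("grouped designs share species effects but nest unit effects", {
  # 3 species x 4 times x 2 locations, temporal model grouped by location
  grid <- expand.grid(species = c("a", "b", "c"), time = 1:4,
                      location = c("L1", "L2"), stringsAsFactors = FALSE)
  tab <- community_table(grid$species, grid$time, grid$location,
                         count = rep(1L, nrow(grid)))
  struct <- build_random_effects(tab, model_spec())
  levels <- vapply(struct$blocks, `[[`, 0L, "n_levels")
  expect_equal(unname(levels["among_species"]), 3L)          # shared
  expect_equal(unname(levels["species_by_unit_correlated"]), 3L * 4L * 2L)
  expect_equal(unname(levels["common_unit_correlated"]), 4L * 2L)
  # ragged grid: drop one year from L2
  tab2 <- tab[!(tab$location == "L2" & tab$time == 4), ]
  struct2 <- build_random_effects(
    sadglmm:::validate_community_table(as.data.frame(tab2)), model_spec())
  levels2 <- vapply(struct2$blocks, `[[`, 0L, "n_levels")
  expect_equal(unname(levels2["species_by_unit_correlated"]), 3L * 4L + 3L * 3L)
  expect_equal(unname(levels2["common_unit_correlated"]), 7L)
})

test_that("additional effect types index observations and sampling units", {
  grid <- expand.grid(species = c("a", "b"), time = 1:3,
                      replicate = c("r1", "r2"), stringsAsFactors = FALSE)
  tab <- community_table(grid$species, grid$time, replicate = grid$replicate,
                         count = rep(2L, nrow(grid)))
  spec <- model_spec(effects = c("among_species", "observation_level",
                                 "sampling_unit_iid"))
  struct <- build_random_effects(tab, spec)
  levels <- vapply(struct$blocks, `[[`, 0L, "n_levels")
  expect_equal(unname(levels["observation_level"]), nrow(grid))
  expect_equal(unname(levels["sampling_unit_iid"]), 3L * 2L)
  expect_error(model_spec(effects = "not_an_effect"), "unknown")
  expect_error(model_spec(effects = character(0)), "at least one")
})

test_that("the likelihood is invariant to row order and species relabeling", {
  tab <- small_sim_table(S = 8, Tn = 6, seed = 14)
  vc <- variance_components(beta0 = log(mean(tab$count) + 1),
                            sigma2_h = 0.4, sigma2_e = 0.3, sigma2_c = 0.05,
                            gamma = 0.3, gamma_c = 0.5)
  spec <- model_spec()
  nll1 <- laplace_nll(tab, spec, vc)
  set.seed(2)
  shuffled <- tab[sample(nrow(tab)), ]
  rownames(shuffled) <- NULL
  nll2 <- laplace_nll(sadglmm:::validate_community_table(shuffled), spec, vc)
  expect_equal(nll1, nll2, tolerance = 1e-9)
  # relabel species (permutation of names)
  relab <- tab
  relab$species <- factor(relab$species,
                          levels = sort(unique(relab$species)),
                          labels = rev(sprintf("z%02d", 1:8)))
  relab$species <- as.character(relab$species)
  nll3 <- laplace_nll(sadglmm:::validate_community_table(as.data.frame(relab)),
                      spec, vc)
  expect_equal(nll1, nll3, tolerance = 1e-9)
})

test_that("temporal OU and spatial exponential kernels agree on a line", {
  # a spatial model whose locations sit on a line at the time coordinates
  # must give the same likelihood as the temporal model (dense vs
  # tridiagonal precision paths)
  tab <- small_sim_table(S = 6, Tn = 5, seed = 31)
  vc_t <- variance_components(beta0 = 2, sigma2_h = 0.3, sigma2_e = 0.4,
                              sigma2_c = 0.1, gamma = 0.35, gamma_c = 0.35)
  nll_t <- laplace_nll(tab, model_spec(), vc_t)

  sp_tab <- community_table(species = tab$species,
                            time = 1,
                            location = as.character(tab$time),
                            count = tab$count)
  times <- sort(unique(tab$time))
  D <- abs(outer(times, times, "-"))
  dimnames(D) <- list(as.character(times), as.character(times))
  vc_s <- variance_components(beta0 = 2, sigma2_h = 0.3, sigma2_e = 0.4,
                              sigma2_c = 0.1, alpha = 0.35, alpha_c = 0.35)
  nll_s <- laplace_nll(sp_tab, model_spec("spatial", distances = D), vc_s)
  expect_equal(nll_t, nll_s, tolerance = 1e-8)
})

test_that("duplicate observations are rejected", {
  df <- data.frame(species = c("a", "a"), time = c(1, 1),
                   location = "L1", replicate = "1", count = c(1, 2))
  expect_error(sadglmm:::validate_community_table(df), "duplicate")
})
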