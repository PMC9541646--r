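#' Repeated simulate-and-refit experiment for one parameter cell
#'
#' Simulates `n_reps` communities from one [simulation_config()] and fits
#' the temporal three-component model (species heterogeneity,
#' species-by-time, common-time, with separate decay rates) to each,
#' returning the per-replicate estimates next to the generating values.
#' This is the building block of the estimation-accuracy study and of the
#' desk-scale parameter-recovery checks.
#'
#' @param config A [simulation_config()]; its `glmm_truth` attribute (set by
#'   [simulation_study_grid()]) or the transformation of its parameters
#'   provides the generating GLMM-scale values.
#' @param n_reps Number of replicate simulate+fit cycles.
#' @param seed Base seed; replicate k uses `seed + k`.
#' @param n_starts Optimizer starts per fit (1 is adequate at these sample
#'   sizes; raise for difficult cells).
#' @param verbose Report progress?
#' @return A data frame with one row per converged replicate: estimated
#'   `sigma2_h`, `sigma2_e`, `sigma2_c`, `gamma`, `gamma_c`, `beta0`, the
#'   replicate seed, and the generating values as attributes (`truth`).
#' @export
recovery_experiment <- function(config, n_reps = 25, seed = 1L,
                                n_starts = 1, verbose = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  truth <- attr(config, "glmm_truth")
  if (is.null(truth)) {
    g <- config$gamma
    truth <- c(sigma2_h = config$sigma2_r / g^2,
               sigma2_e = config$sigma2_s / (2 * g),
               sigma2_c = config$sigma2_E / (2 * g),
               gamma = g, nu = config$nu)
  }
  spec <- model_spec("temporal",
                     effects = c("among_species",
                                 "species_by_unit_correlated",
                                 "common_unit_correlated"),
                     separate_common_rate = TRUE)
  rows <- vector("list", n_reps)
  for (k in seq_len(n_reps)) {
    cfg <- config; cfg$seed <- as.integer((seed + k) %% .Machine$integer.max)
    sim <- simulate_community(cfg)
    tab <- as_community_table(sim)
    ft <- tryCatch(
      suppressWarnings(fit_sad_glmm(tab, spec, n_starts = n_starts,
                                    seed = cfg$seed)),
      error = function(e) NULL)
    if (!is.null(ft) && ft$converged) {
      e <- ft$estimates
      rows[[k]] <- data.frame(sigma2_h = e$sigma2_h, sigma2_e = e$sigma2_e,
                              sigma2_c = e$sigma2_c, gamma = e$rate,
                              gamma_c = e$rate_c, beta0 = e$beta0,
                              seed = cfg$seed)
    }
    if (verbose) message(sprintf("replicate %d/%d %s", k, n_reps,
                                 if (is.null(rows[[k]])) "(failed)" else ""))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  attr(out, "truth") <- truth
  out
}

#' Estimation-accuracy study over a factorial design grid
#'
#' Runs [recovery_experiment()] for every cell of (a filtered subset of)
#' [simulation_study_grid()] and summarizes the bias of the estimated
#' variance components per cell. Cell sizes can be scaled down from the
#' full design (100 species, 50 retained steps) for quick runs.
#'
#' @param n_reps Replicates per cell.
#' @param gamma,nu,sigma2_e,sigma2_c Optional filters restricting the grid
#'   to matching cells.
#' @param n_species,n_keep Optional overrides of the community size and the
#'   number of retained time steps.
#' @param gamma_set Passed to [simulation_study_grid()].
#' @param seed Base seed.
#' @param verbose Report progress?
#' @return A data frame with one row per cell: the cell's generating values,
#'   the number of converged replicates, and mean bias of `sigma2_h`,
#'   `sigma2_e`, `sigma2_c`.
#' @export
simulation_study <- function(n_reps = 50, gamma = NULL, nu = NULL,
                             sigma2_e = NULL, sigma2_c = NULL,
                             n_species = NULL, n_keep = NULL,
                             gamma_set = "figure", seed = 1L,
                             verbose = FALSE) {
  grid <- simulation_study_grid(gamma_set = gamma_set, seed = seed)
  keep <- vapply(grid, function(cfg) {
    tr <- attr(cfg, "glmm_truth")
    (is.null(gamma) || tr[["gamma"]] %in% gamma) &&
      (is.null(nu) || tr[["nu"]] %in% nu) &&
      (is.null(sigma2_e) || tr[["sigma2_e"]] %in% sigma2_e) &&
      (is.null(sigma2_c) || tr[["sigma2_c"]] %in% sigma2_c)
  }, logical(1))
  grid <- grid[keep]
  if (!length(grid)) stop("no grid cells match the filters")
  rows <- lapply(seq_along(grid), function(k) {
    cfg <- grid[[k]]
    tr <- attr(cfg, "glmm_truth")
    if (!is.null(n_species)) cfg$n_species <- as.integer(n_species)
    if (!is.null(n_keep)) {
      cfg$n_steps <- as.integer(cfg$burn_in + n_keep)
    }
    attr(cfg, "glmm_truth") <- tr
    est <- recovery_experiment(cfg, n_reps = n_reps, seed = seed + 1000L * k,
                               verbose = verbose)
    data.frame(gamma = tr[["gamma"]], nu = tr[["nu"]],
               sigma2_e = tr[["sigma2_e"]], sigma2_c = tr[["sigma2_c"]],
               n_converged = nrow(est),
               bias_sigma2_h = mean(est$sigma2_h) - (1 - tr[["sigma2_e"]]),
               bias_sigma2_e = mean(est$sigma2_e) - tr[["sigma2_e"]],
               bias_sigma2_c = mean(est$sigma2_c) - tr[["sigma2_c"]])
  })
  do.call(rbind, rows)
}
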