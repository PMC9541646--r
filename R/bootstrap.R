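# Percentile-interval bounds by the classical (B+1) order-statistic
# convention: the lower bound is the floor(alpha*(B+1))-th order statistic.
# Interpolation-free, so intervals of monotone transforms are exactly the
# transforms of intervals.
percentile_bound <- function(x, level, side = c("lower", "upper")) {
  side <- match.arg(side)
  x <- sort(x)
  B <- length(x)
  a <- (1 - level) / 2
  k <- max(1L, floor(a * (B + 1)))
  if (side == "lower") x[k] else x[B + 1L - k]
}

#' Parametric-bootstrap uncertainty for a fitted model
#'
#' For each replicate, simulates counts from the fitted model on the
#' original design ([simulate_from_fitted()]) and refits the same model
#' specification, warm-starting from the original estimates with one
#' fallback dispersed start. Percentile confidence intervals are computed
#' from the converged replicates; non-converged replicates are counted and
#' excluded. Per-replicate seeds are derived from the master seed by a
#' counter, so the whole procedure is reproducible.
#'
#' @param fit A converged `sad_glmm`.
#' @param n_reps Number of bootstrap replicates (>= 2; 1000 for production
#'   use, fewer for exploration).
#' @param level Confidence level in (0, 1), default 0.95.
#' @param seed Master seed.
#' @param verbose Report progress every 10 replicates?
#' @return An object of class `sad_bootstrap`: `replicate_estimates` (data
#'   frame, one row per converged replicate, columns = parameters on the
#'   natural scale), `intervals` (data frame with `lower`, `upper`,
#'   `estimate`), `n_requested`, `n_converged`, `level`, `seed`.
#' @export
parametric_bootstrap <- function(fit, n_reps = 1000, level = 0.95,
                                 seed = 1L, verbose = FALSE) {
  stopifnot(inherits(fit, "sad_glmm"))
  if (!fit$converged) stop("fit did not converge")
  if (n_reps < 2) stop("n_reps must be >= 2")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  est0 <- unlist(vc_to_list(fit$estimates))
  reps <- vector("list", n_reps)
  n_ok <- 0L
  # the design is identical for every replicate: reuse the fitted structure
  # and swap in the simulated counts
  struct <- fit$struct
  nm <- names(fit$theta)
  bounds <- theta_bounds(nm)
  ctl <- list(rel.tol = 1e-8, iter.max = 200, eval.max = 800)
  refit_theta <- function(start, cache) {
    objs <- make_objectives(struct, nm, cache)
    tryCatch(nlminb_robust(start, objs$fn, objs$gr,
                           bounds$lower, bounds$upper, ctl),
             error = function(e) list(convergence = 1L, objective = Inf,
                                      message = conditionMessage(e)))
  }
  for (k in seq_len(n_reps)) {
    rep_seed <- (seed + k) %% .Machine$integer.max
    struct$y <- draw_counts(fit$struct, fit$theta, rep_seed)
    # warm start at the original estimates, one dispersed fallback
    res <- refit_theta(fit$theta, new.env(parent = emptyenv()))
    if (!port_converged(res) || !is.finite(res$objective)) {
      set.seed(rep_seed)
      start2 <- fit$theta
      start2[-1] <- start2[-1] + runif(length(nm) - 1, log(0.5), log(1.5))
      start2 <- pmin(pmax(start2, bounds$lower), bounds$upper)
      res <- refit_theta(start2, new.env(parent = emptyenv()))
    }
    if (port_converged(res) && is.finite(res$objective)) {
      n_ok <- n_ok + 1L
      reps[[k]] <- unlist(vc_to_list(theta_to_vc(setNames(res$par, nm),
                                                 struct)))
    }
    if (verbose && k %% 10 == 0)
      message(sprintf("bootstrap replicate %d/%d (%d converged)",
                      k, n_reps, n_ok))
  }
  if (n_ok < n_reps / 2)
    stop("fewer than half the bootstrap replicates converged (",
         n_ok, "/", n_reps, ")")
  tab <- as.data.frame(do.call(rbind, reps[!vapply(reps, is.null, TRUE)]))
  intervals <- data.frame(
    parameter = names(tab),
    estimate = est0[names(tab)],
    lower = vapply(tab, percentile_bound, 0, level = level, side = "lower"),
    upper = vapply(tab, percentile_bound, 0, level = level, side = "upper"),
    row.names = NULL)
  structure(list(replicate_estimates = tab, intervals = intervals,
                 n_requested = n_reps, n_converged = n_ok,
                 level = level, seed = seed, fit = fit),
            class = "sad_bootstrap")
}

#' @export
print.sad_bootstrap <- function(x, ...) {
  cat(sprintf("Parametric bootstrap: %d/%d replicates converged, %.0f%% intervals\n",
              x$n_converged, x$n_requested, 100 * x$level))
  print(x$intervals, digits = 4)
  invisible(x)
}

#' Percentile intervals for derived quantities
#'
#' Applies transformations to every bootstrap replicate before taking
#' percentiles, yielding intervals for derived quantities: population-
#' dynamic parameters, variance proportions, similarity values at chosen
#' lags, return times, and so on. Replicates on which a transform is
#' non-finite (e.g. a ratio at a boundary replicate) are dropped for that
#' transform, with the drop count reported.
#'
#' @param result A `sad_bootstrap`.
#' @param transforms Named list of functions; each receives one replicate as
#'   a named list of parameters (keys as in [write_params()]) and returns a
#'   single number.
#' @param level Confidence level; defaults to the bootstrap's.
#' @return A data frame with columns `quantity`, `estimate`, `lower`,
#'   `upper`, `n_used`, `n_dropped`.
#' @export
summarize_intervals <- function(result, transforms, level = result$level) {
  stopifnot(inherits(result, "sad_bootstrap"))
  if (nrow(result$replicate_estimates) == 0) stop("empty bootstrap result")
  tab <- result$replicate_estimates
  est0 <- as.list(unlist(vc_to_list(result$fit$estimates)))
  rows <- lapply(names(transforms), function(nm) {
    f <- transforms[[nm]]
    vals <- vapply(seq_len(nrow(tab)), function(r) {
      out <- tryCatch(f(as.list(tab[r, , drop = FALSE])),
                      error = function(e) NA_real_)
      if (length(out) != 1) NA_real_ else as.numeric(out)
    }, 0)
    ok <- is.finite(vals)
    if (!any(ok)) stop("transform '", nm, "' is non-finite on all replicates")
    data.frame(quantity = nm,
               estimate = tryCatch(as.numeric(f(est0)), error = function(e) NA_real_),
               lower = percentile_bound(vals[ok], level, "lower"),
               upper = percentile_bound(vals[ok], level, "upper"),
               n_used = sum(ok), n_dropped = sum(!ok))
  })
  do.call(rbind, rows)
}

#' Write bootstrap results to disk
#'
#' The replicate table goes to CSV and the intervals (with level, seeds and
#' package version) to JSON.
#'
#' @param result A `sad_bootstrap`.
#' @param csv_path Path for the replicate table CSV.
#' @param json_path Path for the intervals JSON.
#' @return Invisibly, `c(csv_path, json_path)`.
#' @export
write_bootstrap <- function(result, csv_path, json_path) {
  stopifnot(inherits(result, "sad_bootstrap"))
  write.csv(result$replicate_estimates, csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(package_version = as.character(packageVersion("sadglmm")),
         level = result$level, seed = result$seed,
         n_requested = result$n_requested, n_converged = result$n_converged,
         intervals = result$intervals),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, json_path))
}
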