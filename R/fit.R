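# starting values: intercept from the grand mean count, the method-of-moments
# log-count variance split evenly over included variance components, decay
# rates at 1/(median positive lag)
default_start <- function(struct, data) {
  y <- struct$y
  beta0 <- log(max(mean(y), 1e-3))
  v <- var(log(pmax(y, 0.5)))
  if (!is.finite(v) || v <= 0) v <- 0.1
  nvar <- length(struct$blocks)
  nm <- theta_map(struct)
  theta <- setNames(numeric(length(nm)), nm)
  theta[["beta0"]] <- beta0
  for (bl in struct$blocks)
    theta[[paste0("log_sd_", bl$code)]] <- 0.5 * log(v / nvar)
  if (any(c("log_rate", "log_rate_c") %in% nm)) {
    lag0 <- if (struct$dimension == "temporal") {
      tt <- sort(unique(data$time))
      if (length(tt) > 1) median(diff(tt)) else 1
    } else {
      D <- attr(struct, "median_distance")
      if (is.null(D)) 1 else D
    }
    for (rn in intersect(c("log_rate", "log_rate_c"), nm))
      theta[[rn]] <- log(1 / max(lag0, 1e-6))
  }
  theta
}

theta_bounds <- function(nm) {
  lower <- setNames(rep(-Inf, length(nm)), nm)
  upper <- setNames(rep(Inf, length(nm)), nm)
  sd_idx <- grepl("^log_sd_", nm)
  lower[sd_idx] <- -8; upper[sd_idx] <- 4
  rate_idx <- grepl("^log_rate", nm)
  lower[rate_idx] <- log(1e-4); upper[rate_idx] <- log(100)
  list(lower = lower, upper = upper)
}

#' Fit a dynamic species abundance distribution by Poisson mixed model
#'
#' Maximizes the Laplace-approximated marginal likelihood of the
#' intercept-only Poisson model with the random-effect structure given by
#' `spec`, using a quasi-Newton outer optimizer over the unconstrained
#' parameterization (intercept, log standard deviations, log decay rates).
#' Multiple dispersed starts guard against local optima; the best converged
#' fit is returned. Variance components are reported on the natural scale
#' and decay rates alongside their e-folding scales (`1/gamma` time units,
#' `1/alpha` km).
#'
#' @param data A `community_table`. Zero counts are data: apply
#'   [zero_fill()] beforehand so every registered species has a row at every
#'   sampling event.
#' @param spec A [model_spec()]; defaults to the temporal three-component
#'   structure (species heterogeneity, species-by-time, common-time).
#' @param n_starts Number of optimizer starts (first from method-of-moments
#'   values, the rest jittered by up to +/-50%). Default 3.
#' @param start Optional named theta vector overriding the default start.
#' @param control List passed to [stats::nlminb()]'s control (defaults:
#'   `rel.tol 1e-9`, `iter.max 300`).
#' @param seed Seed for the start jitter.
#' @param verbose Print per-start progress?
#' @return An object of class `sad_glmm` with elements `estimates`
#'   (a [variance_components()]), `loglik`, `theta`, `re_modes`,
#'   `converged`, `boundary` (named flags for components at the boundary),
#'   `opt` (optimizer record per start), `spec`, `n_obs`, `n_species`,
#'   `n_units`, `n_groups`, and the fitting `data`.
#' @export
fit_sad_glmm <- function(data, spec = model_spec(), n_starts = 3,
                         start = NULL, control = list(), seed = 1L,
                         verbose = FALSE) {
  stopifnot(inherits(data, "community_table"))
  if (any(data$count < 0)) stop("counts must be nonnegative")
  struct <- build_random_effects(data, spec)
  if ("observation_level" %in% spec$effects) {
    J <- max(table(paste(data$species, data$time, data$location)))
    if (J < 2)
      warning("observation_level effect with a single replicate per event ",
              "is only weakly separable from the Poisson variance")
  }
  for (bl in struct$blocks)
    if (bl$kind == "corr") {
      nu_max <- max(vapply(bl$chunks, `[[`, 0L, "n"))
      if (nu_max < 2)
        stop("correlated effect '", bl$name,
             "' needs at least 2 units in some group")
    }
  all_zero_sp <- tapply(data$count, data$species, function(z) all(z == 0))
  if (any(all_zero_sp))
    warning(sum(all_zero_sp), " species have all-zero counts; they are ",
            "retained (zeros are data) but pull variance estimates upward")

  nm <- theta_map(struct)
  bounds <- theta_bounds(nm)
  ctl <- modifyList(list(rel.tol = 1e-9, iter.max = 300, eval.max = 1000),
                    control)
  theta0 <- if (is.null(start)) default_start(struct, data) else start[nm]

  set.seed(seed)
  fits <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    th <- theta0
    if (s > 1) { # jitter all but the intercept by up to +/-50%
      jit <- runif(length(th) - 1, log(0.5), log(1.5))
      th[-1] <- pmin(pmax(th[-1] + jit, bounds$lower[-1]), bounds$upper[-1])
    }
    cache <- new.env(parent = emptyenv())
    objs <- make_objectives(struct, nm, cache)
    res <- tryCatch(
      nlminb_robust(th, objs$fn, objs$gr, bounds$lower, bounds$upper, ctl),
      error = function(e) list(convergence = 1L, message = conditionMessage(e),
                               objective = Inf, par = th))
    fits[[s]] <- res
    if (verbose)
      message(sprintf("start %d: nll = %.4f (%s)", s, res$objective,
                      res$message))
  }
  objs <- vapply(fits, function(f) f$objective, 0)
  ok <- is.finite(objs)
  if (!any(ok))
    stop("no start converged; optimizer messages: ",
         paste(vapply(fits, function(f) f$message %||% "?", ""),
               collapse = " | "))
  best <- fits[[which.min(objs)]]
  theta_hat <- setNames(best$par, nm)

  # conditional modes and final likelihood at the optimum
  cache <- new.env(parent = emptyenv())
  nll <- nll_theta(theta_hat, struct, cache = cache, on_fail = "error")
  re_modes <- list()
  for (bl in struct$blocks)
    re_modes[[bl$name]] <- cache$b[bl$offset + seq_len(bl$n_levels)]

  vc <- theta_to_vc(theta_hat, struct)
  # a log-sd within 0.5 of the optimizer floor counts as a zero boundary
  boundary <- vapply(struct$blocks, function(bl) {
    theta_hat[[paste0("log_sd_", bl$code)]] <= -7.5
  }, logical(1))
  names(boundary) <- vapply(struct$blocks, `[[`, "", "name")

  structure(list(estimates = vc, loglik = -nll, theta = theta_hat,
                 re_modes = re_modes,
                 converged = port_converged(best),
                 boundary = boundary,
                 opt = fits, spec = spec,
                 n_obs = struct$N, n_species = struct$n_species,
                 n_units = struct$n_units, n_groups = struct$n_groups,
                 struct = struct, data = data),
            class = "sad_glmm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

port_converged <- function(res) {
  isTRUE(res$convergence == 0) ||
    grepl("relative convergence|X-convergence|singular",
          res$message %||% "")
}

# nlminb with a restart on "false convergence": with finite-difference outer
# gradients PORT can fail to certify a genuine optimum against evaluation
# noise; a restart that reproduces the same objective is accepted
nlminb_robust <- function(start, fn, gr, lower, upper, ctl) {
  res <- nlminb(start, fn, gradient = gr, lower = lower, upper = upper,
                control = ctl)
  if (!port_converged(res) &&
      grepl("false convergence", res$message %||% "")) {
    res2 <- nlminb(res$par, fn, gradient = gr, lower = lower, upper = upper,
                   control = ctl)
    if (port_converged(res2)) return(res2)
    if (is.finite(res2$objective) &&
        abs(res2$objective - res$objective) <
          1e-6 * max(1, abs(res$objective))) {
      res2$convergence <- 0L
      res2$message <- paste(res2$message, "(objective stable under restart)")
      return(res2)
    }
    return(res2)
  }
  res
}

#' @export
print.sad_glmm <- function(x, ...) {
  cat(sprintf("Poisson mixed model fit (%s): %d obs, %d species, %d units, %d groups\n",
              x$spec$dimension, x$n_obs, x$n_species, x$n_units, x$n_groups))
  cat(sprintf("log-likelihood (Laplace): %.3f  converged: %s\n",
              x$loglik, x$converged))
  print(x$estimates)
  if (any(x$boundary))
    cat("components at boundary:",
        paste(names(x$boundary)[x$boundary], collapse = ", "), "\n")
  invisible(x)
}

#' @export
logLik.sad_glmm <- function(object, ...) {
  structure(object$loglik, df = length(object$theta), class = "logLik")
}

#' Post-fit identifiability and boundary diagnostics
#'
#' Flags variance components estimated at the boundary (effectively zero),
#' decay rates whose likelihood is flat over a 10-fold range (non-
#' identifiable scale), and correlated effects estimated from few unit
#' levels, which carry large uncertainty.
#'
#' @param fit A fitted `sad_glmm`.
#' @param few_levels Threshold below which a unit count triggers a warning
#'   flag (default 5).
#' @param flat_tol Log-likelihood change under a 10-fold rate perturbation
#'   below which the rate is flagged flat (default 0.05).
#' @return A data frame of diagnostics (zero rows when all is well) with
#'   columns `check`, `target`, `message`.
#' @export
fit_diagnostics <- function(fit, few_levels = 5, flat_tol = 0.05) {
  stopifnot(inherits(fit, "sad_glmm"))
  out <- data.frame(check = character(), target = character(),
                    message = character(), stringsAsFactors = FALSE)
  add <- function(check, target, message)
    out <<- rbind(out, data.frame(check = check, target = target,
                                  message = message))
  for (nm in names(fit$boundary))
    if (fit$boundary[[nm]])
      add("boundary", nm, "variance estimated at the zero boundary")
  struct <- fit$struct
  for (bl in struct$blocks)
    if (bl$kind == "corr") {
      n_units <- max(vapply(bl$chunks, `[[`, 0L, "n"))
      if (n_units < few_levels)
        add("few_levels", bl$name,
            sprintf("correlated effect estimated from only %d unit levels",
                    n_units))
    }
  # flat-likelihood probe for each rate: 10x range around the estimate
  cache <- new.env(parent = emptyenv())
  for (rn in intersect(c("log_rate", "log_rate_c"), names(fit$theta))) {
    th_lo <- fit$theta; th_lo[[rn]] <- th_lo[[rn]] - log(sqrt(10))
    th_hi <- fit$theta; th_hi[[rn]] <- th_hi[[rn]] + log(sqrt(10))
    d <- tryCatch({
      n0 <- -fit$loglik
      max(abs(nll_theta(th_lo, struct, cache) - n0),
          abs(nll_theta(th_hi, struct, cache) - n0))
    }, error = function(e) NA_real_)
    if (is.finite(d) && d < flat_tol)
      add("flat_rate", rn,
          sprintf("log-likelihood changes by only %.3g over a 10-fold range",
                  d))
  }
  out
}

#' Write a fitted model to a JSON results file
#'
#' Serializes the estimates, log-likelihood, convergence record, model
#' specification, dimensions and package version.
#'
#' @param fit A `sad_glmm`.
#' @param path Output JSON path.
#' @param seed Optional seed to record.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, seed = NULL) {
  lst <- list(package_version = as.character(packageVersion("sadglmm")),
              estimates = vc_to_list(fit$estimates),
              loglik = fit$loglik,
              converged = fit$converged,
              boundary = as.list(fit$boundary),
              spec = list(dimension = fit$spec$dimension,
                          effects = fit$spec$effects,
                          group_by = fit$spec$group_by,
                          separate_common_rate = fit$spec$separate_common_rate),
              n_obs = fit$n_obs, n_species = fit$n_species,
              n_units = fit$n_units, n_groups = fit$n_groups)
  if (!is.null(seed)) lst$seed <- seed
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
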