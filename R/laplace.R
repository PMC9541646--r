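# Laplace approximation of the marginal Poisson lognormal likelihood.
#
# The joint log density of counts y and random effects b is
#   l(b) = sum(y*eta - exp(eta) - log y!) - b' Q b / 2,   eta = beta0 + Z b,
# with Q the block sparse precision of the random effects. The inner Newton
# step maximizes l over b (the conditional mode); the marginal log likelihood
# is then  l(b_hat) + log det(Q)/2 - log det(H)/2  with H = Q + Z' W Z,
# W = diag(exp(eta_hat)). Sparsity: Q is block tridiagonal/dense-small, and
# the symbolic Cholesky of H is computed once and reused across evaluations.

# Dense fast path for small designs. Each observation loads exactly one
# level per random-effect block, so the linear predictor, the gradient and
# Z'WZ are grouped sums over precomputed index templates: no matrix products
# with Z at all, and one LAPACK Cholesky of q x q per Newton step.
inner_newton_dense <- function(struct, beta0, Qd, b0 = NULL, cache = NULL,
                               tol = 1e-8, max_iter = 100L) {
  y <- struct$y
  N <- struct$N
  q <- struct$q
  tol <- tol * max(1, max(y))
  stall_tol <- 1e-4 * max(1, max(y))
  dn <- struct$dense
  K <- ncol(dn$obs_idx)
  lfy <- sum(lfactorial(y))
  linpred <- function(b) beta0 + .rowSums(b[dn$obs_idx], N, K)
  b <- if (is.null(b0)) numeric(q) else b0
  eta <- linpred(b)
  if (any(eta > 500)) { b <- numeric(q); eta <- rep(beta0, N) }
  Qb <- as.vector(Qd %*% b)
  f <- sum(y * eta - exp(eta)) - lfy - 0.5 * sum(b * Qb)
  trace <- numeric(max_iter)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mu <- exp(eta)
    grad <- zt_prod_dense(dn, y - mu, q) - Qb
    gnorm <- max(abs(grad))
    trace[it] <- gnorm
    if (gnorm < tol) { converged <- TRUE; break }
    H <- Qd
    H[dn$uP] <- H[dn$uP] + ztwz_vals_dense(dn, mu)
    R <- tryCatch(chol(H), error = function(e) NULL)
    if (is.null(R))
      return(list(converged = FALSE, reason = "Hessian not positive definite",
                  trace = trace[seq_len(it)]))
    delta <- backsolve(R, backsolve(R, grad, transpose = TRUE))
    step <- 1
    repeat {
      b_new <- b + step * delta
      eta_new <- linpred(b_new)
      if (any(eta_new > 500)) { f_new <- -Inf } else {
        Qb_new <- as.vector(Qd %*% b_new)
        f_new <- sum(y * eta_new - exp(eta_new)) - lfy -
          0.5 * sum(b_new * Qb_new)
      }
      if (f_new >= f - 1e-12 * abs(f)) break
      step <- step / 2
      if (step < 1e-10) {
        if (gnorm < stall_tol) {
          b_new <- b; eta_new <- eta; f_new <- f; Qb_new <- Qb
          converged <- TRUE
          break
        }
        return(list(converged = FALSE, reason = "line search failed",
                    trace = trace[seq_len(it)]))
      }
    }
    if (converged) break
    b <- b_new; eta <- eta_new; f <- f_new; Qb <- Qb_new
  }
  if (!converged)
    return(list(converged = FALSE, reason = "max iterations reached",
                trace = trace))
  mu <- exp(eta)
  H <- Qd
  H[dn$uP] <- H[dn$uP] + ztwz_vals_dense(dn, mu)
  R <- chol(H)
  if (!is.null(cache)) cache$b <- b
  list(converged = TRUE, b = b, eta = eta, mu = mu, joint = f, Qb = Qb,
       R = R, logdetH = 2 * sum(log(diag(R))), iters = it,
       trace = trace[seq_len(it)])
}

inner_newton <- function(struct, beta0, Q, b0 = NULL, cache = NULL,
                         tol = 1e-8, max_iter = 100L) {
  y <- struct$y
  # gradient entries are sums of (y - mu): scale the convergence tolerance by
  # the count magnitude, else large counts stall the line search on rounding
  # noise long after the Laplace error is negligible
  tol <- tol * max(1, max(y))
  stall_tol <- 1e-4 * max(1, max(y))
  Z <- struct$Z; Zt <- struct$Zt
  b <- if (is.null(b0)) numeric(struct$q) else b0
  lfy <- sum(lfactorial(y))
  joint <- function(eta, bQb) sum(y * eta - exp(eta)) - lfy - 0.5 * bQb
  hessian <- function(mu) {
    Zw <- Z
    Zw@x <- Zw@x * sqrt(mu)[Zw@i + 1L]
    H <- Q + Matrix::crossprod(Zw)
    if (!is(H, "dsCMatrix")) H <- Matrix::forceSymmetric(H, "U")
    H
  }
  eta <- beta0 + as.vector(Z %*% b)
  if (any(eta > 500)) { b <- numeric(struct$q); eta <- rep(beta0, struct$N) }
  Qb <- as.vector(Q %*% b)
  f <- joint(eta, sum(b * Qb))
  trace <- numeric(max_iter)
  converged <- FALSE
  Ch <- if (!is.null(cache)) cache$Ch else NULL
  for (it in seq_len(max_iter)) {
    mu <- exp(eta)
    grad <- as.vector(Zt %*% (y - mu)) - Qb
    gnorm <- max(abs(grad))
    trace[it] <- gnorm
    if (gnorm < tol) { converged <- TRUE; break }
    H <- hessian(mu)
    Ch <- tryCatch({
      if (is.null(Ch)) Cholesky(H, LDL = FALSE, perm = TRUE)
      else Matrix::update(Ch, H)
    }, error = function(e) tryCatch(
      Cholesky(H, LDL = FALSE, perm = TRUE), error = function(e2) NULL))
    if (is.null(Ch))
      return(list(converged = FALSE, reason = "Hessian not positive definite",
                  trace = trace[seq_len(it)]))
    delta <- as.vector(solve(Ch, grad))
    # line search: halve until the joint density increases
    step <- 1
    repeat {
      b_new <- b + step * delta
      eta_new <- beta0 + as.vector(Z %*% b_new)
      if (any(eta_new > 500)) { f_new <- -Inf } else {
        Qb_new <- as.vector(Q %*% b_new)
        f_new <- joint(eta_new, sum(b_new * Qb_new))
      }
      if (f_new >= f - 1e-12 * abs(f)) break
      step <- step / 2
      if (step < 1e-10) {
        if (gnorm < stall_tol) { # numerically at the mode already
          b_new <- b; eta_new <- eta; f_new <- f; Qb_new <- Qb
          converged <- TRUE
          break
        }
        return(list(converged = FALSE, reason = "line search failed",
                    trace = trace[seq_len(it)]))
      }
    }
    if (converged) break
    b <- b_new; eta <- eta_new; f <- f_new; Qb <- Qb_new
  }
  if (!converged)
    return(list(converged = FALSE, reason = "max iterations reached",
                trace = trace))
  H <- hessian(exp(eta))
  Ch <- tryCatch({
    if (is.null(Ch)) Cholesky(H, LDL = FALSE, perm = TRUE)
    else Matrix::update(Ch, H)
  }, error = function(e) Cholesky(H, LDL = FALSE, perm = TRUE))
  if (!is.null(cache)) { cache$Ch <- Ch; cache$b <- b }
  logdetH <- 2 * as.numeric(determinant(Ch, sqrt = TRUE)$modulus)
  list(converged = TRUE, b = b, eta = eta, joint = f, logdetH = logdetH,
       iters = it, trace = trace[seq_len(it)])
}

# negative Laplace log likelihood at a named theta vector; on_fail controls
# whether inner-Newton failure raises an error (standalone use) or returns
# +Inf (inside the outer optimizer)
nll_theta <- function(theta, struct, cache = NULL,
                      on_fail = c("inf", "error")) {
  on_fail <- match.arg(on_fail)
  if (any(!is.finite(theta))) {
    if (on_fail == "error") stop("non-finite parameter vector")
    return(Inf)
  }
  b0 <- if (!is.null(cache)) cache$b else NULL
  if (!is.null(struct$dense)) {
    pm <- precision_dense(struct, theta)
    nn <- inner_newton_dense(struct, theta[["beta0"]], pm$Q, b0 = b0,
                             cache = cache)
  } else {
    pm <- precision_matrix(struct, theta)
    nn <- inner_newton(struct, theta[["beta0"]], pm$Q, b0 = b0, cache = cache)
  }
  if (!nn$converged) {
    if (on_fail == "error")
      stop("inner Newton failed: ", nn$reason, " (gradient trace: ",
           paste(signif(nn$trace, 3), collapse = ", "), ")")
    return(Inf)
  }
  -(nn$joint + 0.5 * pm$logdet - 0.5 * nn$logdetH)
}

#' Laplace-approximated negative marginal log-likelihood
#'
#' Evaluates the negative marginal log-likelihood of the intercept-only
#' Poisson mixed model at given variance components, integrating the random
#' effects out by the Laplace approximation: a sparse Newton maximization of
#' the joint log density over the random effects (to gradient max-norm
#' 1e-8), plus half the log-determinant correction of the negative joint
#' Hessian. The random-effect precision exploits the Markov structure of the
#' exponential correlation kernel (tridiagonal in time) and independence
#' across groups.
#'
#' @param data A `community_table`.
#' @param spec A [model_spec()].
#' @param vc A [variance_components()] holding the evaluation point; its
#'   included components must match `spec$effects`.
#' @return The negative log-likelihood (a single number, smaller is better).
#' @export
laplace_nll <- function(data, spec, vc) {
  struct <- build_random_effects(data, spec)
  nm <- theta_map(struct)
  theta <- setNames(numeric(length(nm)), nm)
  theta[["beta0"]] <- vc$beta0
  for (bl in struct$blocks) {
    s2 <- vc[[paste0("sigma2_", bl$code)]]
    if (s2 <= 0)
      stop("spec includes effect '", bl$name,
           "' but the corresponding variance is 0")
    theta[[paste0("log_sd_", bl$code)]] <- 0.5 * log(s2)
  }
  if ("log_rate" %in% nm) theta[["log_rate"]] <- log(vc_rate(vc))
  if ("log_rate_c" %in% nm) theta[["log_rate_c"]] <- log(vc_rate_c(vc))
  nll_theta(theta, struct, cache = new.env(parent = emptyenv()),
            on_fail = "error")
}
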