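# Analytic gradient of the Laplace negative log-likelihood (dense path).
#
# With l(theta) = g(b_hat) + log det Q / 2 - log det H / 2, g the joint log
# density, b_hat the conditional mode and H = Q + Z'WZ, the total derivative
# for a covariance parameter is
#   dl/dt = -b'Q_t b/2 + dlogdetQ/2 - tr(Hinv Q_t)/2 + hv'(Q_t b)/2,
# where Q_t = dQ/dt and hv = Hinv Z'(s .* mu) carries the indirect
# dependence through b_hat (s = diag(Z Hinv Z'), the third-derivative term
# of the Poisson log-link). For the intercept, dW/dbeta0 = W gives
#   dl/dbeta0 = sum(y - mu) - (q - tr(Hinv Q))/2 + hv' Z'mu / 2.

# derivative of the per-pattern precision values w.r.t. log(rate)
pattern_dvalues <- function(coords, rate) {
  if (is.matrix(coords)) {
    R <- exp(-rate * coords)
    Rinv <- chol2inv(chol(R))
    dR <- -rate * coords * R
    dRinv <- -Rinv %*% dR %*% Rinv
    return(list(dx = dRinv[upper.tri(dRinv, diag = TRUE)],
                dlogdet_cor = sum(Rinv * dR)))
  }
  n <- length(coords)
  if (n == 1L) return(list(dx = 0, dlogdet_cor = 0))
  d <- diff(coords)
  r <- exp(-rate * d)
  s <- 1 - r^2
  a <- rate * d
  e <- -2 * a * r^2 / s^2
  ddiag <- c(e, 0) + c(0, e)
  doff <- a * r * (1 + r^2) / s^2
  list(dx = c(ddiag, doff), dlogdet_cor = sum(2 * a * r^2 / s))
}

# dQ/d(log rate) over the whole template, plus d(log det Q)/d(log rate)
precision_dvalues <- function(struct, theta, rate_name) {
  r <- theta_rates(theta, struct)
  tmpl <- struct$tmpl
  shared_c <- !("log_rate_c" %in% names(theta))
  xs <- vector("list", length(struct$blocks))
  dlogdet <- 0
  for (k in seq_along(struct$blocks)) {
    bl <- struct$blocks[[k]]
    bt <- tmpl$block_tmpl[[bl$name]]
    affected <- bl$kind == "corr" &&
      ((rate_name == "log_rate" && (bl$code == "e" ||
                                    (bl$code == "c" && shared_c))) ||
       (rate_name == "log_rate_c" && bl$code == "c" && !shared_c))
    if (!affected) {
      xs[[k]] <- numeric(bt$nx)
      next
    }
    sigma2 <- exp(2 * theta[[paste0("log_sd_", bl$code)]])
    rate <- if (bl$code == "c") r$rate_c else r$rate
    pv <- lapply(bt$pattern_coords, pattern_dvalues, rate = rate)
    if (length(pv) == 1L) {
      xs[[k]] <- rep.int(pv[[1]]$dx / sigma2, length(bt$pattern_id))
    } else {
      xs[[k]] <- unlist(lapply(bt$pattern_id, function(p) pv[[p]]$dx)) / sigma2
    }
    lds <- vapply(pv, `[[`, 0, "dlogdet_cor")
    dlogdet <- dlogdet - sum(lds[bt$pattern_id])
  }
  list(dx = unlist(xs), dlogdet = dlogdet)
}

# gradient of the nll at a converged dense inner solution
laplace_grad_dense <- function(theta, struct, st, Qx) {
  q <- struct$q
  dn <- struct$dense
  tmpl <- struct$tmpl
  y <- struct$y
  b <- st$b; mu <- st$mu; Qb <- st$Qb
  Hinv <- chol2inv(st$R)
  posQ <- (tmpl$j - 1L) * q + tmpl$i
  wQ <- 1 + (tmpl$i != tmpl$j)
  HinvQ_entry <- Hinv[posQ]
  # third-derivative carrier
  s <- .rowSums(Hinv[dn$posF], struct$N, ncol(dn$posF))
  v <- zt_prod_dense(dn, s * mu, q)
  hv <- as.vector(Hinv %*% v)

  g <- setNames(numeric(length(theta)), names(theta))
  trHinvQ <- sum(wQ * Qx * HinvQ_entry)
  Zmu <- zt_prod_dense(dn, mu, q)
  g[["beta0"]] <- -(sum(y - mu) - 0.5 * (q - trHinvQ) + 0.5 * sum(hv * Zmu))

  # template entry ranges per block, in construction order
  nxs <- as.integer(vapply(struct$blocks,
                           function(bl) tmpl$block_tmpl[[bl$name]]$nx, 0))
  ends <- cumsum(nxs)
  starts <- ends - nxs + 1L
  for (k in seq_along(struct$blocks)) {
    bl <- struct$blocks[[k]]
    rows <- bl$offset + seq_len(bl$n_levels)
    ent <- starts[k]:ends[k]
    trk <- sum(wQ[ent] * Qx[ent] * HinvQ_entry[ent])
    dl <- sum(b[rows] * Qb[rows]) - bl$n_levels + trk -
      sum(hv[rows] * Qb[rows])
    g[[paste0("log_sd_", bl$code)]] <- -dl
  }

  for (rn in intersect(c("log_rate", "log_rate_c"), names(theta))) {
    dv <- precision_dvalues(struct, theta, rn)
    dx <- dv$dx
    bi <- b[tmpl$i]; bj <- b[tmpl$j]
    bQtb <- sum(wQ * dx * bi * bj)
    trH <- sum(wQ * dx * HinvQ_entry)
    # dQ b via the (small) dense buffer
    dQ <- matrix(0, q, q)
    dQ[posQ] <- dx
    dQ[(tmpl$i - 1L) * q + tmpl$j] <- dx
    dQb <- as.vector(dQ %*% b)
    dl <- -0.5 * bQtb + 0.5 * dv$dlogdet - 0.5 * trH + 0.5 * sum(hv * dQb)
    g[[rn]] <- -dl
  }
  g
}

# memoized objective/gradient pair for the outer optimizer (dense designs);
# falls back to objective-only (finite-difference outer gradients) on the
# sparse path
make_objectives <- function(struct, nm, cache) {
  if (is.null(struct$dense)) {
    fn <- function(par) {
      names(par) <- nm
      nll_theta(par, struct, cache = cache, on_fail = "inf")
    }
    return(list(fn = fn, gr = NULL))
  }
  memo <- new.env(parent = emptyenv())
  evaluate <- function(par) {
    names(par) <- nm
    if (!is.null(memo$par) && identical(memo$par, unname(par)))
      return(invisible(NULL))
    memo$par <- unname(par)
    memo$nll <- Inf
    memo$grad <- numeric(length(par))
    if (any(!is.finite(par))) return(invisible(NULL))
    pm <- precision_dense(struct, par)
    nn <- inner_newton_dense(struct, par[["beta0"]], pm$Q,
                             b0 = cache$b, cache = cache)
    if (!nn$converged) return(invisible(NULL))
    memo$nll <- -(nn$joint + 0.5 * pm$logdet - 0.5 * nn$logdetH)
    memo$state <- nn
    memo$Qx <- precision_values(struct, par)$x
    memo$grad_done <- FALSE
    invisible(NULL)
  }
  fn <- function(par) { evaluate(par); memo$nll }
  gr <- function(par) {
    evaluate(par)
    if (!is.finite(memo$nll)) return(memo$grad)
    if (!isTRUE(memo$grad_done)) {
      theta <- setNames(memo$par, nm)
      memo$grad <- laplace_grad_dense(theta, struct, memo$state, memo$Qx)
      memo$grad_done <- TRUE
    }
    memo$grad
  }
  list(fn = fn, gr = gr)
}
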