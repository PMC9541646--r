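# Independent adaptive Gauss-Hermite quadrature oracle for the Poisson model
# with a single iid random intercept per cluster. Deliberately shares no code
# with the package's Laplace path: nodes from the Golub-Welsch eigen
# decomposition, per-cluster 1-d Newton mode search, log-sum-exp integration.

gh_nodes <- function(n) {
  k <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- sqrt(k / 2)
  J[cbind(k + 1, k)] <- sqrt(k / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = sqrt(pi) * e$vectors[1, ord]^2)
}

# marginal nll of y ~ Poisson(exp(beta0 + b)), b ~ N(0, sigma^2) per cluster
agh_nll <- function(y, cluster, beta0, sigma, n_nodes = 64) {
  gh <- gh_nodes(n_nodes)
  total <- 0
  for (cl in split(y, cluster)) {
    logjoint <- function(b)
      sum(dpois(cl, exp(beta0 + b), log = TRUE)) + dnorm(b, 0, sigma, log = TRUE)
    # conditional mode by golden-section search (robust, derivative-free)
    b <- optimize(function(bb) vapply(bb, logjoint, 0), c(-30, 30),
                  maximum = TRUE, tol = 1e-12)$maximum
    shat <- 1 / sqrt(sum(exp(beta0 + b)) + 1 / sigma^2)
    z <- b + sqrt(2) * shat * gh$x
    lt <- log(gh$w) + gh$x^2 + vapply(z, logjoint, 0) +
      log(sqrt(2) * shat)
    m <- max(lt)
    total <- total - (m + log(sum(exp(lt - m))))
  }
  total
}
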