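#' Specification of the mixed-model random-effect structure
#'
#' Declares which random effects the intercept-only Poisson model carries and
#' along which dimension correlation decays. Available effects:
#' \describe{
#'   \item{`among_species`}{one effect per species (species heterogeneity,
#'     \eqn{\sigma_h^2}), shared across groups;}
#'   \item{`species_by_unit_correlated`}{one effect per species and sampling
#'     unit (\eqn{\sigma_e^2}), correlated across units within each group and
#'     species with decay rate \eqn{\gamma} (or \eqn{\alpha});}
#'   \item{`common_unit_correlated`}{one effect per sampling unit
#'     (\eqn{\sigma_c^2}), shared by all species, correlated across units
#'     within each group with decay rate \eqn{\gamma_c} (or \eqn{\alpha_c});}
#'   \item{`observation_level`}{one iid effect per observation
#'     (\eqn{\sigma_o^2}, overdispersion);}
#'   \item{`sampling_unit_iid`}{one iid effect per sampling event
#'     (\eqn{\sigma_u^2}), shared by all species within a (group, unit,
#'     replicate).}
#' }
#' For a temporal model the sampling unit is the time point and observations
#' are grouped into independent blocks by location; for a spatial model the
#' unit is the location (correlation decays with distance in km) and grouping
#' is by time point. Space and time are never modeled jointly: when both
#' dimensions vary, fit one model per dimension.
#'
#' @param dimension `"temporal"` or `"spatial"`.
#' @param effects Character vector of effect names (see above).
#' @param group_by Column that defines independent blocks; defaults to
#'   `"location"` for temporal and `"time"` for spatial models. `"none"`
#'   pools everything into one block.
#' @param separate_common_rate Estimate a separate decay rate for the
#'   common-environment effect (\eqn{\gamma_c} / \eqn{\alpha_c})? Default
#'   `TRUE` when both correlated effects are present.
#' @param distances Symmetric matrix of pairwise distances in km with
#'   dimnames naming the locations; required by spatial models with
#'   correlated effects (computed from coordinates via [haversine_matrix()]
#'   when the data carry them).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(dimension = c("temporal", "spatial"),
                       effects = c("among_species",
                                   "species_by_unit_correlated",
                                   "common_unit_correlated"),
                       group_by = NULL,
                       separate_common_rate = TRUE,
                       distances = NULL) {
  dimension <- match.arg(dimension)
  known <- c("among_species", "species_by_unit_correlated",
             "common_unit_correlated", "observation_level",
             "sampling_unit_iid")
  bad <- setdiff(effects, known)
  if (length(bad))
    stop("unknown effect name(s): ", paste(bad, collapse = ", "))
  if (!length(effects)) stop("at least one random effect is required")
  if (is.null(group_by))
    group_by <- if (dimension == "temporal") "location" else "time"
  if (!group_by %in% c("location", "time", "none"))
    stop("group_by must be 'location', 'time' or 'none'")
  structure(list(dimension = dimension, effects = unique(effects),
                 group_by = group_by,
                 separate_common_rate = isTRUE(separate_common_rate),
                 distances = distances),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Model spec:", x$dimension, "Poisson GLMM, intercept-only\n")
  cat("  effects:", paste(x$effects, collapse = ", "), "\n")
  cat("  grouped by:", x$group_by,
      if (x$separate_common_rate) " (separate common decay rate)" else "", "\n")
  invisible(x)
}

# Maps variance-component short codes to effect names and theta entries.
EFFECT_CODES <- c(among_species = "h", species_by_unit_correlated = "e",
                  common_unit_correlated = "c", observation_level = "o",
                  sampling_unit_iid = "u")

#' Build the sparse random-effect design for a community table
#'
#' Translates a [community_table()] and a [model_spec()] into the internal
#' structure the Laplace likelihood operates on: for each effect, an
#' observation-to-level index, and for correlated effects the decomposition
#' into independent chunks (one per group and species, or per group) whose
#' precision is the tridiagonal inverse of the exponential kernel on the
#' chunk's unit coordinates (temporal) or the dense inverse of the distance
#' kernel (spatial). Ragged designs (units observed in some groups only) are
#' handled per chunk.
#'
#' @param data A `community_table` (zero-filled as appropriate).
#' @param spec A [model_spec()].
#' @return An opaque design structure (class `re_structure`) consumed by
#'   [laplace_nll()] and [fit_sad_glmm()].
#' @export
build_random_effects <- function(data, spec) {
  stopifnot(inherits(data, "community_table"), inherits(spec, "model_spec"))
  if (nrow(data) == 0L) stop("data is empty")
  N <- nrow(data)
  unit_var <- if (spec$dimension == "temporal") "time" else "location"
  group <- switch(spec$group_by,
                  location = data$location,
                  time = as.character(data$time),
                  none = rep("all", N))
  unit <- data[[unit_var]]
  species <- data$species

  # unit coordinates: times (numeric) or locations keyed into the distance matrix
  corr_effects <- intersect(spec$effects,
                            c("species_by_unit_correlated",
                              "common_unit_correlated"))
  D <- NULL
  if (spec$dimension == "spatial" && length(corr_effects)) {
    D <- spec$distances
    if (is.null(D)) {
      loc <- attr(data, "locations")
      if (!is.null(loc) && all(c("latitude", "longitude") %in% names(loc)))
        D <- haversine_matrix(data)
      else stop("spatial model needs a distance matrix or coordinates")
    }
    missing_loc <- setdiff(unique(data$location), rownames(D))
    if (length(missing_loc))
      stop("distance matrix lacks locations: ",
           paste(missing_loc, collapse = ", "))
  }

  blocks <- list()
  offset <- 0L
  add_iid <- function(name, code, index, n_levels) {
    blocks[[name]] <<- list(name = name, code = code, kind = "iid",
                            index = index, n_levels = n_levels,
                            offset = offset)
    offset <<- offset + n_levels
  }
  # chunked correlated block: chunk_of maps obs -> chunk id, within each chunk
  # obs map to the ordered unit coordinates of that chunk
  add_corr <- function(name, code, chunk_of, n_chunks) {
    idx <- integer(N)
    chunks <- vector("list", n_chunks)
    lev <- 0L
    obs_by_chunk <- split(seq_len(N), chunk_of)
    for (k in seq_along(obs_by_chunk)) {
      rows <- obs_by_chunk[[k]]
      if (spec$dimension == "temporal") {
        coords <- sort(unique(unit[rows]))
        idx[rows] <- lev + match(unit[rows], coords)
        chunks[[k]] <- list(coords = coords, start = lev + 1L,
                            n = length(coords))
      } else {
        locs <- sort(unique(unit[rows]))
        idx[rows] <- lev + match(unit[rows], locs)
        chunks[[k]] <- list(coords = D[locs, locs, drop = FALSE],
                            start = lev + 1L, n = length(locs))
      }
      lev <- lev + chunks[[k]]$n
    }
    blocks[[name]] <<- list(name = name, code = code, kind = "corr",
                            index = idx, n_levels = lev, offset = offset,
                            chunks = chunks)
    offset <<- offset + lev
  }

  for (eff in spec$effects) {
    code <- EFFECT_CODES[[eff]]
    switch(eff,
      among_species = {
        f <- factor(species)
        add_iid(eff, code, as.integer(f), nlevels(f))
      },
      species_by_unit_correlated = {
        f <- factor(paste(group, species, sep = "\r"))
        add_corr(eff, code, as.integer(f), nlevels(f))
      },
      common_unit_correlated = {
        f <- factor(group)
        add_corr(eff, code, as.integer(f), nlevels(f))
      },
      observation_level = {
        add_iid(eff, code, seq_len(N), N)
      },
      sampling_unit_iid = {
        f <- factor(paste(group, unit, data$replicate, sep = "\r"))
        add_iid(eff, code, as.integer(f), nlevels(f))
      })
  }
  q <- offset

  # sparse indicator matrix Z (N x q), one 1 per obs per block
  Zi <- integer(0); Zj <- integer(0)
  for (bl in blocks) {
    Zi <- c(Zi, seq_len(N))
    Zj <- c(Zj, bl$offset + bl$index)
  }
  Z <- sparseMatrix(i = Zi, j = Zj, x = 1, dims = c(N, q))

  structure(list(y = data$count, N = N, q = q, blocks = blocks, Z = Z,
                 Zt = Matrix::t(Z),
                 dense = if (q <= 400) dense_template(blocks, q, N),
                 tmpl = precision_template(blocks, q),
                 dimension = spec$dimension,
                 separate_common_rate = spec$separate_common_rate,
                 n_species = length(unique(species)),
                 n_units = length(unique(unit)),
                 n_groups = length(unique(group)),
                 data_key = data[, c("species", "time", "location",
                                     "replicate")]),
            class = "re_structure")
}

# theta layout for a given structure: beta0, one log-sd per effect, and the
# decay-rate entries actually identifiable from the included effects
theta_map <- function(struct) {
  codes <- vapply(struct$blocks, `[[`, "", "code")
  nm <- c("beta0", paste0("log_sd_", codes))
  has_e <- "e" %in% codes
  has_c <- "c" %in% codes
  if (has_e) nm <- c(nm, "log_rate")
  if (has_c) {
    if (struct$separate_common_rate || !has_e) nm <- c(nm, "log_rate_c")
  }
  nm
}

theta_rates <- function(theta, struct) {
  rate <- if ("log_rate" %in% names(theta)) exp(theta[["log_rate"]]) else NULL
  rate_c <- if ("log_rate_c" %in% names(theta)) exp(theta[["log_rate_c"]])
            else rate
  list(rate = rate, rate_c = rate_c)
}

# natural-scale variance_components from a named theta vector
theta_to_vc <- function(theta, struct) {
  v <- function(code) {
    nm <- paste0("log_sd_", code)
    if (nm %in% names(theta)) exp(2 * theta[[nm]]) else 0
  }
  r <- theta_rates(theta, struct)
  args <- list(beta0 = theta[["beta0"]],
               sigma2_h = v("h"), sigma2_e = v("e"), sigma2_c = v("c"),
               sigma2_o = v("o"), sigma2_u = v("u"))
  if (struct$dimension == "spatial") {
    args$alpha <- r$rate; args$alpha_c <- r$rate_c
  } else {
    args$gamma <- r$rate; args$gamma_c <- r$rate_c
  }
  do.call(variance_components, args)
}

# Dense-path template for small designs: every observation loads exactly one
# level per block, so Z'WZ has nonzeros only at co-occurring level pairs and
# can be accumulated by grouped sums instead of matrix products.
dense_template <- function(blocks, q, N) {
  K <- length(blocks)
  obs_idx <- matrix(0L, N, K)
  for (k in seq_len(K))
    obs_idx[, k] <- blocks[[k]]$offset + blocks[[k]]$index
  # upper-triangle linear positions of H for every obs and block pair
  pos <- list(); obs <- list()
  for (k1 in seq_len(K)) for (k2 in k1:K) {
    i <- pmin(obs_idx[, k1], obs_idx[, k2])
    j <- pmax(obs_idx[, k1], obs_idx[, k2])
    pos[[length(pos) + 1L]] <- (j - 1L) * q + i
    obs[[length(obs) + 1L]] <- seq_len(N)
  }
  P <- unlist(pos); O <- unlist(obs)
  uP <- sort(unique(P))
  grp <- match(P, uP)
  # grouped-sum machinery without per-call sorting: ordering + group ends
  ord_grp <- order(grp)
  ends_grp <- cumsum(tabulate(grp, length(uP)))
  ord_blk <- vector("list", K)
  ends_blk <- vector("list", K)
  for (k in seq_len(K)) {
    ord_blk[[k]] <- order(obs_idx[, k])
    ends_blk[[k]] <- cumsum(tabulate(obs_idx[, k] - min(obs_idx[, k]) + 1L))
  }
  # ordered-pair linear positions for diag(Z Hinv Z') in the gradient
  posF <- matrix(0L, N, K * K)
  cc <- 0L
  for (k1 in seq_len(K)) for (k2 in seq_len(K)) {
    cc <- cc + 1L
    posF[, cc] <- (obs_idx[, k2] - 1L) * q + obs_idx[, k1]
  }
  list(obs_idx = obs_idx, O = O, grp = grp, uP = uP, q = q,
       ord_grp = ord_grp, ends_grp = ends_grp,
       ord_blk = ord_blk, ends_blk = ends_blk,
       blk_offset = vapply(blocks, `[[`, 0L, "offset"),
       blk_n = vapply(blocks, `[[`, 0L, "n_levels"),
       posF = posF)
}

# Z' r by grouped sums over the dense template (one level per block per obs)
zt_prod_dense <- function(dn, r, q) {
  g <- numeric(q)
  for (k in seq_along(dn$ord_blk)) {
    cs <- cumsum(r[dn$ord_blk[[k]]])[dn$ends_blk[[k]]]
    g[dn$blk_offset[k] + seq_len(dn$blk_n[k])] <- diff(c(0, cs))
  }
  g
}

# grouped sums of mu over co-occurring level pairs (upper-triangle of Z'WZ)
ztwz_vals_dense <- function(dn, mu) {
  x <- mu[dn$O]
  cs <- cumsum(x[dn$ord_grp])[dn$ends_grp]
  diff(c(0, cs))
}

# Precompute, once per design, the upper-triangle triplet template of the
# random-effect precision: row/column indices are fixed; only the values
# change with theta. Correlated chunks sharing the same unit coordinates
# share a pattern, so per-theta work is one small kernel inversion per
# distinct pattern plus vector fills.
precision_template <- function(blocks, q) {
  ii <- list(); jj <- list()
  block_tmpl <- vector("list", length(blocks))
  names(block_tmpl) <- names(blocks)
  for (bn in names(blocks)) {
    bl <- blocks[[bn]]
    if (bl$kind == "iid") {
      idx <- bl$offset + seq_len(bl$n_levels)
      ii[[bn]] <- idx; jj[[bn]] <- idx
      block_tmpl[[bn]] <- list(kind = "iid", nx = bl$n_levels)
      next
    }
    keys <- vapply(bl$chunks, function(ch) {
      if (is.matrix(ch$coords)) paste(rownames(ch$coords), collapse = "|")
      else paste(ch$coords, collapse = "|")
    }, "")
    patterns <- !duplicated(keys)
    pattern_id <- match(keys, keys[patterns])
    pattern_coords <- lapply(bl$chunks[patterns], `[[`, "coords")
    bi <- vector("list", length(bl$chunks)); bj <- bi
    nvals <- integer(length(bl$chunks))
    for (k in seq_along(bl$chunks)) {
      ch <- bl$chunks[[k]]
      n <- ch$n
      base <- bl$offset + ch$start - 1L
      if (is.matrix(ch$coords)) { # dense upper triangle, column-major
        bi[[k]] <- base + unlist(lapply(seq_len(n), seq_len))
        bj[[k]] <- base + rep(seq_len(n), seq_len(n))
        nvals[k] <- n * (n + 1L) / 2L
      } else {                    # tridiagonal: diagonal then superdiagonal
        bi[[k]] <- base + c(seq_len(n), seq_len(max(n - 1L, 0L)))
        bj[[k]] <- base + c(seq_len(n), seq_len(max(n - 1L, 0L)) + 1L)
        nvals[k] <- 2L * n - 1L
      }
    }
    ii[[bn]] <- unlist(bi); jj[[bn]] <- unlist(bj)
    block_tmpl[[bn]] <- list(kind = "corr", pattern_id = pattern_id,
                             pattern_coords = pattern_coords,
                             nvals = nvals, nx = sum(nvals),
                             chunk_n = vapply(bl$chunks, `[[`, 0L, "n"))
  }
  list(i = unlist(ii), j = unlist(jj), block_tmpl = block_tmpl)
}

# per-pattern precision values in template order
pattern_values <- function(coords, rate) {
  if (is.matrix(coords)) {
    P <- dense_precision(coords, rate)
    Q <- matrix(0, nrow(coords), nrow(coords))
    Q[cbind(P$i, P$j)] <- P$x
    list(x = Q[upper.tri(Q, diag = TRUE)], logdet_cor = P$logdet_cor)
  } else {
    n <- length(coords)
    if (n == 1L) return(list(x = 1, logdet_cor = 0))
    r <- exp(-rate * diff(coords))
    s <- 1 - r^2
    d <- c(1, 1 / s) + c(r^2 / s, 0)
    list(x = c(d, -r / s), logdet_cor = sum(log(s)))
  }
}

precision_values <- function(struct, theta) {
  r <- theta_rates(theta, struct)
  tmpl <- struct$tmpl
  xs <- vector("list", length(struct$blocks))
  logdet <- 0
  for (k in seq_along(struct$blocks)) {
    bl <- struct$blocks[[k]]
    bt <- tmpl$block_tmpl[[bl$name]]
    sigma2 <- exp(2 * theta[[paste0("log_sd_", bl$code)]])
    if (bt$kind == "iid") {
      xs[[k]] <- rep.int(1 / sigma2, bt$nx)
      logdet <- logdet - bl$n_levels * log(sigma2)
      next
    }
    rate <- if (bl$code == "c") r$rate_c else r$rate
    if (is.null(rate))
      stop("correlated effect '", bl$name, "' needs a decay rate")
    pv <- lapply(bt$pattern_coords, pattern_values, rate = rate)
    if (length(pv) == 1L) {
      xv <- rep.int(pv[[1]]$x / sigma2, length(bt$pattern_id))
    } else {
      xv <- unlist(lapply(bt$pattern_id, function(p) pv[[p]]$x)) / sigma2
    }
    xs[[k]] <- xv
    lds <- vapply(pv, `[[`, 0, "logdet_cor")
    logdet <- logdet - sum(bt$chunk_n) * log(sigma2) -
      sum(lds[bt$pattern_id])
  }
  list(x = unlist(xs), logdet = logdet)
}

precision_matrix <- function(struct, theta) {
  pv <- precision_values(struct, theta)
  Q <- sparseMatrix(i = struct$tmpl$i, j = struct$tmpl$j, x = pv$x,
                    dims = c(struct$q, struct$q), symmetric = TRUE)
  list(Q = Q, logdet = pv$logdet)
}

# full dense precision for the small-design fast path
precision_dense <- function(struct, theta) {
  pv <- precision_values(struct, theta)
  q <- struct$q
  Qd <- matrix(0, q, q)
  i <- struct$tmpl$i; j <- struct$tmpl$j
  Qd[(j - 1L) * q + i] <- pv$x
  Qd[(i - 1L) * q + j] <- pv$x
  list(Q = Qd, logdet = pv$logdet)
}
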