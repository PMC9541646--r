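#' Great-circle distance matrix between sampling locations
#'
#' Pairwise haversine distances in km (Earth radius 6371 km) between
#' locations given in decimal degrees. Accepts a `community_table` with
#' coordinate metadata or a data frame with `location`, `latitude`,
#' `longitude` columns.
#'
#' @param x A `community_table` with location metadata, or a data frame of
#'   locations.
#' @return A symmetric L x L matrix of distances in km with zero diagonal,
#'   dimnames set to the location identifiers.
#' @export
haversine_matrix <- function(x) {
  loc <- if (inherits(x, "community_table")) attr(x, "locations") else x
  if (is.null(loc) || !all(c("location", "latitude", "longitude") %in% names(loc)))
    stop("location metadata with latitude/longitude required")
  if (any(abs(loc$latitude) > 90) || any(abs(loc$longitude) > 180))
    stop("coordinates out of range: |lat| <= 90, |lon| <= 180 required")
  p <- as.matrix(loc[, c("longitude", "latitude")])
  L <- nrow(p)
  D <- matrix(0, L, L, dimnames = list(loc$location, loc$location))
  for (i in seq_len(L))
    D[i, ] <- geosphere::distHaversine(p[i, ], p, r = 6371) # km
  D[abs(D) < 1e-12] <- 0
  (D + t(D)) / 2
}

#' Read a precomputed distance matrix from CSV
#'
#' Expects a square CSV with location identifiers as header and first
#' column, distances in km.
#'
#' @param path CSV file path.
#' @return A symmetric distance matrix with zero diagonal.
#' @export
read_distance_matrix <- function(path) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  D <- as.matrix(df)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(diag(D) != 0)) stop("distance matrix must have zero diagonal")
  if (any(D < 0)) stop("distances must be nonnegative")
  storage.mode(D) <- "double"
  D
}
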