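#' Candidate lag distances for distance-band weights
#'
#' The default set of band radii (km) screened when selecting the spatial
#' weights structure: 50, 100, 200, 400, 600, 800 and 1000 km.
#'
#' @return Numeric vector of candidate lag distances in km.
#' @export
candidate_lags <- function() {
  c(50, 100, 200, 400, 600, 800, 1000)
}

#' Build distance-band spatial weights
#'
#' Two units are neighbours iff their planar (Euclidean) centroid distance d
#' satisfies 0 < d <= \code{lag_km}. Binary adjacency is row-standardized so
#' each non-isolate row sums to 1. Units with no neighbour within the band
#' ("isolates") keep an all-zero row and are reported.
#'
#' Distinct units at distance exactly 0 (duplicate coordinates) are
#' neighbours of each other but never of themselves.
#'
#' @param centroids two-column matrix or data.frame of planar coordinates in
#'   km; row order defines the unit order.
#' @param lag_km positive band radius in km.
#' @param ids optional character/integer vector of unit ids (defaults to row
#'   numbers).
#' @return An object of class \code{spatial_weights}: a list with elements
#'   \code{W} (row-standardized sparse matrix), \code{ids}, \code{lag_km},
#'   \code{isolates} (ids of zero-row units), \code{n}.
#' @export
build_distance_band_weights <- function(centroids, lag_km, ids = NULL) {
  xy <- as.matrix(centroids)
  if (nrow(xy) < 2L) stop("need at least 2 units to build weights")
  if (!is.numeric(lag_km) || length(lag_km) != 1L || lag_km <= 0)
    stop("lag_km must be a single positive number")
  storage.mode(xy) <- "double"
  n <- nrow(xy)
  if (is.null(ids)) ids <- seq_len(n)
  if (length(ids) != n) stop("ids length must match number of units")

  d <- as.matrix(stats::dist(xy[, 1:2, drop = FALSE]))
  adj <- d <= lag_km
  diag(adj) <- FALSE
  rs <- rowSums(adj)
  W <- Matrix::Matrix(0, n, n, sparse = TRUE)
  nz <- which(adj, arr.ind = TRUE)
  if (nrow(nz)) {
    W <- Matrix::sparseMatrix(i = nz[, 1], j = nz[, 2],
                              x = 1 / rs[nz[, 1]], dims = c(n, n))
  }
  structure(list(W = W, ids = ids, lag_km = lag_km,
                 isolates = ids[rs == 0], n = n),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("spatial_weights: %d units, lag %.0f km, %d isolate(s)\n",
              x$n, x$lag_km, length(x$isolates)))
  invisible(x)
}

#' Moran's I with permutation test
#'
#' I = (n/S0) * sum_ij w_ij z_i z_j / sum_i z_i^2 with z the centred values
#' and S0 the sum of all weights. The p-value is two-sided against the
#' permutation distribution obtained by randomly permuting \code{values}.
#'
#' @param values numeric vector, one per unit; must not be constant.
#' @param weights a \code{spatial_weights} object.
#' @param nperm number of permutations (>= 999 recommended); 0 skips the test.
#' @return list with \code{I}, \code{p_value} (NA when nperm = 0),
#'   \code{expected} (-1/(n-1)), \code{nperm}.
#' @export
morans_i <- function(values, weights, nperm = 999) {
  stopifnot(inherits(weights, "spatial_weights"))
  n <- weights$n
  if (length(values) != n) stop("values length must match weights")
  if (stats::sd(values) == 0) stop("Moran's I undefined for a constant vector")
  W <- weights$W
  S0 <- sum(W)
  if (S0 == 0) stop("all units are isolates: Moran's I undefined")

  stat <- function(v) {
    z <- v - mean(v)
    (n / S0) * as.numeric(Matrix::crossprod(z, W %*% z)) / sum(z * z)
  }
  I_obs <- stat(values)
  p <- NA_real_
  if (nperm > 0) {
    perm <- vapply(seq_len(nperm), function(i) stat(sample(values)), 0)
    p_hi <- (1 + sum(perm >= I_obs)) / (nperm + 1)
    p_lo <- (1 + sum(perm <= I_obs)) / (nperm + 1)
    p <- min(1, 2 * min(p_hi, p_lo))
  }
  list(I = I_obs, p_value = p, expected = -1 / (n - 1), nperm = nperm)
}

#' Serialize spatial weights to sparse triplet text
#'
#' Writes a header (`# lag_km=... n=... isolates=...`) followed by one
#' `i j w` triplet per nonzero weight (1-based indices in unit order).
#'
#' @param weights a \code{spatial_weights} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_weights <- function(weights, path) {
  stopifnot(inherits(weights, "spatial_weights"))
  tri <- Matrix::summary(weights$W)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# lag_km=%g n=%d isolates=%d", weights$lag_km,
                     weights$n, length(weights$isolates)), con)
  writeLines(sprintf("%d %d %.17g", tri$i, tri$j, tri$x), con)
  invisible(path)
}
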