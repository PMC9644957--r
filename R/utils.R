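#' Round half away from zero
#'
#' Presentation rounding used in all report tables. `base::round()` rounds
#' half to even, which disagrees with conventional table rounding at x.5
#' (e.g. 32.5 must print as 33, not 32). All internal computation is done at
#' full precision; this function is applied only when values are displayed
#' or written to report tables.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @export
#' @examples
#' round_half_out(32.5)   # 33
#' round_half_out(0.25, 1) # 0.3
round_half_out <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Volume-weighted quantile
#'
#' Weighted empirical quantile of type "inverse CDF"; used for regional
#' stress summaries where element volumes are the weights.
#'
#' @param x numeric values.
#' @param w non-negative weights, same length as `x`.
#' @param probs probabilities in `[0, 1]`.
#' @return numeric vector of quantiles, one per `probs`.
#' @keywords internal
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  o <- order(x)
  x <- x[o]
  cw <- cumsum(w[o]) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

#' Deterministic farthest-point subsampling
#'
#' Greedy max-min selection of `n` points from a candidate coordinate set.
#' The first point is the candidate nearest the centroid of the set, so the
#' result depends only on the coordinates, not on candidate ordering or RNG
#' state. Used to pick the loaded subset of a muscle attachment area.
#'
#' @param coords numeric matrix (points x 3).
#' @param n number of points to select (`<= nrow(coords)`).
#' @return integer indices into the rows of `coords`.
#' @keywords internal
farthest_point_sample <- function(coords, n) {
  m <- nrow(coords)
  if (n > m) {
    stop("requested ", n, " points from a set of only ", m, call. = FALSE)
  }
  if (n == m) {
    return(seq_len(m))
  }
  ctr <- colMeans(coords)
  d0 <- sqrt(rowSums((coords - rep(ctr, each = m))^2))
  sel <- integer(n)
  sel[1] <- which.min(d0)
  mind <- sqrt(rowSums((coords - rep(coords[sel[1], ], each = m))^2))
  if (n > 1) {
    for (k in 2:n) {
      sel[k] <- which.max(mind)
      dk <- sqrt(rowSums((coords - rep(coords[sel[k], ], each = m))^2))
      mind <- pmin(mind, dk)
    }
  }
  sel
}

#' Nearest-neighbour indices between two point sets
#'
#' For each row of `a`, the index of the nearest row of `b` (Euclidean).
#' Small sets only (attachment areas), so the dense distance matrix is fine.
#' @keywords internal
nearest_index <- function(a, b) {
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
  max.col(-d2, ties.method = "first")
}

#' Stable short hash of an R object
#'
#' Provenance stamp for reports: a deterministic hex digest of the serialized
#' object (serialization version 2, no header), independent of the session.
#' Not cryptographic.
#' @keywords internal
config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  raw <- raw[-seq_len(14)] # strip serialization header
  v <- as.integer(raw)
  h1 <- 5381; h2 <- 52711
  for (byte in v) {
    h1 <- (h1 * 33 + byte) %% 2147483647
    h2 <- (h2 * 17 + byte * 7 + 1) %% 2147483629
  }
  sprintf("%08x%08x", h1, h2)
}
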