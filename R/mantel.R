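#' Geographic distance matrix between populations
#'
#' Great-circle (haversine) distances in km from latitude/longitude in
#' degrees, or plain Euclidean distances for coordinates already on a
#' km grid (as produced by the simulator).
#'
#' @param coords data frame with a label column (`population`, or row
#'   names) and either `lat`/`lon` columns in degrees
#'   (`method = "haversine"`) or `x_km`/`y_km` columns
#'   (`method = "euclidean"`).
#' @param method `"haversine"` (sphere of radius 6371 km) or
#'   `"euclidean"`.
#' @return Symmetric matrix of distances in km, labelled by population.
#' @export
geographic_distances <- function(coords,
                                 method = c("haversine", "euclidean")) {
  method <- match.arg(method)
  labels <- if ("population" %in% names(coords)) {
    as.character(coords$population)
  } else rownames(coords)
  if (method == "haversine") {
    if (!all(c("lat", "lon") %in% names(coords)))
      stop("haversine coordinates need 'lat' and 'lon' columns (degrees)")
    if (any(abs(coords$lat) > 90) || any(abs(coords$lon) > 180))
      stop("coordinates out of range: |lat| <= 90, |lon| <= 180")
    d <- geosphere::distm(cbind(coords$lon, coords$lat),
                          fun = function(p1, p2)
                            geosphere::distHaversine(p1, p2, r = 6371000))
    d <- d / 1000
  } else {
    if (!all(c("x_km", "y_km") %in% names(coords)))
      stop("euclidean coordinates need 'x_km' and 'y_km' columns")
    d <- as.matrix(stats::dist(cbind(coords$x_km, coords$y_km)))
  }
  dimnames(d) <- list(labels, labels)
  d
}

## all permutations of 1..n as a matrix (n! rows); used for exact Mantel
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

#' Mantel test of matrix correlation
#'
#' Pearson correlation between the off-diagonal entries of two distance
#' matrices, with significance from simultaneous row/column permutations
#' of the second matrix.  The alternative is one-tailed positive
#' (isolation by distance: genetic distance increases with geographic
#' distance).  The Monte Carlo p-value uses the `(b + 1) / (m + 1)`
#' estimator; with `exact = TRUE` (n <= 8) all `n!` permutations are
#' enumerated and the p-value is the exact proportion of permutations
#' (including the identity) with `r >= r_obs`.
#'
#' @param a,b symmetric distance matrices over the same labels in the
#'   same order (e.g. pairwise Phi_PT and km).
#' @param n_perm number of random permutations (ignored when exact).
#' @param seed optional integer seed.
#' @param exact enumerate all permutations instead of sampling.
#' @return A list of class `"mantel_result"`: `r`, `p`, `n_perm`,
#'   `exact`.
#' @export
mantel_test <- function(a, b, n_perm = 999, seed = NULL, exact = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  n <- nrow(a)
  if (n < 4) stop("at least 4 labels are required")
  if (!all(dim(a) == dim(b))) stop("matrices must have the same dimension")
  if (!is.null(dimnames(a)[[1]]) && !is.null(dimnames(b)[[1]]) &&
      !identical(dimnames(a)[[1]], dimnames(b)[[1]]))
    stop("matrix labels differ or are ordered differently")
  ut <- upper.tri(a)
  va <- a[ut]
  if (stats::sd(va) == 0 || stats::sd(b[ut]) == 0)
    stop("degenerate distance matrix: no off-diagonal variance")
  r_obs <- stats::cor(va, b[ut])
  if (exact) {
    if (n > 8) stop("exact enumeration is limited to n <= 8")
    perms <- all_permutations(n)
    r_all <- apply(perms, 1, function(o) stats::cor(va, b[o, o][ut]))
    p <- mean(r_all >= r_obs - 1e-12)
    m <- nrow(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (i in seq_len(n_perm)) {
      o <- sample.int(n)
      if (stats::cor(va, b[o, o][ut]) >= r_obs) hits <- hits + 1L
    }
    p <- (hits + 1) / (n_perm + 1)
    m <- n_perm
  }
  structure(list(r = r_obs, p = p, n_perm = m, exact = exact),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, P = %.4g (%s, %d permutations)\n",
              x$r, x$p, if (x$exact) "exact" else "Monte Carlo", x$n_perm))
  invisible(x)
}
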