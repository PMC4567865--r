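## Shared fixtures and independent oracles used across test files.

## random binary matrix wrapped as an aflp_matrix: k populations of n
random_aflp <- function(k = 3, n = 4, loci = 8, regions = NULL,
                        p = NULL) {
  if (is.null(p)) p <- stats::runif(loci, 0.2, 0.8)
  g <- matrix(stats::rbinom(k * n * loci, 1, rep(p, each = k * n)),
              k * n, loci)
  ## ensure some molecular variance
  if (sum(dist(g)) == 0) g[1, 1] <- 1L - g[1, 1]
  pops <- rep(paste0("pop", seq_len(k)), each = n)
  if (is.null(regions)) regions <- rep("r1", k)
  aflp_matrix(g, pops, rep(regions, each = n))
}

## Independent AMOVA sums-of-squares oracle: per-locus one-way ANOVA on
## the raw binary data (design-matrix route).  For squared-Euclidean
## distances the distance-based SS must equal the summed per-locus
## ANOVA SS.
anova_ss_oracle <- function(x) {
  g <- x$genotypes
  pops <- x$population
  ss_within <- ss_among <- 0
  for (l in seq_len(ncol(g))) {
    v <- g[, l]
    gm <- mean(v)
    pm <- tapply(v, pops, mean)[pops]
    ss_within <- ss_within + sum((v - pm)^2)
    ss_among <- ss_among + sum((pm - gm)^2)
  }
  c(among = ss_among, within = ss_within)
}

## Permutation generator independent of the package's recursive one:
## lexicographic successor algorithm.
perms_lexicographic <- function(n) {
  cur <- seq_len(n)
  out <- list(cur)
  repeat {
    i <- n - 1
    while (i >= 1 && cur[i] >= cur[i + 1]) i <- i - 1
    if (i < 1) break
    j <- n
    while (cur[j] <= cur[i]) j <- j - 1
    tmp <- cur[i]; cur[i] <- cur[j]; cur[j] <- tmp
    cur[(i + 1):n] <- rev(cur[(i + 1):n])
    out[[length(out) + 1]] <- cur
  }
  do.call(rbind, out)
}

## deterministic 4-treatment x 2-region germination grid
balanced_germination <- function(counts, dishes = 8, sown = 10) {
  stopifnot(length(counts) == 4 * 2 * dishes)
  grid <- expand.grid(dish = seq_len(dishes),
                      treatment = paste0("T", 1:4),
                      region = c("A", "B"), stringsAsFactors = FALSE)
  germination_data(sprintf("%s_%s_%d", grid$treatment, grid$region,
                           grid$dish),
                   grid$treatment, grid$region, counts, sown)
}
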