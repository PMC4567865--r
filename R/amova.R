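#' Squared Euclidean (band-mismatch) distances between individuals
#'
#' For binary band vectors the squared Euclidean distance equals the
#' number of loci at which two individuals differ, the standard
#' individual-level input for AMOVA on dominant markers.
#'
#' @param x an [aflp_matrix()].
#' @return A symmetric numeric matrix with zero diagonal, labelled by
#'   sample id.
#' @export
binary_squared_distance <- function(x) {
  stopifnot(inherits(x, "aflp_matrix"))
  g <- x$genotypes
  r <- rowSums(g)
  d <- outer(r, r, "+") - 2 * tcrossprod(g)
  diag(d) <- 0
  storage.mode(d) <- "double"
  d
}

## ---- internal AMOVA machinery ------------------------------------------

## sum over groups of (sum of pairwise d within group) / group size
ss_within_groups <- function(d, groups) {
  idx <- split(seq_along(groups), groups)
  sum(vapply(idx, function(i) sum(d[i, i]) / (2 * length(i)), 0))
}

## One-level variance components from (df, SS) and per-population sizes.
## Returns raw (untruncated) components plus the n0 coefficient.
components_one_level <- function(df_among, ss_among, df_within, ss_within,
                                 sizes) {
  N <- sum(sizes)
  k <- length(sizes)
  if (df_among != k - 1)
    stop("among-population df (", df_among, ") inconsistent with ",
         k, " populations")
  if (df_within != N - k)
    stop("within-population df (", df_within,
         ") inconsistent with sample sizes (N = ", N, ")")
  ms_among <- ss_among / df_among
  ms_within <- ss_within / df_within
  n0 <- (N - sum(sizes^2) / N) / (k - 1)
  sigma_within <- ms_within
  sigma_among <- (ms_among - ms_within) / n0
  list(components = c(among_populations = sigma_among,
                      within_populations = sigma_within),
       coefficients = c(n0 = n0))
}

## Two-level (regions / populations / individuals) components from
## (df, SS) per stratum and sizes grouped by region.
## sizes: numeric per population; regions: factor per population.
components_two_level <- function(dfs, sss, sizes, regions) {
  regions <- factor(regions)
  G <- nlevels(regions)
  P <- length(sizes)
  N <- sum(sizes)
  if (G < 2) stop("at least 2 regions are required")
  if (!identical(unname(dfs), c(G - 1, P - G, N - P)))
    stop("df (", paste(dfs, collapse = ", "),
         ") inconsistent with group sizes (expected ",
         paste(c(G - 1, P - G, N - P), collapse = ", "), ")")
  Ng <- tapply(sizes, regions, sum)
  Ag <- tapply(sizes^2, regions, sum) / Ng
  n  <- (N - sum(Ag)) / (P - G)
  np <- (sum(Ag) - sum(sizes^2) / N) / (G - 1)
  npp <- (N - sum(Ng^2) / N) / (G - 1)
  ms <- sss / dfs
  sigma_c <- ms[3]
  sigma_b <- (ms[2] - sigma_c) / n
  sigma_a <- (ms[1] - sigma_c - np * sigma_b) / npp
  list(components = c(among_regions = unname(sigma_a),
                      among_populations = unname(sigma_b),
                      within_populations = unname(sigma_c)),
       coefficients = c(n = n, n_prime = np, n_doubleprime = npp))
}

## Phi statistics from raw components (negative components truncated to 0
## for the ratios, software convention).
phi_from_components <- function(comp) {
  ct <- pmax(comp, 0)
  tot <- sum(ct)
  if (length(comp) == 2) {
    c(Phi_PT = unname(ct["among_populations"] / tot))
  } else {
    c(Phi_RT = unname(ct["among_regions"] / tot),
      Phi_PR = unname(ct["among_populations"] /
                        (ct["among_populations"] + ct["within_populations"])),
      Phi_PT = unname((ct["among_regions"] + ct["among_populations"]) / tot))
  }
}

new_amova <- function(strata, comp, coefs, phi, perm_p = NULL,
                      n_perm = 0) {
  ct <- pmax(comp$components, 0)
  structure(list(
    strata = strata,
    components = ct,
    components_raw = comp$components,
    percentages = 100 * ct / sum(ct),
    coefficients = comp$coefficients,
    phi = phi,
    perm_p = perm_p,
    n_perm = n_perm), class = "amova")
}

#' @export
print.amova <- function(x, digits = 3, ...) {
  cat("Analysis of molecular variance\n\n")
  tab <- x$strata
  tab$MS <- tab$SS / tab$df
  tab$sigma2 <- signif(x$components, digits + 2)
  tab$percent <- round(x$percentages, 1)
  print(tab, row.names = FALSE)
  cat("\nPhi statistics:\n")
  for (nm in names(x$phi)) {
    cat(sprintf("  %s = %.4f", nm, x$phi[nm]))
    if (!is.null(x$perm_p) && nm %in% names(x$perm_p))
      cat(sprintf("  (P = %.4g, %d permutations)", x$perm_p[nm], x$n_perm))
    cat("\n")
  }
  invisible(x)
}

#' One-level AMOVA on an individual distance matrix
#'
#' Decomposes the total sum of squared distances into among- and
#' within-population strata, extracts variance components with the
#' unequal-sample-size coefficient `n0`, and tests
#' `Phi_PT = sigma2_among / (sigma2_among + sigma2_within)` by randomly
#' reassigning individuals to populations (holding sample sizes fixed).
#' The permutation p-value uses the `(b + 1) / (m + 1)` estimator, so it
#' can never be exactly zero.
#'
#' @param d symmetric distance matrix (typically
#'   [binary_squared_distance()]); entries are squared distances.
#' @param pops population label per row of `d`.
#' @param n_perm number of permutations (0 skips the test).
#' @param seed optional integer seed for the permutation stream.
#' @return An object of class `"amova"` with elements `strata`
#'   (data frame of name/df/SS), `components` (variance components,
#'   negatives truncated to 0), `components_raw`, `percentages`, `phi`,
#'   `perm_p` and `n_perm`.
#' @export
amova_one_level <- function(d, pops, n_perm = 999, seed = NULL) {
  d <- as.matrix(d)
  pops <- factor(as.character(pops), levels = unique(as.character(pops)))
  N <- nrow(d)
  stopifnot(length(pops) == N)
  sizes <- as.numeric(table(pops))
  if (length(sizes) < 2) stop("at least 2 populations are required")
  if (any(sizes < 2)) stop("every population needs at least 2 members")
  ss_tot <- sum(d) / (2 * N)
  if (ss_tot <= 0) stop("no molecular variance")
  ss_w <- ss_within_groups(d, pops)
  ss_a <- ss_tot - ss_w
  comp <- components_one_level(length(sizes) - 1, ss_a, N - length(sizes),
                               ss_w, sizes)
  phi <- phi_from_components(comp$components)
  strata <- data.frame(
    stratum = c("among_populations", "within_populations"),
    df = c(length(sizes) - 1, N - length(sizes)),
    SS = c(ss_a, ss_w))
  perm_p <- NULL
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    obs <- phi["Phi_PT"]
    hits <- 0L
    for (b in seq_len(n_perm)) {
      pp <- sample(pops)
      ssw_p <- ss_within_groups(d, pp)
      cp <- components_one_level(length(sizes) - 1, ss_tot - ssw_p,
                                 N - length(sizes), ssw_p, sizes)
      if (phi_from_components(cp$components)["Phi_PT"] >= obs)
        hits <- hits + 1L
    }
    perm_p <- c(Phi_PT = (hits + 1) / (n_perm + 1))
  }
  new_amova(strata, comp, comp$coefficients, phi, perm_p, n_perm)
}

#' Two-level hierarchical AMOVA (regions / populations / individuals)
#'
#' Decomposes molecular variance into among-region, among-population
#' (within regions) and within-population strata and reports the three
#' Phi statistics: `Phi_RT` (regions vs total), `Phi_PR` (populations
#' within regions) and `Phi_PT` (combined among-region and
#' among-population fraction).  Permutation schemes follow the stratum
#' being tested: `Phi_PT` permutes individuals among all populations,
#' `Phi_PR` permutes individuals among populations within their region,
#' and `Phi_RT` permutes whole populations among regions.
#'
#' @inheritParams amova_one_level
#' @param regions region label per row of `d`; must be constant within
#'   populations, with at least 2 populations per region.
#' @return An object of class `"amova"`; see [amova_one_level()].
#' @export
amova_two_level <- function(d, pops, regions, n_perm = 999, seed = NULL) {
  d <- as.matrix(d)
  pops <- factor(as.character(pops), levels = unique(as.character(pops)))
  regions <- factor(as.character(regions),
                    levels = unique(as.character(regions)))
  N <- nrow(d)
  stopifnot(length(pops) == N, length(regions) == N)
  pr <- unique(data.frame(pops, regions))
  if (anyDuplicated(pr$pops))
    stop("population assigned to more than one region")
  pop_region <- pr$regions[match(levels(pops), pr$pops)]
  if (any(table(pop_region) < 2))
    stop("every region needs at least 2 populations")
  sizes <- as.numeric(table(pops))
  if (any(sizes < 2)) stop("every population needs at least 2 members")
  G <- nlevels(regions); P <- nlevels(pops)

  ss_tot <- sum(d) / (2 * N)
  if (ss_tot <= 0) stop("no molecular variance")
  ss_wp <- ss_within_groups(d, pops)
  ss_wr <- ss_within_groups(d, regions)
  ss_ar <- ss_tot - ss_wr          # among regions
  ss_ap <- ss_wr - ss_wp           # among populations within regions
  dfs <- c(G - 1, P - G, N - P)
  sss <- c(ss_ar, ss_ap, ss_wp)
  comp <- components_two_level(dfs, sss, sizes, pop_region)
  phi <- phi_from_components(comp$components)
  strata <- data.frame(
    stratum = c("among_regions", "among_populations", "within_populations"),
    df = dfs, SS = sss)

  perm_p <- NULL
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    hits <- c(Phi_RT = 0L, Phi_PR = 0L, Phi_PT = 0L)
    pop_idx <- split(seq_len(N), pops)
    for (b in seq_len(n_perm)) {
      ## Phi_PT: individuals among all populations
      p_pt <- sample(pops)
      ssw <- ss_within_groups(d, p_pt)
      cp <- components_two_level(dfs, c(ss_ar, ss_wr - ssw, ssw), sizes,
                                 pop_region)
      if (phi_from_components(cp$components)["Phi_PT"] >= phi["Phi_PT"])
        hits["Phi_PT"] <- hits["Phi_PT"] + 1L
      ## Phi_PR: individuals among populations within regions
      p_pr <- pops
      for (g in levels(regions)) {
        m <- regions == g
        p_pr[m] <- sample(pops[m])
      }
      ssw <- ss_within_groups(d, p_pr)
      cp <- components_two_level(dfs, c(ss_ar, ss_wr - ssw, ssw), sizes,
                                 pop_region)
      if (phi_from_components(cp$components)["Phi_PR"] >= phi["Phi_PR"])
        hits["Phi_PR"] <- hits["Phi_PR"] + 1L
      ## Phi_RT: whole populations among regions
      perm_reg_of_pop <- sample(pop_region)
      reg_ind <- perm_reg_of_pop[pops]
      ssw_r <- ss_within_groups(d, factor(reg_ind))
      cp <- components_two_level(dfs,
                                 c(ss_tot - ssw_r, ssw_r - ss_wp, ss_wp),
                                 sizes, perm_reg_of_pop)
      if (phi_from_components(cp$components)["Phi_RT"] >= phi["Phi_RT"])
        hits["Phi_RT"] <- hits["Phi_RT"] + 1L
    }
    perm_p <- (hits + 1) / (n_perm + 1)
  }
  new_amova(strata, comp, comp$coefficients, phi, perm_p, n_perm)
}

#' Recover AMOVA variance components from a published summary
#'
#' Starting from the degrees of freedom and sums of squares of a printed
#' AMOVA table, together with the per-population sample sizes (and the
#' region of each population for a three-stratum design), recomputes
#' mean squares, unequal-sample-size coefficients, variance components,
#' percentages and Phi statistics exactly as [amova_one_level()] /
#' [amova_two_level()] would from raw distances.
#'
#' @param df integer vector of degrees of freedom, ordered from the top
#'   stratum down (length 2: among/within populations; length 3: among
#'   regions / among populations / within populations).
#' @param ss sums of squares matching `df`.
#' @param sizes per-population sample sizes.
#' @param regions region label per population (required when
#'   `length(df) == 3`).
#' @return An object of class `"amova"` (without permutation p-values).
#' @export
components_from_summary <- function(df, ss, sizes, regions = NULL) {
  stopifnot(length(df) == length(ss))
  if (length(df) == 2) {
    comp <- components_one_level(df[1], ss[1], df[2], ss[2], sizes)
    strata <- data.frame(
      stratum = c("among_populations", "within_populations"),
      df = df, SS = ss)
  } else if (length(df) == 3) {
    if (is.null(regions))
      stop("a three-stratum summary needs the region of every population")
    comp <- components_two_level(df, ss, sizes, regions)
    strata <- data.frame(
      stratum = c("among_regions", "among_populations",
                  "within_populations"),
      df = df, SS = ss)
  } else stop("expected 2 or 3 strata")
  new_amova(strata, comp, comp$coefficients,
            phi_from_components(comp$components))
}

#' Pairwise population differentiation matrix (Phi_PT)
#'
#' Runs a one-level AMOVA for every pair of populations and assembles
#' the symmetric matrix of pairwise `Phi_PT` values (negative estimates
#' are truncated to 0; the raw values are returned as an attribute
#' `"raw"` for diagnostics).  Optionally attaches permutation p-values.
#'
#' @inheritParams amova_one_level
#' @param x an [aflp_matrix()].
#' @return Symmetric matrix of pairwise `Phi_PT`, labelled by
#'   population, with attributes `"raw"` (untruncated estimates) and,
#'   when `n_perm > 0`, `"p"` (permutation p-values).
#' @export
pairwise_phi_pt <- function(x, n_perm = 0, seed = NULL) {
  stopifnot(inherits(x, "aflp_matrix"))
  pops <- levels(x$population)
  if (length(pops) < 2) stop("at least 2 populations are required")
  if (!is.null(seed)) set.seed(seed)
  d <- binary_squared_distance(x)
  k <- length(pops)
  phi <- raw <- pval <- matrix(0, k, k, dimnames = list(pops, pops))
  diag(pval) <- NA_real_
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    m <- x$population %in% pops[c(i, j)]
    a <- amova_one_level(d[m, m], droplevels(x$population[m]),
                         n_perm = n_perm)
    raw[i, j] <- raw[j, i] <- unname(a$phi["Phi_PT"])
    phi[i, j] <- phi[j, i] <- max(0, unname(a$phi["Phi_PT"]))
    if (n_perm > 0) pval[i, j] <- pval[j, i] <- unname(a$perm_p["Phi_PT"])
  }
  attr(phi, "raw") <- raw
  if (n_perm > 0) attr(phi, "p") <- pval
  phi
}
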