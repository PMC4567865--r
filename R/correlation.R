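#' Read a per-population trait table
#'
#' Reads the tab-separated per-population table of structural,
#' reproductive and genetic-diversity traits.  Expected columns:
#' `label`, `population`, `region`, then numeric traits (`HA` habitat
#' area in m2, `NI` individual count, `PD` cushions per m2, `CS`
#' cushion size in cm2, `CD` shoots per m2, `NF` flowers per
#' individual, `NC` capsules per individual, `FS` fruit set, `He`
#' Nei's gene diversity, `I` Shannon index, `PPL` percent polymorphic
#' loci).  Missing columns are allowed.
#'
#' An example table for 20 isolated populations of a rare cushion-
#' forming pink sampled in two regions (10 populations each) ships with
#' the package:
#' `system.file("extdata", "population_traits.tsv", package = "isopop")`.
#'
#' @param path file to read.
#' @return A data frame with one row per population.
#' @export
read_population_table <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  if (!"population" %in% names(d)) stop("missing 'population' column")
  if ("PD.HA" %in% names(d)) names(d)[names(d) == "PD.HA"] <- "PD"
  d
}

#' Derive density and fruit-set traits
#'
#' Adds (or recomputes) population density `PD = NI / HA` (cushions per
#' m2) and per-population fruit set `FS = NC / NF` (capsules per
#' flower; missing when no flowers were produced).  When both `PD` and
#' `NI` are present, the consistency `PD * HA ~ NI` is checked and a
#' warning is issued on gross disagreement.
#'
#' @param table a per-population trait data frame with `HA` and `NI`
#'   columns (and `NF`/`NC` for fruit set).
#' @return The table with `PD` (and `FS` when possible) filled in.
#' @seealso [region_fruit_set()] for the ratio-of-means region-level
#'   definition.
#' @export
derive_traits <- function(table) {
  if (!all(c("HA", "NI") %in% names(table)))
    stop("'HA' and 'NI' columns are required")
  if (any(table$HA <= 0)) stop("habitat area must be positive")
  pd <- table$NI / table$HA
  if ("PD" %in% names(table)) {
    rel <- abs(table$PD * table$HA - table$NI) / pmax(table$NI, 1)
    if (any(rel > 0.5, na.rm = TRUE))
      warning("PD * HA disagrees with NI for: ",
              paste(table$population[rel > 0.5], collapse = ", "))
  }
  table$PD <- pd
  if (all(c("NF", "NC") %in% names(table)))
    table$FS <- ifelse(table$NF > 0, table$NC / table$NF, NA_real_)
  table
}

#' Region-level fruit set as a ratio of means
#'
#' Region fruit set defined as (mean capsules per individual) / (mean
#' flowers per individual) over the populations of the region — the
#' ratio-of-means definition, which differs from the mean of the
#' per-population ratios when flower counts vary.
#'
#' @param table a per-population trait data frame with `region`, `NF`
#'   and `NC` columns.
#' @return Named numeric vector of fruit set per region.
#' @export
region_fruit_set <- function(table) {
  stopifnot(all(c("region", "NF", "NC") %in% names(table)))
  nc <- tapply(table$NC, table$region, mean)
  nf <- tapply(table$NF, table$region, mean)
  nc / nf
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Mid-ranks are used for ties; `rho` is the Pearson correlation of the
#' ranks and the two-sided p-value comes from the t approximation with
#' `n - 2` degrees of freedom.  With `exact = TRUE` (n <= 8) the
#' p-value is instead the exact two-sided permutation probability of
#' `|rho|` under random ranking.
#'
#' @param x,y numeric vectors (pairs with missing values are dropped;
#'   at least 4 complete pairs required).
#' @param exact compute the exact permutation p-value (n <= 8).
#' @return A list with elements `rho`, `p` and `n`.
#' @export
spearman <- function(x, y, exact = FALSE) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("at least 4 complete pairs are required")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("zero rank variance: constant vector")
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n > 8) stop("exact permutation p is limited to n <= 8")
    perms <- all_permutations(n)
    rho_all <- apply(perms, 1, function(o) stats::cor(rx, ry[o]))
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Spearman correlation screen across population traits
#'
#' Computes the lower-triangle matrix of Spearman correlations between
#' the requested variables, either for all populations or separately
#' per region.  Cells are starred at the 0.05 (`*`) and 0.01 (`**`)
#' two-sided levels; no multiple-testing correction is applied, so with
#' 45 cells per screen roughly two spuriously starred cells are
#' expected under independence.
#'
#' @param table a per-population trait data frame.
#' @param variables ordered character vector of trait columns to
#'   screen.
#' @param subset `"all"` (one screen over every population) or
#'   `"by-region"` (one screen per region).
#' @return For `"all"`, an object of class `"correlation_screen"` with
#'   matrices `rho`, `p`, `n` and `stars`; for `"by-region"`, a named
#'   list of such objects.
#' @export
correlation_screen <- function(table, variables,
                               subset = c("all", "by-region")) {
  subset <- match.arg(subset)
  unknown <- setdiff(variables, names(table))
  if (length(unknown)) stop("unknown variable: ",
                            paste(unknown, collapse = ", "))
  if (subset == "by-region") {
    regs <- unique(as.character(table$region))
    out <- lapply(regs, function(r)
      correlation_screen(table[table$region == r, , drop = FALSE],
                         variables, "all"))
    names(out) <- regs
    return(out)
  }
  k <- length(variables)
  rho <- p <- nn <- matrix(NA_real_, k, k,
                           dimnames = list(variables, variables))
  diag(rho) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    s <- spearman(table[[variables[i]]], table[[variables[j]]])
    rho[i, j] <- rho[j, i] <- s$rho
    p[i, j] <- p[j, i] <- s$p
    nn[i, j] <- nn[j, i] <- s$n
  }
  stars <- matrix("", k, k, dimnames = dimnames(rho))
  stars[p < 0.05] <- "*"
  stars[p < 0.01] <- "**"
  diag(stars) <- ""
  structure(list(rho = rho, p = p, n = nn, stars = stars,
                 variables = variables), class = "correlation_screen")
}

#' @export
print.correlation_screen <- function(x, digits = 3, ...) {
  k <- length(x$variables)
  disp <- matrix("", k, k, dimnames = dimnames(x$rho))
  for (i in 2:k) for (j in 1:(i - 1))
    disp[i, j] <- paste0(format(round(x$rho[i, j], digits)), x$stars[i, j])
  cat("Spearman correlation screen (lower triangle; * p<0.05, ** p<0.01)\n")
  print(as.data.frame(disp[-1, -k, drop = FALSE]))
  invisible(x)
}
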