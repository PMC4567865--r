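#' Per-locus band frequency within one population
#'
#' Fraction of individuals of the population that carry the band
#' (dominant phenotype) at each locus.
#'
#' @param x an [aflp_matrix()].
#' @param population a population label present in `x`.
#' @return Named numeric vector, one entry per locus, in \[0, 1\].
#' @export
band_frequency <- function(x, population) {
  stopifnot(inherits(x, "aflp_matrix"))
  if (!population %in% levels(x$population))
    stop("unknown population: ", population)
  colMeans(x$genotypes[x$population == population, , drop = FALSE])
}

#' Allele frequencies from dominant band frequencies
#'
#' For a dominant biallelic marker the band phenotype pools the
#' homozygous and heterozygous carriers, so the band-allele frequency
#' `p` must be inferred from the band frequency.  Two estimators are
#' offered: `"sqrt_hwe"` takes the null-allele frequency as the square
#' root of the band-absence frequency under Hardy-Weinberg equilibrium
#' (`q = sqrt(1 - band_freq)`, `p = 1 - q`), the long-standing
#' convention for dominant data; `"band_as_allele"` treats the band
#' itself as an allele (`p = band_freq`), useful as a sensitivity
#' check.
#'
#' @param band_freq numeric vector of band frequencies in \[0, 1\].
#' @param estimator `"sqrt_hwe"` (default) or `"band_as_allele"`.
#' @return A two-column matrix with columns `p` and `q`, rows matching
#'   `band_freq`; `p + q = 1`.
#' @export
allele_frequencies_dominant <- function(band_freq,
                                        estimator = c("sqrt_hwe",
                                                      "band_as_allele")) {
  estimator <- match.arg(estimator)
  if (any(band_freq < 0 | band_freq > 1, na.rm = TRUE))
    stop("band frequencies must lie in [0, 1]")
  q <- switch(estimator,
              sqrt_hwe = sqrt(1 - band_freq),
              band_as_allele = 1 - band_freq)
  cbind(p = 1 - q, q = q)
}

per_locus_diversity <- function(x, population, estimator, fun) {
  pq <- allele_frequencies_dominant(band_frequency(x, population), estimator)
  mean(fun(pq[, "p"], pq[, "q"]))
}

#' Nei's gene diversity of one population
#'
#' Expected heterozygosity `H = 1 - sum(p_i^2)` evaluated per locus from
#' the inferred allele frequencies and averaged over all loci.  For a
#' biallelic locus the per-locus maximum is 0.5.
#'
#' @inheritParams band_frequency
#' @inheritParams allele_frequencies_dominant
#' @return Average gene diversity (unitless).
#' @export
nei_gene_diversity <- function(x, population,
                               estimator = c("sqrt_hwe", "band_as_allele")) {
  per_locus_diversity(x, population, match.arg(estimator),
                      function(p, q) 1 - p^2 - q^2)
}

#' Shannon's information index of one population
#'
#' Per-locus `-(p log p + q log q)` (with `0 log 0 = 0`) averaged over
#' loci.  The index is reported with the conventional positive sign; the
#' per-locus maximum for biallelic data is `log(2)`.
#'
#' @inheritParams nei_gene_diversity
#' @return Average Shannon index (unitless, >= 0).
#' @export
shannon_index <- function(x, population,
                          estimator = c("sqrt_hwe", "band_as_allele")) {
  xlx <- function(v) ifelse(v > 0, v * log(v), 0)
  per_locus_diversity(x, population, match.arg(estimator),
                      function(p, q) -(xlx(p) + xlx(q)))
}

#' Percentage of polymorphic loci within one population
#'
#' A locus counts as polymorphic when its band frequency inside the
#' population is strictly between 0 and 1; no rare-allele cutoff is
#' applied.  A locus variable elsewhere but fixed inside the population
#' does not count.
#'
#' @inheritParams band_frequency
#' @return Percentage in \[0, 100\].
#' @export
percent_polymorphic <- function(x, population) {
  f <- band_frequency(x, population)
  100 * mean(f > 0 & f < 1)
}

#' Per-population diversity summary table
#'
#' Computes, for every population of the matrix, the number of
#' individuals, the percentage of polymorphic loci, Nei's gene
#' diversity and Shannon's information index.
#'
#' @inheritParams nei_gene_diversity
#' @return A data frame with columns `population`, `region`,
#'   `n_individuals`, `percent_polymorphic`, `nei_He`, `shannon_I`.
#' @export
diversity_summary <- function(x, estimator = c("sqrt_hwe", "band_as_allele")) {
  estimator <- match.arg(estimator)
  pops <- levels(x$population)
  reg <- vapply(pops, function(p)
    as.character(x$region[x$population == p][1]), "")
  data.frame(
    population = pops,
    region = unname(reg),
    n_individuals = as.integer(table(x$population)[pops]),
    percent_polymorphic = vapply(pops, function(p)
      percent_polymorphic(x, p), 0),
    nei_He = vapply(pops, function(p)
      nei_gene_diversity(x, p, estimator), 0),
    shannon_I = vapply(pops, function(p)
      shannon_index(x, p, estimator), 0),
    row.names = NULL)
}
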