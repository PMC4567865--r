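#' Binary dominant-marker genotype matrix
#'
#' Constructs a validated container for AFLP-style dominant-marker data:
#' a binary individuals-by-loci band matrix together with the population
#' each individual was sampled from and the region each population
#' belongs to.  A band scored as `1` means the fragment is present
#' (the dominant phenotype); `0` means absent.  Missing genotype codes
#' are rejected: ambiguous samples are expected to be rescored or
#' dropped before analysis.
#'
#' @param genotypes integer or numeric matrix of 0/1 band calls, rows =
#'   individuals, columns = loci.  Row names are used as sample ids and
#'   column names as locus ids when present.
#' @param population character or factor of length `nrow(genotypes)`
#'   giving the population of each individual.
#' @param region character or factor of length `nrow(genotypes)` giving
#'   the region of each individual; must be constant within populations.
#' @param sample_ids,locus_ids optional explicit ids; default to the
#'   dimnames of `genotypes` or generated labels.
#'
#' @return An object of class `"aflp_matrix"`: a list with elements
#'   `genotypes` (integer matrix), `population` (factor) and `region`
#'   (factor), all aligned by row.
#' @seealso [read_aflp_matrix()], [genotyping_error_rate()],
#'   [diversity_summary()], [amova_one_level()]
#' @export
aflp_matrix <- function(genotypes, population, region,
                        sample_ids = rownames(genotypes),
                        locus_ids = colnames(genotypes)) {
  genotypes <- as.matrix(genotypes)
  if (is.null(sample_ids)) sample_ids <- paste0("ind", seq_len(nrow(genotypes)))
  if (is.null(locus_ids)) locus_ids <- paste0("L", seq_len(ncol(genotypes)))
  if (length(sample_ids) != nrow(genotypes))
    stop("number of sample ids does not match the number of genotype rows")
  if (length(locus_ids) != ncol(genotypes))
    stop("number of locus ids does not match the number of genotype columns")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  bad <- which(!(genotypes %in% c(0, 1)) | is.na(genotypes))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(genotypes)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(genotypes)) + 1L
    stop(sprintf(
      "non-binary genotype at row %d (sample '%s'), locus '%s': value '%s'",
      i, sample_ids[i], locus_ids[j], as.character(genotypes[i, j])))
  }
  storage.mode(genotypes) <- "integer"
  dimnames(genotypes) <- list(sample_ids, locus_ids)
  if (length(population) != nrow(genotypes))
    stop("'population' must have one entry per individual")
  if (length(region) != nrow(genotypes))
    stop("'region' must have one entry per individual")
  population <- factor(as.character(population),
                       levels = unique(as.character(population)))
  region <- factor(as.character(region), levels = unique(as.character(region)))
  ## each population must sit inside exactly one region
  pr <- unique(data.frame(population, region))
  if (anyDuplicated(pr$population))
    stop("population assigned to more than one region: ",
         paste(pr$population[duplicated(pr$population)], collapse = ", "))
  sizes <- table(population)
  if (any(sizes < 2))
    stop("every population needs at least 2 individuals; too small: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  structure(list(genotypes = genotypes, population = population,
                 region = region),
            class = "aflp_matrix")
}

#' @export
print.aflp_matrix <- function(x, ...) {
  cat("AFLP binary genotype matrix\n")
  cat(sprintf("  %d individuals x %d loci, %d populations in %d region(s)\n",
              nrow(x$genotypes), ncol(x$genotypes),
              nlevels(x$population), nlevels(x$region)))
  invisible(x)
}

#' @export
dim.aflp_matrix <- function(x) dim(x$genotypes)

#' Subset an AFLP matrix by population or region
#'
#' @param x an [aflp_matrix()].
#' @param populations,regions labels to keep (either may be `NULL`).
#' @return A new `aflp_matrix` restricted to the selected individuals.
#' @export
subset_aflp <- function(x, populations = NULL, regions = NULL) {
  stopifnot(inherits(x, "aflp_matrix"))
  keep <- rep(TRUE, nrow(x$genotypes))
  if (!is.null(populations)) {
    unknown <- setdiff(populations, levels(x$population))
    if (length(unknown)) stop("unknown population: ",
                              paste(unknown, collapse = ", "))
    keep <- keep & x$population %in% populations
  }
  if (!is.null(regions)) {
    unknown <- setdiff(regions, levels(x$region))
    if (length(unknown)) stop("unknown region: ",
                              paste(unknown, collapse = ", "))
    keep <- keep & x$region %in% regions
  }
  aflp_matrix(x$genotypes[keep, , drop = FALSE],
              as.character(x$population)[keep],
              as.character(x$region)[keep])
}

#' Read a binary genotype matrix from a delimited text file
#'
#' Two dialects are supported.  The canonical `"tsv"` layout is a
#' tab-separated file with a single header row `sample`, `population`,
#' `region`, followed by one column per locus; each data row carries the
#' 0/1 band calls of one individual.  The `"genalex"` layout mimics the
#' two-header-row flat export common for dominant-marker spreadsheets:
#' line 1 holds the counts `n_loci`, `n_samples`, `n_pops` followed by
#' the per-population sample sizes; line 2 holds a title followed by two
#' blanks and the population names; line 3 is the column header
#' (`sample`, `pop`, locus ids); since that layout carries no region
#' column, a `regions` mapping from population to region must be given
#' (or all populations are placed in a single region `"all"`).
#'
#' @param path file to read.
#' @param dialect `"tsv"` (default) or `"genalex"`.
#' @param regions optional named character vector mapping population
#'   labels to region labels (used by the `"genalex"` dialect).
#' @return An [aflp_matrix()].  Row order of the file is preserved.
#' @export
read_aflp_matrix <- function(path, dialect = c("tsv", "genalex"),
                             regions = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    d <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
    need <- c("sample", "population", "region")
    if (!all(need %in% names(d)[1:3]))
      stop("expected leading columns 'sample', 'population', 'region' in ",
           path)
    loci <- setdiff(names(d), need)
    g <- parse_binary_block(d[loci], d$sample, loci)
    aflp_matrix(g, d$population, d$region, sample_ids = d$sample,
                locus_ids = loci)
  } else {
    lines <- readLines(path)
    if (length(lines) < 4) stop("truncated genotype file: ", path)
    body <- utils::read.delim(text = paste(lines[-(1:2)], collapse = "\n"),
                              check.names = FALSE, colClasses = "character")
    loci <- names(body)[-(1:2)]
    g <- parse_binary_block(body[loci], body[[1]], loci)
    pop <- body[[2]]
    if (is.null(regions)) {
      reg <- rep("all", length(pop))
    } else {
      if (!all(pop %in% names(regions)))
        stop("no region mapping for population: ",
             paste(setdiff(unique(pop), names(regions)), collapse = ", "))
      reg <- unname(regions[pop])
    }
    aflp_matrix(g, pop, reg, sample_ids = body[[1]], locus_ids = loci)
  }
}

## Parse a character data.frame of 0/1 calls, reporting the offending
## row/locus on failure.
parse_binary_block <- function(block, sample_ids, loci) {
  g <- matrix(NA_integer_, nrow(block), length(loci))
  for (j in seq_along(loci)) {
    v <- trimws(block[[j]])
    ok <- v %in% c("0", "1")
    if (!all(ok)) {
      i <- which(!ok)[1]
      stop(sprintf("non-binary value '%s' at row %d (sample '%s'), locus '%s'",
                   v[i], i, sample_ids[i], loci[j]))
    }
    g[, j] <- as.integer(v)
  }
  g
}

#' Write a binary genotype matrix in the canonical tab-separated layout
#'
#' Emits exactly the layout read by `read_aflp_matrix(dialect = "tsv")`,
#' so a write/read round trip reproduces the object.
#'
#' @param x an [aflp_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_aflp_matrix <- function(x, path) {
  stopifnot(inherits(x, "aflp_matrix"))
  d <- data.frame(sample = rownames(x$genotypes),
                  population = as.character(x$population),
                  region = as.character(x$region),
                  x$genotypes, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Genotyping error rate from replicated samples
#'
#' Reproducibility of a dominant-marker run is commonly quantified by
#' rescoring a subset of samples and counting discordant band calls.
#' The rate returned here is the number of discordant locus calls across
#' all replicate pairs divided by (number of pairs x number of loci),
#' i.e. each pair-locus combination counts once.
#'
#' @param x an [aflp_matrix()] containing both members of every pair.
#' @param pairs two-column matrix or data frame of sample ids
#'   (original, replicate).  No sample may appear in two pairs.
#' @return A single fraction in \[0, 1\].
#' @export
genotyping_error_rate <- function(x, pairs) {
  stopifnot(inherits(x, "aflp_matrix"))
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 1) stop("at least one replicate pair is required")
  if (ncol(pairs) != 2) stop("'pairs' must have two columns")
  ids <- rownames(x$genotypes)
  missing <- setdiff(c(pairs), ids)
  if (length(missing)) stop("replicate sample not in matrix: ",
                            paste(missing, collapse = ", "))
  if (anyDuplicated(c(pairs)))
    stop("a sample appears in more than one replicate pair")
  a <- x$genotypes[pairs[, 1], , drop = FALSE]
  b <- x$genotypes[pairs[, 2], , drop = FALSE]
  sum(a != b) / (nrow(pairs) * ncol(x$genotypes))
}
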