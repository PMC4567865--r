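#' Simulation configuration for the synthetic study
#'
#' Bundles every knob of the synthetic-data generator.  The defaults
#' emulate the scale and structure of the motivating study system: two
#' regions of ten populations with 15 individuals each scored at 308
#' dominant loci, within-region differentiation of roughly 0.3 (first
#' region) and 0.37 (second), a between-region component of about 14%
#' of molecular variance, isolation by distance in the second region,
#' region trait contrasts of the magnitude seen in the bundled example
#' table (e.g. cushion densities of ~139 vs ~1599 shoots per m2), and
#' germination dishes of 10 seeds with cell probabilities near 0.5.
#'
#' Population differentiation uses the Balding-Nichols beta model: a
#' daughter frequency is drawn from
#' `Beta(p (1 - F) / F, (1 - p) (1 - F) / F)` around the parent
#' frequency `p`, so the differentiation parameter `F` is directly
#' comparable to a Phi statistic.  By default the beta step acts on the
#' band-presence frequency itself, so AMOVA on the resulting binary
#' data recovers `f_within` without bias.  With `dominance = TRUE` the
#' step instead acts on the frequency of a dominant allele of a
#' diploid locus and individuals show the band with probability
#' `1 - (1 - p)^2`; phenotype-level Phi_PT then exceeds the allelic
#' `F` (the dominance transformation stretches frequency differences),
#' which is worth having when stress-testing the square-root
#' allele-frequency estimator against its own generative assumption.
#'
#' @param n_regions number of regions.
#' @param pops_per_region populations per region.
#' @param inds_per_pop individuals sampled per population (>= 2).
#' @param n_loci number of dominant loci.
#' @param f_within within-region differentiation per region (recycled),
#'   each in \[0, 1).
#' @param f_between between-region differentiation in \[0, 1).
#' @param ibd_region index of a region whose populations are placed on
#'   a geographic line with stepwise drift (isolation by distance), or
#'   `NULL` for none.
#' @param dominance apply the beta step to allele (not band)
#'   frequencies and emit dominant phenotypes; see Details.
#' @param trait_effects named list of per-trait settings, each
#'   `list(family = "t"|"gamma", mean = <per region>, sd = <per
#'   region>)`; `NULL` uses built-in defaults mirroring the example
#'   table.
#' @param germination list with elements `treatments` (labels), `modes`
#'   (treatments x regions matrix of cell germination modes),
#'   `concentration` (> 2), `dishes` and `sown`; `NULL` uses defaults.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_regions = 2, pops_per_region = 10,
                       inds_per_pop = 15, n_loci = 308,
                       f_within = c(0.30, 0.37), f_between = 0.14,
                       ibd_region = 2, dominance = FALSE,
                       trait_effects = NULL, germination = NULL) {
  stopifnot(n_regions >= 1, pops_per_region >= 2, inds_per_pop >= 2,
            n_loci >= 1)
  f_within <- rep_len(f_within, n_regions)
  if (any(f_within < 0 | f_within >= 1) || f_between < 0 || f_between >= 1)
    stop("differentiation parameters must lie in [0, 1)")
  if (!is.null(ibd_region) && (ibd_region < 1 || ibd_region > n_regions))
    ibd_region <- NULL
  if (is.null(trait_effects)) trait_effects <- default_trait_effects()
  if (is.null(germination)) germination <- default_germination_cells(n_regions)
  structure(list(n_regions = n_regions, pops_per_region = pops_per_region,
                 inds_per_pop = inds_per_pop, n_loci = n_loci,
                 f_within = f_within, f_between = f_between,
                 ibd_region = ibd_region, dominance = dominance,
                 trait_effects = trait_effects, germination = germination),
            class = "sim_config")
}

## Region trait contrasts of the magnitude seen in the example table.
default_trait_effects <- function() {
  list(
    HA = list(family = "gamma", mean = c(34600, 3280), sd = c(41000, 3100)),
    NI = list(family = "gamma", mean = c(23, 29), sd = c(6.6, 18)),
    CS = list(family = "t", mean = c(1055, 1435), sd = c(640, 560)),
    CD = list(family = "t", mean = c(139, 1599), sd = c(66, 500)),
    NF = list(family = "gamma", mean = c(8.6, 20.8), sd = c(10.5, 17.5)),
    NC = list(family = "gamma", mean = c(3.1, 3.7), sd = c(5.6, 4.9)),
    He = list(family = "t", mean = c(0.139, 0.145), sd = c(0.018, 0.020)),
    I = list(family = "t", mean = c(0.214, 0.217), sd = c(0.027, 0.031)),
    PPL = list(family = "t", mean = c(46.9, 42.4), sd = c(5.2, 8.2)))
}

default_germination_cells <- function(n_regions = 2) {
  modes <- cbind(c(0.55, 0.35, 0.50, 0.55),
                 c(0.62, 0.42, 0.57, 0.62))[, seq_len(min(n_regions, 2)),
                                            drop = FALSE]
  if (n_regions > 2)
    modes <- modes[, rep_len(1:2, n_regions), drop = FALSE]
  list(treatments = c("14HD-light", "22HD-light", "22/14-light",
                      "22/14-dark"),
       modes = modes, concentration = 30, dishes = 8, sown = 10)
}

## One Balding-Nichols beta step around parent frequencies p with
## differentiation F (vectorized over p; F = 0 returns p unchanged).
balding_nichols <- function(p, f) {
  if (f <= 0) return(p)
  stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

#' Simulate a binary dominant-marker dataset under an island model
#'
#' Draws ancestral band frequencies uniformly on (0.05, 0.95), applies
#' a Balding-Nichols beta step per region (`f_between`) and per
#' population (`f_within`), and emits Bernoulli band calls per
#' individual.  For the `ibd_region` the populations sit on a line
#' 10 km apart and the beta steps accumulate along the chain, so
#' differentiation grows with distance; the per-step `F` is calibrated
#' so that the average pairwise differentiation matches `f_within`.
#' Coordinates of the remaining regions are scattered uniformly in a
#' 50 km box; regions are offset 300 km from each other.
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed; the generator is a pure function
#'   of (config, seed).
#' @return A list with elements `genotypes` (an [aflp_matrix()]) and
#'   `coords` (data frame of `population`, `region`, `x_km`, `y_km`).
#' @export
simulate_aflp <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  R <- config$n_regions; P <- config$pops_per_region
  n <- config$inds_per_pop; L <- config$n_loci
  p0 <- stats::runif(L, 0.05, 0.95)
  pop_names <- as.vector(t(outer(seq_len(R), seq_len(P), function(r, i)
    sprintf("R%dP%02d", r, i))))
  pop_region <- rep(paste0("R", seq_len(R)), each = P)

  freq <- matrix(NA_real_, R * P, L)      # band (or allele) freq per pop
  coords <- data.frame(population = pop_names, region = pop_region,
                       x_km = NA_real_, y_km = NA_real_)
  for (r in seq_len(R)) {
    p_reg <- balding_nichols(p0, config$f_between)
    rows <- (r - 1) * P + seq_len(P)
    if (!is.null(config$ibd_region) && r == config$ibd_region) {
      ## stepwise drift along a line; calibrate the per-step F so the
      ## mean pairwise differentiation matches f_within
      mean_lag <- mean(abs(outer(seq_len(P), seq_len(P), "-"))[
        upper.tri(diag(P))])
      f_step <- 1 - (1 - config$f_within[r])^(1 / mean_lag)
      p_cur <- balding_nichols(p_reg, f_step)
      freq[rows[1], ] <- p_cur
      for (i in 2:P) {
        p_cur <- balding_nichols(p_cur, f_step)
        freq[rows[i], ] <- p_cur
      }
      coords$x_km[rows] <- (r - 1) * 300 + (seq_len(P) - 1) * 10
      coords$y_km[rows] <- 0
    } else {
      for (i in seq_len(P))
        freq[rows[i], ] <- balding_nichols(p_reg, config$f_within[r])
      coords$x_km[rows] <- (r - 1) * 300 + stats::runif(P, 0, 50)
      coords$y_km[rows] <- stats::runif(P, 0, 50)
    }
  }
  band_p <- if (config$dominance) 1 - (1 - freq)^2 else freq
  ind_pop <- rep(seq_len(R * P), each = n)
  g <- matrix(stats::rbinom(R * P * n * L, 1,
                            band_p[ind_pop, , drop = FALSE]),
              R * P * n, L)
  rownames(g) <- paste0(pop_names[ind_pop], "_", rep(seq_len(n), R * P))
  colnames(g) <- sprintf("L%03d", seq_len(L))
  list(genotypes = aflp_matrix(g, pop_names[ind_pop],
                               pop_region[ind_pop]),
       coords = coords)
}

#' Simulate a per-population trait table
#'
#' Draws each trait from its configured family (`"t"`: location-scale
#' Student t with 30 degrees of freedom rescaled to the requested
#' standard deviation; `"gamma"`: moment-matched shape/rate) at the
#' region-specific mean and sd, then derives population density
#' (`PD = NI / HA`) and fruit set exactly as [derive_traits()] does.
#'
#' @inheritParams simulate_aflp
#' @return A per-population trait data frame (`population`, `region`,
#'   traits).
#' @export
simulate_population_table <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  R <- config$n_regions; P <- config$pops_per_region
  tab <- data.frame(
    population = as.vector(t(outer(seq_len(R), seq_len(P), function(r, i)
      sprintf("R%dP%02d", r, i)))),
    region = rep(paste0("R", seq_len(R)), each = P))
  reg_idx <- rep(seq_len(R), each = P)
  nu <- 30
  for (trait in names(config$trait_effects)) {
    e <- config$trait_effects[[trait]]
    m <- rep_len(e$mean, R)[reg_idx]
    s <- rep_len(e$sd, R)[reg_idx]
    tab[[trait]] <- if (e$family == "gamma") {
      stats::rgamma(R * P, shape = m^2 / s^2, rate = m / s^2)
    } else {
      m + s * stats::rt(R * P, nu) / sqrt(nu / (nu - 2))
    }
  }
  if ("NI" %in% names(tab)) tab$NI <- pmax(2, round(tab$NI))
  if (all(c("HA", "NI") %in% names(tab))) tab <- derive_traits(tab)
  tab
}

#' Simulate dish-level germination counts
#'
#' For every treatment x region cell, draws the dish germination
#' probabilities from the mode/concentration beta distribution of the
#' hierarchical model and the germinated counts binomially —
#' the generating process matches the likelihood of
#' [fit_germination()], so round-trip parameter recovery is meaningful.
#'
#' @inheritParams simulate_aflp
#' @return A [germination_data()] frame (`dishes` per cell, `sown`
#'   seeds each).
#' @export
simulate_germination <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  gcfg <- config$germination
  if (gcfg$concentration <= 2) stop("concentration must exceed 2")
  treatments <- gcfg$treatments
  regions <- paste0("R", seq_len(ncol(gcfg$modes)))
  modes <- pmin(pmax(gcfg$modes, 1e-6), 1 - 1e-6)
  rows <- expand.grid(dish = seq_len(gcfg$dishes),
                      treatment = treatments, region = regions,
                      stringsAsFactors = FALSE)
  omega <- modes[cbind(match(rows$treatment, treatments),
                       match(rows$region, regions))]
  kap <- gcfg$concentration
  pi <- stats::rbeta(nrow(rows), omega * (kap - 2) + 1,
                     (1 - omega) * (kap - 2) + 1)
  germination_data(
    dish = sprintf("%s_%s_d%d", rows$treatment, rows$region, rows$dish),
    treatment = rows$treatment, region = rows$region,
    germinated = stats::rbinom(nrow(rows), gcfg$sown, pi),
    sown = gcfg$sown)
}
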