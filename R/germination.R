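#' Dish-level germination count data
#'
#' Validates a germination trial: one row per petri dish with the
#' number of seeds germinated out of the seeds sown, plus the
#' temperature/light treatment and the seed-source region.
#'
#' @param dish dish identifiers (unique).
#' @param treatment treatment label per dish.
#' @param region region label per dish.
#' @param germinated germinated-seed count per dish.
#' @param sown seeds sown per dish (default 10).
#' @return A data frame of class `"germination_data"`.
#' @export
germination_data <- function(dish, treatment, region, germinated,
                             sown = 10L) {
  d <- data.frame(dish = as.character(dish),
                  treatment = factor(as.character(treatment),
                                     levels = unique(as.character(treatment))),
                  region = factor(as.character(region),
                                  levels = unique(as.character(region))),
                  germinated = as.integer(germinated),
                  sown = as.integer(sown))
  if (anyDuplicated(d$dish)) stop("duplicate dish id")
  if (any(d$germinated < 0 | d$germinated > d$sown))
    stop("germinated counts must lie in [0, sown]")
  class(d) <- c("germination_data", "data.frame")
  d
}

#' Hierarchical two-way beta-logistic model of germination counts
#'
#' Bayesian analogue of a two-way logistic ANOVA for dish-level
#' germination counts.  Each dish's germination probability `pi` is
#' beta distributed around its cell (treatment x region) mode `omega`
#' with a concentration `kappa` shared by all cells
#' (`pi ~ Beta(omega * (kappa - 2) + 1, (1 - omega) * (kappa - 2) + 1)`),
#' and the count is binomial.  The cell mode is an inverse-logit of a
#' grand mean plus treatment, region and interaction deflections, each
#' family constrained to sum to zero and given a `Normal(0, sigma)`
#' prior whose precision carries a vague gamma prior; `kappa - 2` has a
#' vague gamma prior.
#'
#' Sampling is Metropolis-within-Gibbs: dish probabilities and the
#' deflection-scale precisions are updated by their conjugate Gibbs
#' draws, the cell parameters and `log(kappa - 2)` by componentwise
#' adaptive random-walk Metropolis.  Convergence (split-Rhat) and
#' effective sample sizes are reported for the cell modes and `kappa`;
#' shortfalls against `ess_target` attach a warning rather than an
#' error, so reduced settings can be used for simulation studies.
#'
#' @param data a [germination_data()] frame; the design must be a
#'   complete treatments x regions grid with at least 2 dishes per
#'   cell, at least 2 treatments and 2 regions.
#' @param chains,iter,warmup,thin MCMC settings (defaults 4 chains,
#'   20000 iterations, 2000 warmup).
#' @param seed optional integer seed.
#' @param ess_target effective-sample-size goal (default 10000).
#' @return An object of class `"germination_fit"`: pooled `cell_theta`
#'   draw matrix (one column per cell mode, named
#'   `"treatment:region"`), per-chain draws, `kappa` and deflection
#'   draws, `diagnostics`, and the factor levels.
#' @seealso [marginal_contrasts()], [letter_groups()]
#' @export
fit_germination <- function(data, chains = 4, iter = 20000, warmup = 2000,
                            thin = 1, seed = NULL, ess_target = 10000) {
  stopifnot(inherits(data, "germination_data"))
  J <- nlevels(data$treatment); K <- nlevels(data$region)
  if (J < 2 || K < 2) stop("at least 2 treatments and 2 regions are required")
  cells <- table(data$treatment, data$region)
  if (any(cells < 2))
    stop("every treatment x region cell needs at least 2 dishes")
  if (!is.null(seed)) set.seed(seed)

  y <- data$germinated; n <- data$sown
  jj <- as.integer(data$treatment); kk <- as.integer(data$region)
  cell_of <- (kk - 1L) * J + jj            # dish -> cell index (column-major)
  boundary <- all(y == 0) || all(y == n)

  nfree <- J * K                            # 1 + (J-1) + (K-1) + (J-1)(K-1)
  ## map free parameters to full sum-to-zero deflections
  expand <- function(th) {
    b0 <- th[1]
    bt <- th[2:J]; bt <- c(bt, -sum(bt))
    br <- th[(J + 1):(J + K - 1)]; br <- c(br, -sum(br))
    bi <- matrix(0, J, K)
    bi[1:(J - 1), 1:(K - 1)] <- th[(J + K):nfree]
    bi[J, 1:(K - 1)] <- -colSums(bi[1:(J - 1), 1:(K - 1), drop = FALSE])
    bi[, K] <- -rowSums(bi[, 1:(K - 1), drop = FALSE])
    list(b0 = b0, bt = bt, br = br, bi = bi,
         omega = stats::plogis(b0 + outer(bt, br, "+") + bi))
  }

  loglik <- function(omega, kappa, pi) {
    a <- omega * (kappa - 2) + 1
    b <- (1 - omega) * (kappa - 2) + 1
    sum(stats::dbeta(pi, a[cell_of], b[cell_of], log = TRUE))
  }
  logprior_cells <- function(ex, sig) {
    stats::dnorm(ex$b0, 0, 10, log = TRUE) +
      sum(stats::dnorm(ex$bt, 0, sig[1], log = TRUE)) +
      sum(stats::dnorm(ex$br, 0, sig[2], log = TRUE)) +
      sum(stats::dnorm(ex$bi, 0, sig[3], log = TRUE))
  }

  emp <- tapply((y + 0.5) / (n + 1), list(jj, kk), mean)
  run_chain <- function() {
    th <- stats::rnorm(nfree, 0, 0.1)
    th[1] <- stats::qlogis(mean(emp)) + stats::rnorm(1, 0, 0.1)
    kappa <- 10 + stats::rexp(1, 1 / 10)
    sig <- c(1, 1, 1)
    pi <- pmin(pmax((y + 0.5) / (n + 1), 1e-6), 1 - 1e-6)
    steps <- rep(0.3, nfree + 1)             # cells + log(kappa-2)
    acc <- nuse <- rep(0, nfree + 1)
    keep <- matrix(NA_real_, floor((iter - warmup) / thin),
                   J * K + 1 + 1 + 3 + J + K)
    k <- 0L
    ex <- expand(th)
    for (t in seq_len(iter)) {
      ## Gibbs: dish probabilities
      a <- ex$omega * (kappa - 2) + 1
      b <- (1 - ex$omega) * (kappa - 2) + 1
      pi <- stats::rbeta(length(y), a[cell_of] + y, b[cell_of] + n - y)
      pi <- pmin(pmax(pi, 1e-9), 1 - 1e-9)
      ## Metropolis: cell parameters
      lp <- loglik(ex$omega, kappa, pi) + logprior_cells(ex, sig)
      for (i in seq_len(nfree)) {
        prop <- th
        prop[i] <- prop[i] + stats::rnorm(1, 0, steps[i])
        exp_p <- expand(prop)
        lp_p <- loglik(exp_p$omega, kappa, pi) + logprior_cells(exp_p, sig)
        if (is.finite(lp_p) && log(stats::runif(1)) < lp_p - lp) {
          th <- prop; ex <- exp_p; lp <- lp_p; acc[i] <- acc[i] + 1
        }
        nuse[i] <- nuse[i] + 1
      }
      ## Metropolis: concentration on log(kappa - 2)
      lk <- log(kappa - 2)
      lk_p <- lk + stats::rnorm(1, 0, steps[nfree + 1])
      kap_p <- 2 + exp(lk_p)
      num <- loglik(ex$omega, kap_p, pi) +
        stats::dgamma(kap_p - 2, 0.01, 0.01, log = TRUE) + lk_p
      den <- loglik(ex$omega, kappa, pi) +
        stats::dgamma(kappa - 2, 0.01, 0.01, log = TRUE) + lk
      if (is.finite(num) && log(stats::runif(1)) < num - den) {
        kappa <- kap_p; acc[nfree + 1] <- acc[nfree + 1] + 1
      }
      nuse[nfree + 1] <- nuse[nfree + 1] + 1
      ## Gibbs: deflection-scale precisions (vague gamma priors)
      sig[1] <- 1 / sqrt(stats::rgamma(1, 0.01 + J / 2,
                                       0.01 + sum(ex$bt^2) / 2))
      sig[2] <- 1 / sqrt(stats::rgamma(1, 0.01 + K / 2,
                                       0.01 + sum(ex$br^2) / 2))
      sig[3] <- 1 / sqrt(stats::rgamma(1, 0.01 + J * K / 2,
                                       0.01 + sum(ex$bi^2) / 2))
      sig <- pmin(pmax(sig, 1e-3), 1e3)
      if (t <= warmup && t %% 50 == 0) {
        steps <- steps * exp(1.2 * (acc / nuse - 0.44))
        acc[] <- nuse[] <- 0
      }
      if (t > warmup && (t - warmup) %% thin == 0) {
        k <- k + 1L
        keep[k, ] <- c(as.vector(ex$omega), kappa, ex$b0, sig, ex$bt, ex$br)
      }
    }
    keep
  }

  chain_draws <- lapply(seq_len(chains), function(ch) run_chain())
  cell_names <- as.vector(outer(levels(data$treatment),
                                levels(data$region),
                                function(a, b) paste(a, b, sep = ":")))
  cols <- c(cell_names, "kappa", "b0", "sigma_treat", "sigma_region",
            "sigma_inter",
            paste0("bt_", levels(data$treatment)),
            paste0("br_", levels(data$region)))
  chain_draws <- lapply(chain_draws, function(m) {
    colnames(m) <- cols
    m
  })
  pooled <- do.call(rbind, chain_draws)

  monitored <- c(cell_names, "kappa")
  diag_tab <- mcmc_diagnostics(stats::setNames(lapply(monitored, function(p)
    lapply(chain_draws, function(m) m[, p])), monitored))
  warn <- character(0)
  if (any(diag_tab$ess[diag_tab$parameter %in% cell_names] < ess_target))
    warn <- c(warn, sprintf("ESS below target (%d) for some cell modes",
                            ess_target))
  if (any(diag_tab$rhat > 1.01, na.rm = TRUE))
    warn <- c(warn, "split-Rhat above 1.01 for at least one parameter")
  if (boundary)
    warn <- c(warn, "all counts at the boundary (all zero or all full)")
  if (length(warn)) warning(paste(warn, collapse = "; "), call. = FALSE)

  structure(list(
    cell_theta = pooled[, cell_names, drop = FALSE],
    draws = pooled,
    chain_draws = chain_draws,
    diagnostics = diag_tab,
    treatments = levels(data$treatment),
    regions = levels(data$region),
    warnings = warn), class = "germination_fit")
}

#' @export
print.germination_fit <- function(x, ...) {
  cat("Hierarchical beta-logistic germination fit\n")
  est <- apply(x$cell_theta, 2, posterior_mode)
  h <- apply(x$cell_theta, 2, hdi)
  tab <- data.frame(cell = colnames(x$cell_theta),
                    mode = round(est, 3),
                    hdi_low = round(h[1, ], 3), hdi_high = round(h[2, ], 3))
  print(tab, row.names = FALSE)
  cat(sprintf("kappa (concentration): %.1f\n",
              posterior_mode(x$draws[, "kappa"])))
  invisible(x)
}

#' Marginal contrasts between factor levels of a germination fit
#'
#' For each pair of levels of the chosen factor, computes the draw-wise
#' difference of the marginal germination probabilities (cell modes
#' averaged over the levels of the other factor), its highest density
#' interval, and whether the difference is credible (HDI excludes
#' zero).
#'
#' @param fit a [fit_germination()] result.
#' @param factor `"treatment"` or `"region"`.
#' @param hdi_mass HDI mass (default 0.95).
#' @return A data frame with one row per level pair (`level_1`,
#'   `level_2`, `diff` = posterior mean of level_1 minus level_2,
#'   `hdi_low`, `hdi_high`, `credible`); the draw-wise difference
#'   vectors are attached as attribute `"draws"`.
#' @export
marginal_contrasts <- function(fit, factor = c("treatment", "region"),
                               hdi_mass = 0.95) {
  stopifnot(inherits(fit, "germination_fit"))
  factor <- match.arg(factor)
  J <- length(fit$treatments); K <- length(fit$regions)
  theta <- fit$cell_theta                  # columns in column-major (J x K)
  if (factor == "treatment") {
    levels <- fit$treatments
    marg <- sapply(seq_len(J), function(j)
      rowMeans(theta[, j + J * (seq_len(K) - 1), drop = FALSE]))
  } else {
    levels <- fit$regions
    marg <- sapply(seq_len(K), function(k)
      rowMeans(theta[, (k - 1) * J + seq_len(J), drop = FALSE]))
  }
  colnames(marg) <- levels
  pairs <- utils::combn(levels, 2)
  draws <- lapply(seq_len(ncol(pairs)), function(i)
    marg[, pairs[1, i]] - marg[, pairs[2, i]])
  h <- vapply(draws, hdi, numeric(2), mass = hdi_mass)
  out <- data.frame(level_1 = pairs[1, ], level_2 = pairs[2, ],
                    diff = vapply(draws, mean, 0),
                    hdi_low = h[1, ], hdi_high = h[2, ],
                    credible = h[1, ] > 0 | h[2, ] < 0)
  attr(out, "draws") <- draws
  attr(out, "levels") <- levels
  out
}

#' Compact letter display from pairwise credibility decisions
#'
#' Assigns letter groups to factor levels so that two levels share a
#' letter exactly when their pairwise difference is not credible
#' (insert-and-absorb algorithm).
#'
#' @param contrasts a [marginal_contrasts()] data frame (all pairs of
#'   the factor must be present).
#' @return Named character vector: level -> letter string.
#' @export
letter_groups <- function(contrasts) {
  levels <- attr(contrasts, "levels")
  if (is.null(levels))
    levels <- unique(c(contrasts$level_1, contrasts$level_2))
  groups <- list(levels)
  sig <- contrasts[contrasts$credible, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    l1 <- sig$level_1[i]; l2 <- sig$level_2[i]
    new_groups <- list()
    for (g in groups) {
      if (all(c(l1, l2) %in% g)) {
        new_groups <- c(new_groups, list(setdiff(g, l1)),
                        list(setdiff(g, l2)))
      } else new_groups <- c(new_groups, list(g))
    }
    ## absorb groups contained in another group
    keep <- vapply(seq_along(new_groups), function(a)
      !any(vapply(seq_along(new_groups), function(b)
        a != b && all(new_groups[[a]] %in% new_groups[[b]]) &&
          !(all(new_groups[[b]] %in% new_groups[[a]]) && a < b),
        TRUE)), TRUE)
    groups <- new_groups[keep]
  }
  ## order groups by their first level and assign letters
  first <- vapply(groups, function(g) min(match(g, levels)), 0)
  groups <- groups[order(first)]
  out <- stats::setNames(rep("", length(levels)), levels)
  for (i in seq_along(groups))
    for (l in groups[[i]])
      out[l] <- paste0(out[l], letters[i])
  out
}
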