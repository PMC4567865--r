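#' Bayesian two-group comparison of a population trait
#'
#' Fits a Bayesian two-group model to per-population trait values and
#' returns posterior draws for the group parameters, their difference
#' and a standardized effect size.  Two likelihoods are available:
#'
#' * `"student_t"` — the robust unequal-variance model: each group has
#'   its own location `mu` and scale `sigma`, with a common
#'   degrees-of-freedom parameter `nu` shared between groups.  Priors
#'   are the established robust-estimation defaults: `mu_k ~
#'   Normal(pooled mean, 1000 * pooled sd)`, `sigma_k ~ Uniform(pooled
#'   sd / 1000, pooled sd * 1000)`, `nu - 1 ~ Exponential(mean 29)`.
#' * `"gamma"` — for strictly positive right-skewed traits such as
#'   habitat area: each group has its own shape and rate with vague
#'   `Gamma(0.01, 0.01)` hyperpriors; the group mean is `shape / rate`
#'   and the reported difference is on the original scale.
#'
#' Sampling uses componentwise adaptive random-walk Metropolis (step
#' sizes tuned during warmup to a 44% acceptance rate).  Effective
#' sample sizes and split-chain Rhat are computed for every reported
#' parameter; a warning is attached (and raised) when the difference
#' parameter falls short of `ess_target` or any Rhat exceeds 1.01.
#'
#' @param values_a,values_b numeric trait values of the two groups
#'   (n >= 3 each).
#' @param likelihood `"student_t"` (default) or `"gamma"`.
#' @param transform `"none"` or `"sqrt"`; with `"sqrt"` the data are
#'   square-root transformed before fitting and the difference is
#'   reported on the transformed scale, with a back-transformed
#'   difference of squared locations also provided.
#' @param chains number of MCMC chains (default 4).
#' @param iter,warmup iterations per chain and warmup iterations
#'   (defaults 30000 / 3000).
#' @param thin keep every `thin`-th draw.
#' @param seed optional integer seed.
#' @param ess_target effective-sample-size goal for reported
#'   parameters (default 10000).
#' @param labels length-2 character vector naming the groups.
#' @return An object of class `"two_group_fit"`: per-chain draw
#'   matrices, pooled `draws` (including `diff` = group a minus group
#'   b and `effect_size`), a `diagnostics` data frame, and the model
#'   settings.
#' @seealso [summarize_comparison()], [hdi()]
#' @export
fit_two_group <- function(values_a, values_b,
                          likelihood = c("student_t", "gamma"),
                          transform = c("none", "sqrt"),
                          chains = 4, iter = 30000, warmup = 3000,
                          thin = 1, seed = NULL, ess_target = 10000,
                          labels = c("a", "b")) {
  likelihood <- match.arg(likelihood)
  transform <- match.arg(transform)
  ya <- as.numeric(values_a); yb <- as.numeric(values_b)
  if (length(ya) < 3 || length(yb) < 3)
    stop("each group needs at least 3 values")
  if (anyNA(ya) || anyNA(yb)) stop("missing trait values are not allowed")
  if (transform == "sqrt") {
    if (any(ya < 0) || any(yb < 0))
      stop("square-root transform requires non-negative data")
    ya <- sqrt(ya); yb <- sqrt(yb)
  }
  if (likelihood == "gamma" && (any(ya <= 0) || any(yb <= 0)))
    stop("the gamma likelihood requires strictly positive data")
  if (!is.null(seed)) set.seed(seed)

  pooled <- c(ya, yb)
  pm <- mean(pooled); ps <- stats::sd(pooled)
  if (ps == 0) ps <- 1

  if (likelihood == "student_t") {
    lo <- log(ps / 1000); hi <- log(ps * 1000)
    logpost <- function(th) {
      mu1 <- th[1]; mu2 <- th[2]
      ls1 <- th[3]; ls2 <- th[4]; lnu <- th[5]
      if (ls1 < lo || ls1 > hi || ls2 < lo || ls2 > hi) return(-Inf)
      nu <- 1 + exp(lnu)
      s1 <- exp(ls1); s2 <- exp(ls2)
      sum(stats::dt((ya - mu1) / s1, nu, log = TRUE)) - length(ya) * ls1 +
        sum(stats::dt((yb - mu2) / s2, nu, log = TRUE)) - length(yb) * ls2 +
        stats::dnorm(mu1, pm, 1000 * ps, log = TRUE) +
        stats::dnorm(mu2, pm, 1000 * ps, log = TRUE) +
        stats::dexp(nu - 1, 1 / 29, log = TRUE) + lnu
    }
    init <- function() c(mu_a = mean(ya) + stats::rnorm(1, 0, ps / 10),
                         mu_b = mean(yb) + stats::rnorm(1, 0, ps / 10),
                         ls_a = log(stats::sd(ya) + ps / 100) +
                           stats::rnorm(1, 0, 0.2),
                         ls_b = log(stats::sd(yb) + ps / 100) +
                           stats::rnorm(1, 0, 0.2),
                         lnu = log(29) + stats::rnorm(1, 0, 0.3))
    derive <- function(k) {
      mu1 <- k[, "mu_a"]; mu2 <- k[, "mu_b"]
      s1 <- exp(k[, "ls_a"]); s2 <- exp(k[, "ls_b"])
      d <- (mu1 - mu2) / sqrt((s1^2 + s2^2) / 2)
      cbind(mean_a = mu1, mean_b = mu2, sigma_a = s1, sigma_b = s2,
            nu = 1 + exp(k[, "lnu"]), diff = mu1 - mu2,
            effect_size = d / sqrt(d^2 + 4))
    }
  } else {
    logpost <- function(th) {
      k1 <- exp(th[1]); r1 <- exp(th[2])
      k2 <- exp(th[3]); r2 <- exp(th[4])
      sum(stats::dgamma(ya, shape = k1, rate = r1, log = TRUE)) +
        sum(stats::dgamma(yb, shape = k2, rate = r2, log = TRUE)) +
        sum(stats::dgamma(c(k1, r1, k2, r2), 0.01, 0.01, log = TRUE)) +
        sum(th)                       # Jacobian of the log transforms
    }
    momint <- function(y) {
      k <- max(mean(y)^2 / stats::var(y), 0.1)
      c(log(k), log(k / mean(y)))
    }
    init <- function() {
      v <- c(momint(ya), momint(yb)) + stats::rnorm(4, 0, 0.2)
      names(v) <- c("lk_a", "lr_a", "lk_b", "lr_b")
      v
    }
    derive <- function(k) {
      sh1 <- exp(k[, "lk_a"]); ra1 <- exp(k[, "lr_a"])
      sh2 <- exp(k[, "lk_b"]); ra2 <- exp(k[, "lr_b"])
      m1 <- sh1 / ra1; m2 <- sh2 / ra2
      v1 <- sh1 / ra1^2; v2 <- sh2 / ra2^2
      d <- (m1 - m2) / sqrt((v1 + v2) / 2)
      cbind(mean_a = m1, mean_b = m2, shape_a = sh1, shape_b = sh2,
            diff = m1 - m2, effect_size = d / sqrt(d^2 + 4))
    }
  }

  chain_draws <- lapply(seq_len(chains), function(ch) {
    raw <- run_rwm_chain(logpost, init(), iter = iter, warmup = warmup,
                         thin = thin, step0 = if (likelihood ==
                                                 "student_t") ps / 5 else 0.3)
    derive(raw)
  })
  pooled_draws <- do.call(rbind, chain_draws)

  monitored <- c("mean_a", "mean_b", "diff", "effect_size")
  diag_tab <- mcmc_diagnostics(stats::setNames(lapply(monitored, function(p)
    lapply(chain_draws, function(k) k[, p])), monitored))

  warn <- character(0)
  if (diag_tab$ess[diag_tab$parameter == "diff"] < ess_target)
    warn <- c(warn, sprintf("ESS of the group difference below target (%d)",
                            ess_target))
  if (any(diag_tab$rhat > 1.01, na.rm = TRUE))
    warn <- c(warn, "split-Rhat above 1.01 for at least one parameter")
  if (length(warn)) warning(paste(warn, collapse = "; "), call. = FALSE)

  fit <- structure(list(
    draws = pooled_draws,
    chain_draws = chain_draws,
    diagnostics = diag_tab,
    likelihood = likelihood,
    transform = transform,
    labels = labels,
    warnings = warn,
    n = c(length(ya), length(yb))), class = "two_group_fit")
  if (transform == "sqrt") {
    fit$diff_backtransformed <-
      pooled_draws[, "mean_a"]^2 - pooled_draws[, "mean_b"]^2
  }
  fit
}

#' @export
print.two_group_fit <- function(x, ...) {
  cat(sprintf("Bayesian two-group fit (%s likelihood%s), groups %s (n=%d) vs %s (n=%d)\n",
              x$likelihood,
              if (x$transform == "sqrt") ", sqrt transform" else "",
              x$labels[1], x$n[1], x$labels[2], x$n[2]))
  print(summarize_comparison(x))
  invisible(x)
}

#' Summarize a two-group fit into a credibility decision
#'
#' Reduces the posterior of the group difference to the "most credible
#' difference" (posterior mode of the pooled draws, via kernel
#' density), its highest density interval, a credibility flag (the HDI
#' excludes zero) and the standardized effect size `r = d / sqrt(d^2 +
#' 4)` where `d` is the draw-wise standardized mean difference.
#'
#' @param fit a [fit_two_group()] result.
#' @param hdi_mass HDI mass (default 0.95).
#' @return A list of class `"comparison_summary"` with elements
#'   `mean_diff`, `hdi_low`, `hdi_high`, `credible`, `effect_size` and
#'   `hdi_mass`.
#' @export
summarize_comparison <- function(fit, hdi_mass = 0.95) {
  stopifnot(inherits(fit, "two_group_fit"))
  d <- fit$draws[, "diff"]
  h <- hdi(d, hdi_mass)
  structure(list(
    mean_diff = posterior_mode(d),
    hdi_low = h[1], hdi_high = h[2],
    credible = h[1] > 0 || h[2] < 0,
    effect_size = mean(fit$draws[, "effect_size"]),
    hdi_mass = hdi_mass), class = "comparison_summary")
}

#' @export
print.comparison_summary <- function(x, ...) {
  cat(sprintf(
    "  most credible difference %.4g, %d%% HDI [%.4g, %.4g]%s, effect size r = %.2f\n",
    x$mean_diff, round(100 * x$hdi_mass), x$hdi_low, x$hdi_high,
    if (x$credible) " (credible)" else "", x$effect_size))
  invisible(x)
}
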