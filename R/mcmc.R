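#' Highest density interval of a sample
#'
#' Shortest contiguous interval containing the requested probability
#' mass of the (sorted) draws.  For unimodal posteriors this is the
#' usual HDI; for strongly multimodal draws the shortest contiguous
#' interval is still returned.
#'
#' @param draws numeric vector of at least 100 posterior draws.
#' @param mass interval mass in (0, 1), default 0.95.
#' @return Numeric vector `c(low, high)`.
#' @export
hdi <- function(draws, mass = 0.95) {
  draws <- draws[is.finite(draws)]
  if (length(draws) < 100)
    stop("at least 100 draws are required for an HDI")
  if (mass <= 0 || mass >= 1) stop("'mass' must lie in (0, 1)")
  s <- sort(draws)
  n <- length(s)
  k <- max(1L, ceiling(mass * n))
  if (k >= n) return(c(s[1], s[n]))
  widths <- s[(k + 1):n] - s[1:(n - k)]
  i <- which.min(widths)
  c(s[i], s[i + k])
}

## Posterior mode via kernel density of the pooled draws ("most credible
## value").
posterior_mode <- function(draws) {
  draws <- draws[is.finite(draws)]
  if (length(draws) < 10) return(stats::median(draws))
  if (stats::sd(draws) == 0) return(draws[1])
  dd <- stats::density(draws, n = 2048)
  dd$x[which.max(dd$y)]
}

## Split-chain potential scale reduction factor (split-Rhat).
## chains: list of numeric vectors of equal length.
split_rhat <- function(chains) {
  half <- unlist(lapply(chains, function(ch) {
    n <- length(ch) %/% 2
    list(ch[1:n], ch[(n + 1):(2 * n)])
  }), recursive = FALSE)
  m <- length(half)
  n <- length(half[[1]])
  means <- vapply(half, mean, 0)
  vars <- vapply(half, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

## Multi-chain effective sample size (sum of per-chain estimates via
## coda's spectral method).
ess_chains <- function(chains) {
  sum(vapply(chains, function(ch) {
    if (stats::sd(ch) == 0) return(0)
    unname(coda::effectiveSize(coda::mcmc(ch)))
  }, 0))
}

## Diagnostics table for a named list of parameters, each a list of
## per-chain draw vectors.
mcmc_diagnostics <- function(param_chains) {
  data.frame(
    parameter = names(param_chains),
    ess = vapply(param_chains, ess_chains, 0),
    rhat = vapply(param_chains, split_rhat, 0),
    row.names = NULL)
}

## Adaptive random-walk Metropolis step on one coordinate of theta.
## logpost must accept the full theta vector.  Returns list(theta, acc).
rw_update <- function(theta, i, logpost, lp_cur, step) {
  prop <- theta
  prop[i] <- prop[i] + stats::rnorm(1, 0, step)
  lp_prop <- logpost(prop)
  if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp_cur) {
    list(theta = prop, lp = lp_prop, acc = TRUE)
  } else {
    list(theta = theta, lp = lp_cur, acc = FALSE)
  }
}

## Generic componentwise adaptive RWM sampler.
## logpost: function(theta) -> log posterior (unnormalized)
## init: named numeric vector
## Returns matrix of kept draws (iter - warmup rows, thinned).
run_rwm_chain <- function(logpost, init, iter, warmup, thin = 1,
                          step0 = 0.5) {
  p <- length(init)
  steps <- rep(step0, p)
  acc <- nacc <- rep(0, p)
  theta <- init
  lp <- logpost(theta)
  if (!is.finite(lp)) stop("initial value has zero posterior density")
  keep <- matrix(NA_real_, floor((iter - warmup) / thin), p,
                 dimnames = list(NULL, names(init)))
  k <- 0L
  for (t in seq_len(iter)) {
    for (i in seq_len(p)) {
      res <- rw_update(theta, i, logpost, lp, steps[i])
      theta <- res$theta; lp <- res$lp
      acc[i] <- acc[i] + res$acc
      nacc[i] <- nacc[i] + 1
    }
    if (t <= warmup && t %% 50 == 0) {
      rate <- acc / nacc
      steps <- steps * exp(1.2 * (rate - 0.44))
      acc[] <- nacc[] <- 0
    }
    if (t > warmup && (t - warmup) %% thin == 0) {
      k <- k + 1L
      keep[k, ] <- theta
    }
  }
  keep
}
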