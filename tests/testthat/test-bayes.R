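test_that("hdi matches closed-form anchors", {
  ## uniform grid: the shortest 95% window has width 0.95
  u <- seq(0, 1, length.out = 10001)
  h <- hdi(u, 0.95)
  expect_equal(h[2] - h[1], 0.95, tolerance = 1e-3)
  ## standard normal: 95% HDI ~ (-1.96, 1.96)
  set.seed(41)
  z <- rnorm(1e5)
  h <- hdi(z, 0.95)
  expect_equal(h[1], -1.96, tolerance = 0.03)
  expect_equal(h[2], 1.96, tolerance = 0.03)
  ## degenerate draws collapse to a point
  expect_equal(unname(hdi(rep(2.5, 200))), c(2.5, 2.5))
  expect_error(hdi(rnorm(50)), "at least 100")
  expect_error(hdi(z, 1.2), "must lie")
})

test_that("two-group t model recovers a known mean difference", {
  set.seed(42)
  a <- rnorm(50, 5, 1); b <- rnorm(50, 0, 1)
  fit <- suppressWarnings(fit_two_group(a, b, chains = 2, iter = 8000,
                                        warmup = 1500, seed = 1))
  s <- summarize_comparison(fit)
  expect_lt(abs(s$mean_diff - 5), 0.5)
  expect_true(s$credible)
  expect_gt(s$effect_size, 0.8)
  ## identical populations: HDI straddles zero
  set.seed(43)
  c1 <- rnorm(30); c2 <- rnorm(30)
  nullfit <- suppressWarnings(fit_two_group(c1, c2, chains = 2,
                                            iter = 6000, warmup = 1200,
                                            seed = 2))
  s0 <- summarize_comparison(nullfit)
  expect_lt(s0$hdi_low, 0)
  expect_gt(s0$hdi_high, 0)
})

test_that("label swap negates the difference and flips the HDI", {
  set.seed(44)
  a <- rnorm(20, 2, 1.5); b <- rnorm(20, 0, 0.5)
  f1 <- suppressWarnings(fit_two_group(a, b, chains = 2, iter = 6000,
                                       warmup = 1200, seed = 3))
  f2 <- suppressWarnings(fit_two_group(b, a, chains = 2, iter = 6000,
                                       warmup = 1200, seed = 3))
  s1 <- summarize_comparison(f1); s2 <- summarize_comparison(f2)
  expect_lt(abs(s1$mean_diff + s2$mean_diff), 0.25)
  expect_lt(abs(s1$hdi_low + s2$hdi_high), 0.25)
  expect_lt(abs(s1$hdi_high + s2$hdi_low), 0.25)
})

test_that("the t likelihood resists an extreme outlier", {
  set.seed(45)
  base_a <- rnorm(10, 10, 1); b <- rnorm(10, 10, 1)
  out_a <- c(base_a[-10], 60)        # one wild value
  fit <- suppressWarnings(fit_two_group(out_a, b, chains = 2, iter = 6000,
                                        warmup = 1200, seed = 4))
  s <- summarize_comparison(fit)
  ## the sample mean moves by ~5; the robust posterior mode moves far less
  naive_shift <- mean(out_a) - mean(b)
  expect_lt(abs(s$mean_diff), naive_shift / 2)
})

test_that("gamma likelihood handles positive skewed data and guards", {
  set.seed(46)
  a <- rgamma(20, 2, 1 / 500); b <- rgamma(20, 2, 1 / 100)
  fit <- suppressWarnings(fit_two_group(a, b, likelihood = "gamma",
                                        chains = 2, iter = 8000,
                                        warmup = 1500, seed = 5))
  s <- summarize_comparison(fit)
  expect_gt(s$mean_diff, 0)
  expect_lt(abs(s$mean_diff - (mean(a) - mean(b))), 400)
  expect_error(fit_two_group(c(-1, 2, 3), c(1, 2, 3),
                             likelihood = "gamma"), "strictly positive")
  expect_error(fit_two_group(1:2, 1:5), "at least 3")
})

test_that("sqrt transform reports both scales", {
  set.seed(47)
  a <- rgamma(15, 4, 1); b <- rgamma(15, 2, 1)
  fit <- suppressWarnings(fit_two_group(a, b, transform = "sqrt",
                                        chains = 2, iter = 4000,
                                        warmup = 800, seed = 6))
  expect_false(is.null(fit$diff_backtransformed))
  ## back-transformed difference of squared locations tracks the
  ## difference of means in sign
  expect_gt(mean(fit$diff_backtransformed), 0)
})

test_that("credibility flags follow the draws", {
  set.seed(48)
  fake <- structure(list(
    draws = cbind(diff = abs(rnorm(1000)) + 0.1,
                  effect_size = rep(0.5, 1000))),
    class = "two_group_fit")
  expect_true(summarize_comparison(fake)$credible)
  fake$draws[, "diff"] <- rnorm(1000)
  expect_false(summarize_comparison(fake)$credible)
})

test_that("the hand-rolled sampler agrees with a JAGS fit", {
  set.seed(49)
  a <- rnorm(25, 3, 2); b <- rnorm(25, 1, 1)
  fit <- suppressWarnings(fit_two_group(a, b, chains = 2, iter = 10000,
                                        warmup = 2000, seed = 7))
  model <- "model {
    for (i in 1:na) { ya[i] ~ dt(mu1, tau1, nu) }
    for (i in 1:nb) { yb[i] ~ dt(mu2, tau2, nu) }
    mu1 ~ dnorm(pm, 1 / (1000 * ps)^2)
    mu2 ~ dnorm(pm, 1 / (1000 * ps)^2)
    s1 ~ dunif(ps / 1000, ps * 1000); tau1 <- 1 / s1^2
    s2 ~ dunif(ps / 1000, ps * 1000); tau2 <- 1 / s2^2
    numinus ~ dexp(1 / 29); nu <- numinus + 1
  }"
  pooled <- c(a, b)
  jm <- rjags::jags.model(textConnection(model),
                          data = list(ya = a, yb = b, na = 25, nb = 25,
                                      pm = mean(pooled), ps = sd(pooled)),
                          n.chains = 2, quiet = TRUE)
  update(jm, 2000, progress.bar = "none")
  post <- rjags::coda.samples(jm, c("mu1", "mu2"), 10000,
                              progress.bar = "none")
  jags_diff <- mean(unlist(lapply(post, function(m) m[, "mu1"] - m[, "mu2"])))
  expect_lt(abs(mean(fit$draws[, "diff"]) - jags_diff), 0.2)
})
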