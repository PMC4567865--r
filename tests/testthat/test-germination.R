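test_that("a designed treatment effect is detected and letters assigned", {
  cfg <- sim_config(germination = list(
    treatments = paste0("T", 1:4),
    modes = cbind(c(0.6, 0.3, 0.5, 0.5), c(0.6, 0.3, 0.5, 0.5)),
    concentration = 50, dishes = 8, sown = 10))
  dat <- simulate_germination(cfg, seed = 51)
  fit <- suppressWarnings(fit_germination(dat, chains = 2, iter = 2500,
                                          warmup = 600, seed = 52))
  ## recovery: posterior cell means close to generating modes
  truth <- rep(c(0.6, 0.3, 0.5, 0.5), 2)
  est <- colMeans(fit$cell_theta)
  expect_true(all(abs(est - truth) < 0.12))
  ct <- marginal_contrasts(fit, "treatment")
  low <- ct$level_1 == "T2" | ct$level_2 == "T2"
  expect_true(all(ct$credible[low]))       # T2 differs from all others
  expect_false(any(ct$credible[!low]))     # the rest do not differ
  letters <- letter_groups(ct)
  expect_equal(unname(letters["T2"]), "b")
  expect_true(all(letters[c("T1", "T3", "T4")] == "a"))
})

test_that("a null design yields no credible contrasts", {
  cfg <- sim_config(germination = list(
    treatments = paste0("T", 1:4),
    modes = matrix(0.5, 4, 2), concentration = 50, dishes = 8, sown = 10))
  dat <- simulate_germination(cfg, seed = 53)
  fit <- suppressWarnings(fit_germination(dat, chains = 2, iter = 2500,
                                          warmup = 600, seed = 54))
  ct <- marginal_contrasts(fit, "treatment")
  cr <- marginal_contrasts(fit, "region")
  expect_false(any(ct$credible))
  expect_false(any(cr$credible))
  expect_true(all(letter_groups(ct) == "a"))
})

test_that("marginal region contrast equals the mean of cell differences", {
  cfg <- sim_config()
  dat <- simulate_germination(cfg, seed = 55)
  fit <- suppressWarnings(fit_germination(dat, chains = 2, iter = 1500,
                                          warmup = 400, seed = 56))
  cr <- marginal_contrasts(fit, "region")
  draws <- attr(cr, "draws")[[1]]
  J <- length(fit$treatments)
  cellwise <- rowMeans(fit$cell_theta[, 1:J] - fit$cell_theta[, J + 1:J])
  expect_equal(unname(draws), unname(cellwise), tolerance = 1e-12)
})

test_that("deflection families stay sum-to-zero in every retained draw", {
  cfg <- sim_config()
  dat <- simulate_germination(cfg, seed = 57)
  fit <- suppressWarnings(fit_germination(dat, chains = 1, iter = 800,
                                          warmup = 200, seed = 58))
  bt <- fit$draws[, grep("^bt_", colnames(fit$draws))]
  br <- fit$draws[, grep("^br_", colnames(fit$draws))]
  expect_lt(max(abs(rowSums(bt))), 1e-10)
  expect_lt(max(abs(rowSums(br))), 1e-10)
  expect_true(all(fit$draws[, "kappa"] > 2))
  expect_true(all(fit$cell_theta > 0 & fit$cell_theta < 1))
})

test_that("cell estimates shrink toward the pooled proportion", {
  ## one cell much higher than the rest: its posterior mean must sit
  ## between its own empirical proportion and the pooled one
  counts <- c(rep(9, 8),                       # T1/A high
              rep(4, 8), rep(5, 8), rep(5, 8), # rest near 0.45
              rep(5, 8), rep(4, 8), rep(5, 8), rep(4, 8))
  dat <- balanced_germination(counts)
  fit <- suppressWarnings(fit_germination(dat, chains = 2, iter = 2500,
                                          warmup = 600, seed = 59))
  cell_emp <- 0.9
  pooled_emp <- mean(counts / 10)
  est <- mean(fit$cell_theta[, "T1:A"])
  expect_gt(est, pooled_emp)
  expect_lt(est, cell_emp)
})

test_that("more seeds per dish narrow every cell interval", {
  cfg10 <- sim_config(germination = list(
    treatments = c("T1", "T2"), modes = matrix(0.5, 2, 2),
    concentration = 50, dishes = 8, sown = 10))
  cfg100 <- sim_config(germination = list(
    treatments = c("T1", "T2"), modes = matrix(0.5, 2, 2),
    concentration = 50, dishes = 8, sown = 100))
  f10 <- suppressWarnings(fit_germination(simulate_germination(cfg10,
                                                               seed = 60),
                                          chains = 2, iter = 2000,
                                          warmup = 500, seed = 61))
  f100 <- suppressWarnings(fit_germination(simulate_germination(cfg100,
                                                                seed = 60),
                                           chains = 2, iter = 2000,
                                           warmup = 500, seed = 61))
  w10 <- apply(f10$cell_theta, 2, function(d) diff(hdi(d)))
  w100 <- apply(f100$cell_theta, 2, function(d) diff(hdi(d)))
  expect_true(all(w100 < w10))
})

test_that("input validation catches broken designs", {
  expect_error(germination_data("d1", "T1", "A", 11, 10), "in \\[0, sown\\]")
  grid <- expand.grid(dish = 1:2, treatment = c("T1", "T2"), region = "A")
  d <- germination_data(paste0("d", 1:4), grid$treatment, grid$region,
                        c(5, 5, 5, 5))
  expect_error(suppressWarnings(fit_germination(d)), "2 regions")
})

test_that("letter grouping resolves the chain pattern a / ab / b", {
  ## A differs from C; B differs from neither
  contrasts <- data.frame(level_1 = c("A", "A", "B"),
                          level_2 = c("B", "C", "C"),
                          diff = c(0.1, 0.3, 0.2),
                          hdi_low = c(-0.05, 0.1, -0.02),
                          hdi_high = c(0.25, 0.5, 0.42),
                          credible = c(FALSE, TRUE, FALSE))
  attr(contrasts, "levels") <- c("A", "B", "C")
  letters <- letter_groups(contrasts)
  expect_equal(unname(letters), c("a", "ab", "b"))
})
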