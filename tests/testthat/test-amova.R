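test_that("binary squared distances equal the per-pair mismatch count", {
  set.seed(21)
  x <- random_aflp(k = 2, n = 5, loci = 20)
  d <- binary_squared_distance(x)
  g <- x$genotypes
  for (i in 1:10) for (j in 1:10)
    expect_equal(d[i, j], sum(g[i, ] != g[j, ]))
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), rep(0, 10))
})

test_that("distance-based SS matches the per-locus ANOVA oracle", {
  set.seed(22)
  for (i in 1:20) {
    x <- random_aflp(k = 3, n = 4, loci = 8)
    a <- amova_one_level(binary_squared_distance(x), x$population,
                         n_perm = 0)
    oracle <- anova_ss_oracle(x)
    expect_equal(a$strata$SS[1], unname(oracle["among"]), tolerance = 1e-9)
    expect_equal(a$strata$SS[2], unname(oracle["within"]), tolerance = 1e-9)
    expect_equal(sum(a$strata$SS),
                 unname(oracle["among"] + oracle["within"]),
                 tolerance = 1e-9)
  }
})

test_that("components from a (df, SS) summary match the raw-data run", {
  set.seed(23)
  ## unequal sample sizes on purpose
  g <- matrix(rbinom(13 * 12, 1, 0.5), 13, 12)
  pops <- rep(c("a", "b", "c"), c(5, 4, 4))
  x <- aflp_matrix(g, pops, rep("r", 13))
  a <- amova_one_level(binary_squared_distance(x), x$population, n_perm = 0)
  b <- components_from_summary(a$strata$df, a$strata$SS,
                               as.numeric(table(pops)))
  expect_equal(b$components_raw, a$components_raw, tolerance = 1e-12)
  expect_equal(b$phi, a$phi, tolerance = 1e-12)
  expect_equal(b$percentages, a$percentages, tolerance = 1e-12)
  ## two-level consistency
  y <- random_aflp(k = 4, n = 4, loci = 10, regions = c("r1", "r1",
                                                        "r2", "r2"))
  a2 <- amova_two_level(binary_squared_distance(y), y$population,
                        y$region, n_perm = 0)
  b2 <- components_from_summary(a2$strata$df, a2$strata$SS, rep(4, 4),
                                regions = c("r1", "r1", "r2", "r2"))
  expect_equal(b2$components_raw, a2$components_raw, tolerance = 1e-12)
  expect_equal(b2$phi, a2$phi, tolerance = 1e-12)
  ## inconsistent df vs sizes is an error
  expect_error(components_from_summary(c(3, 9), c(10, 20), c(5, 4, 4)),
               "inconsistent")
})

test_that("n0 equals the common size for balanced designs", {
  set.seed(24)
  x <- random_aflp(k = 4, n = 6, loci = 10)
  a <- amova_one_level(binary_squared_distance(x), x$population, n_perm = 0)
  expect_equal(unname(a$coefficients["n0"]), 6)
  ## two-level balanced: n = n' = common size is not expected, but the
  ## coefficient identities must reproduce SS via MS * df
  expect_equal(a$strata$SS, (a$strata$SS / a$strata$df) * a$strata$df)
})

test_that("extreme fixtures give the textbook Phi values", {
  ## two internally identical populations differing between
  g <- rbind(matrix(1L, 4, 6), matrix(0L, 4, 6))
  x <- aflp_matrix(g, rep(c("p1", "p2"), each = 4), rep("r", 8))
  a <- amova_one_level(binary_squared_distance(x), x$population, n_perm = 0)
  expect_equal(unname(a$phi["Phi_PT"]), 1)
  expect_equal(unname(a$percentages["within_populations"]), 0)
  ## identical composition in both regions: no regional variance
  set.seed(25)
  block <- matrix(rbinom(8 * 10, 1, 0.5), 8, 10)
  y <- aflp_matrix(rbind(block, block),
                   rep(c("a1", "a2", "b1", "b2"), each = 4),
                   rep(c("r1", "r2"), each = 8))
  a2 <- amova_two_level(binary_squared_distance(y), y$population,
                        y$region, n_perm = 0)
  expect_lt(abs(a2$phi["Phi_RT"]), 0.05)
  ## degenerate data refuse to decompose
  z <- aflp_matrix(matrix(1L, 4, 5), rep(c("p1", "p2"), each = 2),
                   rep("r", 4))
  expect_error(amova_one_level(binary_squared_distance(z), z$population),
               "no molecular variance")
})

test_that("Phi_PT is invariant to locus order and within-pop relabeling", {
  set.seed(26)
  x <- random_aflp(k = 3, n = 5, loci = 15)
  a <- amova_one_level(binary_squared_distance(x), x$population, n_perm = 0)
  perm <- sample(15)
  xp <- aflp_matrix(x$genotypes[, perm], as.character(x$population),
                    as.character(x$region))
  ap <- amova_one_level(binary_squared_distance(xp), xp$population,
                        n_perm = 0)
  expect_equal(ap$phi, a$phi, tolerance = 1e-12)
  ## reorder individuals within populations
  ord <- order(x$population, runif(15))
  xr <- aflp_matrix(x$genotypes[ord, ], as.character(x$population)[ord],
                    as.character(x$region)[ord])
  ar <- amova_one_level(binary_squared_distance(xr), xr$population,
                        n_perm = 0)
  expect_equal(ar$phi, a$phi, tolerance = 1e-12)
})

test_that("permutation p-values are reproducible and sane", {
  set.seed(27)
  x <- random_aflp(k = 3, n = 5, loci = 20)
  d <- binary_squared_distance(x)
  a1 <- amova_one_level(d, x$population, n_perm = 99, seed = 5)
  a2 <- amova_one_level(d, x$population, n_perm = 99, seed = 5)
  expect_identical(a1$perm_p, a2$perm_p)
  expect_gte(unname(a1$perm_p["Phi_PT"]), 1 / 100)
  expect_lte(unname(a1$perm_p["Phi_PT"]), 1)
})

test_that("pairwise Phi_PT agrees with individual one-level AMOVAs", {
  set.seed(28)
  x <- random_aflp(k = 3, n = 6, loci = 25,
                   p = runif(25, 0.3, 0.7))
  pw <- pairwise_phi_pt(x)
  d <- binary_squared_distance(x)
  pops <- levels(x$population)
  for (i in 1:2) for (j in (i + 1):3) {
    m <- x$population %in% pops[c(i, j)]
    a <- amova_one_level(d[m, m], droplevels(x$population[m]), n_perm = 0)
    expect_equal(pw[pops[i], pops[j]],
                 max(0, unname(a$phi["Phi_PT"])), tolerance = 1e-12)
  }
  ## identical pair of populations: Phi truncated to 0
  g <- rbind(matrix(0L, 3, 6), matrix(0L, 3, 6))
  g[c(1, 4), 1:3] <- 1L   # same composition in both pops
  y <- aflp_matrix(g, rep(c("p1", "p2"), each = 3), rep("r", 6))
  expect_equal(pairwise_phi_pt(y)["p1", "p2"], 0)
})
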