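test_that("generators are pure functions of (config, seed)", {
  cfg <- sim_config(pops_per_region = 3, inds_per_pop = 4, n_loci = 30)
  a1 <- simulate_aflp(cfg, seed = 81)
  a2 <- simulate_aflp(cfg, seed = 81)
  expect_identical(a1$genotypes$genotypes, a2$genotypes$genotypes)
  expect_identical(a1$coords, a2$coords)
  t1 <- simulate_population_table(cfg, seed = 82)
  t2 <- simulate_population_table(cfg, seed = 82)
  expect_identical(t1, t2)
  g1 <- simulate_germination(cfg, seed = 83)
  g2 <- simulate_germination(cfg, seed = 83)
  expect_identical(g1, g2)
  ## a different seed changes the data
  expect_false(identical(a1$genotypes$genotypes,
                         simulate_aflp(cfg, seed = 84)$genotypes$genotypes))
})

test_that("simulated structures respect the configured shapes", {
  cfg <- sim_config(n_regions = 2, pops_per_region = 4, inds_per_pop = 5,
                    n_loci = 40)
  s <- simulate_aflp(cfg, seed = 85)
  expect_equal(dim(s$genotypes), c(2 * 4 * 5, 40L))
  expect_equal(nlevels(s$genotypes$population), 8)
  expect_equal(nlevels(s$genotypes$region), 2)
  expect_equal(nrow(s$coords), 8)
  tab <- simulate_population_table(cfg, seed = 86)
  expect_equal(nrow(tab), 8)
  ## gamma-family traits are strictly positive
  expect_true(all(tab$HA > 0))
  expect_true(all(tab$NF > 0))
  expect_equal(tab$PD, tab$NI / tab$HA)
  germ <- simulate_germination(cfg, seed = 87)
  expect_s3_class(germ, "germination_data")
  expect_equal(nrow(germ), 4 * 2 * 8)
  expect_true(all(germ$germinated >= 0 & germ$germinated <= germ$sown))
})

test_that("panmixia yields Phi_PT centred on zero", {
  cfg <- sim_config(n_regions = 1, pops_per_region = 6, inds_per_pop = 8,
                    n_loci = 60, f_within = 0, f_between = 0,
                    ibd_region = NULL)
  set.seed(88)
  phis <- replicate(15, {
    s <- simulate_aflp(cfg)
    a <- amova_one_level(binary_squared_distance(s$genotypes),
                         s$genotypes$population, n_perm = 0)
    unname(a$phi["Phi_PT"])
  })
  expect_lt(abs(mean(phis)), 0.03)
})

test_that("between-region variance grows with f_between", {
  set.seed(89)
  grid <- c(0, 0.05, 0.1, 0.2)
  mean_pct <- vapply(grid, function(fb) {
    cfg <- sim_config(n_regions = 2, pops_per_region = 4,
                      inds_per_pop = 6, n_loci = 60,
                      f_within = 0.1, f_between = fb, ibd_region = NULL)
    mean(replicate(20, {
      s <- simulate_aflp(cfg)
      a <- amova_two_level(binary_squared_distance(s$genotypes),
                           s$genotypes$population, s$genotypes$region,
                           n_perm = 0)
      unname(a$percentages["among_regions"])
    }))
  }, 0)
  expect_true(all(diff(mean_pct) > 0))
})

test_that("trait generator drives the two-group decision as designed", {
  ## strong region effect: credible; zero effect: mostly not credible
  set.seed(90)
  cfg_eff <- sim_config(pops_per_region = 10,
                        trait_effects = list(
                          X = list(family = "t", mean = c(0, 3),
                                   sd = c(1, 1))))
  cfg_null <- sim_config(pops_per_region = 10,
                         trait_effects = list(
                           X = list(family = "t", mean = c(0, 0),
                                    sd = c(1, 1))))
  flags <- vapply(1:10, function(i) {
    tab <- simulate_population_table(cfg_eff, seed = 90 + i)
    fit <- suppressWarnings(fit_two_group(
      tab$X[tab$region == "R2"], tab$X[tab$region == "R1"],
      chains = 2, iter = 3000, warmup = 600, seed = i))
    summarize_comparison(fit)$credible
  }, TRUE)
  expect_gte(mean(flags), 0.9)
  null_flags <- vapply(1:10, function(i) {
    tab <- simulate_population_table(cfg_null, seed = 190 + i)
    fit <- suppressWarnings(fit_two_group(
      tab$X[tab$region == "R2"], tab$X[tab$region == "R1"],
      chains = 2, iter = 3000, warmup = 600, seed = i))
    summarize_comparison(fit)$credible
  }, TRUE)
  expect_lte(mean(null_flags), 0.2)
})

test_that("germination cells are clipped away from the boundary", {
  cfg <- sim_config(germination = list(
    treatments = c("T1", "T2"), modes = matrix(c(0, 1, 0.5, 0.5), 2, 2),
    concentration = 30, dishes = 4, sown = 10))
  g <- simulate_germination(cfg, seed = 91)
  expect_true(all(g$germinated >= 0 & g$germinated <= 10))
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(f_within = 1.2), "\\[0, 1\\)")
  expect_error(sim_config(f_between = -0.1), "\\[0, 1\\)")
  cfg <- sim_config(germination = list(treatments = c("T1", "T2"),
                                       modes = matrix(0.5, 2, 2),
                                       concentration = 1.5,
                                       dishes = 4, sown = 10))
  expect_error(simulate_germination(cfg, seed = 92), "exceed 2")
})
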