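#' Run the full comparative-analysis pipeline
#'
#' Orchestrates every stage of the comparative analysis of isolated
#' populations — diversity summaries, one- and two-level AMOVA,
#' pairwise differentiation, Mantel isolation-by-distance tests per
#' region, Bayesian two-group trait comparisons, the germination model
#' with marginal contrasts and letter groups, and the Spearman
#' correlation screens — and writes the report tables, a
#' full-precision JSON sidecar and a run manifest to `out_dir`.
#'
#' The configuration is a named list (or a path to a YAML file with
#' the same structure) holding exactly one of:
#'
#' * `input`: paths `genotypes` (canonical tab-separated layout),
#'   `traits`, `germination` (CSV of dish/treatment/region/
#'   germinated/sown), and optionally `coords` (CSV with `population`
#'   plus `lat`/`lon` or `x_km`/`y_km` columns);
#' * `simulate`: `TRUE` or a list of [sim_config()] arguments.
#'
#' plus optional `n_perm` (default 999), `seed` (default 1), `mcmc`
#' (list of `chains`, `iter`, `warmup`; pipeline defaults are modest —
#' raise them for publication-grade effective sample sizes), and
#' `compare` (list of `list(trait=, likelihood=, transform=)` entries;
#' the default compares habitat area under a gamma likelihood, square-
#' root-transformed population density and capsule counts, and the
#' remaining structural/reproductive traits under the robust t model).
#'
#' All randomness is derived from `seed`; two runs with the same
#' configuration and seed produce byte-identical outputs (the manifest
#' records settings and versions, not timestamps).
#'
#' @param config named list or path to a YAML file.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the report bundle as a named list.
#' @export
run_pipeline <- function(config, out_dir = "isopop-results") {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulate) && !identical(config$simulate, FALSE)
  if (has_input == has_sim)
    stop("exactly one of 'input' and 'simulate' must be configured")
  n_perm <- config$n_perm %||% 999
  seed <- as.integer(config$seed %||% 1)
  mcmc <- utils::modifyList(list(chains = 2, iter = 6000, warmup = 1000),
                            config$mcmc %||% list())
  compare <- config$compare %||% list(
    list(trait = "HA", likelihood = "gamma", transform = "none"),
    list(trait = "PD", likelihood = "student_t", transform = "sqrt"),
    list(trait = "CS", likelihood = "student_t", transform = "none"),
    list(trait = "CD", likelihood = "student_t", transform = "none"),
    list(trait = "NF", likelihood = "student_t", transform = "none"),
    list(trait = "NC", likelihood = "student_t", transform = "sqrt"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- list()

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    message(sprintf("[isopop] stage %-14s %6.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }
  write_tab <- function(d, file) {
    num <- vapply(d, is.numeric, TRUE)
    d[num] <- lapply(d[num], function(v) round(v, 4))
    utils::write.csv(d, file.path(out_dir, file), row.names = FALSE)
  }

  ## ---- inputs -----------------------------------------------------------
  inputs <- stage("inputs", {
    if (has_sim) {
      args <- if (isTRUE(config$simulate)) list() else config$simulate
      cfg <- do.call(sim_config, args)
      aflp <- simulate_aflp(cfg, seed = seed)
      list(genotypes = aflp$genotypes, coords = aflp$coords,
           coord_method = "euclidean",
           traits = simulate_population_table(cfg, seed = seed + 1L),
           germination = simulate_germination(cfg, seed = seed + 2L))
    } else {
      inp <- config$input
      coords <- NULL; method <- "haversine"
      if (!is.null(inp$coords)) {
        coords <- utils::read.csv(inp$coords)
        if (all(c("x_km", "y_km") %in% names(coords))) method <- "euclidean"
      }
      germ <- NULL
      if (!is.null(inp$germination)) {
        g <- utils::read.csv(inp$germination)
        germ <- germination_data(g$dish, g$treatment, g$region,
                                 g$germinated, g$sown)
      }
      list(genotypes = if (!is.null(inp$genotypes))
        read_aflp_matrix(inp$genotypes),
        coords = coords, coord_method = method,
        traits = if (!is.null(inp$traits)) read_population_table(inp$traits),
        germination = germ)
    }
  })

  ## ---- genetic stages ---------------------------------------------------
  if (!is.null(inputs$genotypes)) {
    x <- inputs$genotypes
    bundle$diversity <- stage("diversity", diversity_summary(x))
    write_tab(bundle$diversity, "diversity.csv")

    bundle$amova <- stage("amova", {
      d <- binary_squared_distance(x)
      one <- amova_one_level(d, x$population, n_perm = n_perm,
                             seed = seed + 10L)
      two <- if (nlevels(x$region) >= 2)
        amova_two_level(d, x$population, x$region, n_perm = n_perm,
                        seed = seed + 11L)
      list(one_level = one, two_level = two)
    })
    amova_rows <- do.call(rbind, lapply(names(bundle$amova), function(nm) {
      a <- bundle$amova[[nm]]
      if (is.null(a)) return(NULL)
      data.frame(analysis = nm, a$strata, MS = a$strata$SS / a$strata$df,
                 sigma2 = unname(a$components),
                 percent = unname(a$percentages))
    }))
    write_tab(amova_rows, "amova.csv")

    bundle$pairwise_phi <- stage("pairwise_phi",
                                 pairwise_phi_pt(x, n_perm = 0,
                                                 seed = seed + 12L))
    write_tab(as.data.frame(bundle$pairwise_phi), "pairwise_phi.csv")

    if (!is.null(inputs$coords)) {
      bundle$mantel <- stage("mantel", {
        gd <- geographic_distances(inputs$coords, inputs$coord_method)
        lapply(stats::setNames(nm = levels(x$region)), function(r) {
          pops <- unique(as.character(x$population[x$region == r]))
          if (length(pops) < 4) return(NULL)
          mantel_test(bundle$pairwise_phi[pops, pops], gd[pops, pops],
                      n_perm = n_perm, seed = seed + 13L)
        })
      })
      mt <- Filter(Negate(is.null), bundle$mantel)
      write_tab(data.frame(region = names(mt),
                           r = vapply(mt, `[[`, 0, "r"),
                           p = vapply(mt, `[[`, 0, "p"),
                           n_perm = vapply(mt, `[[`, 0, "n_perm")),
                "mantel.csv")
    }
  }

  ## ---- trait stages -----------------------------------------------------
  if (!is.null(inputs$traits)) {
    tab <- inputs$traits
    regs <- unique(as.character(tab$region))
    if (length(regs) == 2) {
      bundle$comparisons <- stage("comparisons", {
        lapply(compare, function(cmp) {
          v <- tab[[cmp$trait]]
          if (is.null(v)) return(NULL)
          fit <- suppressWarnings(fit_two_group(
            v[tab$region == regs[2]], v[tab$region == regs[1]],
            likelihood = cmp$likelihood, transform = cmp$transform,
            chains = mcmc$chains, iter = mcmc$iter, warmup = mcmc$warmup,
            seed = seed + 20L + match(cmp$trait, names(tab)),
            labels = c(regs[2], regs[1])))
          c(list(trait = cmp$trait, likelihood = cmp$likelihood,
                 transform = cmp$transform),
            unclass(summarize_comparison(fit)))
        })
      })
      cmp_rows <- do.call(rbind, lapply(Filter(Negate(is.null),
                                               bundle$comparisons),
                                        function(s)
        data.frame(trait = s$trait, likelihood = s$likelihood,
                   transform = s$transform, mean_diff = s$mean_diff,
                   hdi_low = s$hdi_low, hdi_high = s$hdi_high,
                   credible = s$credible, effect_size = s$effect_size)))
      write_tab(cmp_rows, "comparisons.csv")
    }
    vars <- intersect(c("HA", "NI", "PD", "CS", "CD", "NF", "NC",
                        "He", "I", "PPL"), names(tab))
    bundle$correlations <- stage("correlations", {
      ## per-region screens need at least 4 populations in the region
      big <- names(which(table(tab$region) >= 4))
      list(all = correlation_screen(tab, vars),
           by_region = if (length(big))
             correlation_screen(tab[tab$region %in% big, , drop = FALSE],
                                vars, "by-region"))
    })
    write_tab(data.frame(variable = vars,
                         as.data.frame(bundle$correlations$all$rho)),
              "correlations_all.csv")
  }

  ## ---- germination ------------------------------------------------------
  if (!is.null(inputs$germination)) {
    bundle$germination <- stage("germination", {
      fit <- suppressWarnings(fit_germination(
        inputs$germination, chains = mcmc$chains, iter = mcmc$iter,
        warmup = mcmc$warmup, seed = seed + 30L))
      ct <- marginal_contrasts(fit, "treatment")
      list(fit = fit,
           treatment_contrasts = ct,
           region_contrasts = marginal_contrasts(fit, "region"),
           letters = letter_groups(ct))
    })
    write_tab(bundle$germination$treatment_contrasts,
              "germination_treatment_contrasts.csv")
    write_tab(bundle$germination$region_contrasts,
              "germination_region_contrasts.csv")
    cells <- bundle$germination$fit$cell_theta
    write_tab(data.frame(cell = colnames(cells),
                         mode = apply(cells, 2, posterior_mode),
                         t(apply(cells, 2, hdi))) |>
                stats::setNames(c("cell", "mode", "hdi_low", "hdi_high")),
              "germination_cells.csv")
  }

  ## ---- machine-readable sidecar and manifest ----------------------------
  sidecar <- list(
    amova = if (!is.null(bundle$amova)) lapply(bundle$amova, function(a)
      if (!is.null(a)) list(phi = as.list(a$phi),
                            percentages = as.list(a$percentages),
                            perm_p = as.list(a$perm_p))),
    mantel = if (!is.null(bundle$mantel))
      lapply(Filter(Negate(is.null), bundle$mantel), function(m)
        list(r = m$r, p = m$p)),
    comparisons = bundle$comparisons,
    germination_letters = as.list(bundle$germination$letters))
  jsonlite::write_json(sidecar, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  manifest <- list(
    package = "isopop",
    package_version = as.character(utils::packageVersion("isopop")),
    r_version = R.version.string,
    seed = seed, n_perm = n_perm, mcmc = mcmc,
    mode = if (has_sim) "simulate" else "input",
    config = config)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(bundle)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
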