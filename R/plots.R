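#' Bar plot of germination cell estimates with HDI whiskers and letters
#'
#' Draws, per treatment, one bar per region at the posterior mode of
#' the cell germination probability, with 95% HDI whiskers and the
#' compact letters of the treatment contrasts above the bars.
#'
#' @param fit a [fit_germination()] result.
#' @param letters optional named letter vector from [letter_groups()];
#'   computed from the treatment contrasts when missing.
#' @param ... passed to [graphics::barplot()].
#' @return Invisibly, the matrix of cell modes.
#' @export
plot_germination <- function(fit, letters = NULL, ...) {
  stopifnot(inherits(fit, "germination_fit"))
  J <- length(fit$treatments); K <- length(fit$regions)
  est <- matrix(apply(fit$cell_theta, 2, posterior_mode), J, K,
                dimnames = list(fit$treatments, fit$regions))
  h <- apply(fit$cell_theta, 2, hdi)
  lo <- matrix(h[1, ], J, K); hi <- matrix(h[2, ], J, K)
  if (is.null(letters))
    letters <- letter_groups(marginal_contrasts(fit, "treatment"))
  mids <- graphics::barplot(t(est), beside = TRUE, ylim = c(0, 1.05),
                            ylab = "germination probability",
                            legend.text = fit$regions, ...)
  graphics::arrows(mids, t(lo), mids, t(hi), angle = 90, code = 3,
                   length = 0.04)
  graphics::text(colMeans(mids), apply(hi, 1, max) + 0.06,
                 letters[fit$treatments])
  invisible(est)
}

#' Scatter plot of genetic versus geographic distance
#'
#' The classic isolation-by-distance panel: pairwise Phi_PT against
#' pairwise km, with the Mantel statistic in the title.
#'
#' @param phi pairwise differentiation matrix ([pairwise_phi_pt()]).
#' @param geo geographic distance matrix over the same populations.
#' @param mantel optional [mantel_test()] result to annotate.
#' @param ... passed to [graphics::plot()].
#' @export
plot_ibd <- function(phi, geo, mantel = NULL, ...) {
  ut <- upper.tri(phi)
  graphics::plot(geo[ut], phi[ut], xlab = "geographic distance (km)",
                 ylab = expression(Phi[PT]),
                 main = if (!is.null(mantel))
                   sprintf("Mantel r = %.3f, P = %.3g", mantel$r, mantel$p),
                 ...)
}
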