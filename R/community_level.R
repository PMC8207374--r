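# Community-level syntheses: one row per selected species, relating
# neighborhood effects to species abundance (plot basal area), period
# differences to survival effects, and comparing community graphs across
# model modes by Procrustes rotation.

#' Per-species plot basal area
#'
#' Total basal area (m^2) over all alive stems >= \code{gbh_min} cm gbh at
#' the given census, whole plot (no border restriction).
#'
#' @param trees census data frame.
#' @param census census index (defaults to 1, the period-1 start).
#' @param gbh_min inclusion floor, cm (default 10).
#' @return named numeric vector, m^2 per species.
#' @export
species_plot_ba <- function(trees, census = 1, gbh_min = 10) {
  g <- trees[[gbh_col(census)]]
  keep <- trees[[status_col(census)]] %in% "alive" & !is.na(g) & g >= gbh_min
  ba <- tapply(basal_area(g[keep]), trees$species[keep], sum) / 1e4
  ba[order(names(ba))]
}

#' Classify species by over-understory index
#' @param oui numeric OUI values (0-100).
#' @return factor: understory (< 20), intermediate (20-55), overstory
#'   (> 55).
#' @export
oui_class <- function(oui) {
  factor(ifelse(oui < 20, "understory",
                ifelse(oui > 55, "overstory", "intermediate")),
         levels = c("understory", "intermediate", "overstory"))
}

#' Regress a species-level effect on plot abundance
#'
#' Ordinary least squares of per-species neighborhood effects on log10
#' plot basal area, with adjusted and PRESS-predicted R^2.
#'
#' @param effect per-species effect values.
#' @param plot_ba per-species plot basal area, m^2 (same order).
#' @return list: \code{slope}, \code{se}, \code{t}, \code{p},
#'   \code{adj_r2}, \code{pred_r2}, \code{n}.
#' @export
effect_vs_abundance <- function(effect, plot_ba) {
  ok <- is.finite(effect) & is.finite(plot_ba) & plot_ba > 0
  if (sum(ok) < 3) stop("need at least 3 species")
  x <- log10(plot_ba[ok])
  fit <- ols_fit(cbind(intercept = 1, logba = x), effect[ok])
  list(slope = fit$coef[["logba"]], se = fit$se[[2]], t = fit$t[[2]],
       p = fit$p[[2]], adj_r2 = fit$adj_r2, pred_r2 = fit$pred_r2,
       n = fit$n)
}

#' Correlate period differences in growth effects with survival effects
#'
#' Pearson correlation (and the matching OLS line) between e.g. the
#' difference in CON growth effects (P2 - P1) and the CON or HET survival
#' coefficient in P1, optionally on a species subset.
#'
#' @param diff_growth per-species differences (response).
#' @param survival_effect per-species survival coefficients (predictor).
#' @param subset optional logical species filter.
#' @return list: \code{r}, \code{p}, \code{slope}, \code{slope_t},
#'   \code{n}.
#' @export
difference_vs_survival <- function(diff_growth, survival_effect,
                                   subset = NULL) {
  if (!is.null(subset)) {
    diff_growth <- diff_growth[subset]
    survival_effect <- survival_effect[subset]
  }
  ok <- is.finite(diff_growth) & is.finite(survival_effect)
  if (sum(ok) < 3) stop("need at least 3 complete species pairs")
  ct <- stats::cor.test(survival_effect[ok], diff_growth[ok])
  fit <- ols_fit(cbind(intercept = 1, x = survival_effect[ok]),
                 diff_growth[ok])
  list(r = unname(ct$estimate), p = ct$p.value,
       slope = fit$coef[["x"]], slope_t = fit$t[[2]], n = fit$n)
}

#' Procrustes comparison of two community-level graphs
#'
#' Superimposes Y onto X by translation, rotation and scaling and reports
#' the Procrustes correlation sqrt(1 - m^2) with a row-permutation
#' significance test.
#'
#' @param X,Y species x 2 matrices with matching rows.
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed for the permutation test.
#' @return list: \code{correlation}, \code{p}, \code{m2}.
#' @export
procrustes_compare <- function(X, Y, n_perm = 999, seed = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!all(dim(X) == dim(Y))) stop("X and Y must have matching dimensions")
  if (qr(scale(X, scale = FALSE))$rank < 2 ||
      qr(scale(Y, scale = FALSE))$rank < 2)
    stop("rank-deficient input matrix")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pr <- vegan::protest(X, Y, permutations = n_perm)
  list(correlation = unname(pr$t0), p = pr$signif,
       m2 = unname(pr$ss))
}
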