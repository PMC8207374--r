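# Per-species growth and survival regressions over the model grid.
# Growth: ln(agr) = intercept + alpha ln(ba_t1) + beta ln(Sba_CON) +
#                   gamma ln(Sba_HET) + error     (least squares)
# Survival: same linear predictor on the logit of surviving the period.
# Fits are compared by AICc and summarized by unweighted averaging of raw
# coefficients over all fits within 2 AICc of the best one.

#' Small-sample corrected AIC
#'
#' @param loglik model log-likelihood.
#' @param k number of estimated parameters (for least squares this
#'   includes the residual variance).
#' @param n number of observations.
#' @return AICc = -2 loglik + 2k + 2k(k+1)/(n-k-1); \code{Inf} when
#'   n <= k + 1.
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) return(Inf)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Absolute growth rate of focal trees
#'
#' Basal-area increment per year between the period's censuses (cm^2/y by
#' default; \code{basis = "gbh"} gives cm/y). Values at or below zero are
#' floored at \code{eps} before log transformation (or dropped when
#' \code{drop_nonpositive}). Trees not alive at both ends, or with a
#' missing gbh, are excluded with a reason.
#'
#' @param trees census data frame.
#' @param period \code{period_spec}.
#' @param eps floor for non-positive growth (default 0.01 cm^2/y).
#' @param basis \code{"ba"} (default) or \code{"gbh"}.
#' @param drop_nonpositive drop instead of floor (default FALSE).
#' @return data frame: \code{focal_id}, \code{ba_t1}, \code{ln_ba},
#'   \code{agr}, \code{ln_agr}.
#' @export
growth_rate <- function(trees, period, eps = 0.01, basis = c("ba", "gbh"),
                        drop_nonpositive = FALSE) {
  basis <- match.arg(basis)
  g1 <- trees[[gbh_col(period$start)]]
  g2 <- trees[[gbh_col(period$end)]]
  ok <- trees[[status_col(period$start)]] %in% "alive" &
    trees[[status_col(period$end)]] %in% "alive" & !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  agr <- if (basis == "ba") (basal_area(g2) - basal_area(g1)) / period$duration
  else (g2 - g1) / period$duration
  keep <- rep(TRUE, length(agr))
  if (drop_nonpositive) keep <- agr > 0
  agr_f <- pmax(agr, eps)
  out <- data.frame(focal_id = trees$tree_id[ok][keep],
                    ba_t1 = basal_area(g1[keep]),
                    ln_ba = log(basal_area(g1[keep])),
                    agr = agr_f[keep], ln_agr = log(agr_f[keep]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Iterative size-regression outlier exclusion
#'
#' Regresses ln(agr) on ln(ba) and iteratively drops observations with
#' residuals below -3 SD of the residuals, refitting until none remain.
#' Only the size regression is used, never the neighbor model.
#'
#' @param obs growth observations (needs \code{ln_agr}, \code{ln_ba}).
#' @param sd_threshold residual threshold in SD units (default 3).
#' @return the retained subset of \code{obs}.
#' @export
exclude_outliers <- function(obs, sd_threshold = 3) {
  repeat {
    if (nrow(obs) < 3) break
    f <- stats::lm(ln_agr ~ ln_ba, data = obs)
    res <- stats::residuals(f)
    drop <- res < -sd_threshold * stats::sd(res)
    if (!any(drop)) break
    obs <- obs[!drop, , drop = FALSE]
  }
  obs
}

# closed-form OLS with SEs, AICc, adjusted and PRESS-predicted R^2.
# Returns NULL on rank deficiency.
ols_fit <- function(X, y) {
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 2) return(NULL)
  qrx <- qr(X)
  if (qrx$rank < p) return(NULL)
  coef <- drop(qr.coef(qrx, y))
  res <- drop(y - X %*% coef)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  sigma2 <- rss / (n - p)
  R <- qr.R(qrx)
  se <- sqrt(diag(chol2inv(R)) * sigma2)
  tval <- coef / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  k <- p + 1  # mean parameters + residual variance
  h <- rowSums(qr.Q(qrx)^2)
  press <- sum((res / (1 - h))^2)
  list(coef = coef, se = se, t = tval, p = pval, n = n, k = k,
       df_resid = n - p, loglik = ll, aicc = aicc(ll, k, n),
       adj_r2 = 100 * (1 - (rss / (n - p)) / (tss / (n - 1))),
       pred_r2 = 100 * (1 - press / tss))
}

growth_design <- function(data, form) {
  switch(form,
    ba = cbind(intercept = 1, ba = data$ln_ba),
    ba_all = cbind(intercept = 1, ba = data$ln_ba, all = data$ln_all),
    ba_con_het = cbind(intercept = 1, ba = data$ln_ba, con = data$ln_con,
                       het = data$ln_het),
    stop("unknown model form: ", form))
}

empty_fit_row <- function(response, form, reason) {
  list(response = response, form = form, n = NA_integer_,
             k = NA_integer_, aicc = NA_real_,
             est_intercept = NA_real_, est_ba = NA_real_,
             est_all = NA_real_, est_con = NA_real_, est_het = NA_real_,
             se_ba = NA_real_, se_all = NA_real_, se_con = NA_real_,
             se_het = NA_real_, t_con = NA_real_, t_het = NA_real_,
             p_con = NA_real_, p_het = NA_real_,
             adj_r2 = NA_real_, pred_r2 = NA_real_,
             rl2 = NA_real_, adj_rl2 = NA_real_,
             effect_all = NA_real_, effect_con = NA_real_,
             effect_het = NA_real_,
             signed_effect_con = NA_real_, signed_effect_het = NA_real_,
             excluded = TRUE, excluded_reason = reason)
}

rows_to_frame <- function(rows) {
  cols <- names(rows[[1]])
  out <- lapply(cols, function(cn) unlist(lapply(rows, `[[`, cn),
                                          use.names = FALSE))
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

fill_terms <- function(row, fit, terms) {
  row$n <- fit$n; row$k <- fit$k; row$aicc <- fit$aicc
  row$est_intercept <- fit$coef[["intercept"]]
  row$est_ba <- fit$coef[["ba"]]
  row$se_ba <- fit$se[[which(terms == "ba")]]
  for (tm in intersect(c("all", "con", "het"), terms)) {
    i <- which(terms == tm)
    row[[paste0("est_", tm)]] <- fit$coef[[i]]
    row[[paste0("se_", tm)]] <- fit$se[[i]]
    if (tm %in% c("con", "het")) {
      row[[paste0("t_", tm)]] <- fit$t[[i]]
      row[[paste0("p_", tm)]] <- fit$p[[i]]
    }
  }
  row
}

#' Fit one growth model
#'
#' Ordinary least squares on ln-transformed variables. Effect sizes for
#' neighbor terms are squared partial correlations t^2/(t^2 + df_resid)
#' (in [0, 1]); signed versions carry the coefficient's sign. Predicted
#' R^2 comes from the PRESS statistic.
#'
#' @param data observations: \code{ln_agr}, \code{ln_ba}, and the neighbor
#'   columns the form needs (\code{ln_all} or \code{ln_con}/\code{ln_het}).
#' @param form \code{"ba"}, \code{"ba_all"} or \code{"ba_con_het"}.
#' @return one-row data frame (see package overview); on failure a row
#'   with \code{excluded = TRUE} and a reason.
#' @export
fit_growth <- function(data, form = c("ba_con_het", "ba_all", "ba")) {
  rows_to_frame(list(fit_growth_row(data, match.arg(form))))
}

fit_growth_row <- function(data, form) {
  data <- data[stats::complete.cases(growth_design(data, form)), ,
               drop = FALSE]
  if (nrow(data) < 3) return(empty_fit_row("growth", form, "too few obs"))
  X <- growth_design(data, form)
  fit <- ols_fit(X, data$ln_agr)
  if (is.null(fit)) return(empty_fit_row("growth", form, "collinear"))
  row <- empty_fit_row("growth", form, NA_character_)
  row$excluded <- FALSE
  row <- fill_terms(row, fit, colnames(X))
  row$adj_r2 <- fit$adj_r2
  row$pred_r2 <- fit$pred_r2
  es <- function(tv) tv^2 / (tv^2 + fit$df_resid)
  if (form == "ba_all") row$effect_all <- es(fit$t[[3]])
  if (form == "ba_con_het") {
    row$effect_con <- es(fit$t[[3]])
    row$effect_het <- es(fit$t[[4]])
    row$signed_effect_con <- sign(fit$coef[[3]]) * row$effect_con
    row$signed_effect_het <- sign(fit$coef[[4]]) * row$effect_het
  }
  row
}

#' Fit one survival model (logistic regression)
#'
#' Binomial GLM with logit link on the binary outcome (1 = survived the
#' period, so a negative neighbor coefficient means a harmful neighbor).
#' Effects are the raw coefficients; the likelihood pseudo-R^2 is
#' R_L^2 = 100 (L0 - Lp)/L0 with L0 the intercept-only log-likelihood, and
#' its adjusted version applies the linear-regression df adjustment.
#' Estimates whose SE exceeds \code{se_cap} (default 100, an instability
#' guard) are flagged excluded.
#'
#' @param data observations: \code{surv} (0/1), \code{ln_ba}, neighbor
#'   columns as per form.
#' @inheritParams fit_growth
#' @param se_cap exclusion threshold on coefficient standard errors.
#' @return one-row data frame.
#' @export
fit_survival <- function(data, form = c("ba_con_het", "ba_all", "ba"),
                         se_cap = 100) {
  rows_to_frame(list(fit_survival_row(data, match.arg(form), se_cap)))
}

fit_survival_row <- function(data, form, se_cap = 100) {
  data <- data[stats::complete.cases(growth_design(data, form)) &
                 !is.na(data$surv), , drop = FALSE]
  if (length(unique(data$surv)) < 2)
    return(empty_fit_row("survival", form, "one outcome class"))
  X <- growth_design(data, form)
  y <- data$surv
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 2) return(empty_fit_row("survival", form, "too few obs"))
  if (qr(X)$rank < p) return(empty_fit_row("survival", form, "collinear"))
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial()))
  if (!fit$converged || fit$boundary)
    return(empty_fit_row("survival", form, "unstable"))
  coef <- fit$coefficients
  Rm <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
  Rm[lower.tri(Rm)] <- 0
  se <- sqrt(diag(chol2inv(Rm)))
  mu <- fit$fitted.values
  llp <- sum(stats::dbinom(y, 1, mu, log = TRUE))
  ll0 <- sum(stats::dbinom(y, 1, mean(y), log = TRUE))
  k <- p
  res <- list(coef = coef, se = se, t = coef / se,
              p = 2 * stats::pnorm(-abs(coef / se)), n = n, k = k,
              df_resid = n - p, loglik = llp, aicc = aicc(llp, k, n))
  row <- empty_fit_row("survival", form, NA_character_)
  row$excluded <- FALSE
  row <- fill_terms(row, res, colnames(X))
  rl2 <- 100 * (ll0 - llp) / ll0
  row$rl2 <- rl2
  row$adj_rl2 <- 100 * (1 - (1 - rl2 / 100) * (n - 1) / (n - p))
  if (form == "ba_all") row$effect_all <- coef[["all"]]
  if (form == "ba_con_het") {
    row$effect_con <- coef[["con"]]
    row$effect_het <- coef[["het"]]
  }
  if (any(se > se_cap)) {
    row$excluded <- TRUE
    row$excluded_reason <- "unstable"
  }
  row
}

#' Convert a logistic coefficient to a percent change in odds
#' @param beta raw logistic coefficient.
#' @return 100 (exp(beta) - 1): percent increase/decrease in the odds per
#'   unit of the predictor.
#' @export
odds_percent <- function(beta) 100 * (exp(beta) - 1)

#' Growth-model sample composition exclusions
#'
#' A growth fit is flagged and excluded when fewer than \code{min_con}
#' focal trees have any CON neighbor, or fewer than \code{min_zero_het}
#' focal trees have no HET neighbor at all (such fits gravitate to
#' degenerate radii). Survival models carry no such restriction.
#'
#' @param sum_con,sum_het per-focal raw neighborhood sums at the fit's
#'   radii.
#' @param min_con,min_zero_het thresholds (default 5).
#' @return \code{NA_character_} when retained, otherwise the reason.
#' @export
apply_fit_exclusions <- function(sum_con, sum_het, min_con = 5,
                                 min_zero_het = 5) {
  if (sum(sum_con > 0) < min_con) return("fewer than min_con with CON")
  if (sum(sum_het == 0) < min_zero_het)
    return("fewer than min_zero_het without HET")
  NA_character_
}

#' Scan the (radius x overlap-tolerance) model grid
#'
#' One fit per grid cell. For the two-term form the cells are all
#' (r_con, r_het) pairs crossed with all (dd_con, dd_het) canopies present
#' in \code{pred}; for \code{"ba_all"} the cells are the r grid; for
#' \code{"ba"} a single fit. Individual cell failures are recorded as
#' excluded rows, never aborting the scan.
#'
#' @param base per-focal response data: \code{focal_id} plus
#'   \code{ln_agr}/\code{ln_ba} (growth) or \code{surv}/\code{ln_ba}
#'   (survival).
#' @param pred predictor table(s) as from \code{\link{predictor_table}},
#'   with added \code{dd_con}/\code{dd_het} columns when scanned over
#'   several canopies (absent columns are treated as a single dd = NA
#'   setting, e.g. nonspatial).
#' @param response \code{"growth"} or \code{"survival"}.
#' @param form model form (default two-term).
#' @param growth_exclusions apply \code{\link{apply_fit_exclusions}}
#'   (default TRUE for growth).
#' @return data frame of fit rows with grid coordinates.
#' @export
scan_grid <- function(base, pred, response = c("growth", "survival"),
                      form = "ba_con_het", growth_exclusions = TRUE) {
  response <- match.arg(response)
  fit_fun <- if (response == "growth") fit_growth_row else fit_survival_row
  if (!"dd_con" %in% names(pred)) pred$dd_con <- NA_real_
  if (!"dd_het" %in% names(pred)) pred$dd_het <- NA_real_
  dd_pairs <- unique(pred[, c("dd_con", "dd_het")])
  radii <- sort(unique(pred$r))
  rows <- list()
  add <- function(row) rows[[length(rows) + 1L]] <<- row
  for (q in seq_len(nrow(dd_pairs))) {
    sub <- pred[
      (is.na(dd_pairs$dd_con[q]) | pred$dd_con %in% dd_pairs$dd_con[q]) &
      (is.na(dd_pairs$dd_het[q]) | pred$dd_het %in% dd_pairs$dd_het[q]), ]
    # per-focal x per-radius matrices aligned with base$focal_id
    mat <- function(col) {
      m <- matrix(NA_real_, nrow(base), length(radii),
                  dimnames = list(base$focal_id, radii))
      i <- cbind(match(sub$focal_id, base$focal_id), match(sub$r, radii))
      ok <- !is.na(i[, 1])
      m[i[ok, , drop = FALSE]] <- sub[[col]][ok]
      m
    }
    ln_con <- mat("ln_con"); ln_het <- mat("ln_het")
    s_con <- mat("sum_con"); s_het <- mat("sum_het")
    ln_all <- mat("ln_all")
    if (form == "ba") {
      row <- fit_fun(base, form)
      row$dd_con <- dd_pairs$dd_con[q]; row$dd_het <- dd_pairs$dd_het[q]
      row$r_con <- NA_real_; row$r_het <- NA_real_; row$r_all <- NA_real_
      add(row)
    } else if (form == "ba_all") {
      for (r in radii) {
        data <- base
        data$ln_all <- ln_all[, as.character(r)]
        row <- fit_fun(data, form)
        row$dd_con <- dd_pairs$dd_con[q]; row$dd_het <- dd_pairs$dd_het[q]
        row$r_con <- NA_real_; row$r_het <- NA_real_; row$r_all <- r
        add(row)
      }
    } else {
      for (rc in radii) for (rh in radii) {
        data <- base
        data$ln_con <- ln_con[, as.character(rc)]
        data$ln_het <- ln_het[, as.character(rh)]
        row <- fit_fun(data, form)
        if (response == "growth" && growth_exclusions && !row$excluded) {
          reason <- apply_fit_exclusions(s_con[, as.character(rc)],
                                         s_het[, as.character(rh)])
          if (!is.na(reason)) {
            row$excluded <- TRUE
            row$excluded_reason <- reason
          }
        }
        row$dd_con <- dd_pairs$dd_con[q]; row$dd_het <- dd_pairs$dd_het[q]
        row$r_con <- rc; row$r_het <- rh; row$r_all <- NA_real_
        add(row)
      }
    }
  }
  rows_to_frame(rows)
}

# simple bimodality diagnostic on a coefficient set: two density modes
# either straddling zero or separated by >= 2 |mean|
bimodality_flag <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 8 || stats::sd(x) == 0) return(FALSE)
  d <- stats::density(x)
  y <- d$y
  pk <- which(diff(sign(diff(y))) == -2) + 1L
  pk <- pk[y[pk] >= 0.1 * max(y)]
  if (length(pk) < 2) return(FALSE)
  locs <- d$x[pk]
  hi <- locs[order(y[pk], decreasing = TRUE)][1:2]
  (min(hi) < 0 && max(hi) > 0) || abs(diff(hi)) >= 2 * abs(mean(x))
}

#' Model-average the 2-AICc band
#'
#' Unweighted means of raw coefficients across all retained fits within
#' \code{delta} AICc of the best one, with the band's radius and dd
#' summaries, the least-squares slope of each coefficient on its radius,
#' and a bimodality diagnostic (reported, not acted on).
#'
#' @param fits rows from \code{\link{scan_grid}}.
#' @param delta AICc band half-width (default 2).
#' @return one-row data frame (\code{GridSummary}): per-term mean
#'   coefficient, band size, mean/min/max radius, mean dd, slope on
#'   radius, bimodality flag; NULL when no fit is retained.
#' @export
average_band <- function(fits, delta = 2) {
  ok <- fits[!fits$excluded & is.finite(fits$aicc), , drop = FALSE]
  if (!nrow(ok)) return(NULL)
  band <- ok[ok$aicc - min(ok$aicc) <= delta, , drop = FALSE]
  slope <- function(est, r) {
    if (length(unique(r[!is.na(est)])) < 2) return(NA_real_)
    stats::coef(stats::lm(est ~ r))[["r"]]
  }
  out <- data.frame(
    n_models = nrow(band), aicc_min = min(ok$aicc),
    mean_con = mean(band$est_con), mean_het = mean(band$est_het),
    mean_all = mean(band$est_all),
    mean_effect_con = mean(band$effect_con),
    mean_effect_het = mean(band$effect_het),
    mean_signed_effect_con = mean(band$signed_effect_con),
    mean_signed_effect_het = mean(band$signed_effect_het),
    mean_r_con = mean(band$r_con), r_con_min = suppressWarnings(min(band$r_con)),
    r_con_max = suppressWarnings(max(band$r_con)),
    mean_r_het = mean(band$r_het), r_het_min = suppressWarnings(min(band$r_het)),
    r_het_max = suppressWarnings(max(band$r_het)),
    mean_dd_con = mean(band$dd_con), mean_dd_het = mean(band$dd_het),
    slope_con_on_r = slope(band$est_con, band$r_con),
    slope_het_on_r = slope(band$est_het, band$r_het),
    bimodal_con = bimodality_flag(band$est_con),
    bimodal_het = bimodality_flag(band$est_het),
    stringsAsFactors = FALSE)
  out
}

#' Classify a model against the reference by AICc
#'
#' The reference model (by default the nonspatial "ba + ALL" with linear
#' decay) differs strongly when |dAICc| > \code{threshold} (default 7).
#'
#' @param model_aicc AICc of the candidate (e.g. best-in-grid) model.
#' @param reference_aicc AICc of the reference fit on the same
#'   observations.
#' @param threshold strong-difference threshold (default 7).
#' @return \code{"much_better"} (dAICc <= -threshold),
#'   \code{"much_worse"} (>= threshold) or \code{"indistinguishable"}.
#' @export
compare_to_reference <- function(model_aicc, reference_aicc, threshold = 7) {
  d <- model_aicc - reference_aicc
  ifelse(d <= -threshold, "much_better",
         ifelse(d >= threshold, "much_worse", "indistinguishable"))
}
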