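# Growth and survival regressions: arithmetic, oracles against stats::lm
# and stats::glm, exclusion rules, grid scanning, band averaging.

test_that("growth rate is the annualized basal-area increment with flooring", {
  plt <- plot_spec(100, 100, 20, c(1986, 1996))
  per <- period_spec(1, 2, plt)
  trees <- data.frame(
    tree_id = c("g", "flat", "dead"), species = "A", x = 50, y = 50,
    gbh_1 = c(10, 30, 30), status_1 = "alive",
    gbh_2 = c(20, 30, NA), status_2 = c("alive", "alive", "dead"),
    stringsAsFactors = FALSE)
  gr <- growth_rate(trees, per)
  expect_setequal(gr$focal_id, c("g", "flat"))   # dead tree excluded
  expect_equal(gr$agr[gr$focal_id == "g"],
               (basal_area(20) - basal_area(10)) / 10)
  expect_equal(round(gr$agr[gr$focal_id == "g"], 3), 2.387)
  expect_equal(gr$agr[gr$focal_id == "flat"], 0.01)  # floored at eps
  expect_equal(nrow(growth_rate(trees, per, drop_nonpositive = TRUE)), 1)
  # gbh basis
  expect_equal(growth_rate(trees, per, basis = "gbh")$agr[1], 1)
})

test_that("outlier exclusion drops only gross negative residuals and is idempotent", {
  set.seed(21)
  n <- 120
  obs <- data.frame(ln_ba = runif(n, 2, 7))
  obs$ln_agr <- 0.3 + 0.5 * obs$ln_ba + rnorm(n, 0, 0.3)
  expect_identical(exclude_outliers(obs), obs)   # clean set: nothing drops
  bad <- obs
  bad$ln_agr[1] <- bad$ln_agr[1] - 10 * 0.3 * sqrt(n / (n - 2))
  kept <- exclude_outliers(bad)
  expect_false(1 %in% as.integer(rownames(kept)))
  expect_identical(exclude_outliers(kept), kept)
})

test_that("growth fits agree with stats::lm and hand-computed AICc/PRESS", {
  set.seed(8)
  n <- 60
  d <- data.frame(ln_ba = runif(n, 2, 7), ln_con = rnorm(n, 4, 1.5),
                  ln_het = rnorm(n, 5, 1))
  d$ln_agr <- 0.2 + 0.5 * d$ln_ba - 0.2 * d$ln_con - 0.1 * d$ln_het +
    rnorm(n, 0, 0.4)
  row <- fit_growth(d, "ba_con_het")
  ref <- lm(ln_agr ~ ln_ba + ln_con + ln_het, data = d)
  cf <- summary(ref)$coefficients
  expect_equal(row$est_con, cf["ln_con", 1])
  expect_equal(row$se_con, cf["ln_con", 2])
  expect_equal(row$t_het, cf["ln_het", 3])
  expect_equal(row$p_con, cf["ln_con", 4])
  expect_equal(row$adj_r2, 100 * summary(ref)$adj.r.squared)
  # AICc from logLik with k = mean parameters + error variance
  k <- 5
  expect_equal(row$aicc,
               -2 * as.numeric(logLik(ref)) + 2 * k + 2 * k * (k + 1) /
                 (n - k - 1))
  # PRESS predicted R^2 by explicit leave-one-out refits
  press <- sum(vapply(seq_len(n), function(i) {
    f <- lm(ln_agr ~ ln_ba + ln_con + ln_het, data = d[-i, ])
    (d$ln_agr[i] - predict(f, d[i, ]))^2
  }, 0))
  expect_equal(row$pred_r2,
               100 * (1 - press / sum((d$ln_agr - mean(d$ln_agr))^2)))
  # effect sizes are squared partial correlations in [0, 1]
  expect_equal(row$effect_con,
               row$t_con^2 / (row$t_con^2 + ref$df.residual))
  expect_true(row$effect_con >= 0 && row$effect_con <= 1)
  expect_equal(sign(row$signed_effect_con), sign(row$est_con))
  # a term with t^2 = df_resid has effect size exactly 0.5
  expect_equal(sqrt(ref$df.residual)^2 /
                 (sqrt(ref$df.residual)^2 + ref$df.residual), 0.5)
  # collinear design is flagged, not fitted
  d$ln_het <- d$ln_con
  expect_identical(fit_growth(d, "ba_con_het")$excluded_reason, "collinear")
})

test_that("growth fits recover known generative parameters", {
  set.seed(31)
  n <- 500
  d <- data.frame(ln_ba = runif(n, 2, 7), ln_con = rnorm(n, 4, 1.5),
                  ln_het = rnorm(n, 5, 1))
  d$ln_agr <- 0.2 + 0.5 * d$ln_ba - 0.2 * d$ln_con - 0.1 * d$ln_het +
    rnorm(n, 0, 0.2)
  row <- fit_growth(d, "ba_con_het")
  expect_lt(abs(row$est_ba - 0.5), 3 * row$se_ba)
  expect_lt(abs(row$est_con - (-0.2)), 3 * row$se_con)
  expect_lt(abs(row$est_het - (-0.1)), 3 * row$se_het)
})

test_that("survival fits agree with stats::glm and recover known parameters", {
  set.seed(9)
  n <- 500
  d <- data.frame(ln_ba = runif(n, 2, 7), ln_con = rnorm(n, 4, 1.5),
                  ln_het = rnorm(n, 5, 1))
  eta <- 3 + 0.3 * d$ln_ba - 0.5 * d$ln_con - 0.2 * d$ln_het
  d$surv <- rbinom(n, 1, plogis(eta))
  row <- fit_survival(d, "ba_con_het")
  ref <- glm(surv ~ ln_ba + ln_con + ln_het, data = d, family = binomial)
  cf <- summary(ref)$coefficients
  expect_equal(row$est_con, cf["ln_con", 1], tolerance = 1e-6)
  expect_equal(row$se_con, cf["ln_con", 2], tolerance = 1e-5)
  expect_lt(abs(row$est_con - (-0.5)), 3 * row$se_con)
  # survival effects are the raw coefficients
  expect_identical(row$effect_con, row$est_con)
  # pseudo-R^2: 100 (L0 - Lp)/L0, positive for an informative model
  ll0 <- as.numeric(logLik(glm(surv ~ 1, data = d, family = binomial)))
  llp <- as.numeric(logLik(ref))
  expect_equal(row$rl2, 100 * (ll0 - llp) / ll0, tolerance = 1e-6)
  expect_gt(row$rl2, 0)
  # one outcome class cannot be fitted
  d1 <- d; d1$surv <- 1
  expect_identical(fit_survival(d1)$excluded_reason, "one outcome class")
})

test_that("odds conversion and instability exclusion behave as specified", {
  expect_equal(odds_percent(log(2)), 100)
  expect_equal(odds_percent(0), 0)
  # quasi-separated data gives huge SEs -> excluded as unstable
  d <- data.frame(ln_ba = rep(c(1, 2), each = 20),
                  ln_con = rep(c(10, -10), each = 20),
                  ln_het = rnorm(40),
                  surv = rep(c(0, 1), each = 20))
  row <- fit_survival(d, "ba_con_het")
  expect_true(row$excluded)
})

test_that("growth sample-composition exclusions follow the five-tree rules", {
  # 4 focal trees with CON neighbors -> excluded
  expect_match(apply_fit_exclusions(c(rep(1, 4), rep(0, 16)), rep(0, 20)),
               "min_con")
  # 5 with CON and 5 with zero HET -> retained
  expect_true(is.na(apply_fit_exclusions(c(rep(1, 5), rep(0, 15)),
                                         c(rep(2, 15), rep(0, 5)))))
  # only 4 without any HET neighbor -> excluded
  expect_match(apply_fit_exclusions(rep(1, 20), c(rep(0, 4), rep(2, 16))),
               "min_zero_het")
  # engineered fixture matches brute-force counts
  set.seed(2)
  sc <- rpois(30, 0.3); sh <- rpois(30, 3)
  got <- apply_fit_exclusions(sc, sh)
  expect_identical(is.na(got), sum(sc > 0) >= 5 && sum(sh == 0) >= 5)
})

test_that("grid scans enumerate the documented cell counts", {
  set.seed(5)
  nf <- 8
  base <- data.frame(focal_id = paste0("f", 1:nf),
                     ln_agr = rnorm(nf), ln_ba = rnorm(nf, 4),
                     stringsAsFactors = FALSE)
  radii <- c(2, 4, 6, 8, 10)
  dd <- c(0, 0.6)
  grid <- expand.grid(focal_id = base$focal_id, r = radii,
                      dd_con = dd, dd_het = dd)
  grid$sum_con <- rpois(nrow(grid), 2); grid$sum_het <- rpois(nrow(grid), 3)
  grid$ln_con <- log1p(grid$sum_con + rnorm(nrow(grid), 0, 0.1)^2)
  grid$ln_het <- log1p(grid$sum_het + rnorm(nrow(grid), 0, 0.1)^2)
  grid$ln_all <- log1p(grid$sum_con + grid$sum_het)
  # reduced grid: 5 radii x 5 radii x 4 dd pairs = 100 cells
  fits <- scan_grid(base, grid, "growth", growth_exclusions = FALSE)
  expect_equal(nrow(fits), 100)
  # ba + ALL: one cell per radius per dd pair
  expect_equal(nrow(scan_grid(base, grid, "growth", form = "ba_all")), 20)
  # nonspatial (no dd columns): radii^2 cells
  ns <- grid[grid$dd_con == 0 & grid$dd_het == 0,
             setdiff(names(grid), c("dd_con", "dd_het"))]
  expect_equal(nrow(scan_grid(base, ns, "growth",
                              growth_exclusions = FALSE)), 25)
})

test_that("band averaging equals a brute-force 2-AICc filter", {
  set.seed(12)
  n <- 80
  base <- data.frame(focal_id = paste0("f", 1:n), ln_ba = runif(n, 2, 7),
                     stringsAsFactors = FALSE)
  radii <- c(3, 6, 9, 12)
  grid <- expand.grid(focal_id = base$focal_id, r = radii)
  grid$sum_con <- rgamma(nrow(grid), 2, 0.1) * grid$r
  grid$sum_het <- rgamma(nrow(grid), 2, 0.05) * grid$r
  grid$ln_con <- log1p(grid$sum_con); grid$ln_het <- log1p(grid$sum_het)
  grid$ln_all <- log1p(grid$sum_con + grid$sum_het)
  con6 <- grid$ln_con[grid$r == 6][match(base$focal_id,
                                         grid$focal_id[grid$r == 6])]
  base$ln_agr <- 0.2 + 0.5 * base$ln_ba - 0.25 * con6 + rnorm(n, 0, 0.3)
  fits <- scan_grid(base, grid, "growth", growth_exclusions = FALSE)
  s <- average_band(fits)
  ok <- fits[!fits$excluded & is.finite(fits$aicc), ]
  band <- ok[ok$aicc - min(ok$aicc) <= 2, ]
  expect_equal(s$n_models, nrow(band))
  expect_equal(s$mean_con, mean(band$est_con))
  expect_equal(s$mean_r_con, mean(band$r_con))
  expect_equal(s$r_con_max - s$r_con_min,
               max(band$r_con) - min(band$r_con))
  # a single-model band reproduces that model, with zero radius range
  one <- fits[which.min(fits$aicc), ]
  s1 <- average_band(one)
  expect_equal(s1$mean_con, one$est_con)
  expect_equal(s1$r_con_max - s1$r_con_min, 0)
  # two models with known coefficients average plainly
  two <- fits[order(fits$aicc)[1:2], ]
  two$est_con <- c(-0.1, -0.3)
  two$aicc <- c(0, 1)
  expect_equal(average_band(two)$mean_con, -0.2)
})

test_that("reference comparison classifies by the +/-7 AICc rule", {
  expect_identical(compare_to_reference(92, 100), "much_better")
  expect_identical(compare_to_reference(100, 100), "indistinguishable")
  expect_identical(compare_to_reference(107.1, 100), "much_worse")
  expect_identical(compare_to_reference(106.9, 100), "indistinguishable")
})
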