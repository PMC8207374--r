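# Synthetic forest censuses with known structure: clustered multi-species
# stem maps, right-skewed size distributions, and growth/survival dynamics
# generated from the package's own neighborhood regression equations, so
# that the inferential pipeline can be validated by parameter recovery.

#' Specification of a synthetic forest
#'
#' Defaults describe the emulated study system: two 100 x 400 m plots,
#' 20 m analysis borders, censuses spanning periods of 10.00 and 11.07
#' years, clustered species maps, and gbh >= 10 cm with a right-skewed
#' (truncated exponential) size distribution.
#'
#' @param width,length plot dimensions, m.
#' @param n_plots number of plots (default 2).
#' @param border analysis border, m.
#' @param census_dates census schedule (decimal years).
#' @param n_species number of species.
#' @param density_ha stems (>= 10 cm gbh) per hectare (default 2000).
#' @param abundance \code{"logseries"} (Fisher-type rank abundances) or
#'   \code{"fixed"} (equal counts, for unit tests), or a numeric vector of
#'   per-species counts per plot.
#' @param clustering \code{"thomas"} (parent-offspring clusters) or
#'   \code{"csr"} (complete spatial randomness).
#' @param parents_per_ha,cluster_sd Thomas process: cluster parents per
#'   hectare per species and within-cluster Gaussian sd, m.
#' @param gbh_rate,gbh_max truncated-exponential gbh model: rate (per cm)
#'   of the excess over 10 cm, and upper truncation, cm.
#' @param growth growth-equation parameters on the ln scale:
#'   list(intercept, alpha, beta_con, gamma_het, sigma).
#' @param survival logistic survival parameters:
#'   list(intercept, alpha, beta_con, gamma_het).
#' @param r_con,r_het true neighborhood radii, m.
#' @param dd_con,dd_het true overlap tolerances, m.
#' @param decay distance decay of the true model.
#' @param fill_mode crown filling of the true model (\code{"larsm"},
#'   \code{"equal"}, or \code{"none"} for the nonspatial/point limit).
#' @param adjust_mode crown plasticity of the true model.
#' @param density points per m^2 for \code{"equal"} filling.
#' @return list of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(width = 100, length = 400, n_plots = 2,
                           border = 20,
                           census_dates = c(1986, 1996, 2007.07),
                           n_species = 20, density_ha = 2000,
                           abundance = "logseries",
                           clustering = c("thomas", "csr"),
                           parents_per_ha = 2, cluster_sd = 10,
                           gbh_rate = 0.05, gbh_max = 300,
                           growth = list(intercept = 0.2, alpha = 0.5,
                                         beta_con = -0.2, gamma_het = -0.1,
                                         sigma = 0.6),
                           survival = list(intercept = 3.0, alpha = 0.3,
                                           beta_con = -0.3,
                                           gamma_het = -0.1),
                           r_con = 10, r_het = 10, dd_con = 0, dd_het = 0,
                           decay = "linear",
                           fill_mode = c("larsm", "equal", "none"),
                           adjust_mode = c("removal", "relocation"),
                           density = 10) {
  clustering <- match.arg(clustering)
  fill_mode <- match.arg(fill_mode)
  adjust_mode <- match.arg(adjust_mode)
  stopifnot(density_ha > 0, gbh_rate > 0, gbh_max > 10,
            growth$sigma > 0, r_con >= 1, r_het >= 1)
  structure(as.list(environment()), class = "synthetic_spec")
}

spec_plot <- function(spec)
  plot_spec(spec$width, spec$length, spec$border, spec$census_dates)

# rank abundances: Fisher-style log-series shape (p_k ~ x^k / k), scaled
# to the target total
logseries_counts <- function(total, n_species, x = 0.98) {
  k <- seq_len(n_species)
  p <- x^k / k
  counts <- round_half_up(total * p / sum(p))
  counts[counts < 1] <- 1
  counts
}

rtrunc_exp <- function(n, rate, lo, hi) {
  u <- stats::runif(n)
  lo - log(1 - u * (1 - exp(-rate * (hi - lo)))) / rate
}

#' Generate one plot's first census
#'
#' Species counts follow the spec's abundance model; positions are a
#' Thomas cluster process (offspring wrapped torus-fashion into the plot,
#' preserving counts) or CSR; gbh is truncated-exponential above 10 cm.
#'
#' @param spec a \code{synthetic_spec}.
#' @param seed master seed.
#' @param plot_id integer tag used in tree ids (default 1).
#' @return census data frame (canonical columns, census 1 only).
#' @export
generate_stand <- function(spec, seed = 1L, plot_id = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, paste0("stand", plot_id), "synth"))
  area_ha <- spec$width * spec$length / 1e4
  total <- round_half_up(spec$density_ha * area_ha)
  counts <- if (is.numeric(spec$abundance)) spec$abundance
  else if (spec$abundance == "fixed")
    rep(round_half_up(total / spec$n_species), spec$n_species)
  else logseries_counts(total, spec$n_species)
  sp_names <- sprintf("SP%02d", seq_along(counts))
  rows <- list()
  for (s in seq_along(counts)) {
    n <- counts[s]
    if (n < 1) next
    if (spec$clustering == "csr") {
      x <- stats::runif(n, 0, spec$width)
      y <- stats::runif(n, 0, spec$length)
    } else {
      npar <- max(1L, stats::rpois(1, spec$parents_per_ha * area_ha))
      px <- stats::runif(npar, 0, spec$width)
      py <- stats::runif(npar, 0, spec$length)
      pick <- sample.int(npar, n, replace = TRUE)
      x <- (px[pick] + stats::rnorm(n, 0, spec$cluster_sd)) %% spec$width
      y <- (py[pick] + stats::rnorm(n, 0, spec$cluster_sd)) %% spec$length
    }
    rows[[s]] <- data.frame(
      species = sp_names[s], x = round(x, 1), y = round(y, 1),
      gbh = rtrunc_exp(n, spec$gbh_rate, 10, spec$gbh_max),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- data.frame(tree_id = sprintf("P%d_T%05d", plot_id,
                                      seq_len(nrow(out))),
                    species = out$species, x = out$x, y = out$y,
                    gbh_1 = out$gbh, status_1 = "alive",
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# point clouds of the spec's true model for one census ("none" = stems)
true_clouds <- function(trees, census, spec, seed) {
  if (spec$fill_mode == "none")
    clouds <- fill_plot(trees, census, fill_mode = "larsm", seed = seed,
                        cr_zero = TRUE)
  else
    clouds <- fill_plot(trees, census, fill_mode = spec$fill_mode,
                        density = spec$density, seed = seed)
  if (spec$fill_mode != "none" && (spec$dd_con > 0 || spec$dd_het > 0))
    adjust_plot(clouds, spec$dd_con, spec$dd_het, spec$adjust_mode,
                seed)$clouds
  else clouds
}

# flat point arrays, sorted by x, with integer owner-tree indices; this
# supports fast per-focal windowed distance queries during generation
flat_points <- function(clouds) {
  n <- vapply(clouds, function(cl) length(cl$x), integer(1))
  owner <- rep(seq_along(clouds), n)
  px <- unlist(lapply(clouds, `[[`, "x"), use.names = FALSE)
  py <- unlist(lapply(clouds, `[[`, "y"), use.names = FALSE)
  pw <- rep(vapply(clouds, `[[`, 0, "weight"), n)
  ord <- order(px, method = "radix")
  list(px = px[ord], py = py[ord], pw = pw[ord], owner = owner[ord])
}

# decayed CON/HET point-weight sums around (x0, y0); `use` is a logical
# over trees (candidate neighbor set), `con` a logical over trees
sums_at <- function(fp, x0, y0, use, con, r_con, r_het, decay) {
  rmax <- max(r_con, r_het)
  lo <- findInterval(x0 - rmax, fp$px) + 1L
  hi <- findInterval(x0 + rmax, fp$px)
  if (hi < lo) return(c(con = 0, het = 0))
  sl <- lo:hi
  sl <- sl[use[fp$owner[sl]] & abs(fp$py[sl] - y0) <= rmax]
  if (!length(sl)) return(c(con = 0, het = 0))
  d <- sqrt((fp$px[sl] - x0)^2 + (fp$py[sl] - y0)^2)
  w <- fp$pw[sl] * decay_factor(d, decay)
  isc <- con[fp$owner[sl]]
  c(con = sum(w[isc & d <= r_con]), het = sum(w[!isc & d <= r_het]))
}

#' Generate the next census from the model equations
#'
#' Survival is drawn first, sequentially from the largest tree down, so
#' that each tree's survival probability depends only on larger neighbors
#' whose fate is already decided - making the generative neighbor set
#' identical to the one the fitted survival models use. Growth is then
#' drawn for the survivors from the ln-linear growth equation with
#' lognormal error (agr > 0 by construction, so no shrinkage), and the new
#' gbh is back-computed from ba_t1 + agr * duration. Dead trees keep their
#' last measured gbh.
#'
#' @param trees census data frame holding census \code{period$start}.
#' @param spec a \code{synthetic_spec}.
#' @param period \code{period_spec} (duration sets the growth increment).
#' @param seed master seed.
#' @return \code{trees} with added \code{gbh_<end>} and
#'   \code{status_<end>} columns, plus attribute \code{"true_predictors"}
#'   (per-tree CON/HET sums used in generation).
#' @export
generate_dynamics <- function(trees, spec, period, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, paste0("dyn", period$start), "synth"))
  census <- period$start
  g1 <- trees[[gbh_col(census)]]
  alive <- trees[[status_col(census)]] %in% "alive" & !is.na(g1)
  clouds <- true_clouds(trees, census, spec, seed)
  ids <- names(clouds)
  fp <- flat_points(clouds)
  idx <- match(ids, trees$tree_id)
  gbh_of <- g1[idx]
  sp_of <- trees$species[idx]
  cx <- vapply(clouds, function(cl) cl$center[1], 0)
  cy <- vapply(clouds, function(cl) cl$center[2], 0)
  ord <- order(-gbh_of, ids, method = "radix")

  # survival, largest tree first: only strictly larger, already-decided
  # survivors act as neighbors
  n <- length(ids)
  survived <- rep(NA, n)
  s_con <- s_het <- rep(NA_real_, n)
  u <- stats::runif(n)
  for (o in ord) {
    use <- gbh_of > gbh_of[o] & survived %in% TRUE
    s <- sums_at(fp, cx[o], cy[o], use, sp_of == sp_of[o],
                 spec$r_con, spec$r_het, spec$decay)
    s_con[o] <- s[["con"]]; s_het[o] <- s[["het"]]
    eta <- spec$survival$intercept +
      spec$survival$alpha * log(basal_area(gbh_of[o])) +
      spec$survival$beta_con * log1p(s[["con"]]) +
      spec$survival$gamma_het * log1p(s[["het"]])
    survived[o] <- u[o] < stats::plogis(eta)
  }

  # growth predictors: larger-or-equal surviving neighbors
  g_con <- g_het <- rep(NA_real_, n)
  for (o in seq_len(n)) {
    if (!survived[o]) next
    use <- gbh_of >= gbh_of[o] & survived & seq_len(n) != o
    s <- sums_at(fp, cx[o], cy[o], use, sp_of == sp_of[o],
                 spec$r_con, spec$r_het, spec$decay)
    g_con[o] <- s[["con"]]; g_het[o] <- s[["het"]]
  }
  ba1 <- basal_area(gbh_of)
  mu <- spec$growth$intercept + spec$growth$alpha * log(ba1) +
    spec$growth$beta_con * log1p(g_con) +
    spec$growth$gamma_het * log1p(g_het)
  agr <- exp(mu + stats::rnorm(n, 0, spec$growth$sigma))
  gbh2 <- gbh_from_basal_area(ba1 + agr * period$duration)

  out <- trees
  gcol <- gbh_col(period$end); scol <- status_col(period$end)
  out[[gcol]] <- NA_real_
  out[[scol]] <- ifelse(alive, "dead", "absent")
  out[[gcol]][idx] <- ifelse(survived, gbh2, gbh_of)
  out[[scol]][idx] <- ifelse(survived, "alive", "dead")
  attr(out, "true_predictors") <- data.frame(
    tree_id = ids, surv_con = s_con, surv_het = s_het,
    growth_con = g_con, growth_het = g_het, survived = survived,
    stringsAsFactors = FALSE)
  out
}

#' Generate a complete multi-plot, multi-census synthetic forest
#'
#' @param spec a \code{synthetic_spec}.
#' @param seed master seed.
#' @return list with one element per plot: list(\code{trees} with all
#'   censuses, \code{plot}).
#' @export
generate_forest <- function(spec, seed = 1L) {
  plt <- spec_plot(spec)
  lapply(seq_len(spec$n_plots), function(p) {
    trees <- generate_stand(spec, seed, plot_id = p)
    for (ci in seq_len(length(spec$census_dates) - 1)) {
      per <- period_spec(ci, ci + 1, plt)
      trees <- generate_dynamics(trees, spec, per,
                                 seed = seed + 1000L * p)
    }
    list(trees = trees, plot = plt)
  })
}
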