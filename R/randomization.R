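# Location-randomization null model: trees are re-placed at random in the
# plot under minimum nearest-neighbor distance rules by size class,
# preserving each species' size structure exactly; the whole fitting
# pipeline is re-run per randomized layout and observed effects are judged
# against +/- 3 SE limits of the null distribution.

#' Randomization configuration
#'
#' @param n_runs number of randomized layouts (default 100).
#' @param class_bounds lower gbh bounds of the size classes, cm
#'   (default 10/30/60/120/240/480: six classes partitioning [10, Inf)).
#' @param min_same minimum nearest-neighbor distance within a size class,
#'   m (default 1).
#' @param min_diff minimum distance between different size classes, m
#'   (default 0.5).
#' @param max_attempts placement retries per tree before the constraint is
#'   relaxed with a warning (default 200).
#' @return list of class \code{randomization_config}. The distance matrix
#'   is \code{min_same} on the diagonal and \code{min_diff} off it; pass a
#'   full matrix via \code{min_matrix} to override.
#' @param min_matrix optional full k x k distance matrix, m.
#' @export
randomization_config <- function(n_runs = 100,
                                 class_bounds = c(10, 30, 60, 120, 240, 480),
                                 min_same = 1, min_diff = 0.5,
                                 min_matrix = NULL, max_attempts = 200) {
  k <- length(class_bounds)
  if (is.null(min_matrix)) {
    min_matrix <- matrix(min_diff, k, k)
    diag(min_matrix) <- min_same
  }
  stopifnot(all(min_matrix >= 0), nrow(min_matrix) == k)
  structure(list(n_runs = n_runs, class_bounds = class_bounds,
                 min_matrix = min_matrix, max_attempts = max_attempts),
            class = "randomization_config")
}

#' Randomize tree locations under minimum-distance rules
#'
#' Every tree keeps its species, sizes and statuses but receives a new
#' uniform location in the plot, placed sequentially in descending size
#' order subject to the per-size-class minimum nearest-neighbor distances.
#' After \code{max_attempts} failed draws the constraint is relaxed for
#' that tree (with a warning). The per-species gbh multiset is preserved
#' exactly. Deterministic given (seed, run_index).
#'
#' @param trees census data frame.
#' @param plot \code{plot_spec}.
#' @param config \code{randomization_config}.
#' @param run_index 1-based randomization run number.
#' @param seed master seed.
#' @param census census whose gbh defines the size classes (default 1).
#' @return \code{trees} with new \code{x}, \code{y}.
#' @export
randomize_positions <- function(trees, plot = plot_spec(),
                                config = randomization_config(),
                                run_index = 1, seed = 1L, census = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, paste0("run", run_index), "randomize"))
  g <- trees[[gbh_col(census)]]
  g[is.na(g)] <- config$class_bounds[1]
  cls <- findInterval(g, config$class_bounds)
  cls[cls < 1] <- 1L
  ord <- order(-g, trees$tree_id, method = "radix")
  n <- nrow(trees)
  px <- numeric(n); py <- numeric(n); pcls <- integer(n)
  placed <- 0L
  relaxed <- 0L
  for (i in ord) {
    need <- config$min_matrix[cls[i], ]
    ok <- FALSE
    for (a in seq_len(config$max_attempts)) {
      cx <- stats::runif(1, 0, plot$width)
      cy <- stats::runif(1, 0, plot$length)
      if (placed == 0L) { ok <- TRUE; break }
      j <- seq_len(placed)
      d2 <- (px[j] - cx)^2 + (py[j] - cy)^2
      if (all(d2 >= need[pcls[j]]^2)) { ok <- TRUE; break }
    }
    if (!ok) relaxed <- relaxed + 1L
    placed <- placed + 1L
    px[placed] <- cx; py[placed] <- cy; pcls[placed] <- cls[i]
  }
  if (relaxed > 0)
    warning(sprintf("minimum-distance constraint relaxed for %d tree(s)",
                    relaxed))
  out <- trees
  out$x[ord] <- px
  out$y[ord] <- py
  out
}

#' Null envelopes for per-species effects
#'
#' Classifies each observed effect against the mean +/- 3 SE of its
#' randomization distribution, where SE is the standard deviation of the
#' effect across randomized layouts. Magnitude bands for the departure
#' |observed - null mean|: growth moderate 0.06 to <0.1, large >= 0.1;
#' survival moderate 0.6 to <1.0, large >= 1.0.
#'
#' @param observed named numeric vector of per-species effects.
#' @param null_runs matrix (runs x species, columns matching
#'   \code{observed}) of the same effect under randomized layouts.
#' @param response \code{"growth"} or \code{"survival"} (sets the
#'   magnitude bands).
#' @param k_se envelope half-width in SE units (default 3).
#' @return data frame per species: null mean, SE, limits, classification
#'   (\code{positive}/\code{ns}/\code{negative}), magnitude band.
#' @export
null_envelopes <- function(observed, null_runs,
                           response = c("growth", "survival"), k_se = 3) {
  response <- match.arg(response)
  if (nrow(null_runs) < 2) stop("need at least 2 randomization runs")
  if (is.null(colnames(null_runs)) ||
      !identical(colnames(null_runs), names(observed)))
    stopifnot(ncol(null_runs) == length(observed))
  mu <- colMeans(null_runs, na.rm = TRUE)
  se <- apply(null_runs, 2, stats::sd, na.rm = TRUE)
  lo <- mu - k_se * se
  hi <- mu + k_se * se
  classification <- ifelse(observed > hi, "positive",
                           ifelse(observed < lo, "negative", "ns"))
  dep <- abs(observed - mu)
  bands <- if (response == "growth") c(0.06, 0.1) else c(0.6, 1.0)
  magnitude <- cut(dep, breaks = c(-Inf, bands, Inf), right = FALSE,
                   labels = c("small", "moderate", "large"))
  data.frame(species = names(observed), observed = unname(observed),
             null_mean = unname(mu), null_se = unname(se),
             lower = unname(lo), upper = unname(hi),
             classification = unname(classification),
             magnitude = as.character(magnitude),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Null distribution of the community regression slope
#'
#' Summarizes per-run community-level regression slopes and t values
#' against the observed ones: sign counts, t envelope, and the empirical
#' two-tailed p (rank of |observed t| among the null).
#'
#' @param observed_slope,observed_t observed community regression slope
#'   and t value.
#' @param null_slopes,null_ts per-run values under randomization.
#' @return list: \code{n_positive}, \code{n_negative}, \code{t_range},
#'   \code{n_more_extreme}, \code{p_empirical}.
#' @export
null_slope_distribution <- function(observed_slope, observed_t,
                                    null_slopes, null_ts) {
  ok <- is.finite(null_slopes) & is.finite(null_ts)
  null_slopes <- null_slopes[ok]; null_ts <- null_ts[ok]
  nmore <- sum(abs(null_ts) >= abs(observed_t))
  list(n_positive = sum(null_slopes > 0),
       n_negative = sum(null_slopes < 0),
       t_range = range(null_ts),
       n_more_extreme = nmore,
       p_empirical = (1 + nmore) / (length(null_ts) + 1))
}
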