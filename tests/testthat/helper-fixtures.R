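# Shared fixture builders. All fixtures are generated in code; no data
# files are read.

# minimal two-census wide table
toy_census <- function() {
  data.frame(
    tree_id = c("a", "b", "c", "d"),
    species = c("SP1", "SP1", "SP2", "SP2"),
    x = c(25, 30, 50, 60), y = c(100, 110, 200, 210),
    gbh_1 = c(15, 40, 25, 90), status_1 = "alive",
    gbh_2 = c(18, 45, 25, NA),
    status_2 = c("alive", "alive", "dead", "dead"),
    stringsAsFactors = FALSE)
}

# a small CSR census with simulated dynamics; cached per option set
small_forest <- local({
  cache <- list()
  function(seed = 11, width = 100, length = 100, n_species = 5,
           density_ha = 500, beta_con = -0.2, gamma_het = -0.1,
           fill_mode = "larsm", gbh_max = 150) {
    key <- paste(seed, width, length, n_species, density_ha, beta_con,
                 gamma_het, fill_mode, gbh_max)
    if (!is.null(cache[[key]])) return(cache[[key]])
    spec <- synthetic_spec(
      width = width, length = length, n_plots = 1, n_species = n_species,
      density_ha = density_ha, abundance = "fixed", clustering = "csr",
      gbh_max = gbh_max,
      growth = list(intercept = 0.2, alpha = 0.5, beta_con = beta_con,
                    gamma_het = gamma_het, sigma = 0.4),
      survival = list(intercept = 3, alpha = 0.3, beta_con = beta_con,
                      gamma_het = gamma_het),
      fill_mode = fill_mode)
    plt <- plot_spec(width, length, 20, spec$census_dates)
    trees <- generate_stand(spec, seed)
    trees <- generate_dynamics(trees, spec, period_spec(1, 2, plt), seed)
    out <- list(spec = spec, plot = plt, trees = trees,
                period = period_spec(1, 2, plt))
    cache[[key]] <<- out
    out
  }
})

# brute-force O(n^2) shading oracle over a cloud list (non-hierarchical)
oracle_flags <- function(clouds, dd_con, dd_het) {
  tab <- cloud_table(clouds)
  out <- list()
  for (cl in clouds) {
    flags <- rep(FALSE, length(cl$x))
    for (i in seq_along(cl$x)) {
      for (j in seq_len(nrow(tab))) {
        if (tab$tree_id[j] == cl$tree_id) next
        if (tab$gbh[j] <= cl$gbh) next
        dd <- if (tab$species[j] == cl$species) dd_con else dd_het
        if (dd <= 0) next
        d <- sqrt((tab$x[j] - cl$x[i])^2 + (tab$y[j] - cl$y[i])^2)
        if (d <= dd) { flags[i] <- TRUE; break }
      }
    }
    out[[cl$tree_id]] <- flags
  }
  out
}

# brute-force neighborhood sum over a canopy's points
oracle_sum <- function(focal_id, canopy, trees, period, r, decay, class,
                       pos = NULL) {
  i <- match(focal_id, trees$tree_id)
  if (is.null(pos)) pos <- c(trees$x[i], trees$y[i])
  fg <- trees[[paste0("gbh_", period$start)]][i]
  surv <- trees$tree_id[trees[[paste0("status_", period$end)]] %in% "alive"]
  total <- 0
  for (cl in canopy$clouds) {
    if (cl$tree_id == focal_id || cl$gbh < fg) next
    if (!cl$tree_id %in% surv) next
    if (class == "CON" && !identical(cl$species, trees$species[i])) next
    if (class == "HET" && identical(cl$species, trees$species[i])) next
    for (k in seq_along(cl$x)) {
      d <- sqrt((cl$x[k] - pos[1])^2 + (cl$y[k] - pos[2])^2)
      if (d <= r) {
        dk <- max(d, 0.1)
        w <- switch(decay, none = 1, linear = 1 / dk, squared = 1 / dk^2)
        total <- total + cl$weight * w
      }
    }
  }
  total
}
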