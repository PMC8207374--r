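# Pipeline orchestration: simulate -> predictors -> fit -> average ->
# community -> randomize, with per-stage CSV artifacts, config-hash
# caching and a run manifest. The pipeline operates on one plot per run;
# multi-plot studies run it once per plot and pool the per-species tables.

pipeline_stages <- c("simulate", "predictors", "fit", "average",
                     "community", "randomize")

default_config <- function() {
  list(
    seed = 1,
    output = "crownzoi_artifacts",
    synthetic = list(width = 100, length = 100, n_plots = 1,
                     n_species = 6, density_ha = 600,
                     abundance = "fixed", clustering = "csr"),
    period = list(start = 1, end = 2),
    selection = list(size_class = c(10, 100), min_n = 30, min_dead = 3),
    grid = list(radii = c(4, 8, 12, 16, 20), dd = 0),
    mode = list(type = "spatial", fill = "larsm", adjust = "removal",
                position = "stem", decay = "linear"),
    randomization = list(n_runs = 0)
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]]))
      merge_config(base[[k]], override[[k]])
    else override[[k]]
  }
  base
}

validate_config <- function(config) {
  errs <- character()
  if (is.null(config$census) && is.null(config$synthetic))
    errs <- c(errs, "either 'census' (file) or 'synthetic' must be given")
  if (!is.null(config$grid$radii) && any(config$grid$radii < 1))
    errs <- c(errs, "grid radii must be >= 1 m")
  if (!is.null(config$grid$dd) && any(config$grid$dd < 0))
    errs <- c(errs, "dd values must be >= 0")
  if (!config$mode$type %in% c("spatial", "nonspatial"))
    errs <- c(errs, "mode$type must be spatial or nonspatial")
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  invisible(TRUE)
}

stage_path <- function(out_dir, stage)
  file.path(out_dir, paste0(stage, ".csv"))

stage_cached <- function(out_dir, stage, config) {
  path <- stage_path(out_dir, stage)
  meta <- paste0(path, ".meta.json")
  if (!file.exists(path) || !file.exists(meta)) return(FALSE)
  m <- try(jsonlite::read_json(meta), silent = TRUE)
  !inherits(m, "try-error") &&
    identical(m$config_hash, unname(config_hash(config)))
}

#' Run the analysis pipeline
#'
#' Runs the requested stages in dependency order, caching each stage's
#' CSV artifact keyed by the configuration hash (a rerun with an
#' unchanged config skips completed stages). See the package vignette
#' for the configuration format.
#'
#' @param config configuration list or path to a YAML file.
#' @param stages subset of \code{c("simulate", "predictors", "fit",
#'   "average", "community", "randomize")}; \code{"all"} (default) runs
#'   everything up to \code{community}, plus \code{randomize} when
#'   \code{randomization$n_runs > 0}.
#' @param seed overrides the config seed.
#' @param force recompute even when cached.
#' @param quiet suppress progress messages.
#' @return invisibly, the output directory (which contains
#'   \code{manifest.json} and the per-stage CSVs).
#' @export
run_pipeline <- function(config, stages = "all", seed = NULL,
                         force = FALSE, quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  config <- merge_config(default_config(), config)
  if (!is.null(seed)) config$seed <- seed
  validate_config(config)
  if (identical(stages, "all")) {
    stages <- c("simulate", "predictors", "fit", "average", "community")
    if (isTRUE(config$randomization$n_runs > 0))
      stages <- c(stages, "randomize")
  }
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  stages <- pipeline_stages[pipeline_stages %in% stages]
  out_dir <- config$output
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  manifest <- list(config_hash = unname(config_hash(config)),
                   seed = config$seed,
                   version = as.character(utils::packageVersion("crownzoi")),
                   stages = list())
  for (st in stages) {
    if (!force && stage_cached(out_dir, st, config)) {
      say("stage ", st, ": cached, skipping")
      manifest$stages[[st]] <- "cached"
      next
    }
    say("stage ", st, ": running")
    t0 <- Sys.time()
    switch(st,
           simulate = stage_simulate(config, out_dir),
           predictors = stage_predictors(config, out_dir),
           fit = stage_fit(config, out_dir),
           average = stage_average(config, out_dir),
           community = stage_community(config, out_dir),
           randomize = stage_randomize(config, out_dir))
    manifest$stages[[st]] <-
      sprintf("%.1fs", as.numeric(Sys.time() - t0, units = "secs"))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}

config_plot <- function(config) {
  syn <- config$synthetic
  if (!is.null(config$plot))
    do.call(plot_spec, config$plot)
  else if (!is.null(syn))
    plot_spec(syn$width %||% 100, syn$length %||% 400,
              syn$border %||% 20,
              syn$census_dates %||% c(1986, 1996, 2007.07))
  else plot_spec()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_census <- function(config, out_dir) {
  path <- if (!is.null(config$census)) config$census
  else stage_path(out_dir, "simulate")
  if (!file.exists(path))
    stop("census not found (", path, "); run the simulate stage first ",
         "or point 'census' at a file", call. = FALSE)
  read_census(path, plot = config_plot(config))$trees
}

stage_simulate <- function(config, out_dir) {
  if (!is.null(config$census)) {
    # external census: copy through so downstream stages have one path
    trees <- read_census(config$census, plot = config_plot(config))$trees
  } else {
    syn <- config$synthetic
    syn$n_plots <- 1
    spec <- do.call(synthetic_spec, syn)
    trees <- generate_forest(spec, seed = config$seed)[[1]]$trees
  }
  write_census(trees, stage_path(out_dir, "simulate"))
  jsonlite::write_json(
    list(config_hash = unname(config_hash(config)), seed = config$seed),
    paste0(stage_path(out_dir, "simulate"), ".meta.json"),
    auto_unbox = TRUE)
  invisible(NULL)
}

pipeline_species <- function(trees, config, plt, per) {
  sel <- config$selection
  select_focal_species(trees, per, plt, size_class = unlist(sel$size_class),
                       min_n = sel$min_n, min_dead = sel$min_dead)
}

compute_predictors <- function(trees, config, plt, per) {
  species <- pipeline_species(trees, config, plt, per)
  if (!length(species)) stop("no species passes the selection thresholds")
  radii <- unlist(config$grid$radii)
  dd <- unlist(config$grid$dd)
  spatial <- config$mode$type == "spatial"
  dd_pairs <- if (spatial) expand.grid(dd_con = dd, dd_het = dd)
  else data.frame(dd_con = NA_real_, dd_het = NA_real_)
  out <- list()
  for (q in seq_len(nrow(dd_pairs))) {
    canopy <- NULL
    if (spatial) {
      clouds <- fill_plot(trees, per$start, fill_mode = config$mode$fill,
                          seed = config$seed)
      canopy <- adjust_plot(clouds, dd_pairs$dd_con[q], dd_pairs$dd_het[q],
                            config$mode$adjust, seed = config$seed)
    }
    for (sp in species) {
      focal <- focal_subset(trees, sp, per, plt,
                            unlist(config$selection$size_class))
      tab <- predictor_table(focal, trees, per, canopy, radii,
                             decay = config$mode$decay,
                             position_mode = config$mode$position)
      tab$species <- sp
      tab$dd_con <- dd_pairs$dd_con[q]
      tab$dd_het <- dd_pairs$dd_het[q]
      out[[length(out) + 1L]] <- tab
    }
  }
  do.call(rbind, out)
}

stage_predictors <- function(config, out_dir) {
  trees <- load_census(config, out_dir)
  plt <- config_plot(config)
  per <- period_spec(config$period$start, config$period$end, plt)
  pred <- compute_predictors(trees, config, plt, per)
  write_result_table(pred, stage_path(out_dir, "predictors"), config,
                     config$seed)
  invisible(NULL)
}

fit_one_species <- function(trees, pred_sp, per, config) {
  focal_ids <- unique(pred_sp$focal_id)
  rows <- list()
  gr <- growth_rate(trees, per)
  gr <- exclude_outliers(gr[gr$focal_id %in% focal_ids, , drop = FALSE])
  if (nrow(gr) >= 5) {
    f <- scan_grid(gr, pred_sp[pred_sp$focal_id %in% gr$focal_id, ],
                   response = "growth")
    rows[[length(rows) + 1L]] <- f
  }
  idx <- match(focal_ids, trees$tree_id)
  sv <- data.frame(focal_id = focal_ids,
                   surv = as.integer(
                     trees[[status_col(per$end)]][idx] %in% "alive"),
                   ln_ba = log(basal_area(trees[[gbh_col(per$start)]][idx])),
                   stringsAsFactors = FALSE)
  if (length(unique(sv$surv)) == 2) {
    f <- scan_grid(sv, pred_sp, response = "survival")
    rows[[length(rows) + 1L]] <- f
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

stage_fit <- function(config, out_dir) {
  trees <- load_census(config, out_dir)
  plt <- config_plot(config)
  per <- period_spec(config$period$start, config$period$end, plt)
  pp <- stage_path(out_dir, "predictors")
  if (!file.exists(pp))
    stop("predictors not found; run the predictors stage first",
         call. = FALSE)
  pred <- utils::read.csv(pp, stringsAsFactors = FALSE)
  fits <- lapply(split(pred, pred$species), function(ps) {
    f <- fit_one_species(trees, ps, per, config)
    if (!is.null(f)) f$species <- ps$species[1]
    f
  })
  fits <- do.call(rbind, fits[!vapply(fits, is.null, logical(1))])
  write_result_table(fits, stage_path(out_dir, "fit"), config, config$seed)
  invisible(NULL)
}

stage_average <- function(config, out_dir) {
  fp <- stage_path(out_dir, "fit")
  if (!file.exists(fp))
    stop("fits not found; run the fit stage first", call. = FALSE)
  fits <- utils::read.csv(fp, stringsAsFactors = FALSE)
  out <- list()
  for (sp in unique(fits$species)) for (resp in unique(fits$response)) {
    sub <- fits[fits$species == sp & fits$response == resp, , drop = FALSE]
    if (!nrow(sub)) next
    s <- average_band(sub)
    if (is.null(s)) next
    s$species <- sp
    s$response <- resp
    out[[length(out) + 1L]] <- s
  }
  write_result_table(do.call(rbind, out), stage_path(out_dir, "average"),
                     config, config$seed)
  invisible(NULL)
}

community_from_artifacts <- function(trees, summaries, per) {
  ba <- species_plot_ba(trees, census = per$start)
  g <- summaries[summaries$response == "growth", , drop = FALSE]
  s <- summaries[summaries$response == "survival", , drop = FALSE]
  species <- sort(unique(summaries$species))
  data.frame(
    species = species,
    plot_ba = unname(ba[species]),
    growth_con = g$mean_signed_effect_con[match(species, g$species)],
    growth_het = g$mean_signed_effect_het[match(species, g$species)],
    surv_con = s$mean_con[match(species, s$species)],
    surv_het = s$mean_het[match(species, s$species)],
    stringsAsFactors = FALSE)
}

stage_community <- function(config, out_dir) {
  trees <- load_census(config, out_dir)
  plt <- config_plot(config)
  per <- period_spec(config$period$start, config$period$end, plt)
  ap <- stage_path(out_dir, "average")
  if (!file.exists(ap))
    stop("averages not found; run the average stage first", call. = FALSE)
  summaries <- utils::read.csv(ap, stringsAsFactors = FALSE)
  comm <- community_from_artifacts(trees, summaries, per)
  if (sum(stats::complete.cases(comm[, c("growth_con", "plot_ba")])) >= 3) {
    reg <- effect_vs_abundance(comm$growth_con, comm$plot_ba)
    comm$abundance_slope <- reg$slope
    comm$abundance_p <- reg$p
  }
  write_result_table(comm, stage_path(out_dir, "community"), config,
                     config$seed)
  invisible(NULL)
}

stage_randomize <- function(config, out_dir) {
  trees <- load_census(config, out_dir)
  plt <- config_plot(config)
  per <- period_spec(config$period$start, config$period$end, plt)
  ap <- stage_path(out_dir, "average")
  if (!file.exists(ap))
    stop("averages not found; run the average stage first", call. = FALSE)
  observed <- utils::read.csv(ap, stringsAsFactors = FALSE)
  obs_g <- observed[observed$response == "growth", , drop = FALSE]
  rc <- randomization_config(n_runs = config$randomization$n_runs)
  runs <- list()
  for (k in seq_len(rc$n_runs)) {
    rt <- randomize_positions(trees, plt, rc, run_index = k,
                              seed = config$seed)
    pred <- compute_predictors(rt, config, plt, per)
    smry <- list()
    for (sp in unique(pred$species)) {
      f <- fit_one_species(rt, pred[pred$species == sp, ], per, config)
      if (is.null(f)) next
      fg <- f[f$response == "growth", , drop = FALSE]
      s <- if (nrow(fg)) average_band(fg) else NULL
      if (!is.null(s)) smry[[sp]] <- s$mean_con
    }
    runs[[k]] <- unlist(smry)
  }
  species <- sort(Reduce(union, lapply(runs, names)))
  mat <- do.call(rbind, lapply(runs, function(r) r[species]))
  colnames(mat) <- species
  obs <- obs_g$mean_con[match(species, obs_g$species)]
  names(obs) <- species
  env <- null_envelopes(obs, mat, response = "growth")
  write_result_table(env, stage_path(out_dir, "randomize"), config,
                     config$seed)
  invisible(NULL)
}
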