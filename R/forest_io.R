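#' Plot geometry and census schedule
#'
#' @param width,length plot extent in m (defaults 100 x 400).
#' @param border inner border width in m used to restrict focal trees
#'   (default 20). Must be smaller than half the smallest plot side.
#' @param census_dates ordered numeric vector of census dates (decimal
#'   years); consecutive differences define the period lengths.
#' @return object of class \code{plot_spec}.
#' @export
#' @examples
#' plot_spec()  # the default two-period 100 x 400 m layout
plot_spec <- function(width = 100, length = 400, border = 20,
                      census_dates = c(1986, 1996, 2007.07)) {
  stopifnot(width > 0, length > 0, border >= 0)
  if (border >= min(width, length) / 2)
    stop("border must be < min(width, length) / 2")
  if (is.unsorted(census_dates, strictly = TRUE))
    stop("census_dates must be strictly increasing")
  structure(list(width = width, length = length, border = border,
                 census_dates = census_dates),
            class = "plot_spec")
}

#' A census period (two consecutive censuses)
#'
#' @param start_census,end_census 1-based census indices.
#' @param plot a \code{plot_spec}; duration is the census-date difference.
#' @param duration_years override for the duration (years); defaults to the
#'   difference of the plot's census dates.
#' @return object of class \code{period_spec} with fields \code{start},
#'   \code{end}, \code{duration}.
#' @export
period_spec <- function(start_census, end_census, plot = plot_spec(),
                        duration_years = NULL) {
  stopifnot(start_census >= 1, end_census > start_census,
            end_census <= length(plot$census_dates))
  dur <- if (is.null(duration_years))
    plot$census_dates[end_census] - plot$census_dates[start_census]
  else duration_years
  if (dur <= 0) stop("period duration must be positive")
  structure(list(start = start_census, end = end_census, duration = dur),
            class = "period_spec")
}

#' @rdname period_spec
#' @param trees a census table (used only for error checking elsewhere).
#' @export
census_indices <- function(trees) {
  idx <- sub("^gbh_", "", grep("^gbh_", names(trees), value = TRUE))
  as.integer(idx)
}

gbh_col <- function(census) paste0("gbh_", census)
status_col <- function(census) paste0("status_", census)

.status_levels <- c("alive", "dead", "absent")

#' Read a stem-mapped census table
#'
#' Wide dialect: one row per tree with columns \code{tree_id},
#' \code{species}, \code{x_m}, \code{y_m}, then \code{gbh_<k>} and
#' \code{status_<k>} per census \code{k} (and optional \code{oui}).
#' Records with unparseable or out-of-bounds coordinates are rejected and
#' itemized in the returned report rather than aborting the read.
#'
#' @param path delimited text file with a header row.
#' @param plot a \code{plot_spec} giving the coordinate bounds.
#' @param schema optional named character vector mapping canonical names
#'   (\code{tree_id}, \code{species}, \code{x_m}, \code{y_m}) to the file's
#'   column names.
#' @param sep field separator (default \code{","}).
#' @param gbh_floor minimum credible alive gbh in cm (default 10); violations
#'   are reported but records are kept.
#' @return list with \code{trees} (validated census data frame),
#'   \code{plot}, and \code{report} (data frame of rejected/flagged records
#'   with \code{tree_id} and \code{reason}).
#' @export
read_census <- function(path, plot = plot_spec(), schema = NULL, sep = ",",
                        gbh_floor = 10) {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (!is.null(schema))
    for (canon in names(schema))
      names(raw)[names(raw) == schema[[canon]]] <- canon
  required <- c("tree_id", "species", "x_m", "y_m")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("census file is missing required column(s): ",
         paste(missing, collapse = ", "))
  censuses <- sort(as.integer(sub("^gbh_", "",
                                  grep("^gbh_[0-9]+$", names(raw),
                                       value = TRUE))))
  if (!length(censuses))
    stop("census file has no gbh_<census> columns")
  for (k in censuses)
    if (!status_col(k) %in% names(raw))
      stop("census file is missing required column(s): ", status_col(k))

  trees <- data.frame(tree_id = raw$tree_id, species = raw$species,
                      x = suppressWarnings(as.numeric(raw$x_m)),
                      y = suppressWarnings(as.numeric(raw$y_m)),
                      stringsAsFactors = FALSE)
  for (k in censuses) {
    trees[[gbh_col(k)]] <- suppressWarnings(as.numeric(raw[[gbh_col(k)]]))
    st <- raw[[status_col(k)]]
    st[!st %in% .status_levels] <- NA
    trees[[status_col(k)]] <- st
  }
  if ("oui" %in% names(raw))
    trees$oui <- suppressWarnings(as.numeric(raw$oui))

  report <- validate_census(trees, plot, censuses, gbh_floor)
  drop <- unique(report$tree_id[report$fatal])
  list(trees = trees[!trees$tree_id %in% drop, , drop = FALSE],
       plot = plot,
       report = report[, c("tree_id", "reason")])
}

validate_census <- function(trees, plot, censuses, gbh_floor) {
  rep <- list()
  note <- function(ids, reason, fatal)
    if (length(ids)) rep[[length(rep) + 1L]] <<- data.frame(
      tree_id = ids, reason = reason, fatal = fatal,
      stringsAsFactors = FALSE)
  if (anyDuplicated(trees$tree_id))
    note(unique(trees$tree_id[duplicated(trees$tree_id)]),
         "duplicate tree_id", TRUE)
  bad_xy <- is.na(trees$x) | is.na(trees$y)
  note(trees$tree_id[bad_xy], "unparseable coordinates", TRUE)
  oob <- !bad_xy & (trees$x < 0 | trees$x > plot$width |
                    trees$y < 0 | trees$y > plot$length)
  note(trees$tree_id[oob], "coordinate outside plot extent", TRUE)
  for (k in censuses) {
    small <- !is.na(trees[[gbh_col(k)]]) &
      trees[[status_col(k)]] %in% "alive" & trees[[gbh_col(k)]] < gbh_floor
    note(trees$tree_id[small],
         sprintf("alive gbh below floor (%g cm) at census %d", gbh_floor, k),
         FALSE)
  }
  if (length(censuses) > 1)
    for (i in seq_len(length(censuses) - 1)) {
      a <- trees[[status_col(censuses[i])]]
      b <- trees[[status_col(censuses[i + 1])]]
      res <- !is.na(a) & !is.na(b) & a == "dead" & b == "alive"
      note(trees$tree_id[res], "status transition dead -> alive", TRUE)
    }
  if (length(rep)) do.call(rbind, rep)
  else data.frame(tree_id = character(), reason = character(),
                  fatal = logical(), stringsAsFactors = FALSE)
}

#' Write a census table in the canonical wide dialect
#'
#' Round-trips with \code{\link{read_census}} for all required fields.
#'
#' @param trees census data frame (internal canonical columns).
#' @param path output file.
#' @param sep field separator.
#' @export
write_census <- function(trees, path, sep = ",") {
  out <- trees
  names(out)[names(out) == "x"] <- "x_m"
  names(out)[names(out) == "y"] <- "y_m"
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Read a long-format census (one row per tree x census)
#'
#' Columns: \code{tree_id}, \code{species}, \code{x_m}, \code{y_m},
#' \code{census}, \code{gbh}, \code{status}. Reshaped to the wide dialect
#' then validated identically to \code{\link{read_census}}.
#'
#' @inheritParams read_census
#' @export
read_census_long <- function(path, plot = plot_spec(), sep = ",",
                             gbh_floor = 10) {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  required <- c("tree_id", "species", "x_m", "y_m", "census", "gbh", "status")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("census file is missing required column(s): ",
         paste(missing, collapse = ", "))
  wide <- stats::reshape(raw, direction = "wide",
                         idvar = c("tree_id", "species", "x_m", "y_m"),
                         timevar = "census", v.names = c("gbh", "status"),
                         sep = "_")
  names(wide) <- sub("^gbh_", "gbh_", names(wide))
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  utils::write.table(wide, tmp, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  read_census(tmp, plot = plot, gbh_floor = gbh_floor)
}

in_border <- function(trees, plot) {
  b <- plot$border
  trees$x >= b & trees$x <= plot$width - b &
    trees$y >= b & trees$y <= plot$length - b
}

in_size_class <- function(gbh, size_class) {
  !is.na(gbh) & gbh >= size_class[1] & gbh < size_class[2]
}

#' Species passing focal sample-size thresholds
#'
#' A species qualifies when, among its alive trees in the size class that
#' lie inside the plot border at the period start, at least \code{min_n}
#' are present and at least \code{min_dead} of them die over the period.
#'
#' @param trees census data frame.
#' @param period a \code{period_spec}.
#' @param plot a \code{plot_spec}.
#' @param size_class half-open gbh interval in cm, default \code{c(10, 100)}.
#' @param min_n minimum number of focal-class trees (default 50).
#' @param min_dead minimum number dying over the period (default 5).
#' @return character vector of qualifying species codes (possibly empty).
#' @export
select_focal_species <- function(trees, period, plot = plot_spec(),
                                 size_class = c(10, 100),
                                 min_n = 50, min_dead = 5) {
  if (!nrow(trees)) return(character())
  g1 <- trees[[gbh_col(period$start)]]
  s1 <- trees[[status_col(period$start)]]
  s2 <- trees[[status_col(period$end)]]
  eligible <- s1 %in% "alive" & in_size_class(g1, size_class) &
    in_border(trees, plot)
  n <- tapply(eligible, trees$species, sum)
  dead <- tapply(eligible & s2 %in% "dead", trees$species, sum)
  sp <- names(n)[n >= min_n & dead >= min_dead]
  sort(sp[!is.na(sp)])
}

#' Focal trees of one species for one period
#'
#' Focal trees are alive at the period start, in the size class, and at
#' least \code{border} m from every plot edge (closed test: a tree exactly
#' on the border line is kept). Neighbors are never border-restricted.
#'
#' @inheritParams select_focal_species
#' @param species species code.
#' @return the focal subset of \code{trees} (same columns).
#' @export
focal_subset <- function(trees, species, period, plot = plot_spec(),
                         size_class = c(10, 100)) {
  g1 <- trees[[gbh_col(period$start)]]
  s1 <- trees[[status_col(period$start)]]
  keep <- trees$species == species & s1 %in% "alive" &
    in_size_class(g1, size_class) & in_border(trees, plot)
  trees[keep, , drop = FALSE]
}

#' Read a pipeline configuration file (YAML)
#' @param path YAML file.
#' @return nested list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a result table with a JSON metadata sidecar
#'
#' The sidecar (\code{<path>.meta.json}) records the configuration hash,
#' the master seed and a timestamp so every result file is traceable.
#'
#' @param df data frame to write.
#' @param path CSV output path.
#' @param config configuration list (hashed into the sidecar).
#' @param seed master seed used for the computation.
#' @export
write_result_table <- function(df, path, config = list(), seed = NA) {
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(config_hash = config_hash(config), seed = seed,
               written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               rows = nrow(df))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}
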