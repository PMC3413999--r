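# Track tables, wound geometry, distance series and population summaries.

TRACK_COLUMNS <- c("cell_id", "time_min", "x_um", "y_um", "channel")

# Internal channel labels and their CSV dialect counterparts.  The track CSV
# stores the fluorescence colour (red = photoconverted cohort labelled at the
# wound, green = cells recruited later).
CHANNEL_LEVELS <- c("photoconverted", "nonphotoconverted")
CHANNEL_FROM_DIALECT <- c(red = "photoconverted", green = "nonphotoconverted")
CHANNEL_TO_DIALECT <- c(photoconverted = "red", nonphotoconverted = "green")

#' Construct an observation set of cell centroids
#'
#' An `observation_set` is a long-format table of cell centroid positions
#' over time: one row per `(cell_id, time_min)` with planar coordinates in
#' micrometres and the fluorescence channel of the cell.  Rows are kept in
#' canonical `(cell_id, time_min)` order so that save/load round-trips are
#' stable.
#'
#' @param df data.frame with columns `cell_id`, `time_min`, `x_um`, `y_um`,
#'   `channel` (values `"photoconverted"` or `"nonphotoconverted"`).
#' @return A validated `observation_set` (a data.frame subclass).
#' @examples
#' obs <- observation_set(data.frame(
#'   cell_id = "c1", time_min = c(0, 10), x_um = c(5, 8), y_um = 0,
#'   channel = "photoconverted"
#' ))
#' nrow(obs)
#' @export
observation_set <- function(df) {
  ww_assert(is.data.frame(df), "observation_set() expects a data.frame",
            "woundwalk_format_error")
  missing_cols <- setdiff(TRACK_COLUMNS, names(df))
  if (length(missing_cols)) {
    ww_abort(sprintf("missing column '%s'", missing_cols[[1L]]),
             "woundwalk_format_error")
  }
  df <- as.data.frame(df)[TRACK_COLUMNS]
  df$cell_id <- as.character(df$cell_id)
  df$channel <- as.character(df$channel)
  for (col in c("time_min", "x_um", "y_um")) {
    ww_assert(is.numeric(df[[col]]),
              sprintf("column '%s' must be numeric", col),
              "woundwalk_format_error")
    ww_assert(all(is.finite(df[[col]])),
              sprintf("column '%s' contains non-finite values", col),
              "woundwalk_format_error")
  }
  bad_channel <- setdiff(unique(df$channel), CHANNEL_LEVELS)
  if (length(bad_channel)) {
    ww_abort(sprintf("unknown channel value '%s'", bad_channel[[1L]]),
             "woundwalk_format_error")
  }
  key <- paste(df$cell_id, df$time_min, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][[1L]]
    ww_abort(sprintf("duplicate (cell_id, time) pair: %s",
                     sub("\r", " @ t=", dup, fixed = TRUE)),
             "woundwalk_format_error")
  }
  df <- df[order(df$cell_id, df$time_min), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("observation_set", "data.frame")
  df
}

#' @export
print.observation_set <- function(x, ...) {
  cat(sprintf("<observation_set: %d records, %d cells, %d timepoints>\n",
              nrow(x), length(unique(x$cell_id)),
              length(unique(x$time_min))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 4L))
  invisible(x)
}

#' Read a track table from CSV
#'
#' The canonical track dialect is a UTF-8 CSV with header
#' `cell_id,time_min,x_um,y_um,channel`, `.` as the decimal separator and
#' `channel` one of `red` (photoconverted) or `green` (nonphotoconverted),
#' as exported by upstream image-analysis software.
#'
#' @param path path to an existing CSV file.
#' @return An [observation_set()].
#' @seealso [save_tracks()] for the inverse operation.
#' @export
load_tracks <- function(path) {
  ww_assert(file.exists(path), sprintf("track file not found: %s", path),
            "woundwalk_io_error")
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(TRACK_COLUMNS, names(raw))
  if (length(missing_cols)) {
    ww_abort(sprintf("missing column '%s' in %s", missing_cols[[1L]], path),
             "woundwalk_format_error")
  }
  raw <- raw[TRACK_COLUMNS]
  for (col in c("time_min", "x_um", "y_um")) {
    num <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(num) | !is.finite(num))
    if (length(bad)) {
      # +1 for the header row: data row i lives on file line i + 1
      ww_abort(sprintf("non-numeric value '%s' in column '%s' at line %d of %s",
                       raw[[col]][bad[[1L]]], col, bad[[1L]] + 1L, path),
               "woundwalk_format_error")
    }
    raw[[col]] <- num
  }
  bad_channel <- which(!raw$channel %in% names(CHANNEL_FROM_DIALECT))
  if (length(bad_channel)) {
    ww_abort(sprintf("unknown channel '%s' at line %d of %s (expected red/green)",
                     raw$channel[bad_channel[[1L]]], bad_channel[[1L]] + 1L,
                     path),
             "woundwalk_format_error")
  }
  raw$channel <- unname(CHANNEL_FROM_DIALECT[raw$channel])
  observation_set(raw)
}

#' Write a track table to CSV
#'
#' Writes the canonical dialect (see [load_tracks()]); loading the file back
#' reproduces the observation set (coordinates survive at 15 significant
#' digits).
#'
#' @param obs an [observation_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_tracks <- function(obs, path) {
  obs <- observation_set(obs)
  out <- as.data.frame(obs)
  out$channel <- unname(CHANNEL_TO_DIALECT[out$channel])
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    ww_abort(sprintf("cannot write track file %s: %s",
                     path, conditionMessage(ok)),
             "woundwalk_io_error")
  }
  invisible(path)
}

#' Describe the wound edge as a line in the imaging plane
#'
#' Tail transection produces a straight cut; the wound edge is modelled as
#' the infinite line through `p1` and `p2`.  `interior_sign` selects the
#' side of the line on which the tissue (and hence the cells) lies:
#' `+1` means the interior lies in the direction of the normal
#' `(dy, -dx) / |p2 - p1|` (i.e. to the right when walking from `p1` to
#' `p2`), `-1` the opposite side.
#'
#' @param p1,p2 numeric length-2 vectors, points on the wound line (um).
#' @param interior_sign `+1` or `-1`.
#' @return A `wound_geometry` object.
#' @examples
#' # wound along the y axis, tissue in the +x half plane:
#' wound_geometry(c(0, 0), c(0, 1), +1)
#' @export
wound_geometry <- function(p1, p2, interior_sign = 1) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  ww_assert(length(p1) == 2 && length(p2) == 2 &&
              all(is.finite(c(p1, p2))),
            "p1 and p2 must be finite length-2 coordinates")
  ww_assert(interior_sign %in% c(-1, 1), "interior_sign must be +1 or -1")
  if (all(p1 == p2)) {
    ww_abort("degenerate wound line: p1 equals p2")
  }
  structure(list(p1 = p1, p2 = p2, interior_sign = as.numeric(interior_sign)),
            class = "wound_geometry")
}

#' @export
print.wound_geometry <- function(x, ...) {
  cat(sprintf("<wound line through (%g, %g) and (%g, %g), interior sign %+d>\n",
              x$p1[1], x$p1[2], x$p2[1], x$p2[2], as.integer(x$interior_sign)))
  invisible(x)
}

#' Distance of every observation from the wound edge
#'
#' Computes the perpendicular distance of each cell centroid from the wound
#' line, signed so that the tissue interior is positive, then clamped at
#' zero: a cell on the wound line, or recorded beyond it, reports distance
#' 0.  This is the 1-D coordinate `x(t)` on which all the models operate.
#'
#' @param obs an [observation_set()].
#' @param wound a [wound_geometry()].
#' @return A `distance_series` data.frame with columns `cell_id`,
#'   `time_min`, `distance_um`, `channel`.
#' @export
compute_distances <- function(obs, wound) {
  obs <- observation_set(obs)
  ww_assert(inherits(wound, "wound_geometry"),
            "wound must be a wound_geometry object")
  d <- wound$p2 - wound$p1
  len <- sqrt(sum(d^2))
  normal <- wound$interior_sign * c(d[2], -d[1]) / len
  dist <- (obs$x_um - wound$p1[1]) * normal[1] +
    (obs$y_um - wound$p1[2]) * normal[2]
  out <- data.frame(cell_id = obs$cell_id, time_min = obs$time_min,
                    distance_um = pmax(0, dist), channel = obs$channel,
                    stringsAsFactors = FALSE)
  class(out) <- c("distance_series", "data.frame")
  out
}

as_distance_series <- function(df) {
  ww_assert(is.data.frame(df) &&
              all(c("cell_id", "time_min", "distance_um") %in% names(df)),
            "expected a distance_series (cell_id, time_min, distance_um)",
            "woundwalk_format_error")
  ww_assert(all(is.finite(df$distance_um)) && all(df$distance_um >= 0),
            "distances must be finite and >= 0", "woundwalk_format_error")
  if (is.null(df$channel)) df$channel <- rep("photoconverted", nrow(df))
  class(df) <- unique(c("distance_series", class(df)))
  df
}

#' Per-timepoint population moments of the distance-from-wound coordinate
#'
#' For each observation time with at least `min_cells` recorded cells,
#' computes the cell count `n_cells`, the mean distance `m(t)` and the mean
#' squared distance `s(t)` as unweighted per-cell averages.  Times with
#' fewer than `min_cells` cells are dropped, which reproduces the missing
#' late sections seen in sparse subjects.
#'
#' @param ds a `distance_series` from [compute_distances()].
#' @param min_cells minimum number of cells for a timepoint to be retained
#'   (default 1).
#' @return A `population_summary` data.frame with columns `time_min`,
#'   `n_cells`, `mean_dist`, `mean_sq_dist`, sorted by time.  Empty input
#'   yields an empty summary, not an error.
#' @export
population_summary <- function(ds, min_cells = 1L) {
  ds <- as_distance_series(ds)
  ww_assert(length(min_cells) == 1L && min_cells >= 1,
            "min_cells must be >= 1")
  if (!nrow(ds)) {
    out <- data.frame(time_min = numeric(), n_cells = integer(),
                      mean_dist = numeric(), mean_sq_dist = numeric())
    class(out) <- c("population_summary", "data.frame")
    return(out)
  }
  grp <- factor(ds$time_min, levels = sort(unique(ds$time_min)))
  agg <- rowsum(cbind(one = 1, d = ds$distance_um, d2 = ds$distance_um^2),
                group = grp)
  n <- agg[, "one"]
  out <- data.frame(time_min = as.numeric(rownames(agg)),
                    n_cells = as.integer(n),
                    mean_dist = agg[, "d"] / n,
                    mean_sq_dist = agg[, "d2"] / n)
  out <- out[out$n_cells >= min_cells, , drop = FALSE]
  rownames(out) <- NULL
  # Jensen: population second moment can never fall below the squared mean
  ww_assert(all(out$mean_sq_dist - out$mean_dist^2 >=
                  -1e-8 * pmax(1, out$mean_sq_dist)),
            "internal error: mean_sq_dist < mean_dist^2")
  class(out) <- c("population_summary", "data.frame")
  out
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("<population_summary: %d timepoints, %s cells at first time>\n",
              nrow(x), if (nrow(x)) x$n_cells[[1L]] else "0"))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 4L))
  invisible(x)
}
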