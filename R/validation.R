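# Monte-Carlo model-adequacy check: spatially binned cell distributions,
# ensemble means, mode trajectories, and the observed-vs-model comparison.

DEFAULT_BIN_CENTERS <- seq(50, 950, by = 100)  # width 100 um, [0, 1000)

bin_breaks <- function(centers) {
  w <- unique(diff(centers))
  ww_assert(length(centers) >= 1 &&
              (length(centers) == 1L || all(abs(w - w[1]) < 1e-9)),
            "bin centers must be evenly spaced")
  w <- if (length(centers) == 1L) 100 else w[1]
  ww_assert(w > 0, "bin width must be > 0")
  c(centers - w / 2, centers[length(centers)] + w / 2)
}

#' Spatial histogram of cell distances per timepoint
#'
#' Bins distances into half-open bins `[c - w/2, c + w/2)` around each
#' centre `c` (default width 100 um, centres 50, 150, ..., 950 um).  Cells
#' at or beyond the last break (1000 um by default) are excluded from the
#' bins and counted separately in `overflow`.
#'
#' @param ds a `distance_series`.
#' @param times observation times to bin (default: all times present in
#'   `ds`).  Times with no cells yield all-zero rows.
#' @param bin_centers evenly spaced bin centres, um.
#' @return A `binned_distribution`: list with `times`, `bin_centers`,
#'   `counts` (times x bins matrix) and `overflow` (per-time count of
#'   out-of-range cells).
#' @export
bin_distances <- function(ds, times = NULL,
                          bin_centers = DEFAULT_BIN_CENTERS) {
  ds <- as_distance_series(ds)
  breaks <- bin_breaks(bin_centers)
  if (is.null(times)) times <- sort(unique(ds$time_min))
  nb <- length(bin_centers)
  counts <- matrix(0, nrow = length(times), ncol = nb,
                   dimnames = list(format(times), format(bin_centers)))
  overflow <- setNames(numeric(length(times)), format(times))
  for (i in seq_along(times)) {
    d <- ds$distance_um[ds$time_min == times[i]]
    if (!length(d)) next
    idx <- findInterval(d, breaks)           # half-open [lo, hi)
    idx[d < breaks[1L]] <- 0L                # below first break: dropped
    overflow[i] <- sum(idx > nb)
    tab <- tabulate(idx[idx >= 1L & idx <= nb], nbins = nb)
    counts[i, ] <- tab
  }
  structure(list(times = as.numeric(times),
                 bin_centers = as.numeric(bin_centers),
                 counts = counts, overflow = overflow),
            class = "binned_distribution")
}

#' @export
print.binned_distribution <- function(x, ...) {
  cat(sprintf("<binned_distribution: %d times x %d bins (centres %g..%g um)>\n",
              length(x$times), length(x$bin_centers),
              min(x$bin_centers), max(x$bin_centers)))
  invisible(x)
}

#' Ensemble-mean spatial distribution of simulated cohorts
#'
#' Bins every replicate of a simulated ensemble (after reducing it to
#' distances with `wound`) and averages the per-(time, bin) counts over
#' replicates, giving the model's expected spatial distribution.
#'
#' @param ensemble a non-empty list of [observation_set()]s sharing one
#'   observation time grid (e.g. from [simulate_ensemble()]).
#' @param wound a [wound_geometry()]; use [simulation_wound()] for
#'   simulated tracks.
#' @param times times at which to bin (default: the first replicate's
#'   grid).
#' @param bin_centers evenly spaced bin centres, um.
#' @return A `binned_distribution` whose `counts` are real-valued
#'   replicate means.
#' @export
ensemble_mean_distribution <- function(ensemble, wound, times = NULL,
                                       bin_centers = DEFAULT_BIN_CENTERS) {
  ww_assert(is.list(ensemble) && length(ensemble) >= 1,
            "ensemble must be a non-empty list of observation sets")
  grids <- lapply(ensemble, function(o) sort(unique(o$time_min)))
  ref <- grids[[1L]]
  same <- vapply(grids, function(g) length(g) == length(ref) &&
                   all(g == ref), logical(1L))
  if (!all(same)) {
    ww_abort("replicates have inconsistent observation time grids")
  }
  if (is.null(times)) times <- ref
  acc <- NULL
  over <- NULL
  for (obs in ensemble) {
    bd <- bin_distances(compute_distances(obs, wound), times = times,
                        bin_centers = bin_centers)
    if (is.null(acc)) {
      acc <- bd$counts
      over <- bd$overflow
    } else {
      acc <- acc + bd$counts
      over <- over + bd$overflow
    }
  }
  structure(list(times = as.numeric(times),
                 bin_centers = as.numeric(bin_centers),
                 counts = acc / length(ensemble),
                 overflow = over / length(ensemble)),
            class = "binned_distribution")
}

#' Trajectory of the population mode over time
#'
#' For each timepoint, the bin centre holding the largest (mean) count.
#' Ties are broken toward the smallest distance (the wound).  Times whose
#' bins are all zero get `NA` and are flagged, not fabricated.
#'
#' @param bd a `binned_distribution`.
#' @return A `mode_trajectory` data.frame with columns `time_min`,
#'   `mode_um` (NA where undefined).
#' @export
mode_trajectory <- function(bd) {
  ww_assert(inherits(bd, "binned_distribution"),
            "bd must be a binned_distribution")
  mode_um <- apply(bd$counts, 1L, function(row) {
    if (all(row == 0)) NA_real_ else bd$bin_centers[which.max(row)]
  })
  out <- data.frame(time_min = bd$times, mode_um = as.numeric(mode_um))
  class(out) <- c("mode_trajectory", "data.frame")
  out
}

#' Total-variation distance between two binned distributions
#'
#' Normalises two non-negative count vectors to probability vectors and
#' returns `0.5 * sum(|p - q|)`; `NA` if either vector sums to zero.
#'
#' @param counts_p,counts_q non-negative count vectors of equal length.
#' @return TV distance in `[0, 1]`, or `NA`.
#' @export
tv_distance <- function(counts_p, counts_q) {
  ww_assert(length(counts_p) == length(counts_q),
            "count vectors differ in length")
  sp <- sum(counts_p); sq <- sum(counts_q)
  if (sp == 0 || sq == 0) return(NA_real_)
  0.5 * sum(abs(counts_p / sp - counts_q / sq))
}

#' Compare two candidate models against observed binned data
#'
#' For each timepoint, reports the total-variation distance between each
#' model's normalised spatial distribution and the observed one, both
#' mode trajectories, and the per-time residual of the first (adjacent to
#' the wound) bin — models of free redistribution tend to underestimate
#' how many cells stay next to the wound.  The qualitative winner is the
#' model whose mode trajectory stays closer (mean absolute deviation) to
#' the observed mode trajectory.
#'
#' The TV distance is a quantitative convenience added by this package;
#' the original adequacy argument was visual.
#'
#' @param observed,model_a,model_b `binned_distribution`s on identical
#'   times and bins.
#' @param labels length-2 character, names for the two models.
#' @return A `model_comparison`: list with `table` (per-time data.frame),
#'   `winner`, `mode_mad` (named mean absolute mode deviations) and
#'   `labels`.
#' @export
compare_models <- function(observed, model_a, model_b,
                           labels = c("model_a", "model_b")) {
  for (bd in list(observed, model_a, model_b)) {
    ww_assert(inherits(bd, "binned_distribution"),
              "inputs must be binned_distributions")
  }
  same_axes <- function(a, b) {
    length(a$times) == length(b$times) && all(a$times == b$times) &&
      length(a$bin_centers) == length(b$bin_centers) &&
      all(a$bin_centers == b$bin_centers)
  }
  if (!same_axes(observed, model_a) || !same_axes(observed, model_b)) {
    ww_abort("mismatched binning: times/bin centres differ between inputs",
             "woundwalk_format_error")
  }
  nt <- length(observed$times)
  tv_a <- tv_b <- numeric(nt)
  for (i in seq_len(nt)) {
    tv_a[i] <- tv_distance(model_a$counts[i, ], observed$counts[i, ])
    tv_b[i] <- tv_distance(model_b$counts[i, ], observed$counts[i, ])
  }
  m_obs <- mode_trajectory(observed)$mode_um
  m_a <- mode_trajectory(model_a)$mode_um
  m_b <- mode_trajectory(model_b)$mode_um
  tab <- data.frame(time_min = observed$times,
                    tv_a = tv_a, tv_b = tv_b,
                    mode_obs = m_obs, mode_a = m_a, mode_b = m_b,
                    first_bin_resid_a = model_a$counts[, 1L] - observed$counts[, 1L],
                    first_bin_resid_b = model_b$counts[, 1L] - observed$counts[, 1L])
  names(tab)[names(tab) == "tv_a"] <- paste0("tv_", labels[1L])
  names(tab)[names(tab) == "tv_b"] <- paste0("tv_", labels[2L])
  names(tab)[names(tab) == "mode_a"] <- paste0("mode_", labels[1L])
  names(tab)[names(tab) == "mode_b"] <- paste0("mode_", labels[2L])
  names(tab)[names(tab) == "first_bin_resid_a"] <-
    paste0("first_bin_resid_", labels[1L])
  names(tab)[names(tab) == "first_bin_resid_b"] <-
    paste0("first_bin_resid_", labels[2L])
  rownames(tab) <- NULL
  ok <- !is.na(m_obs)
  mad_a <- mean(abs(m_a[ok] - m_obs[ok]))
  mad_b <- mean(abs(m_b[ok] - m_obs[ok]))
  winner <- if (is.na(mad_a) || is.na(mad_b)) NA_character_
  else if (mad_a < mad_b) labels[1L]
  else if (mad_b < mad_a) labels[2L]
  else "tie"
  structure(list(table = tab, winner = winner,
                 mode_mad = setNames(c(mad_a, mad_b), labels),
                 labels = labels),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model-adequacy comparison (mode criterion)\n")
  cat(sprintf("  mean |mode - observed mode|: %s = %.4g um, %s = %.4g um\n",
              x$labels[1L], x$mode_mad[[1L]],
              x$labels[2L], x$mode_mad[[2L]]))
  cat(sprintf("  qualitative winner: %s\n", x$winner))
  cat(sprintf("  final-time TV distances: %s = %.3f, %s = %.3f\n",
              x$labels[1L], x$table[[paste0("tv_", x$labels[1L])]][nrow(x$table)],
              x$labels[2L], x$table[[paste0("tv_", x$labels[2L])]][nrow(x$table)]))
  invisible(x)
}
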