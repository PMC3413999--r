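# Synthetic track generator: biased random walk in the distance-from-wound
# coordinate with a reflecting boundary at the wound edge (x = 0).
#
# One Euler-Maruyama step of the drift-diffusion SDE per substep:
#   x <- | x + v dt + sqrt(2 D dt) * xi |,  xi ~ N(0, 1)
# Because observation intervals exceed the cells' directional persistence
# time, the exact Gaussian propagator (not lattice steps) is the faithful
# choice; substeps only refine behaviour near the reflecting boundary.

#' Initial-condition descriptors for the simulator
#'
#' `init_uniform(w0)` scatters cells uniformly over `[lo, w0]` um from the
#' wound (default `[0, 80]` um, the width of the labelling zone at the
#' wound edge); `init_point(x0)` starts every cell at `x0`.  A cohort
#' released in a band away from the wound (e.g. non-labelled cells 400 to
#' 800 um out) is `init_uniform(800, lo = 400)`.
#'
#' @param w0 outer edge of the release zone, um.
#' @param lo inner edge of the release zone, um (default 0, the wound).
#' @param x0 common starting distance, um.
#' @return An `init_spec` list used by [simulation_params()].
#' @export
init_uniform <- function(w0 = 80, lo = 0) {
  ww_assert(is.numeric(w0) && length(w0) == 1L && is.numeric(lo) &&
              length(lo) == 1L && lo >= 0 && w0 > lo,
            "need 0 <= lo < w0")
  structure(list(type = "uniform", w0 = as.numeric(w0), lo = as.numeric(lo)),
            class = "init_spec")
}

#' @rdname init_uniform
#' @export
init_point <- function(x0) {
  ww_assert(is.numeric(x0) && length(x0) == 1L && x0 >= 0, "x0 must be >= 0")
  structure(list(type = "point", x0 = as.numeric(x0)), class = "init_spec")
}

#' Parameters of a synthetic cell-cohort simulation
#'
#' @param v drift coefficient, um/min (signed; negative = toward the wound).
#' @param D diffusion coefficient, um^2/min; must be `>= 0` (simulation of a
#'   negative fitted diffusion is refused).
#' @param n_cells number of cells in the cohort.
#' @param times strictly increasing observation grid, minutes (default
#'   every 10 min over a 16-h time-lapse).
#' @param init an [init_uniform()] or [init_point()] spec.
#' @param dropout_rate per-observation probability that a cell is missing
#'   from a frame (segmentation dropout); `0 <= rate < 1`, default 0.
#' @param substeps integration substeps per observation interval (default
#'   10); more substeps resolve the reflecting boundary more finely.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param channel channel label stamped on the emitted records.
#' @return A validated `simulation_params` object.
#' @export
simulation_params <- function(v = 0, D = 10, n_cells = 100L,
                              times = seq(0, 960, by = 10),
                              init = init_uniform(80),
                              dropout_rate = 0, substeps = 10L,
                              seed = NULL,
                              channel = c("photoconverted",
                                          "nonphotoconverted")) {
  channel <- match.arg(channel)
  ww_assert(is.numeric(v) && length(v) == 1L && is.finite(v),
            "v must be a finite number")
  ww_assert(is.numeric(D) && length(D) == 1L && is.finite(D) && D >= 0,
            "D must be >= 0 (cannot simulate a negative diffusion)")
  ww_assert(n_cells >= 1, "n_cells must be >= 1")
  ww_assert(length(times) >= 1 && all(is.finite(times)) &&
              all(diff(times) > 0),
            "times must be a strictly increasing grid")
  ww_assert(inherits(init, "init_spec"),
            "init must come from init_uniform() or init_point()")
  ww_assert(dropout_rate >= 0 && dropout_rate < 1,
            "dropout_rate must be in [0, 1)")
  ww_assert(substeps >= 1, "substeps must be >= 1")
  if (!is.null(seed)) {
    ww_assert(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
              "seed must be a single integer")
    seed <- as.integer(seed)
  }
  structure(list(v = v, D = D, n_cells = as.integer(n_cells),
                 times = as.numeric(times), init = init,
                 dropout_rate = dropout_rate,
                 substeps = as.integer(substeps),
                 seed = seed, channel = channel),
            class = "simulation_params")
}

#' The wound geometry matching simulated tracks
#'
#' Simulated records place the distance coordinate on the x axis with the
#' wound line at `x = 0` and tissue in the `+x` half plane, so running
#' [compute_distances()] with this geometry recovers the simulated 1-D
#' coordinate exactly.
#'
#' @return A [wound_geometry()].
#' @export
simulation_wound <- function() wound_geometry(c(0, 0), c(0, 1), +1)

#' Simulate one cohort of cells
#'
#' Evolves `n_cells` independent walkers on the observation grid by the
#' reflected drift-diffusion update (see file header) and emits them as an
#' [observation_set()] with `x_um` = distance, `y_um` = 0.  With a non-zero
#' `dropout_rate`, each (cell, time) record is independently dropped with
#' that probability.  Identical `seed` gives identical output.
#'
#' @param p a [simulation_params()] object.
#' @return An [observation_set()].
#' @examples
#' p <- simulation_params(v = 1, D = 0, n_cells = 2,
#'                        times = c(0, 10, 20), init = init_point(0),
#'                        seed = 1)
#' simulate_cells(p)
#' @export
simulate_cells <- function(p) {
  ww_assert(inherits(p, "simulation_params"),
            "p must come from simulation_params()")
  if (!is.null(p$seed)) set.seed(p$seed)
  n <- p$n_cells
  K <- length(p$times)
  x <- switch(p$init$type,
              uniform = runif(n, p$init$lo, p$init$w0),
              point = rep(p$init$x0, n))
  X <- matrix(0, nrow = n, ncol = K)
  X[, 1L] <- x
  if (K > 1L) {
    for (k in 2:K) {
      dt <- (p$times[k] - p$times[k - 1L]) / p$substeps
      step_sd <- sqrt(2 * p$D * dt)
      for (s in seq_len(p$substeps)) {
        x <- abs(x + p$v * dt + step_sd * rnorm(n))
      }
      X[, k] <- x
    }
  }
  cell_ids <- sprintf("cell%04d", seq_len(n))
  keep <- if (p$dropout_rate > 0) {
    runif(n * K) >= p$dropout_rate
  } else rep(TRUE, n * K)
  df <- data.frame(cell_id = rep(cell_ids, times = K),
                   time_min = rep(p$times, each = n),
                   x_um = as.vector(X), y_um = 0,
                   channel = p$channel, stringsAsFactors = FALSE)
  observation_set(df[keep, , drop = FALSE])
}

#' Simulate an ensemble of independent replicate cohorts
#'
#' Replicate seeds are derived deterministically from the master seed
#' (`set.seed(seed); sample.int(2^31 - 2, n_reps)`), so ensembles are
#' bit-reproducible and `simulate_ensemble(p, 1)` equals
#' `simulate_cells()` run with the first derived seed.
#'
#' @param p a [simulation_params()] object; its `seed` is the master seed
#'   (required here).
#' @param n_reps number of replicates (>= 1).
#' @return A list of `n_reps` [observation_set()]s.
#' @export
simulate_ensemble <- function(p, n_reps) {
  ww_assert(inherits(p, "simulation_params"),
            "p must come from simulation_params()")
  ww_assert(n_reps >= 1, "n_reps must be >= 1")
  ww_assert(!is.null(p$seed), "simulate_ensemble() needs a master seed in p")
  set.seed(p$seed)
  seeds <- sample.int(2147483646L, as.integer(n_reps))
  lapply(seeds, function(s) {
    pr <- p
    pr$seed <- s
    simulate_cells(pr)
  })
}
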