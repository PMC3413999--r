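# Independent brute-force oracles and small fixture builders used across
# the suite.  These stay deliberately naive: loops and normal equations,
# never the code paths they check.

# Closed-form OLS via the normal equations.
ols_oracle <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  r <- y - X %*% beta
  rss <- sum(r^2)
  sigma2 <- rss / (nrow(X) - ncol(X))
  list(beta = unname(drop(beta)),
       se = unname(sqrt(diag(solve(XtX)) * sigma2)), rss = rss)
}

# Loop-based histogram with half-open bins [c - w/2, c + w/2).
brute_bin <- function(d, centers) {
  w <- if (length(centers) > 1) diff(centers)[1] else 100
  counts <- vapply(centers, function(cc) sum(d >= cc - w / 2 & d < cc + w / 2),
                   numeric(1))
  list(counts = counts, overflow = sum(d >= max(centers) + w / 2))
}

brute_tv <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  0.5 * sum(abs(p - q))
}

# Direct construction of a population summary data.frame for fit tests.
make_summary <- function(time, mean_dist, mean_sq_dist, n_cells = 100L) {
  structure(data.frame(time_min = time, n_cells = n_cells,
                       mean_dist = mean_dist, mean_sq_dist = mean_sq_dist),
            class = c("population_summary", "data.frame"))
}

# A small well-formed track data.frame.
make_tracks_df <- function(n_cells = 3, times = c(0, 10, 20)) {
  expand <- expand.grid(cell_id = sprintf("c%d", seq_len(n_cells)),
                        time_min = times, stringsAsFactors = FALSE)
  expand$x_um <- 100 + 10 * seq_len(nrow(expand))
  expand$y_um <- 5
  expand$channel <- "photoconverted"
  expand
}

# Shared full-scale simulation worlds (values from the pooled coefficient
# tables) used by the acceptance tests and a few unit tests.
world_dd_pooled <- function(seed, n_cells = 1000L) {
  simulation_params(v = 0.26, D = 8, n_cells = n_cells,
                    times = seq(0, 960, by = 10), init = init_uniform(80),
                    seed = seed)
}

world_toward_wound <- function(seed, n_cells = 1000L) {
  simulation_params(v = -0.35, D = 40, n_cells = n_cells,
                    times = seq(0, 480, by = 10),
                    init = init_uniform(800, lo = 400), seed = seed)
}

# Estimate of the pipeline drift/diffusion for one simulated replicate.
fit_replicate <- function(p) {
  ps <- population_summary(
    compute_distances(simulate_cells(p), simulation_wound()))
  list(dr = fit_drift_linear(ps),
       pd = fit_pure_diffusion(ps),
       dd = fit_drift_diffusion(ps),
       ps = ps)
}
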