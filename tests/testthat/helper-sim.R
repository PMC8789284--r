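# Shared small synthetic medulla (built once per test run); 8 x 9 lattice
# with a 9-column dorsal rim keeps every stage fast while exercising the
# full pale/yellow/DRA structure.
shared_spec <- function() lattice_spec(n_rows = 8, n_cols = 9, n_dra = 9,
                                       seed = 42)

shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_medulla(shared_spec())
    cache
  }
})

read_fixture_counts <- function(name) {
  read.csv(system.file("extdata", paste0(name, ".csv"), package = "medcon"),
           check.names = FALSE)
}

truth_column_of <- function(sim) {
  sim$truth$synapses$column_id[match(sim$synapses$synapse_id,
                                     sim$truth$synapses$synapse_id)]
}

# Brute-force perpendicular-projection oracle: two-stage dense sampling of
# the ellipse (global n-point scan, then an n-point rescan of the
# bracketing window), fully independent of the package's optimizer.
dense_arc_oracle <- function(e, p, n = 1e5) {
  ts <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  pts <- predict(e, ts)
  d2 <- (pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2
  j <- which.min(d2)
  cum <- c(0, cumsum(sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)))
  h <- 2 * pi / n
  tr <- seq(ts[j] - h, ts[j] + h, length.out = n + 1)
  pr <- predict(e, tr)
  d2r <- (pr[, 1] - p[1])^2 + (pr[, 2] - p[2])^2
  k <- which.min(d2r)
  cumr <- c(0, cumsum(sqrt(diff(pr[, 1])^2 + diff(pr[, 2])^2)))
  mid <- n / 2 + 1  # position of ts[j] within the refined window
  list(foot = pr[k, ], arc = cum[j] + (cumr[k] - cumr[mid]),
       dist = sqrt(d2r[k]))
}
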