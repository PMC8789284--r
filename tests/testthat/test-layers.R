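test_that("slab depth fractions are linear, signed and unit-correct", {
  ax <- slab_depth_axis(thickness_um = 40)
  expect_equal(depth_fraction(c(0, 0, 0), ax), 0)
  expect_equal(depth_fraction(c(5, -3, 20000), ax), 50)
  expect_equal(depth_fraction(c(0, 0, -4000), ax), -10)  # 4 um distal
  expect_equal(depth_fraction(c(0, 0, 44000), ax), 110)
  expect_error(slab_depth_axis(thickness_um = 0), "thickness")
  expect_error(slab_depth_axis(normal = c(0, 0, 0)), "zero normal")
})

test_that("layer lookup is half-open with 100% in the deepest layer", {
  fr <- layer_frame("medulla")
  expect_equal(length(fr$labels), 10)
  expect_equal(layer_of(50, fr), "M5")       # 45.9-54.1% band
  expect_equal(layer_of(8.2, fr), "M2")      # boundary belongs to upper layer
  expect_equal(layer_of(c(-5, 0, 100, 101), fr),
               c("outside", "M1", "M10", "outside"))
  lob <- layer_frame("lobula")
  expect_equal(length(lob$labels), 7)
  expect_equal(layer_of(4.2, lob), lob$labels[2])
  expect_error(layer_frame("medulla", boundaries = c(0, 50, 40, 100),
                           labels = c("a", "b", "c")), "strictly increasing")
})

test_that("layer lookup composed with depth recovers generator truth exactly", {
  sim <- shared_sim()
  axis <- spec_depth_axis(sim$spec)
  fr <- layer_frame("medulla")
  truth <- sim$truth$synapses
  got <- layer_of(depth_fraction(as.matrix(sim$synapses[c("x", "y", "z")]),
                                 axis), fr)
  in_med <- truth$compartment == "medulla"
  expect_true(all(in_med == (got != "outside")))
  expect_equal(got[in_med], truth$layer[in_med])
})

test_that("smoothed profiles are zero-phase with analytic peak and mass", {
  pr <- smoothed_profile(0, sigma = 0.4)
  expect_equal(max(pr$density), 1 / (0.4 * sqrt(2 * pi)), tolerance = 1e-6)
  expect_equal(pr$positions[which.max(pr$density)], 0, tolerance = 1e-9)
  # symmetric kernel: profile of a symmetric sample is symmetric
  expect_equal(pr$density, rev(pr$density), tolerance = 1e-9)

  pr0 <- smoothed_profile(numeric(0), sigma = 0.6)
  expect_equal(pr0$total_count, 0L)
  expect_equal(profile_mass(pr0), 0)
  expect_error(smoothed_profile(1, sigma = 0), "positive")

  # 1000 uniform draws on [0, 10]: mass within 1%, interior density ~100/um
  set.seed(10)
  v <- runif(1000, 0, 10)
  pr2 <- smoothed_profile(v, sigma = 0.6)
  expect_equal(profile_mass(pr2), 1000, tolerance = 0.01)
  interior <- pr2$positions > 2 & pr2$positions < 8
  expect_lt(max(abs(pr2$density[interior] - 100)) / 100, 0.15)
})

test_that("profile mass conservation holds across bandwidths and inputs", {
  set.seed(11)
  for (sigma in c(0.4, 0.6)) {
    for (rep in 1:10) {
      n <- sample(1:400, 1)
      v <- switch(sample(3, 1),
                  runif(n, -5, 25),
                  rnorm(n, 10, 3),
                  rep(2.5, n))   # degenerate all-equal input
      pr <- smoothed_profile(v, sigma)
      expect_equal(profile_mass(pr), n, tolerance = 0.01)
      expect_true(all(pr$density >= 0))
    }
  }
})

test_that("direct least-squares ellipse fit recovers known shapes", {
  # noiseless circle: exact to 1e-6
  t <- seq(0, 2 * pi, length.out = 13)[-13]
  f <- fit_ellipse_lsq(cbind(10 * cos(t), 10 * sin(t)))
  expect_equal(f$a, 10, tolerance = 1e-6)
  expect_equal(f$b, 10, tolerance = 1e-6)
  expect_equal(f$center, c(0, 0), tolerance = 1e-6)

  # noisy ellipse: 2% parameter recovery
  set.seed(12)
  e <- ellipse_model(c(3, -2), 30, 12, 0.4)
  pts <- predict(e, runif(50, 0, 2 * pi)) +
    matrix(rnorm(100, 0, 0.2), ncol = 2)
  f2 <- fit_ellipse_lsq(pts)
  expect_equal(f2$a / 30, 1, tolerance = 0.02)
  expect_equal(f2$b / 12, 1, tolerance = 0.02)
  expect_equal(f2$angle, 0.4, tolerance = 0.02)
  expect_lt(sqrt(sum((f2$center - c(3, -2))^2)), 0.3)

  # translation/rotation equivariance
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  pts2 <- sweep(pts %*% t(R), 2, c(-15, 40), `+`)
  f3 <- fit_ellipse_lsq(pts2)
  expect_equal(f3$a, f2$a, tolerance = 1e-9)
  expect_equal(f3$b, f2$b, tolerance = 1e-9)
  expect_equal(f3$center, as.numeric(R %*% f2$center + c(-15, 40)),
               tolerance = 1e-9)
  expect_equal((f3$angle - f2$angle) %% pi, th %% pi, tolerance = 1e-9)

  expect_error(fit_ellipse_lsq(cbind(1:10, 2 * (1:10) + 3)), "degenerate")
  expect_error(fit_ellipse_lsq(cbind(1:3, c(0, 1, 0))), "at least 6")
})

test_that("perpendicular arc projection matches closed forms", {
  e <- ellipse_model(c(0, 0), 20, 8)
  ap <- arc_position(c(25, 0), e)   # on the major axis beyond the a-vertex
  expect_equal(ap$arc_length, 0, tolerance = 1e-9)
  expect_equal(ap$normal_distance, 5, tolerance = 1e-9)

  # circle: arc is radius * polar angle, signed distance radial
  circ <- ellipse_model(c(1, 1), 10, 10)
  for (th in c(0.3, 1.2, 2.5, 4.4)) {
    p <- c(1 + 13 * cos(th), 1 + 13 * sin(th))
    ap <- arc_position(p, circ)
    expect_equal(ap$arc_length, 10 * th, tolerance = 1e-6)
    expect_equal(ap$normal_distance, 3, tolerance = 1e-9)
  }
  inside <- arc_position(c(1 + 4, 1), circ)
  expect_equal(inside$normal_distance, -6, tolerance = 1e-9)
  expect_error(arc_position(c(1, 1), circ), "center")
})

test_that("arc projection agrees with a dense-sampling oracle", {
  set.seed(13)
  n_pairs <- 60
  for (i in seq_len(n_pairs)) {
    a <- runif(1, 5, 40); b <- runif(1, 2, a)
    e <- ellipse_model(runif(2, -20, 20), a, b, runif(1, 0, pi))
    p <- e$center + runif(2, -60, 60)
    if (sqrt(sum((p - e$center)^2)) < 1e-6) next
    got <- arc_position(p, e)
    orc <- dense_arc_oracle(e, p)
    expect_lt(sqrt(sum((got$foot - orc$foot)^2)), 1e-3)
    expect_lt(abs(got$arc_length - orc$arc), 1e-2)
    expect_equal(abs(got$normal_distance), orc$dist, tolerance = 1e-3)
  }
})

test_that("linearized dorsal-rim profile localizes a rim cell's input", {
  # rim columns on a true elliptical arc at ~4 um spacing; a Dm-DRA1-like
  # cell spans 11 consecutive columns with input strongest in the middle.
  # The fitted-ellipse arc profile is compared against the analytic
  # expected density of the construction (per-column Poisson rates with
  # uniform within-column scatter, Gaussian-smoothed).
  set.seed(14)
  e_true <- ellipse_model(c(0, 0), 60, 45, 0.2)
  ts <- seq(0.2, 1.8, length.out = 24)
  centers <- predict(e_true, ts)
  fit <- fit_ellipse_lsq(centers)
  expect_equal(fit$a, 60, tolerance = 1e-6)  # noiseless rim refit
  arcs <- arc_positions(centers, fit)$arc_length_um
  cell_cols <- 7:17
  s <- seq(-1.2, 1.2, length.out = length(cell_cols))
  lam <- 150 * dnorm(s, 0, 0.5) / dnorm(0, 0, 0.5)
  syn_arcs <- unlist(lapply(seq_along(cell_cols), function(k) {
    n <- rpois(1, lam[k])
    rep(arcs[cell_cols[k]], n) + runif(n, -2, 2)
  }))
  pr <- smoothed_profile(syn_arcs, sigma = 0.6)
  x <- pr$positions
  expected <- rowSums(sapply(seq_along(cell_cols), function(k)
    lam[k] * (pnorm((x - arcs[cell_cols[k]] + 2) / 0.6) -
                pnorm((x - arcs[cell_cols[k]] - 2) / 0.6)) / 4))
  pitch <- mean(abs(diff(arcs)))
  # realized peak sits within two column pitches of the expected peak,
  # which itself lies at the arbor center
  expect_lt(abs(x[which.max(pr$density)] - x[which.max(expected)]),
            2 * pitch)
  expect_lt(abs(x[which.max(expected)] - mean(arcs[cell_cols])), pitch)
  # 90% mass width matches the expected-density width within 20%
  q90 <- function(d) {
    cdf <- cumsum(d) / sum(d)
    x[which.min(abs(cdf - 0.95))] - x[which.min(abs(cdf - 0.05))]
  }
  expect_equal(q90(pr$density), q90(expected), tolerance = 0.2)
})
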