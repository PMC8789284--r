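test_that("lattice geometry and mosaic sampling follow the spec", {
  lat0 <- generate_lattice(lattice_spec(n_rows = 5, n_cols = 5, n_dra = 0,
                                        pale_prob = 0, seed = 1))
  expect_equal(sum(lat0$columns$subtype == "pale"), 0)
  expect_true(all(lat0$columns$subtype == "yellow"))

  # nearest-neighbour distance of every interior column equals the pitch
  lat <- generate_lattice(lattice_spec(n_rows = 7, n_cols = 7, n_dra = 0,
                                       seed = 2, pitch_um = 5))
  cc <- lat$columns
  interior <- lat$truth$row %in% 2:6 & lat$truth$col %in% 2:6
  for (i in which(interior)) {
    d <- sqrt((cc$x - cc$x[i])^2 + (cc$y - cc$y[i])^2)
    expect_equal(min(d[-i]) / 1000, 5, tolerance = 1e-9)
  }

  # full-scale mosaic draw lands in the central 99% binomial interval
  lat_full <- generate_lattice(lattice_spec(seed = 11))  # 30 x 26, 42 DRA
  expect_equal(nrow(lat_full$columns), 780)
  expect_equal(sum(lat_full$columns$subtype == "DRA"), 42)
  n_free <- 780 - 42
  n_pale <- sum(lat_full$columns$subtype == "pale")
  bounds <- qbinom(c(0.005, 0.995), n_free, 0.38)
  expect_gte(n_pale, bounds[1])
  expect_lte(n_pale, bounds[2])

  # DRA count exceeding the rim is rejected
  expect_error(lattice_spec(n_rows = 3, n_cols = 3, n_dra = 42),
               "rim length")
})

test_that("DRA columns form one contiguous rim stretch", {
  lat <- generate_lattice(lattice_spec(n_rows = 8, n_cols = 9, n_dra = 12,
                                       seed = 3))
  dra <- lat$truth[lat$truth$subtype == "DRA", ]
  on_rim <- dra$row %in% c(1, 8) | dra$col %in% c(1, 9)
  expect_true(all(on_rim))
  # contiguity: every DRA column has a DRA neighbour (rim adjacency)
  cc <- lat$columns[lat$columns$subtype == "DRA", ]
  for (i in seq_len(nrow(cc))) {
    d <- sqrt((cc$x - cc$x[i])^2 + (cc$y - cc$y[i])^2) / 1000
    expect_lte(min(d[-i]), 5 + 1e-9)
  }
})

test_that("photoreceptor terminals land in their canonical layer bands", {
  sim <- shared_sim()
  term <- sim$truth$terminals
  central <- term[!grepl("DRA", term$subtype_tag), ]
  dra <- term[grepl("DRA", term$subtype_tag), ]

  r8c <- central$terminal_depth_pct[central$pr == "R8"]
  r7c <- central$terminal_depth_pct[central$pr == "R7"]
  expect_true(all(r8c >= 26.2 & r8c < 36.1))   # central R8 in M3
  expect_true(all(r7c >= 54.1 & r7c < 62.3))   # central R7 in M6

  expect_true(all(dra$terminal_depth_pct >= 54.1 &
                    dra$terminal_depth_pct < 62.3))  # both DRA types in M6
  # R8-DRA terminates before (shallower than) R7-DRA in every column
  for (col in unique(dra$column_id)) {
    d <- dra[dra$column_id == col, ]
    expect_lt(d$terminal_depth_pct[d$pr == "R8"],
              d$terminal_depth_pct[d$pr == "R7"])
  }

  # every photoreceptor root sits distally in the chiasm (depth < 0)
  axis <- spec_depth_axis(sim$spec)
  pr_skels <- sim$skeletons[grepl("^R[78]_", names(sim$skeletons))]
  root_depths <- vapply(pr_skels, function(s) {
    depth_fraction(skeleton_coords(s), axis)[match(s$root, s$nodes$node_id)]
  }, numeric(1))
  expect_true(all(root_depths < 0))
})

test_that("target-cell placement respects span, tiling and pale occupancy", {
  sim <- shared_sim()
  members <- sim$truth$members
  cols <- sim$columns
  pitch <- sim$spec$pitch_um * 1000

  # one Mi1 per column, named by its column
  mi1 <- members[members$type_label == "Mi1", ]
  expect_equal(sort(mi1$column_id), sort(cols$column_id))
  expect_equal(nrow(mi1), nrow(cols))

  # Dm8 arbor columns all within arbor_span * pitch of the home center
  dm8 <- members[members$type_label == "Dm8", ]
  for (cid in unique(dm8$cell_id)) {
    m <- dm8[dm8$cell_id == cid, ]
    home <- cols[cols$column_id == m$column_id[m$home], ]
    arb <- cols[match(m$column_id, cols$column_id), ]
    d <- sqrt((arb$x - home$x)^2 + (arb$y - home$y)^2)
    expect_true(all(d <= 2 * pitch + 1))
  }

  # aMe12 occupancy equals the ground-truth pale set exactly
  ame <- members[members$type_label == "aMe12", ]
  expect_setequal(ame$column_id,
                  sim$truth$columns$column_id[sim$truth$columns$subtype ==
                                                "pale"])
})

test_that("synapse sampling follows the rules, weights and compartments", {
  sim <- shared_sim()
  syn <- sim$synapses
  cells <- sim$cells

  # a template with r8_weight = 0 (Dm8) receives only R7-type input
  dm8_syn <- syn[grepl("^Dm8_", syn$post_cell), ]
  pre_type <- cells$type_label[match(dm8_syn$pre_cell, cells$cell_id)]
  expect_true(nrow(dm8_syn) > 50)
  expect_true(all(pre_type == "R7"))

  # rule with mean 0 emits nothing
  spec <- lattice_spec(n_rows = 3, n_cols = 3, n_dra = 0, seed = 5)
  sim0 <- simulate_medulla(spec, templates = default_templates()["Dm9"],
                           rules = rules_for("Dm9", 0))
  expect_equal(nrow(sim0$synapses), 0)

  # realized chiasm fraction of the R7 -> R8 connection (chiasm_fraction
  # 0.8) lies in the central 99% binomial interval at the realized n
  r78 <- syn[grepl("^R8_", syn$post_cell), ]
  n <- nrow(r78); k <- sum(r78$compartment == "chiasm")
  expect_gte(k, qbinom(0.005, n, 0.8))
  expect_lte(k, qbinom(0.995, n, 0.8))

  # per-rule totals concentrate around the expected Poisson mass:
  # R7 -> R8 has one target per central column at lambda = 3
  n_central <- sum(sim$columns$subtype != "DRA")
  lambda <- 3 * n_central
  expect_lt(abs(n - lambda), 4 * sqrt(lambda))

  # ground-truth column of every synapse is the nearest lattice center
  assigned <- assign_points_to_columns(syn, sim$columns)
  expect_equal(assigned, truth_column_of(sim))
})

test_that("identical seeds give byte-identical generator output", {
  spec <- lattice_spec(n_rows = 4, n_cols = 5, n_dra = 4, seed = 99)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_medulla(simulate_medulla(spec), d1)
  write_medulla(simulate_medulla(spec), d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_equal(f1, f2)
  for (f in f1)
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), label = f)
})
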