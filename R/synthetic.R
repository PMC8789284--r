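# Seeded generator of ground-truthed synthetic medullas: a hexagonal column
# lattice with a stochastic pale/yellow mosaic and a dorsal-rim arc,
# photoreceptor axons terminating in their canonical layers (central R7 in
# M6, R8 in M3; DRA R7 and R8 both in M6 with R8 shallower), multicolumnar
# target-cell arbors with per-type layer distributions and R7/R8 and
# pale/yellow selectivity, and Poisson synapse counts with a configurable
# fraction of synapses placed distally in the optic chiasm.
#
# The generator is the study-conditions oracle for the analysis stages:
# every emitted file is accompanied by a ground-truth record (true column
# subtype, true home column, true per-synapse column / compartment / layer).

#' Lattice specification for the synthetic medulla
#'
#' Defaults encode the study conditions: a ~780-column medulla (30 x 26
#' hexagonal lattice), pale probability 0.38, 42 dorsal-rim (DRA) columns on
#' a contiguous stretch of the lattice rim, 5 um column pitch and a 40 um
#' planar slab for the depth axis.
#'
#' @param n_rows,n_cols Lattice dimensions.
#' @param pitch_um Nearest-neighbour column spacing in micrometres.
#' @param pale_prob Per-column probability of the pale fate among non-DRA
#'   columns.
#' @param n_dra Number of DRA columns (contiguous along the lattice rim;
#'   must not exceed the rim length).
#' @param medulla_thickness_um Slab thickness (distal to proximal surface).
#' @param seed Integer seed; the whole simulation runs on one seeded stream.
#' @return Object of class `lattice_spec`.
#' @export
lattice_spec <- function(n_rows = 30, n_cols = 26, pitch_um = 5,
                         pale_prob = 0.38, n_dra = 42,
                         medulla_thickness_um = 40, seed = 1L) {
  stopifnot(n_rows >= 1, n_cols >= 1, pitch_um > 0,
            pale_prob >= 0, pale_prob <= 1, n_dra >= 0,
            medulla_thickness_um > 0)
  rim <- if (n_rows == 1 || n_cols == 1) n_rows * n_cols
         else 2 * n_rows + 2 * n_cols - 4
  if (n_dra > rim)
    stop("n_dra (", n_dra, ") exceeds the lattice rim length (", rim, ")")
  structure(list(n_rows = n_rows, n_cols = n_cols, pitch_um = pitch_um,
                 pale_prob = pale_prob, n_dra = n_dra,
                 medulla_thickness_um = medulla_thickness_um,
                 seed = as.integer(seed)),
            class = "lattice_spec")
}

#' Depth axis implied by a lattice spec
#' @param spec A [lattice_spec()].
#' @return A [slab_depth_axis()] with the spec's thickness.
#' @export
spec_depth_axis <- function(spec) {
  slab_depth_axis(origin = c(0, 0, 0), normal = c(0, 0, 1),
                  thickness_um = spec$medulla_thickness_um)
}

# boundary column indices of an n_rows x n_cols grid, in one contiguous
# cyclic order (bottom row left->right, right edge up, top row right->left,
# left edge down)
.rim_order <- function(n_rows, n_cols) {
  idx <- function(i, j) (i - 1) * n_cols + j
  if (n_rows == 1) return(idx(1, 1:n_cols))
  if (n_cols == 1) return(idx(1:n_rows, 1))
  c(idx(1, 1:n_cols),
    idx(2:(n_rows - 1), n_cols),
    idx(n_rows, n_cols:1),
    idx((n_rows - 1):2, 1))
}

#' Generate the hexagonal column lattice
#'
#' Columns sit on an offset hexagonal grid at `pitch_um` spacing in the
#' plane z = 0. `n_dra` contiguous rim columns are flagged DRA; each
#' remaining column is pale with probability `pale_prob` (independent,
#' seeded draws), otherwise yellow.
#'
#' @param spec A [lattice_spec()]. Calling this function seeds the global
#'   RNG stream from `spec$seed`.
#' @return List with `columns` (column table: `column_id,x,y,z,subtype`,
#'   coordinates nm) and `truth` (data frame `column_id,subtype,row,col`).
#' @export
generate_lattice <- function(spec) {
  stopifnot(inherits(spec, "lattice_spec"))
  set.seed(spec$seed)
  pitch <- spec$pitch_um * NM_PER_UM
  ij <- expand.grid(col = seq_len(spec$n_cols), row = seq_len(spec$n_rows))
  x <- (ij$col - 1 + 0.5 * ((ij$row - 1) %% 2)) * pitch
  y <- (ij$row - 1) * pitch * sqrt(3) / 2
  n <- nrow(ij)
  subtype <- rep(NA_character_, n)
  if (spec$n_dra > 0) {
    rim <- .rim_order(spec$n_rows, spec$n_cols)
    # start on the top row so the DRA sits at the dorsal rim
    start <- match((spec$n_rows - 1) * spec$n_cols + 1, rim)
    rim <- rim[((seq_along(rim) + start - 2) %% length(rim)) + 1]
    subtype[rim[seq_len(spec$n_dra)]] <- "DRA"
  }
  free <- which(is.na(subtype))
  subtype[free] <- ifelse(stats::runif(length(free)) < spec$pale_prob,
                          "pale", "yellow")
  columns <- data.frame(column_id = sprintf("c%04d", seq_len(n)),
                        x = x, y = y, z = 0, subtype = subtype)
  list(columns = columns,
       truth = data.frame(column_id = columns$column_id, subtype = subtype,
                          row = ij$row, col = ij$col))
}

.m6 <- c(54.1, 62.3)
.m3 <- c(26.2, 36.1)

.pct_to_z <- function(pct, spec) pct / 100 * spec$medulla_thickness_um * NM_PER_UM

.axon_skeleton <- function(cell_id, x, y, spec, terminal_pct,
                           chiasm_pct = -15) {
  depths <- c(seq(chiasm_pct, terminal_pct, by = 5), terminal_pct)
  depths <- depths[!duplicated(depths)]
  n <- length(depths)
  skeleton(cell_id, data.frame(
    node_id = seq_len(n),
    parent_id = c(NA_integer_, seq_len(n - 1)),
    x = rep(x, n), y = rep(y, n),
    z = .pct_to_z(depths, spec),
    radius = rep(100, n)))
}

#' Generate photoreceptor axons for every column
#'
#' Each column receives two unbranched axons entering distally in the optic
#' chiasm (root depth < 0) and terminating at a depth drawn uniformly within
#' the type's target band: central R7 in M6 (54.1--62.3%), central R8 in M3
#' (26.2--36.1%); in DRA columns both terminate in M6, with R8-DRA strictly
#' shallower than R7-DRA.
#'
#' @param columns Column table from [generate_lattice()].
#' @param spec The [lattice_spec()] (RNG stream continues; do not reseed).
#' @return List with `skeletons` (named list), `cells` (cell table rows) and
#'   `terminals` (data frame `column_id,cell_id,pr,subtype_tag,
#'   terminal_depth_pct`).
#' @export
generate_photoreceptors <- function(columns, spec) {
  n <- nrow(columns)
  r7_pct <- numeric(n); r8_pct <- numeric(n)
  is_dra <- columns$subtype == "DRA"
  r7_pct[!is_dra] <- stats::runif(sum(!is_dra), .m6[1], .m6[2])
  r8_pct[!is_dra] <- stats::runif(sum(!is_dra), .m3[1], .m3[2])
  if (any(is_dra)) {
    d1 <- stats::runif(sum(is_dra), .m6[1], .m6[2])
    d2 <- stats::runif(sum(is_dra), .m6[1], .m6[2])
    r7_pct[is_dra] <- pmax(d1, d2)   # R7-DRA deeper
    r8_pct[is_dra] <- pmin(d1, d2)   # R8-DRA terminates before R7-DRA
  }
  tag7 <- ifelse(is_dra, "R7-DRA", ifelse(columns$subtype == "pale",
                                          "pR7", "yR7"))
  tag8 <- ifelse(is_dra, "R8-DRA", ifelse(columns$subtype == "pale",
                                          "pR8", "yR8"))
  skels <- vector("list", 2 * n)
  ids <- character(2 * n)
  for (i in seq_len(n)) {
    id7 <- paste0("R7_", columns$column_id[i])
    id8 <- paste0("R8_", columns$column_id[i])
    skels[[2 * i - 1]] <- .axon_skeleton(id7, columns$x[i], columns$y[i],
                                         spec, r7_pct[i])
    skels[[2 * i]] <- .axon_skeleton(id8, columns$x[i], columns$y[i],
                                     spec, r8_pct[i])
    ids[c(2 * i - 1, 2 * i)] <- c(id7, id8)
  }
  names(skels) <- ids
  cells <- data.frame(
    cell_id = ids,
    type_label = rep(c("R7", "R8"), n),
    class_label = "R",
    status = "identified_type",
    subtype_tag = as.character(rbind(tag7, tag8)))
  terminals <- data.frame(
    column_id = rep(columns$column_id, each = 2),
    cell_id = as.character(rbind(paste0("R7_", columns$column_id),
                                 paste0("R8_", columns$column_id))),
    pr = rep(c("R7", "R8"), n),
    subtype_tag = as.character(rbind(tag7, tag8)),
    terminal_depth_pct = as.numeric(rbind(r7_pct, r8_pct)))
  cells$type_label <- rep(c("R7", "R8"), n)
  list(skeletons = skels, cells = cells, terminals = terminals)
}

#' Target-cell template
#'
#' Describes one postsynaptic cell type of the generator: how far its arbor
#' spreads (in column units), which layers its synapses sample, its
#' source-photoreceptor and mosaic selectivity, its home-column enrichment
#' and the probability of receiving a synapse distally in the optic chiasm.
#'
#' @param type_label Cell type name (e.g. `"Dm8"`).
#' @param class_label Cell class (e.g. `"Dm"`).
#' @param arbor_span Arbor radius in column units (0 = home column only).
#' @param layer_profile Named numeric vector of layer weights (must sum
#'   to 1), e.g. `c(M6 = 1)`.
#' @param home_column_boost Multiplier (>= 1) applied to the Poisson mean in
#'   the cell's home column (Dm8-like enrichment; 1 = none).
#' @param r7_weight,r8_weight Nonnegative multipliers for R7 / R8 sources.
#' @param pale_weight,yellow_weight Nonnegative multipliers for pale /
#'   yellow source columns (ignored in the DRA, which has no mosaic).
#' @param chiasm_fraction Probability that a synapse is placed distal to M1
#'   (negative depth), in the optic chiasm.
#' @param per_column One cell per column (Mi1-like) instead of a tiling of
#'   multicolumnar cells.
#' @param occupy `"all"` or `"pale"`; `"pale"` restricts arbors to
#'   ground-truth pale columns and adds vertical processes there
#'   (aMe12-like).
#' @param photoreceptor_target `NA`, `"R7"` or `"R8"`: the "cells" of this
#'   template are the column's photoreceptors themselves (used for
#'   R7 <-> R8 axo-axonal synapses); no new skeletons are generated.
#' @param n_cells Number of cells for tiling templates (default: enough to
#'   cover the lattice with overlap).
#' @return Object of class `cell_template`.
#' @export
cell_template <- function(type_label, class_label = type_label,
                          arbor_span = 1, layer_profile = c(M6 = 1),
                          home_column_boost = 1,
                          r7_weight = 1, r8_weight = 1,
                          pale_weight = 1, yellow_weight = 1,
                          chiasm_fraction = 0, per_column = FALSE,
                          occupy = c("all", "pale"),
                          photoreceptor_target = NA_character_,
                          n_cells = NULL) {
  occupy <- match.arg(occupy)
  stopifnot(arbor_span >= 0, home_column_boost >= 0,
            r7_weight >= 0, r8_weight >= 0,
            pale_weight >= 0, yellow_weight >= 0,
            chiasm_fraction >= 0, chiasm_fraction <= 1)
  if (abs(sum(layer_profile) - 1) > 1e-9)
    stop("layer_profile weights must sum to 1")
  structure(list(type_label = type_label, class_label = class_label,
                 arbor_span = arbor_span, layer_profile = layer_profile,
                 home_column_boost = home_column_boost,
                 r7_weight = r7_weight, r8_weight = r8_weight,
                 pale_weight = pale_weight, yellow_weight = yellow_weight,
                 chiasm_fraction = chiasm_fraction, per_column = per_column,
                 occupy = occupy,
                 photoreceptor_target = photoreceptor_target,
                 n_cells = n_cells),
            class = "cell_template")
}

#' Connectivity rule
#'
#' One (source photoreceptor subtype, target template) pair with a base
#' Poisson mean per (column, overlapping target cell). The effective mean is
#' `mean * source_weight * mosaic_weight * home_boost`, where the weights
#' come from the target template.
#'
#' @param subtype Source subtype: `pR7`, `yR7`, `pR8`, `yR8`, `R7-DRA` or
#'   `R8-DRA`.
#' @param target Target template `type_label`.
#' @param mean Base synapse mean (>= 0).
#' @return Object of class `connectivity_rule`.
#' @export
connectivity_rule <- function(subtype, target, mean) {
  stopifnot(subtype %in% c("pR7", "yR7", "pR8", "yR8", "R7-DRA", "R8-DRA"),
            mean >= 0)
  structure(list(subtype = subtype, target = target, mean = mean),
            class = "connectivity_rule")
}

#' Expand a template into per-subtype rules
#'
#' Convenience: one [connectivity_rule()] per central subtype (or per DRA
#' subtype when `dra = TRUE`) sharing a base mean; the template's own
#' weights then encode the selectivity.
#'
#' @param template A [cell_template()] (or its `type_label`).
#' @param mean Base mean per (column, cell).
#' @param dra Emit DRA-subtype rules instead of central ones.
#' @return List of rules.
#' @export
rules_for <- function(template, mean, dra = FALSE) {
  lab <- if (inherits(template, "cell_template")) template$type_label
         else template
  subs <- if (dra) c("R7-DRA", "R8-DRA") else c("pR7", "yR7", "pR8", "yR8")
  lapply(subs, connectivity_rule, target = lab, mean = mean)
}

#' Default target-cell templates
#'
#' A compact set of emblematic medulla target types reflecting the empirical
#' selectivity structure: Mi1 (columnar anchor cells with M1/M5/M9/M10
#' arbors, R8 input), Dm9 (reciprocal R7+R8 partner, all layers M1-M6),
#' Dm8 (R7-exclusive, home-column enriched in M6), Tm5c (R8- and
#' yellow-biased), MeTu (R7-exclusive projection neurons), aMe12
#' (pale-column R8 target with vertical processes spanning M6 to M1/M3),
#' and the DRA-specific Dm-DRA1 (R7-DRA exclusive) and MeTu-DRA.
#' The R7 -> R8 axo-axonal connection is represented by a photoreceptor
#' target template with a high chiasm fraction (~80% of the R7 input to R8
#' lies outside the medulla).
#'
#' @return Named list of [cell_template()] objects.
#' @export
default_templates <- function() {
  tl <- list(
    cell_template("Mi1", "Mi", arbor_span = 0, per_column = TRUE,
                  layer_profile = c(M1 = 0.3, M5 = 0.4, M9 = 0.15, M10 = 0.15),
                  r7_weight = 0, r8_weight = 1, chiasm_fraction = 0),
    cell_template("Dm9", "Dm", arbor_span = 1,
                  layer_profile = c(M1 = 0.25, M2 = 0.1, M3 = 0.25,
                                    M4 = 0.1, M5 = 0.1, M6 = 0.2),
                  r7_weight = 0.55, r8_weight = 1, chiasm_fraction = 0.08),
    cell_template("Dm8", "Dm", arbor_span = 2,
                  layer_profile = c(M6 = 1), home_column_boost = 3,
                  r7_weight = 1, r8_weight = 0, chiasm_fraction = 0),
    cell_template("Tm5c", "Tm", arbor_span = 2,
                  layer_profile = c(M1 = 0.2, M3 = 0.3, M6 = 0.5),
                  r7_weight = 0.15, r8_weight = 1,
                  pale_weight = 0.25, yellow_weight = 1,
                  chiasm_fraction = 0.05),
    cell_template("MeTu", "MeTu", arbor_span = 3,
                  layer_profile = c(M6 = 0.8, M2 = 0.2),
                  r7_weight = 1, r8_weight = 0, chiasm_fraction = 0.05),
    cell_template("aMe12", "VPN", arbor_span = 0, occupy = "pale",
                  layer_profile = c(M1 = 0.2, M3 = 0.3, M6 = 0.5),
                  r7_weight = 0.15, r8_weight = 1, chiasm_fraction = 0.05,
                  n_cells = 3),
    cell_template("R8", "R", photoreceptor_target = "R8", arbor_span = 0,
                  layer_profile = c(M3 = 0.5, M2 = 0.3, M1 = 0.2),
                  r7_weight = 1, r8_weight = 0, chiasm_fraction = 0.8),
    cell_template("Dm-DRA1", "Dm", arbor_span = 2,
                  layer_profile = c(M6 = 1),
                  r7_weight = 1, r8_weight = 0, chiasm_fraction = 0),
    cell_template("MeTu-DRA", "MeTu", arbor_span = 3,
                  layer_profile = c(M6 = 1),
                  r7_weight = 1, r8_weight = 0, chiasm_fraction = 0.05))
  names(tl) <- vapply(tl, `[[`, character(1), "type_label")
  tl
}

#' Default connectivity rules
#'
#' Base means chosen to reproduce the relative selectivity structure of the
#' empirical connectivity tables (R7:R8 ratios, pale:yellow bias, DRA
#' exclusivity) at desk-scale synapse counts.
#'
#' @return List of [connectivity_rule()] objects.
#' @export
default_rules <- function() {
  c(rules_for("Dm9", 3), rules_for("Dm8", 2), rules_for("Mi1", 1.5),
    rules_for("Tm5c", 2), rules_for("MeTu", 1), rules_for("aMe12", 2),
    rules_for("R8", 3),
    rules_for("Dm9", 3, dra = TRUE), rules_for("Dm-DRA1", 3, dra = TRUE),
    rules_for("MeTu-DRA", 2, dra = TRUE))
}

.planar_dist <- function(x1, y1, x2, y2) sqrt((x1 - x2)^2 + (y1 - y2)^2)

# sample a depth (percent) from a template's layer profile
.sample_depth_pct <- function(template, n, frame) {
  if (n == 0) return(numeric(0))
  layers <- names(template$layer_profile)
  pick <- sample(layers, n, replace = TRUE, prob = template$layer_profile)
  vapply(pick, function(l) {
    b <- layer_band(frame, l)
    stats::runif(1, b[1], b[2])
  }, numeric(1))
}

#' Generate target cells for a set of templates
#'
#' Per-column templates place one cell per column; tiling templates place
#' `n_cells` cells (default: enough home columns for overlapping coverage)
#' with arbors spanning all columns within `arbor_span` column pitches of
#' the home center; `occupy = "pale"` templates split the ground-truth pale
#' set among their cells and emit vertical processes (M6 up to M3 or M1) in
#' exactly those columns. DRA-exclusive templates (`r8_weight == 0` and a
#' name carrying `-DRA`, or any template used only by DRA rules) are placed
#' on DRA home columns.
#'
#' @param templates Named list of [cell_template()]s.
#' @param columns Column table from [generate_lattice()].
#' @param spec The [lattice_spec()] (stream continues).
#' @param frame Medulla [layer_frame()].
#' @return List with `skeletons`, `cells` (cell table rows) and `members`
#'   (data frame `cell_id,type_label,column_id,home` of arbor membership).
#' @export
generate_target_cells <- function(templates, columns, spec,
                                  frame = layer_frame("medulla")) {
  pitch <- spec$pitch_um * NM_PER_UM
  skels <- list(); cells <- list(); members <- list()
  for (tpl in templates) {
    if (!is.na(tpl$photoreceptor_target)) next  # photoreceptors already exist
    dra_only <- grepl("-DRA$|_DRA$", tpl$type_label)
    home_pool <- if (tpl$occupy == "pale") which(columns$subtype == "pale")
                 else if (dra_only) which(columns$subtype == "DRA")
                 else seq_len(nrow(columns))
    if (tpl$arbor_span > 0) {
      span_nm <- tpl$arbor_span * pitch
      if (span_nm > max(diff(range(columns$x)), diff(range(columns$y))))
        stop("template ", tpl$type_label, " span exceeds the lattice extent")
    }
    if (tpl$per_column) {
      homes <- home_pool
    } else if (tpl$occupy == "pale") {
      n_cells <- if (is.null(tpl$n_cells)) 1L else tpl$n_cells
      grp <- if (length(home_pool) == 0) integer(0)
             else rep_len(seq_len(n_cells), length(home_pool))
      homes <- split(home_pool, grp)
    } else {
      n_cells <- if (!is.null(tpl$n_cells)) tpl$n_cells
                 else max(1L, ceiling(length(home_pool) /
                                        max(1, tpl$arbor_span^2)))
      homes <- home_pool[unique(round(seq(1, length(home_pool),
                                          length.out = n_cells)))]
    }
    make_cell <- function(cell_id, home_idx, arbor_idx, vertical = FALSE) {
      nodes <- list()
      nid <- 0L
      add_node <- function(x, y, zpct, parent) {
        nid <<- nid + 1L
        nodes[[nid]] <<- data.frame(node_id = nid, parent_id = parent,
                                    x = x, y = y, z = .pct_to_z(zpct, spec),
                                    radius = 150)
        nid
      }
      hx <- columns$x[home_idx]; hy <- columns$y[home_idx]
      root <- add_node(hx, hy, 50, NA_integer_)
      for (ci in arbor_idx) {
        jx <- columns$x[ci] + stats::runif(1, -0.2, 0.2) * pitch
        jy <- columns$y[ci] + stats::runif(1, -0.2, 0.2) * pitch
        if (vertical) {
          top <- if (stats::runif(1) < 0.5) 30 else 4  # short (M3) or long (M1)
          depths <- seq(58, top, by = -6)
          prev <- root
          for (d in depths) prev <- add_node(columns$x[ci], columns$y[ci],
                                             d, prev)
        } else {
          zp <- .sample_depth_pct(tpl, 3L, frame)
          for (d in zp) add_node(jx, jy, d, root)
        }
      }
      skeleton(cell_id, do.call(rbind, nodes))
    }
    if (tpl$occupy == "pale" && !tpl$per_column) {
      for (k in seq_along(homes)) {
        arbor <- homes[[k]]
        if (length(arbor) == 0) next
        cid <- sprintf("%s_%02d", tpl$type_label, k)
        skels[[cid]] <- make_cell(cid, arbor[1], arbor, vertical = TRUE)
        cells[[cid]] <- data.frame(cell_id = cid, type_label = tpl$type_label,
                                   class_label = tpl$class_label,
                                   status = "identified_type",
                                   subtype_tag = NA_character_)
        members[[cid]] <- data.frame(cell_id = cid,
                                     type_label = tpl$type_label,
                                     column_id = columns$column_id[arbor],
                                     home = c(TRUE,
                                              rep(FALSE, length(arbor) - 1)))
      }
    } else {
      for (k in seq_along(homes)) {
        h <- homes[k]
        arbor <- which(.planar_dist(columns$x, columns$y,
                                    columns$x[h], columns$y[h]) <=
                         tpl$arbor_span * pitch + 1)
        if (dra_only) arbor <- arbor[columns$subtype[arbor] == "DRA"]
        # per-column anchor cells carry their column id (Mi1_c0001 ...)
        cid <- if (tpl$per_column)
          paste0(tpl$type_label, "_", columns$column_id[h])
        else sprintf("%s_%03d", tpl$type_label, k)
        skels[[cid]] <- make_cell(cid, h, arbor)
        cells[[cid]] <- data.frame(cell_id = cid, type_label = tpl$type_label,
                                   class_label = tpl$class_label,
                                   status = "identified_type",
                                   subtype_tag = NA_character_)
        members[[cid]] <- data.frame(cell_id = cid,
                                     type_label = tpl$type_label,
                                     column_id = columns$column_id[arbor],
                                     home = arbor == h)
      }
    }
  }
  list(skeletons = skels,
       cells = if (length(cells)) do.call(rbind, c(cells,
                                                   make.row.names = FALSE))
               else NULL,
       members = if (length(members)) do.call(rbind, c(members,
                                                       make.row.names = FALSE))
                 else NULL)
}

#' Sample synapses under the connectivity rules
#'
#' For each rule and each (column of the rule's source subtype, target cell
#' overlapping that column), a synapse count is drawn
#' `Poisson(mean x source weight x mosaic weight x home boost)`. Each
#' synapse is placed at the source column (planar jitter < 0.3 pitch, so the
#' nearest lattice center is the true column by construction) at a depth
#' drawn from the target's layer profile, or distally in the chiasm
#' (negative depth) with the template's `chiasm_fraction`.
#'
#' @param rules List of [connectivity_rule()]s.
#' @param templates Named list of templates.
#' @param columns Column table.
#' @param photoreceptors Result of [generate_photoreceptors()].
#' @param targets Result of [generate_target_cells()].
#' @param spec The [lattice_spec()] (stream continues).
#' @param frame Medulla [layer_frame()].
#' @return List with `synapses` (synapse table) and `truth` (data frame
#'   `synapse_id,column_id,compartment,layer,rule_target`).
#' @export
sample_synapses <- function(rules, templates, columns, photoreceptors,
                            targets, spec, frame = layer_frame("medulla")) {
  pitch <- spec$pitch_um * NM_PER_UM
  term <- photoreceptors$terminals
  members <- targets$members
  syn <- list(); truth <- list()
  sid <- 0L
  for (rule in rules) {
    tpl <- templates[[rule$target]]
    if (is.null(tpl)) stop("rule references unknown template: ", rule$target)
    if (rule$mean == 0) next
    src <- term[term$subtype_tag == rule$subtype, , drop = FALSE]
    if (nrow(src) == 0) next
    src_w <- if (grepl("R7", rule$subtype)) tpl$r7_weight else tpl$r8_weight
    for (i in seq_len(nrow(src))) {
      col_id <- src$column_id[i]
      ci <- match(col_id, columns$column_id)
      mosaic_w <- switch(columns$subtype[ci], pale = tpl$pale_weight,
                         yellow = tpl$yellow_weight, DRA = 1)
      if (!is.na(tpl$photoreceptor_target)) {
        post <- data.frame(cell_id = paste0(tpl$photoreceptor_target, "_",
                                            col_id),
                           home = TRUE)
      } else {
        post <- members[members$type_label == rule$target &
                          members$column_id == col_id, c("cell_id", "home"),
                        drop = FALSE]
      }
      if (nrow(post) == 0) next
      for (j in seq_len(nrow(post))) {
        boost <- if (post$home[j]) max(tpl$home_column_boost, 1) else 1
        lambda <- rule$mean * src_w * mosaic_w * boost
        if (lambda == 0) next
        k <- stats::rpois(1, lambda)
        if (k == 0) next
        in_chiasm <- stats::runif(k) < tpl$chiasm_fraction
        depth <- numeric(k)
        depth[in_chiasm] <- stats::runif(sum(in_chiasm), -15, -2)
        depth[!in_chiasm] <- .sample_depth_pct(tpl, sum(!in_chiasm), frame)
        ang <- stats::runif(k, 0, 2 * pi)
        rad <- sqrt(stats::runif(k)) * 0.3 * pitch
        ids <- sprintf("s%06d", sid + seq_len(k))
        sid <- sid + k
        syn[[length(syn) + 1]] <- data.frame(
          synapse_id = ids, pre_cell = src$cell_id[i],
          post_cell = post$cell_id[j],
          x = columns$x[ci] + rad * cos(ang),
          y = columns$y[ci] + rad * sin(ang),
          z = .pct_to_z(depth, spec),
          compartment = ifelse(in_chiasm, "chiasm", "medulla"))
        truth[[length(truth) + 1]] <- data.frame(
          synapse_id = ids, column_id = col_id,
          compartment = ifelse(in_chiasm, "chiasm", "medulla"),
          layer = ifelse(in_chiasm, NA_character_, layer_of(depth, frame)),
          rule_target = rule$target)
      }
    }
  }
  empty_syn <- data.frame(synapse_id = character(0), pre_cell = character(0),
                          post_cell = character(0), x = numeric(0),
                          y = numeric(0), z = numeric(0),
                          compartment = character(0))
  empty_truth <- data.frame(synapse_id = character(0),
                            column_id = character(0),
                            compartment = character(0), layer = character(0),
                            rule_target = character(0))
  list(synapses = if (length(syn)) do.call(rbind, c(syn,
                                                    make.row.names = FALSE))
                  else empty_syn,
       truth = if (length(truth)) do.call(rbind, c(truth,
                                                   make.row.names = FALSE))
               else empty_truth)
}

#' Simulate a complete synthetic medulla
#'
#' Runs lattice, photoreceptor, target-cell and synapse generation on one
#' seeded stream (`spec$seed`); identical specs give byte-identical outputs
#' when written with [write_medulla()].
#'
#' @param spec A [lattice_spec()].
#' @param templates Named list of templates (default [default_templates()]).
#' @param rules List of rules (default [default_rules()]).
#' @return Object of class `medulla_sim`: list with `spec`, `columns`,
#'   `cells`, `skeletons`, `synapses` and ground truth `truth` (elements
#'   `columns`, `cells`, `synapses`, `members`, `terminals`).
#' @export
simulate_medulla <- function(spec = lattice_spec(),
                             templates = default_templates(),
                             rules = default_rules()) {
  frame <- layer_frame("medulla")
  lat <- generate_lattice(spec)   # seeds the stream
  pr <- generate_photoreceptors(lat$columns, spec)
  tg <- generate_target_cells(templates, lat$columns, spec, frame)
  sy <- sample_synapses(rules, templates, lat$columns, pr, tg, spec, frame)
  cells <- rbind(pr$cells, tg$cells)
  home_map <- if (!is.null(tg$members))
    tg$members[tg$members$home, c("cell_id", "column_id")] else NULL
  truth_cells <- data.frame(cell_id = cells$cell_id,
                            type_label = cells$type_label)
  truth_cells$home_column <- if (is.null(home_map)) NA_character_
    else home_map$column_id[match(truth_cells$cell_id, home_map$cell_id)]
  structure(list(spec = spec, columns = lat$columns, cells = cells,
                 skeletons = c(pr$skeletons, tg$skeletons),
                 synapses = sy$synapses,
                 truth = list(columns = lat$truth, cells = truth_cells,
                              synapses = sy$truth, members = tg$members,
                              terminals = pr$terminals)),
            class = "medulla_sim")
}

#' @export
print.medulla_sim <- function(x, ...) {
  cat("<medulla_sim>", nrow(x$columns), "columns (",
      sum(x$columns$subtype == "pale"), "pale /",
      sum(x$columns$subtype == "yellow"), "yellow /",
      sum(x$columns$subtype == "DRA"), "DRA ),",
      length(x$skeletons), "skeletons,", nrow(x$synapses), "synapses\n")
  invisible(x)
}

#' Write a simulated medulla to a directory
#'
#' Emits `columns.csv`, `cells.csv`, `synapses.csv`, ground-truth CSVs and
#' one SWC file per skeleton under `swc/`, all in the interchange schemas of
#' the readers.
#'
#' @param sim A [simulate_medulla()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_medulla <- function(sim, dir) {
  stopifnot(inherits(sim, "medulla_sim"))
  dir.create(file.path(dir, "swc"), recursive = TRUE, showWarnings = FALSE)
  write_column_table(sim$columns, file.path(dir, "columns.csv"))
  write_cell_table(sim$cells, file.path(dir, "cells.csv"))
  write_synapse_table(sim$synapses, file.path(dir, "synapses.csv"))
  utils::write.csv(sim$truth$columns, file.path(dir, "truth_columns.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$truth$synapses, file.path(dir, "truth_synapses.csv"),
                   row.names = FALSE, quote = FALSE)
  for (s in sim$skeletons)
    write_skeleton(s, file.path(dir, "swc", paste0(s$cell_id, ".swc")))
  invisible(dir)
}
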