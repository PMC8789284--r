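# Column-lattice construction and identity assignment: column centers from
# Mi1 anchor cells (center of mass of the layer-M5 dendrite), nearest-center
# point-to-column assignment, pale/yellow assignment from aMe12 vertical
# processes, and DRA detection from R7/R8 co-termination in layer M6.

#' Best-fit lattice plane of a set of column centers
#'
#' Total-least-squares plane (SVD of the centered coordinates); all planar
#' distances for column assignment are measured in this plane. For a curved
#' medulla sheet this is the desk-scale stand-in for the tangent surface.
#'
#' @param centers n x 3 matrix or a column table (uses `x,y,z`).
#' @return Object of class `lattice_plane`: `origin` (centroid), `basis`
#'   (3 x 2 orthonormal in-plane basis), `normal`.
#' @export
lattice_plane <- function(centers) {
  if (is.data.frame(centers)) centers <- as.matrix(centers[c("x", "y", "z")])
  stopifnot(ncol(centers) == 3, nrow(centers) >= 1)
  origin <- colMeans(centers)
  if (nrow(centers) < 3) {
    basis <- cbind(c(1, 0, 0), c(0, 1, 0))
    normal <- c(0, 0, 1)
  } else {
    sv <- svd(sweep(centers, 2, origin))
    basis <- sv$v[, 1:2, drop = FALSE]
    normal <- sv$v[, 3]
  }
  structure(list(origin = origin, basis = basis, normal = normal),
            class = "lattice_plane")
}

#' Project 3-D points into lattice-plane coordinates
#' @param points n x 3 matrix (nm).
#' @param plane A [lattice_plane()].
#' @return n x 2 matrix of in-plane coordinates (nm).
#' @export
project_to_plane <- function(points, plane) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  sweep(as.matrix(points), 2, plane$origin) %*% plane$basis
}

#' Column centers from Mi1 anchor cells
#'
#' The location of a medulla column is the center of mass (unweighted mean)
#' of the Mi1 dendrite in layer M5: nodes whose depth fraction lies in the
#' M5 band are averaged and projected to the lattice plane's z = reference.
#' One center per skeleton; a cell with no node in M5 is an error.
#'
#' @param mi1_skeletons List of [skeleton()]s, one Mi1-like cell each.
#' @param frame Medulla [layer_frame()].
#' @param axis Depth axis (see [slab_depth_axis()]).
#' @return Column table (`column_id,x,y,z,subtype`), subtype `NA`; the
#'   column_id is derived from the cell id.
#' @export
column_centers_from_mi1 <- function(mi1_skeletons, frame = layer_frame("medulla"),
                                    axis = slab_depth_axis()) {
  band <- layer_band(frame, "M5")
  rows <- lapply(mi1_skeletons, function(s) {
    xyz <- skeleton_coords(s)
    d <- depth_fraction(xyz, axis)
    in_m5 <- d >= band[1] & d < band[2]
    if (!any(in_m5))
      stop("cell ", s$cell_id, " has no node in the M5 band")
    ctr <- colMeans(xyz[in_m5, , drop = FALSE])
    data.frame(column_id = sub("^Mi1_", "", s$cell_id),
               x = ctr[1], y = ctr[2], z = 0, subtype = NA_character_)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Assign points to the nearest column
#'
#' Each point is assigned the column whose center is nearest in the lattice
#' plane (Euclidean distance); exact ties go to the smallest `column_id`.
#' The assignment is deterministic, idempotent and invariant under point
#' order.
#'
#' @param points n x 3 matrix of coordinates (nm) or a synapse table (uses
#'   `x,y,z`).
#' @param columns Column table (>= 1 row).
#' @param plane Optional [lattice_plane()]; default is the best-fit plane of
#'   the column centers.
#' @return Character vector of `column_id`s, one per point.
#' @export
assign_points_to_columns <- function(points, columns, plane = NULL) {
  if (nrow(columns) == 0) stop("empty column list")
  if (is.data.frame(points)) points <- as.matrix(points[c("x", "y", "z")])
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  if (is.null(plane)) plane <- lattice_plane(columns)
  # order columns by id so which.min's first-match rule breaks ties low
  ord <- order(columns$column_id)
  cc <- project_to_plane(as.matrix(columns[ord, c("x", "y", "z")]), plane)
  pp <- project_to_plane(points, plane)
  ids <- columns$column_id[ord]
  vapply(seq_len(nrow(pp)), function(i) {
    d2 <- (cc[, 1] - pp[i, 1])^2 + (cc[, 2] - pp[i, 2])^2
    ids[which.min(d2)]
  }, character(1))
}

#' Detect vertical (columnar) processes in a skeleton
#'
#' A vertical process is a maximal ascending stretch of the arbor within one
#' column whose depth extent spans from the M6 band up to at least the M3
#' band (both the short M6-to-M3 and the long M6-to-M1 processes qualify).
#' Implemented per column: the skeleton's nodes are assigned to columns and
#' a column counts as carrying a vertical process when its nodes reach into
#' M6 (depth >= M6 lower boundary) and ascend to the M3 band or beyond
#' (depth < M3 upper boundary).
#'
#' @param skel A [skeleton()].
#' @param columns Column table.
#' @param frame Medulla [layer_frame()].
#' @param axis Depth axis.
#' @param plane Optional [lattice_plane()].
#' @return Character vector of `column_id`s carrying a vertical process.
#' @export
vertical_process_columns <- function(skel, columns,
                                     frame = layer_frame("medulla"),
                                     axis = slab_depth_axis(), plane = NULL) {
  xyz <- skeleton_coords(skel)
  d <- depth_fraction(xyz, axis)
  col_of_node <- assign_points_to_columns(xyz, columns, plane)
  m6 <- layer_band(frame, "M6"); m3 <- layer_band(frame, "M3")
  hits <- tapply(d, col_of_node, function(dd)
    max(dd) >= m6[1] && min(dd) < m3[2])
  names(hits)[which(hits)]
}

#' Assign pale and yellow columns from aMe12 innervation
#'
#' A column is pale if and only if at least one aMe12 vertical process is
#' assigned to it (nearest-center rule, no distance cutoff); all remaining
#' non-DRA columns are yellow. Existing DRA flags are preserved and override
#' a pale claim (aMe12 only exceptionally enters the DRA).
#'
#' @param ame12_skeletons List of aMe12-like [skeleton()]s (may be empty).
#' @param columns Column table; rows with subtype `"DRA"` keep it.
#' @param frame Medulla [layer_frame()].
#' @param axis Depth axis.
#' @return List with `columns` (subtype filled in: pale/yellow/DRA) and
#'   `provenance` (data frame `column_id,claimed_by` naming the aMe12 cell
#'   that claimed each pale column).
#' @export
pale_from_ame12 <- function(ame12_skeletons, columns,
                            frame = layer_frame("medulla"),
                            axis = slab_depth_axis()) {
  plane <- lattice_plane(columns)
  claims <- list()
  for (s in ame12_skeletons) {
    occ <- vertical_process_columns(s, columns, frame, axis, plane)
    if (length(occ))
      claims[[s$cell_id]] <- data.frame(column_id = occ, claimed_by = s$cell_id)
  }
  prov <- if (length(claims)) do.call(rbind, c(claims, make.row.names = FALSE))
          else data.frame(column_id = character(0), claimed_by = character(0))
  is_dra <- !is.na(columns$subtype) & columns$subtype == "DRA"
  pale <- columns$column_id %in% prov$column_id & !is_dra
  columns$subtype <- ifelse(is_dra, "DRA", ifelse(pale, "pale", "yellow"))
  prov <- prov[!(prov$column_id %in% columns$column_id[is_dra]), , drop = FALSE]
  list(columns = columns, provenance = prov)
}

#' Detect DRA columns from photoreceptor co-termination in M6
#'
#' A column is DRA if and only if both its R7 and R8 terminal depth
#' fractions fall in the M6 band (in the dorsal rim both inner
#' photoreceptors terminate in M6, R8 before R7; elsewhere R8 stops in M3).
#' Columns missing either terminal are flagged indeterminate and excluded.
#'
#' @param terminals Data frame with columns `column_id`, `pr` (`"R7"` /
#'   `"R8"`) and `terminal_depth_pct` (as produced by
#'   [generate_photoreceptors()], or measured from skeleton tips with
#'   [terminal_depths()]).
#' @param columns Column table.
#' @param frame Medulla [layer_frame()].
#' @return Data frame `column_id,dra,indeterminate`.
#' @export
detect_dra_columns <- function(terminals, columns,
                               frame = layer_frame("medulla")) {
  m6 <- layer_band(frame, "M6")
  res <- data.frame(column_id = columns$column_id, dra = FALSE,
                    indeterminate = FALSE)
  for (i in seq_len(nrow(res))) {
    tt <- terminals[terminals$column_id == res$column_id[i], , drop = FALSE]
    d7 <- tt$terminal_depth_pct[tt$pr == "R7"]
    d8 <- tt$terminal_depth_pct[tt$pr == "R8"]
    if (length(d7) == 0 || length(d8) == 0) {
      res$indeterminate[i] <- TRUE
    } else {
      in_m6 <- function(d) d >= m6[1] & d < m6[2]
      res$dra[i] <- any(in_m6(d7)) && any(in_m6(d8))
    }
  }
  res
}

#' Terminal depths of photoreceptor skeletons
#'
#' The terminal of an unbranched axon is its deepest tip: the leaf node with
#' the maximal depth fraction.
#'
#' @param skeletons List of photoreceptor [skeleton()]s named `R7_<col>` /
#'   `R8_<col>` or with an explicit `column_map`.
#' @param axis Depth axis.
#' @param column_map Optional data frame `cell_id,column_id,pr`; by default
#'   both are parsed from the skeleton names.
#' @return Data frame `column_id,cell_id,pr,terminal_depth_pct`.
#' @export
terminal_depths <- function(skeletons, axis = slab_depth_axis(),
                            column_map = NULL) {
  rows <- lapply(skeletons, function(s) {
    d <- depth_fraction(skeleton_coords(s), axis)
    data.frame(cell_id = s$cell_id, terminal_depth_pct = max(d))
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (is.null(column_map)) {
    out$pr <- sub("_.*$", "", out$cell_id)
    out$column_id <- sub("^R[78]_", "", out$cell_id)
  } else {
    m <- match(out$cell_id, column_map$cell_id)
    out$pr <- column_map$pr[m]
    out$column_id <- column_map$column_id[m]
  }
  out[c("column_id", "cell_id", "pr", "terminal_depth_pct")]
}

#' Assign all column identities (pale / yellow / DRA)
#'
#' Composite of [detect_dra_columns()] and [pale_from_ame12()]: DRA flags
#' are set first and override pale claims; every column ends with exactly
#' one subtype, so pale, yellow and DRA partition the column set
#' (indeterminate DRA columns are left to the mosaic assignment).
#'
#' @param columns Column table (subtype ignored on input).
#' @param terminals Terminal-depth table (see [detect_dra_columns()]).
#' @param ame12_skeletons List of aMe12-like skeletons.
#' @param frame Medulla [layer_frame()].
#' @param axis Depth axis.
#' @return List with `columns` (subtype set), `provenance`, `dra_report`.
#' @export
assign_column_identities <- function(columns, terminals, ame12_skeletons,
                                     frame = layer_frame("medulla"),
                                     axis = slab_depth_axis()) {
  dra <- detect_dra_columns(terminals, columns, frame)
  columns$subtype <- ifelse(dra$dra, "DRA", NA_character_)
  res <- pale_from_ame12(ame12_skeletons, columns, frame, axis)
  list(columns = res$columns, provenance = res$provenance, dra_report = dra)
}
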