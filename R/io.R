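# Readers and writers for the interchange formats: SWC skeletons and CSV
# synapse / cell / column tables, plus referential-integrity validation.
#
# SWC dialect: 7 whitespace-separated columns (id, type, x, y, z, radius,
# parent), '#' comments, parent -1 for the root. Node ids are arbitrary
# positive integers (not required contiguous). Coordinates are nm unless
# stated otherwise.

#' Construct a skeleton
#'
#' A skeleton is the rooted tree of 3-D nodes of one reconstructed cell.
#'
#' @param cell_id Cell identifier (character).
#' @param nodes Data frame with columns `node_id`, `parent_id` (NA for the
#'   root), `x`, `y`, `z` (nm), `radius` (nm) and optionally `type`.
#' @return Object of class `skeleton`.
#' @export
skeleton <- function(cell_id, nodes) {
  stopifnot(is.data.frame(nodes),
            all(c("node_id", "parent_id", "x", "y", "z", "radius") %in% names(nodes)))
  if (is.null(nodes$type)) nodes$type <- 0L
  .validate_skeleton_tree(nodes)
  root <- nodes$node_id[is.na(nodes$parent_id)]
  structure(list(cell_id = as.character(cell_id),
                 nodes = nodes[c("node_id", "type", "x", "y", "z", "radius",
                                 "parent_id")],
                 root = root),
            class = "skeleton")
}

.validate_skeleton_tree <- function(nodes, lines = NULL) {
  where <- function(i) if (is.null(lines)) "" else paste0(" (line ", lines[i], ")")
  if (anyDuplicated(nodes$node_id)) {
    i <- which(duplicated(nodes$node_id))[1]
    stop("duplicate node id ", nodes$node_id[i], where(i))
  }
  roots <- which(is.na(nodes$parent_id))
  if (length(roots) == 0) stop("no root node (parent -1) found")
  if (length(roots) > 1)
    stop("multiple roots: nodes ",
         paste(nodes$node_id[roots], collapse = ", "), where(roots[2]))
  parent_idx <- match(nodes$parent_id, nodes$node_id)
  dangling <- which(!is.na(nodes$parent_id) & is.na(parent_idx))
  if (length(dangling) > 0)
    stop("dangling parent id ", nodes$parent_id[dangling[1]], where(dangling[1]))
  # tree check: n_edges = n_nodes - 1 holds by construction (each non-root
  # has one parent); cycles are detected by walking to the root
  n <- nrow(nodes)
  for (i in seq_len(n)) {
    steps <- 0L; j <- i
    while (!is.na(nodes$parent_id[j])) {
      j <- parent_idx[j]
      steps <- steps + 1L
      if (steps > n) stop("cycle detected involving node ", nodes$node_id[i],
                          where(i))
    }
  }
  invisible(TRUE)
}

#' @export
print.skeleton <- function(x, ...) {
  cat("<skeleton>", x$cell_id, "-", nrow(x$nodes), "nodes, root", x$root, "\n")
  invisible(x)
}

#' Read an SWC skeleton file
#'
#' @param path Path to an SWC file.
#' @param cell_id Cell identifier; defaults to the file name without
#'   extension.
#' @param units Coordinate units in the file, `"nm"` (default) or `"um"`;
#'   coordinates are stored internally in nm.
#' @return A [skeleton()].
#' @export
read_skeleton <- function(path, cell_id = NULL, units = c("nm", "um")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(cell_id)) cell_id <- sub("\\.swc$", "", basename(path))
  raw <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (length(keep) == 0) stop("no SWC records in ", path)
  fields <- strsplit(trimws(raw[keep]), "\\s+")
  bad <- which(lengths(fields) != 7)
  if (length(bad) > 0)
    stop("malformed SWC line ", keep[bad[1]], " in ", path,
         ": expected 7 fields, got ", lengths(fields)[bad[1]])
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 7,
              byrow = TRUE)
  nn <- which(apply(m, 1, function(r) any(is.na(r))))
  if (length(nn) > 0)
    stop("non-numeric field on SWC line ", keep[nn[1]], " in ", path)
  scale <- if (units == "um") NM_PER_UM else 1
  nodes <- data.frame(node_id = as.integer(m[, 1]),
                      parent_id = ifelse(m[, 7] == -1, NA_integer_,
                                         as.integer(m[, 7])),
                      x = m[, 3] * scale, y = m[, 4] * scale,
                      z = m[, 5] * scale, radius = m[, 6] * scale,
                      type = as.integer(m[, 2]))
  tryCatch(.validate_skeleton_tree(nodes, lines = keep),
           error = function(e) stop("invalid skeleton in ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
  skeleton(cell_id, nodes)
}

#' Write a skeleton as SWC
#' @param skel A [skeleton()].
#' @param path Output file.
#' @param units Units to write, `"nm"` (default) or `"um"`.
#' @export
write_skeleton <- function(skel, path, units = c("nm", "um")) {
  units <- match.arg(units)
  stopifnot(inherits(skel, "skeleton"))
  scale <- if (units == "um") 1 / NM_PER_UM else 1
  n <- skel$nodes
  lines <- sprintf("%d %d %.9g %.9g %.9g %.9g %d",
                   n$node_id, n$type, n$x * scale, n$y * scale, n$z * scale,
                   n$radius * scale,
                   ifelse(is.na(n$parent_id), -1L, n$parent_id))
  writeLines(c(paste0("# SWC export of cell ", skel$cell_id), lines), path)
  invisible(path)
}

#' All node coordinates of a skeleton
#' @param skel A [skeleton()].
#' @return n x 3 matrix (nm).
#' @export
skeleton_coords <- function(skel) {
  as.matrix(skel$nodes[c("x", "y", "z")])
}

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    stop("missing mandatory column(s) in ", what, ": ",
         paste(missing, collapse = ", "))
}

#' Read a synapse table
#'
#' CSV with header `synapse_id,pre_cell,post_cell,x,y,z[,compartment]`; one
#' record per presynaptic/postsynaptic pairing at a T-bar, coordinates in nm.
#' The `compartment` column (medulla / chiasm / other) is optional and left
#' `NA` when absent.
#'
#' @param path CSV file.
#' @param allow_autapses Keep records with `pre_cell == post_cell`
#'   (default `FALSE`: autapses are rejected).
#' @return Data frame of synapse records.
#' @export
read_synapse_table <- function(path, allow_autapses = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  .require_columns(df, c("synapse_id", "pre_cell", "post_cell", "x", "y", "z"),
                   "synapse table")
  for (cc in c("x", "y", "z")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (nrow(df) > 0 && any(is.na(v)))
      stop("non-numeric coordinate in column '", cc, "', row ",
           which(is.na(v))[1])
    df[[cc]] <- v
  }
  if (is.null(df$compartment))
    df$compartment <- rep(NA_character_, nrow(df))
  df$compartment[!is.na(df$compartment) & df$compartment == ""] <- NA_character_
  if (!allow_autapses && nrow(df) > 0 && any(df$pre_cell == df$post_cell))
    stop("autapse(s) present (pre_cell == post_cell), e.g. cell ",
         df$pre_cell[df$pre_cell == df$post_cell][1],
         "; use allow_autapses = TRUE to keep them")
  df[c("synapse_id", "pre_cell", "post_cell", "x", "y", "z", "compartment")]
}

#' Write a synapse table
#' @param synapses Data frame as returned by [read_synapse_table()].
#' @param path Output file.
#' @export
write_synapse_table <- function(synapses, path) {
  out <- synapses[c("synapse_id", "pre_cell", "post_cell", "x", "y", "z",
                    "compartment")]
  out$compartment[is.na(out$compartment)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cell annotation table
#'
#' CSV with header `cell_id,type_label,class_label,status[,subtype_tag]`.
#' `status` is one of `identified_type`, `identified_class`, `unidentified`;
#' `subtype_tag` marks photoreceptors (`pR7`, `yR7`, `pR8`, `yR8`,
#' `R7-DRA`, `R8-DRA`).
#'
#' @param path CSV file.
#' @return Data frame of cell records.
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  .require_columns(df, c("cell_id", "type_label", "class_label", "status"),
                   "cell table")
  if (is.null(df$subtype_tag)) df$subtype_tag <- NA_character_
  for (cc in c("type_label", "class_label", "subtype_tag"))
    df[[cc]][!is.na(df[[cc]]) & df[[cc]] == ""] <- NA_character_
  bad <- setdiff(unique(df$status),
                 c("identified_type", "identified_class", "unidentified"))
  if (length(bad) > 0) stop("unknown status value(s): ",
                            paste(bad, collapse = ", "))
  i <- which(df$status == "identified_type" & is.na(df$type_label))
  if (length(i) > 0) stop("identified_type cell without type_label: ",
                          df$cell_id[i[1]])
  i <- which(df$status == "identified_class" & is.na(df$class_label))
  if (length(i) > 0) stop("identified_class cell without class_label: ",
                          df$cell_id[i[1]])
  df[c("cell_id", "type_label", "class_label", "status", "subtype_tag")]
}

#' Write a cell annotation table
#' @param cells Data frame as returned by [read_cell_table()].
#' @param path Output file.
#' @export
write_cell_table <- function(cells, path) {
  out <- cells[c("cell_id", "type_label", "class_label", "status",
                 "subtype_tag")]
  for (cc in c("type_label", "class_label", "subtype_tag"))
    out[[cc]][is.na(out[[cc]])] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a column table
#'
#' CSV with header `column_id,x,y,z,subtype`; coordinates in nm, subtype in
#' pale / yellow / DRA (may be empty before assignment).
#'
#' @param path CSV file.
#' @return Data frame of column records.
#' @export
read_column_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  .require_columns(df, c("column_id", "x", "y", "z", "subtype"), "column table")
  for (cc in c("x", "y", "z")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (nrow(df) > 0 && any(is.na(v)))
      stop("non-numeric coordinate in column '", cc, "', row ",
           which(is.na(v))[1])
    df[[cc]] <- v
  }
  df$subtype[!is.na(df$subtype) & df$subtype == ""] <- NA_character_
  if (anyDuplicated(df$column_id))
    stop("duplicate column_id: ", df$column_id[duplicated(df$column_id)][1])
  df[c("column_id", "x", "y", "z", "subtype")]
}

#' Write a column table
#' @param columns Data frame as returned by [read_column_table()].
#' @param path Output file.
#' @export
write_column_table <- function(columns, path) {
  out <- columns[c("column_id", "x", "y", "z", "subtype")]
  out$subtype[is.na(out$subtype)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Referential-integrity validation of a dataset
#'
#' Report-only check that the synapse table, the cell annotations and the
#' skeleton set are mutually consistent: every synapse endpoint is an
#' annotated cell, every annotated cell has a skeleton, and identifiers are
#' unique. The report is empty if and only if the dataset is consistent.
#'
#' @param skeletons List of [skeleton()] objects.
#' @param synapses Synapse data frame.
#' @param cells Cell data frame.
#' @return Data frame with columns `kind` (`unknown_cell`, `no_skeleton`,
#'   `duplicate_id`), `id` and `detail`.
#' @export
validate_dataset <- function(skeletons, synapses, cells) {
  rep_rows <- list()
  add <- function(kind, id, detail)
    rep_rows[[length(rep_rows) + 1]] <<- data.frame(kind = kind, id = id,
                                                    detail = detail)
  skel_ids <- vapply(skeletons, function(s) s$cell_id, character(1))
  for (id in skel_ids[duplicated(skel_ids)])
    add("duplicate_id", id, "duplicate skeleton cell_id")
  for (id in cells$cell_id[duplicated(cells$cell_id)])
    add("duplicate_id", id, "duplicate cell_id in cell table")
  for (id in synapses$synapse_id[duplicated(synapses$synapse_id)])
    add("duplicate_id", id, "duplicate synapse_id")
  known <- unique(cells$cell_id)
  for (side in c("pre_cell", "post_cell")) {
    miss <- unique(synapses[[side]][!(synapses[[side]] %in% known)])
    for (id in miss)
      add("unknown_cell", id, paste0("synapse ", side, " not in cell table"))
  }
  for (id in setdiff(cells$cell_id, skel_ids))
    add("no_skeleton", id, "annotated cell without skeleton")
  if (length(rep_rows) == 0)
    return(data.frame(kind = character(0), id = character(0),
                      detail = character(0)))
  do.call(rbind, rep_rows)
}

#' Write a validation report as JSON
#' @param report Data frame from [validate_dataset()].
#' @param path Output file.
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(list(n_violations = nrow(report), violations = report),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
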