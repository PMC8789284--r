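# Edge counts and the per-cell-type connectivity summary schema: per-subtype
# synapse counts, derived percent columns, reliability threshold (>2
# synapses), selectivity calls (65% rule), identification-coverage
# statistics and optic-chiasm compartment breakdowns.

CENTRAL_SUBTYPES <- c("pR7", "yR7", "pR8", "yR8")
DRA_SUBTYPES <- c("R7-DRA", "R8-DRA")
POOLED_ROWS <- c("Identified_<3", "Unidentified_>=3", "Unidentified_<3")

#' Analysis configuration
#'
#' @param min_synapses Reliability threshold on the per-cell synapse total
#'   with the seed photoreceptors; the conventional choice is 3, i.e. ">2
#'   synapses".
#' @param selectivity_threshold Fraction of input from one source class
#'   above which a cell type is called selective (inclusive; conventional
#'   value 0.65).
#' @param percent_decimals Decimals for presented percentages (default 1).
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(min_synapses = 3L, selectivity_threshold = 0.65,
                            percent_decimals = 1L) {
  stopifnot(min_synapses >= 1,
            selectivity_threshold > 0.5, selectivity_threshold <= 1)
  structure(list(min_synapses = as.integer(min_synapses),
                 selectivity_threshold = selectivity_threshold,
                 percent_decimals = as.integer(percent_decimals)),
            class = "analysis_config")
}

# Presentation rounding. Published connectivity tables follow IEC 60559
# round-half-to-even (e.g. 39/48 -> 81.2, 27/48 -> 56.2), which is base R
# round(); internal arithmetic stays at full precision and rounding is
# applied only when a table is materialized.
.round_pct <- function(x, digits = 1) round(x, digits)

#' Edge counts relative to a seed photoreceptor set
#'
#' Aggregates a synapse table into one edge per ordered (pre, post) cell
#' pair, restricted to the chosen direction relative to the seed set:
#' `from_seed` keeps synapses whose presynaptic cell is a seed photoreceptor
#' (photoreceptor output), `to_seed` those whose postsynaptic cell is
#' (photoreceptor input).
#'
#' @param synapses Synapse table.
#' @param direction `"from_seed"` or `"to_seed"`.
#' @param seed_cells Character vector of seed photoreceptor cell ids.
#' @return Data frame `pre_cell,post_cell,n,n_chiasm` with attributes
#'   `direction` and `seed_cells`.
#' @export
edge_counts <- function(synapses, direction = c("from_seed", "to_seed"),
                        seed_cells) {
  direction <- match.arg(direction)
  if (length(seed_cells) == 0) stop("empty seed set")
  keep <- if (direction == "from_seed") synapses$pre_cell %in% seed_cells
          else synapses$post_cell %in% seed_cells
  s <- synapses[keep, , drop = FALSE]
  if (nrow(s) == 0) {
    out <- data.frame(pre_cell = character(0), post_cell = character(0),
                      n = integer(0), n_chiasm = integer(0))
  } else {
    key <- paste(s$pre_cell, s$post_cell, sep = "\r")
    agg <- tapply(seq_len(nrow(s)), key, function(i)
      c(n = length(i),
        n_chiasm = sum(!is.na(s$compartment[i]) &
                         s$compartment[i] == "chiasm")))
    keys <- strsplit(names(agg), "\r", fixed = TRUE)
    out <- data.frame(pre_cell = vapply(keys, `[`, character(1), 1),
                      post_cell = vapply(keys, `[`, character(1), 2),
                      n = vapply(agg, `[`, numeric(1), "n"),
                      n_chiasm = vapply(agg, `[`, numeric(1), "n_chiasm"),
                      row.names = NULL)
    out <- out[order(out$pre_cell, out$post_cell), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "direction") <- direction
  attr(out, "seed_cells") <- seed_cells
  out
}

#' Partition partner cells by the reliability threshold
#'
#' A partner cell is "reliable" when its synapse total across the seed set
#' reaches `min_synapses` (>2 synapses at the default).
#'
#' @param edges Result of [edge_counts()].
#' @param config An [analysis_config()].
#' @return List with `reliable` and `sub_threshold` (character vectors of
#'   partner cell ids) and `totals` (named totals).
#' @export
threshold_partition <- function(edges, config = analysis_config()) {
  partner <- if (attr(edges, "direction") == "from_seed") edges$post_cell
             else edges$pre_cell
  totals <- tapply(edges$n, partner, sum)
  list(reliable = names(totals)[totals >= config$min_synapses],
       sub_threshold = names(totals)[totals < config$min_synapses],
       totals = totals)
}

# shared percent-column arithmetic; counts = matrix with one column per
# source subtype, rows = summary rows (named types + pooled rows)
.summary_percents <- function(df, subtypes, config, dra) {
  sum_row <- rowSums(df[subtypes])
  r7_cols <- subtypes[grepl("R7", subtypes)]
  r8_cols <- subtypes[grepl("R8", subtypes)]
  r7 <- rowSums(df[, r7_cols, drop = FALSE])
  r8 <- rowSums(df[, r8_cols, drop = FALSE])
  grand <- sum(sum_row)
  tot_r7 <- sum(r7); tot_r8 <- sum(r8)
  pct <- function(num, den) {
    den <- rep_len(den, length(num))
    ifelse(den > 0, 100 * num / den, 0)
  }
  df$Sum <- sum_row
  df[["%R7"]] <- pct(r7, sum_row)
  df[["%R8"]] <- pct(r8, sum_row)
  if (!dra) {
    p <- rowSums(df[c("pR7", "pR8")])
    y <- rowSums(df[c("yR7", "yR8")])
    df[["%p"]] <- pct(p, sum_row)
    df[["%y"]] <- pct(y, sum_row)
  }
  df[["%Total"]] <- pct(sum_row, grand)
  df[["%Total_R7"]] <- pct(r7, tot_r7)
  df[["%Total_R8"]] <- pct(r8, tot_r8)
  attr(df, "grand_total") <- grand
  attr(df, "total_r7") <- tot_r7
  attr(df, "total_r8") <- tot_r8
  df
}

.finish_summary <- function(df, subtypes, config, dra) {
  df <- .summary_percents(df, subtypes, config, dra)
  named <- !(df$Type %in% POOLED_ROWS)
  df <- rbind(df[named, , drop = FALSE][order(-df$Sum[named]), , drop = FALSE],
              df[match(POOLED_ROWS, df$Type), , drop = FALSE])
  df <- df[!is.na(df$Type), , drop = FALSE]
  total <- df[1, , drop = FALSE]
  total$Type <- "Total"
  total$No. <- sum(df$No.)
  for (cc in c(subtypes, "Sum")) total[[cc]] <- sum(df[[cc]])
  total <- .summary_percents(total, subtypes, config, dra)
  # total row percentages are relative to itself except %Total* which are 100
  out <- rbind(df, total)
  pct_cols <- grep("^%", names(out), value = TRUE)
  unrounded <- out[pct_cols]
  for (cc in pct_cols)
    out[[cc]] <- .round_pct(out[[cc]], config$percent_decimals)
  rownames(out) <- NULL
  attr(out, "unrounded_percents") <- unrounded
  attr(out, "dra") <- dra
  class(out) <- c("type_summary", "data.frame")
  out
}

#' Per-type connectivity summary from per-cell edge counts
#'
#' Builds the standard connectivity-table schema: per cell type, the number
#' of reliable partner cells (`No.`), synapse counts per source
#' photoreceptor subtype, their `Sum`, and the derived percentages
#' `%R7 = 100 (pR7 + yR7)/Sum`, `%p = 100 (pR7 + pR8)/Sum`,
#' `%Total = 100 Sum/grand total`, `%Total_R7 = 100 (pR7 + yR7)/(all R7
#' synapses)` (analogously `%R8`, `%y`, `%Total_R8`). Sub-threshold
#' identified cells are pooled as `Identified_<3`, unidentified cells as
#' `Unidentified_>=3` / `Unidentified_<3`, and a `Total` row closes the
#' table. Cells identified only to class (status `identified_class`) are
#' tabulated under their class label. Percentages are half-up rounded at
#' presentation only; unrounded values are kept in the
#' `"unrounded_percents"` attribute.
#'
#' @param edges Result of [edge_counts()].
#' @param cells Cell table (provides partner status/type and seed subtype
#'   tags).
#' @param config An [analysis_config()].
#' @return A `type_summary` data frame (central schema with columns
#'   `Type,No.,pR7,yR7,pR8,yR8,Sum,%R7,%R8,%p,%y,%Total,%Total_R7,%Total_R8`,
#'   or the DRA schema with `DRAR7,DRAR8` and no mosaic columns).
#' @export
type_summary <- function(edges, cells, config = analysis_config()) {
  direction <- attr(edges, "direction")
  partner <- if (direction == "from_seed") edges$post_cell else edges$pre_cell
  source <- if (direction == "from_seed") edges$pre_cell else edges$post_cell
  tag <- cells$subtype_tag[match(source, cells$cell_id)]
  if (any(is.na(tag)))
    stop("seed photoreceptor(s) without subtype_tag: ",
         paste(unique(source[is.na(tag)])[1:min(3, sum(is.na(tag)))],
               collapse = ", "))
  dra <- all(tag %in% DRA_SUBTYPES)
  if (!dra && any(tag %in% DRA_SUBTYPES))
    stop("mixed central and DRA seed subtypes; summarize them separately")
  subtypes <- if (dra) DRA_SUBTYPES else CENTRAL_SUBTYPES
  ci <- match(partner, cells$cell_id)
  status <- cells$status[ci]
  if (any(is.na(status)))
    stop("partner cell(s) missing from the cell table: ",
         unique(partner[is.na(status)])[1])
  per_cell <- rowsum(edges$n, group = partner)
  reliable <- rownames(per_cell)[per_cell[, 1] >= config$min_synapses]
  row_label <- function(cell) {
    i <- match(cell, cells$cell_id)
    rel <- cell %in% reliable
    if (cells$status[i] == "unidentified")
      return(if (rel) "Unidentified_>=3" else "Unidentified_<3")
    if (!rel) return("Identified_<3")
    if (cells$status[i] == "identified_type") cells$type_label[i]
    else cells$class_label[i]
  }
  labels_per_cell <- vapply(unique(partner), row_label, character(1))
  lab_of_edge <- labels_per_cell[match(partner, unique(partner))]
  all_labels <- unique(c(setdiff(labels_per_cell, POOLED_ROWS), POOLED_ROWS))
  counts <- matrix(0, nrow = length(all_labels), ncol = length(subtypes),
                   dimnames = list(all_labels, subtypes))
  for (k in seq_len(nrow(edges)))
    counts[lab_of_edge[k], tag[k]] <- counts[lab_of_edge[k], tag[k]] + edges$n[k]
  n_cells <- table(factor(labels_per_cell, levels = all_labels))
  df <- data.frame(Type = all_labels, No. = as.integer(n_cells),
                   check.names = FALSE)
  for (st in subtypes)
    df[[if (dra) sub("(R[78])-DRA", "DRA\\1", st) else st]] <- counts[, st]
  subcols <- if (dra) c("DRAR7", "DRAR8") else CENTRAL_SUBTYPES
  # drop empty pooled rows except keep schema rows with zero counts
  .finish_summary(df, subcols, config, dra)
}

#' Per-type connectivity summary from aggregated counts
#'
#' Same schema as [type_summary()], starting from already-aggregated
#' per-type counts (e.g. a transcribed printed table): columns `Type`, `No.`
#' and the per-subtype counts (`pR7,yR7,pR8,yR8` central, `DRAR7,DRAR8`
#' DRA). Pooled rows are kept as given; the Total row and all percent
#' columns are recomputed.
#'
#' @param counts Data frame of per-type counts.
#' @param config An [analysis_config()].
#' @return A `type_summary` data frame.
#' @export
type_summary_from_counts <- function(counts, config = analysis_config()) {
  dra <- all(c("DRAR7", "DRAR8") %in% names(counts))
  subcols <- if (dra) c("DRAR7", "DRAR8") else CENTRAL_SUBTYPES
  .require_columns(counts, c("Type", "No.", subcols), "count table")
  df <- counts[counts$Type != "Total", c("Type", "No.", subcols)]
  for (cc in subcols) df[[cc]] <- as.numeric(df[[cc]])
  df$No. <- as.integer(df$No.)
  .finish_summary(df, subcols, config, dra)
}

#' @export
print.type_summary <- function(x, ...) {
  cat("Connectivity summary (", if (attr(x, "dra")) "DRA" else "central",
      " schema, ", nrow(x) - 1, " rows + Total)\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Write a connectivity summary as CSV
#'
#' Column order mirrors the printed-table headers exactly:
#' `Type,No.,pR7,yR7,pR8,yR8,Sum,%R7,%R8,%p,%y,%Total,%Total_R7,%Total_R8`
#' (DRA variant `Type,No.,DRAR7,DRAR8,Sum,%R7,%R8,%Total,%Total_R7,%Total_R8`).
#'
#' @param summary A `type_summary`.
#' @param path Output file.
#' @export
write_type_summary <- function(summary, path) {
  stopifnot(inherits(summary, "type_summary"))
  utils::write.csv(as.data.frame(summary), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Selectivity calls for summary rows
#'
#' A type is R7-selective when at least `selectivity_threshold` (inclusive)
#' of its photoreceptor input comes from R7 (likewise R8, pale, yellow);
#' otherwise mixed on that axis. Calls are made on unrounded percentages
#' recomputed from the count columns.
#'
#' @param summary A `type_summary` (pooled and Total rows are skipped).
#' @param config An [analysis_config()].
#' @return Data frame `Type,source_axis,mosaic_axis` (mosaic axis `NA` for
#'   the DRA schema, which has no pale/yellow mosaic).
#' @export
selectivity_call <- function(summary, config = analysis_config()) {
  stopifnot(inherits(summary, "type_summary"))
  dra <- attr(summary, "dra")
  rows <- summary[!(summary$Type %in% c(POOLED_ROWS, "Total")), , drop = FALSE]
  th <- 100 * config$selectivity_threshold
  r7 <- if (dra) rows$DRAR7 else rows$pR7 + rows$yR7
  r8 <- if (dra) rows$DRAR8 else rows$pR8 + rows$yR8
  tot <- r7 + r8
  src <- ifelse(100 * r7 / tot >= th, "R7-selective",
                ifelse(100 * r8 / tot >= th, "R8-selective", "mixed"))
  if (dra) {
    mosaic <- NA_character_
  } else {
    p <- rows$pR7 + rows$pR8
    y <- rows$yR7 + rows$yR8
    mosaic <- ifelse(100 * p / tot >= th, "pale-selective",
                     ifelse(100 * y / tot >= th, "yellow-selective", "mixed"))
  }
  data.frame(Type = rows$Type, source_axis = src, mosaic_axis = mosaic)
}

#' Identification-coverage statistics
#'
#' Fractions of seed-photoreceptor synapses that land on identified cells:
#' overall, restricted to reliable (>2-synapse) cells, plus the fraction of
#' reliable cells that are identified. Reported as half-up-rounded percents
#' (1 decimal).
#'
#' @param edges Result of [edge_counts()].
#' @param cells Cell table.
#' @param config An [analysis_config()].
#' @return List: `pct_synapses_identified`, `pct_synapses_identified_reliable`,
#'   `pct_reliable_cells_identified`, and the underlying counts.
#' @export
coverage_stats <- function(edges, cells, config = analysis_config()) {
  direction <- attr(edges, "direction")
  partner <- if (direction == "from_seed") edges$post_cell else edges$pre_cell
  status <- cells$status[match(partner, cells$cell_id)]
  identified <- status %in% c("identified_type", "identified_class")
  total <- sum(edges$n)
  id_syn <- sum(edges$n[identified])
  part <- threshold_partition(edges, config)
  rel <- partner %in% part$reliable
  total_rel <- sum(edges$n[rel])
  id_rel <- sum(edges$n[rel & identified])
  rel_cells <- part$reliable
  rel_status <- cells$status[match(rel_cells, cells$cell_id)]
  pct <- function(a, b) if (b > 0) .round_pct(100 * a / b, 1) else 0
  list(pct_synapses_identified = pct(id_syn, total),
       pct_synapses_identified_reliable = pct(id_rel, total_rel),
       pct_reliable_cells_identified =
         pct(sum(rel_status %in% c("identified_type", "identified_class")),
             length(rel_cells)),
       n_synapses = total, n_synapses_identified = id_syn,
       n_synapses_reliable = total_rel,
       n_synapses_identified_reliable = id_rel,
       n_reliable_cells = length(rel_cells))
}

#' Coverage statistics from aggregated summary counts
#'
#' Computes the same identification-coverage percentages from one or more
#' per-type count tables (the pooled rows `Identified_<3`,
#' `Unidentified_>=3`, `Unidentified_<3` carry the sub-threshold and
#' unidentified synapses). Several tables (e.g. the central and DRA output
#' tables) are combined by summation.
#'
#' @param ... Count data frames (each with `Type` and per-subtype counts or
#'   a precomputed `Sum`).
#' @return List: `pct_synapses_identified` (all synapses on cells identified
#'   to type or class), `pct_synapses_identified_reliable` (restricted to
#'   cells at or above the reliability threshold), plus the counts.
#' @export
coverage_from_summary <- function(...) {
  tables <- list(...)
  row_sum <- function(df) {
    if (!is.null(df$Sum)) return(as.numeric(df$Sum))
    subcols <- intersect(c(CENTRAL_SUBTYPES, "DRAR7", "DRAR8"), names(df))
    Reduce(`+`, lapply(df[subcols], as.numeric))
  }
  tot <- 0; unid <- 0; lt3 <- 0; unid_ge3 <- 0
  for (df in tables) {
    df <- df[df$Type != "Total", , drop = FALSE]
    s <- row_sum(df)
    tot <- tot + sum(s)
    unid <- unid + sum(s[df$Type %in% c("Unidentified_>=3",
                                        "Unidentified_<3")])
    lt3 <- lt3 + sum(s[df$Type %in% c("Identified_<3", "Unidentified_<3")])
    unid_ge3 <- unid_ge3 + sum(s[df$Type == "Unidentified_>=3"])
  }
  ge3 <- tot - lt3
  list(pct_synapses_identified = .round_pct(100 * (tot - unid) / tot, 1),
       pct_synapses_identified_reliable =
         .round_pct(100 * (ge3 - unid_ge3) / ge3, 1),
       n_synapses = tot, n_synapses_identified = tot - unid,
       n_synapses_reliable = ge3,
       n_synapses_identified_reliable = ge3 - unid_ge3)
}

#' Optic-chiasm compartment breakdown
#'
#' Fraction of synapses located in the optic chiasm (outside the medulla),
#' per source photoreceptor subtype and per partner cell type. Every synapse
#' contributing to `edges` must carry a compartment; offenders are listed in
#' the error.
#'
#' @param edges Result of [edge_counts()] built from a synapse table whose
#'   `compartment` is fully set (e.g. via [tag_compartments()]).
#' @param synapses The synapse table the edges were built from.
#' @param cells Cell table.
#' @return List with `by_subtype` and `by_partner_type` data frames
#'   (`n`, `n_chiasm`, `chiasm_fraction`).
#' @export
compartment_breakdown <- function(edges, synapses, cells) {
  direction <- attr(edges, "direction")
  seed <- attr(edges, "seed_cells")
  keep <- if (direction == "from_seed") synapses$pre_cell %in% seed
          else synapses$post_cell %in% seed
  s <- synapses[keep, , drop = FALSE]
  if (any(is.na(s$compartment)))
    stop("compartment unset on synapse(s): ",
         paste(utils::head(s$synapse_id[is.na(s$compartment)], 5),
               collapse = ", "))
  src <- if (direction == "from_seed") s$pre_cell else s$post_cell
  partner <- if (direction == "from_seed") s$post_cell else s$pre_cell
  tag <- cells$subtype_tag[match(src, cells$cell_id)]
  ptype <- cells$type_label[match(partner, cells$cell_id)]
  ptype[is.na(ptype)] <- "unidentified"
  brk <- function(group) {
    n <- tapply(rep(1, nrow(s)), group, sum)
    nc <- tapply(s$compartment == "chiasm", group, sum)
    data.frame(group = names(n), n = as.integer(n),
               n_chiasm = as.integer(nc),
               chiasm_fraction = as.numeric(nc / n), row.names = NULL)
  }
  list(by_subtype = brk(tag), by_partner_type = brk(ptype))
}

#' Tag synapse compartments from depth
#'
#' Synapses at negative depth fraction (distal to the distal neuropil
#' surface, i.e. in the optic chiasm) are tagged `chiasm`; those in
#' `[0, 100]` `medulla`; deeper ones `other`. Existing tags are preserved
#' unless `overwrite = TRUE`.
#'
#' @param synapses Synapse table.
#' @param axis Depth axis.
#' @param overwrite Replace existing tags.
#' @return The synapse table with `compartment` filled.
#' @export
tag_compartments <- function(synapses, axis = slab_depth_axis(),
                             overwrite = FALSE) {
  d <- depth_fraction(as.matrix(synapses[c("x", "y", "z")]), axis)
  tag <- ifelse(d < 0, "chiasm", ifelse(d <= 100, "medulla", "other"))
  if (overwrite) synapses$compartment <- tag
  else synapses$compartment <- ifelse(is.na(synapses$compartment), tag,
                                      synapses$compartment)
  synapses
}

#' Pale-fraction statistic
#'
#' @param columns Column table with subtype set, or a list with elements
#'   `n_pale` and `n_total`.
#' @return List `n_pale`, `n_total`, `pct` (integer percent, half-up).
#' @examples
#' pale_fraction(list(n_pale = 297, n_total = 779))$pct  # 38
#' @export
pale_fraction <- function(columns) {
  if (is.data.frame(columns)) {
    n_pale <- sum(columns$subtype == "pale", na.rm = TRUE)
    n_total <- nrow(columns)
  } else {
    n_pale <- columns$n_pale; n_total <- columns$n_total
  }
  list(n_pale = n_pale, n_total = n_total,
       pct = .round_pct(100 * n_pale / n_total, 0))
}
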