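#' Gate specifications
#'
#' A gate is a Boolean predicate tree over marker values. Leaves are either
#' simple thresholds or 2-D polygon gates (the two gate types used in manual
#' cytometry analysis); internal nodes combine children with AND / OR / NOT.
#'
#' @param marker,marker_x,marker_y Marker names the predicate reads.
#' @param op Comparison operator, one of `">"`, `">="`, `"<"`, `"<="`.
#' @param value Threshold on the transformed scale.
#' @param vertices Two-column matrix (x, y) of polygon vertices, >= 3 rows.
#' @param ... Child gates.
#' @param gate Gate to negate.
#' @param name Optional gate name.
#' @return An object of class `gate_spec`.
#' @export
gate_threshold <- function(marker, op, value, name = NULL) {
  if (!op %in% c(">", ">=", "<", "<=")) abort("invalid threshold operator")
  new_gate(list(type = "threshold", marker = marker, op = op,
                value = value), name)
}

#' @rdname gate_threshold
#' @export
gate_polygon <- function(marker_x, marker_y, vertices, name = NULL) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L) abort("polygon gates need at least 3 vertices")
  new_gate(list(type = "polygon", marker_x = marker_x, marker_y = marker_y,
                vertices = unname(vertices)), name)
}

#' @rdname gate_threshold
#' @export
gate_and <- function(..., name = NULL) {
  new_gate(list(type = "and", children = list(...)), name)
}

#' @rdname gate_threshold
#' @export
gate_or <- function(..., name = NULL) {
  new_gate(list(type = "or", children = list(...)), name)
}

#' @rdname gate_threshold
#' @export
gate_not <- function(gate, name = NULL) {
  new_gate(list(type = "not", children = list(gate)), name)
}

new_gate <- function(node, name = NULL) {
  node$name <- name
  structure(node, class = "gate_spec")
}

#' @export
print.gate_spec <- function(x, ...) {
  cat("<gate_spec>", format_gate(x), "\n")
  invisible(x)
}

format_gate <- function(g) {
  switch(g$type,
    threshold = paste0(g$marker, " ", g$op, " ", format(g$value)),
    polygon = paste0("polygon(", g$marker_x, ", ", g$marker_y, ", ",
                     nrow(g$vertices), " vertices)"),
    not = paste0("NOT(", format_gate(g$children[[1]]), ")"),
    paste0(toupper(g$type), "(",
           paste(vapply(g$children, format_gate, ""), collapse = ", "), ")")
  )
}

# Marker lookup: prefer the prefixed column (tfm__ by default), fall back to a
# bare column of the same name (RNA count tables).
gate_column <- function(cells, marker, prefix) {
  col <- paste0(prefix, "__", marker)
  if (col %in% names(cells)) return(cells[[col]])
  if (marker %in% names(cells)) return(cells[[marker]])
  abort(paste0("marker '", marker, "' not found in cell table"))
}

#' Evaluate a gate on a cell table
#'
#' Deterministic Boolean membership. Polygon membership uses ray casting with
#' points on the boundary counted as inside (stable under vertex jitter, the
#' convention of common cytometry tools).
#'
#' @param cells Cell table with transformed marker columns (`tfm__`), or any
#'   data frame whose bare columns match the gate's markers.
#' @param gate A [gate_threshold()] / [gate_polygon()] / combinator tree.
#' @param prefix Column prefix tried first when resolving markers.
#' @return Logical vector, one element per row of `cells`.
#' @export
apply_gate <- function(cells, gate, prefix = "tfm") {
  stopifnot(inherits(gate, "gate_spec") || is.list(gate))
  switch(gate$type,
    threshold = {
      v <- gate_column(cells, gate$marker, prefix)
      switch(gate$op,
             ">" = v > gate$value, ">=" = v >= gate$value,
             "<" = v < gate$value, "<=" = v <= gate$value)
    },
    polygon = {
      x <- gate_column(cells, gate$marker_x, prefix)
      y <- gate_column(cells, gate$marker_y, prefix)
      point_in_polygon(x, y, gate$vertices[, 1], gate$vertices[, 2])
    },
    and = Reduce(`&`, lapply(gate$children, apply_gate, cells = cells,
                             prefix = prefix)),
    or = Reduce(`|`, lapply(gate$children, apply_gate, cells = cells,
                            prefix = prefix)),
    not = !apply_gate(cells, gate$children[[1]], prefix = prefix),
    abort(paste0("unknown gate node type '", gate$type, "'"))
  )
}

#' Point-in-polygon test (ray casting, boundary inclusive)
#'
#' @param x,y Point coordinates (vectors).
#' @param vx,vy Polygon vertex coordinates.
#' @return Logical vector.
#' @export
point_in_polygon <- function(x, y, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(x))
  on_edge <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    # boundary: point on segment (x1,y1)-(x2,y2)
    cross <- (x - x1) * (y2 - y1) - (y - y1) * (x2 - x1)
    within <- pmin(x1, x2) - 1e-12 <= x & x <= pmax(x1, x2) + 1e-12 &
      pmin(y1, y2) - 1e-12 <= y & y <= pmax(y1, y2) + 1e-12
    on_edge <- on_edge | (abs(cross) < 1e-12 & within)
    # crossing rule (half-open in y to count shared vertices once)
    crosses <- ((y1 > y) != (y2 > y)) &
      (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Partition cells into the four IMC immune compartments
#'
#' Hierarchical Boolean gating on transformed CD19 / CD3 / CD45 signals:
#' B cells (CD19+), T cells (CD19- CD3+), other immune (CD19- CD3- CD45+) and
#' non-immune (CD19- CD3- CD45-). The labels are mutually exclusive and
#' exhaustive. Thresholds are dataset-specific configuration.
#'
#' @param cells Cell table with `tfm__CD19`, `tfm__CD3`, `tfm__CD45`.
#' @param thresholds Named numeric vector with elements `CD19`, `CD3`, `CD45`
#'   (transformed scale); a marker is "positive" strictly above its threshold.
#' @return `cells` with a `gate` column (factor with levels `B`, `T`,
#'   `other_immune`, `non_immune`).
#' @export
partition_compartments <- function(cells, thresholds) {
  need <- c("CD19", "CD3", "CD45")
  if (!all(need %in% names(thresholds)))
    abort("`thresholds` must name CD19, CD3 and CD45")
  v <- lapply(need, function(m) gate_column(cells, m, "tfm"))
  names(v) <- need
  pos <- lapply(need, function(m) v[[m]] > thresholds[[m]])
  names(pos) <- need
  gate <- dplyr::case_when(
    pos$CD19 ~ "B",
    pos$CD3 ~ "T",
    pos$CD45 ~ "other_immune",
    TRUE ~ "non_immune"
  )
  cells$gate <- factor(gate, levels = c("B", "T", "other_immune", "non_immune"))
  cells
}

rna_counts_df <- function(expr) {
  if (is.data.frame(expr)) return(expr)
  if (is.matrix(expr) || inherits(expr, "Matrix"))
    return(as.data.frame(as.matrix(expr)))
  abort("`expr` must be a cells x genes matrix or data frame")
}

require_genes <- function(df, genes) {
  missing <- setdiff(genes, names(df))
  if (length(missing))
    abort(paste0("missing gene column(s): ", paste(missing, collapse = ", ")))
}

#' Gate T cells in scRNA-seq counts
#'
#' Membership is `CD3E > 0 & (CD3D > 0 | CD3G > 0) & TRAC > 0`, evaluated on
#' raw counts. This removes NK cells, which lack CD3 chains and TCR alpha
#' constant-region transcripts, without relying on clustering.
#'
#' @param expr Cells x genes count matrix or data frame (raw counts).
#' @return Logical vector, one element per cell.
#' @export
gate_t_cells_rna <- function(expr) {
  df <- rna_counts_df(expr)
  require_genes(df, c("CD3E", "CD3D", "CD3G", "TRAC"))
  df$CD3E > 0 & (df$CD3D > 0 | df$CD3G > 0) & df$TRAC > 0
}

#' Gate CD8 T cells in scRNA-seq counts
#'
#' Membership is `(CD8A > 0 | CD8B > 0) & TRDC == 0 & TRGC1 == 0 &
#' TRGC2 == 0 & CD4 == 0` on raw counts (excluding gamma-delta and CD4
#' T cells), intended to be applied after [gate_t_cells_rna()].
#'
#' @inheritParams gate_t_cells_rna
#' @return Logical vector, one element per cell.
#' @export
gate_cd8_rna <- function(expr) {
  df <- rna_counts_df(expr)
  require_genes(df, c("CD8A", "CD8B", "TRDC", "TRGC1", "TRGC2", "CD4"))
  (df$CD8A > 0 | df$CD8B > 0) &
    df$TRDC == 0 & df$TRGC1 == 0 & df$TRGC2 == 0 & df$CD4 == 0
}

gate_to_list <- function(g) {
  out <- unclass(g)
  if (!is.null(out$children))
    out$children <- lapply(out$children, gate_to_list)
  if (!is.null(out$vertices))
    out$vertices <- lapply(seq_len(nrow(out$vertices)),
                           function(i) as.numeric(out$vertices[i, ]))
  out
}

gate_from_list <- function(l) {
  if (!is.null(l$children)) l$children <- lapply(l$children, gate_from_list)
  if (!is.null(l$vertices)) l$vertices <- do.call(rbind, l$vertices)
  structure(l, class = "gate_spec")
}

#' Serialize gates to / from YAML
#'
#' @param gates Named list of `gate_spec` objects (or a single gate).
#' @param path YAML file path.
#' @return `write_gates`: the path, invisibly; `read_gates`: a named list of
#'   `gate_spec` objects.
#' @export
write_gates <- function(gates, path) {
  if (inherits(gates, "gate_spec")) gates <- list(gate = gates)
  yaml::write_yaml(lapply(gates, gate_to_list), path)
  invisible(path)
}

#' @rdname write_gates
#' @export
read_gates <- function(path) {
  lapply(yaml::read_yaml(path), gate_from_list)
}
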