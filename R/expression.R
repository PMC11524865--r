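#' Read a long-format expression table
#'
#' Expected columns: `gene`, `cell_type`, `rpkm`, `fdr` (tab-delimited,
#' header row). RPKM is a non-negative abundance; `fdr` is the detection
#' false-discovery-rate value in \[0, 1\] carried over from the upstream
#' quantification, consumed as given and never recomputed.
#'
#' @param path path to the TSV file.
#' @return A validated data frame with the four canonical columns.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   na.strings = c("", "NA"), fileEncoding = "UTF-8")
  need <- c("gene", "cell_type", "rpkm", "fdr")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  df <- df[need]
  df$rpkm <- as.numeric(df$rpkm)
  df$fdr <- as.numeric(df$fdr)
  validate_expression(df)
  df
}

validate_expression <- function(df) {
  if (any(df$rpkm < 0, na.rm = TRUE)) stop("rpkm must be >= 0", call. = FALSE)
  if (any(df$fdr < 0 | df$fdr > 1, na.rm = TRUE)) {
    stop("fdr must be in [0, 1]", call. = FALSE)
  }
  key <- paste(df$gene, df$cell_type, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (gene, cell_type) rows", call. = FALSE)
  }
  invisible(df)
}

#' Presence call at the minimum-expression cutoff
#'
#' A gene is called expressed in a cell type when its abundance reaches the
#' RPKM cutoff and its detection FDR does not exceed the FDR cutoff. Both
#' comparisons are inclusive (`rpkm >= rpkm_min`, `fdr <= fdr_max`): the
#' cutoffs are the operational definitions of the reported tables, with the
#' threshold itself counting as detected.
#'
#' @param rpkm,fdr numeric vectors (recycled against each other).
#' @param rpkm_min minimum abundance, RPKM; default 0.1.
#' @param fdr_max maximum detection FDR; default 0.10.
#' @return Logical vector; `NA` abundance or FDR yields `FALSE`.
#' @export
#' @examples
#' call_expressed(c(0.5, 0.09, 5.0), c(0.01, 0.01, 0.5))
#' # TRUE FALSE FALSE
call_expressed <- function(rpkm, fdr, rpkm_min = 0.1, fdr_max = 0.10) {
  !is.na(rpkm) & !is.na(fdr) & rpkm >= rpkm_min & fdr <= fdr_max
}

# Per-group presence and expressed-member bookkeeping for one cell type.
# Returns list(present = logical per group, n_expressed_a = integer per
# group: expressed species-A members in this cell type).
group_calls_one <- function(groups, expr, cell_type, cell_species,
                            rpkm_min, fdr_max, semantics) {
  sp <- cell_species[[cell_type]]
  sub <- expr[expr$cell_type == cell_type, , drop = FALSE]
  called <- sub$gene[call_expressed(sub$rpkm, sub$fdr, rpkm_min, fdr_max)]
  col <- if (sp == "a") "members_a" else "members_b"
  n_expr <- vapply(groups[[col]], function(m) sum(m %in% called), integer(1))
  n_memb <- lengths(groups[[col]])
  present <- if (semantics == "any") n_expr >= 1L else n_expr == n_memb
  n_expr_a <- if (sp == "a") n_expr else integer(nrow(groups))
  list(present = present, n_expressed_a = n_expr_a)
}

#' Group-level presence in a cell type
#'
#' Lifts gene-level presence calls to ortholog groups: a group is present in
#' a cell type when any member gene of the species measured in that cell
#' type is called expressed there (`semantics = "any"`, the default); the
#' stricter all-members rule is available for sensitivity analysis.
#'
#' @param groups an `"ortholog_groups"` table.
#' @param expr long expression table (see [read_expression_table()]).
#' @param cell_type single cell-type label present in `expr`.
#' @param cell_species named character vector mapping cell-type labels to
#'   species `"a"` or `"b"`, e.g. `c(zHC = "a", zSC = "a", IHC = "b",
#'   OHC = "b")`.
#' @param rpkm_min,fdr_max presence cutoffs, see [call_expressed()].
#' @param semantics `"any"` (default) or `"all"`.
#' @return Logical vector, one element per group.
#' @export
group_presence <- function(groups, expr, cell_type, cell_species,
                           rpkm_min = 0.1, fdr_max = 0.10,
                           semantics = c("any", "all")) {
  semantics <- match.arg(semantics)
  if (!cell_type %in% expr$cell_type) {
    stop("cell type '", cell_type, "' absent from expression data",
         call. = FALSE)
  }
  if (!cell_type %in% names(cell_species)) {
    stop("cell type '", cell_type, "' missing from cell_species map",
         call. = FALSE)
  }
  group_calls_one(groups, expr, cell_type, cell_species,
                  rpkm_min, fdr_max, semantics)$present
}

#' Paralog-aware Venn partition of ortholog-group expression
#'
#' Assigns every ortholog group expressed somewhere to exactly one Venn
#' cell: the exact subset of cell types in which it is present (groups
#' present nowhere are dropped). Each cell counts its groups once
#' (`group_count`) and additionally tallies a `paralog_increment`: for each
#' group, the number of duplicated-species member genes expressed beyond the
#' first (`max(0, expressed members - 1)`), counting a member as expressed
#' if it is called in at least one duplicated-species cell type belonging to
#' the cell. These increments represent the extra paralogs of the duplicated
#' genome and attach to that species only.
#'
#' For every cell type `T`, summing `group_count` (plus `paralog_increment`
#' when `T` is a duplicated-species cell type) over the cells containing `T`
#' reproduces the per-cell-type expressed totals ([venn_totals()]).
#'
#' @inheritParams group_presence
#' @param cell_types ordered character vector of at least two cell-type
#'   labels, all present in `expr` and in `cell_species`.
#' @return A data frame of class `"venn_partition"`: one row per non-empty
#'   cell, logical membership columns (one per cell type), a `cell` label,
#'   `group_count` and `paralog_increment`. Attributes: `cell_types`,
#'   `dup_cell_types`, and `assignment` (named cell label per expressed
#'   group).
#' @seealso [venn_totals()], [as_venn_partition()]
#' @export
venn_partition <- function(groups, expr, cell_types, cell_species,
                           rpkm_min = 0.1, fdr_max = 0.10,
                           semantics = c("any", "all")) {
  semantics <- match.arg(semantics)
  if (length(cell_types) < 2) stop("need at least two cell types",
                                   call. = FALSE)
  miss <- setdiff(cell_types, unique(expr$cell_type))
  if (length(miss)) stop("cell type(s) absent from expression data: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(cell_types, names(cell_species))
  if (length(miss)) stop("cell type(s) missing from cell_species map: ",
                         paste(miss, collapse = ", "), call. = FALSE)

  calls <- lapply(cell_types, function(ct) {
    group_calls_one(groups, expr, ct, cell_species, rpkm_min, fdr_max,
                    semantics)
  })
  names(calls) <- cell_types
  present <- vapply(calls, `[[`, logical(nrow(groups)), "present")
  present <- matrix(present, nrow = nrow(groups),
                    dimnames = list(NULL, cell_types))
  n_expr_a <- vapply(calls, `[[`, integer(nrow(groups)), "n_expressed_a")
  n_expr_a <- matrix(n_expr_a, nrow = nrow(groups),
                     dimnames = list(NULL, cell_types))

  dup_cells <- cell_types[cell_species[cell_types] == "a"]
  keep <- rowSums(present) > 0
  if (!any(keep)) {
    cells <- empty_venn_cells(cell_types)
    return(structure(cells, cell_types = cell_types,
                     dup_cell_types = dup_cells,
                     assignment = character(0),
                     class = c("venn_partition", "data.frame")))
  }
  presentk <- present[keep, , drop = FALSE]
  called_by_ct <- lapply(dup_cells, function(ct) {
    sub <- expr[expr$cell_type == ct, , drop = FALSE]
    sub$gene[call_expressed(sub$rpkm, sub$fdr, rpkm_min, fdr_max)]
  })
  names(called_by_ct) <- dup_cells
  kept_idx <- which(keep)
  # expressed duplicated-species members within the group's own cell:
  # a member counts if called in any dup cell type the group is present in
  n_a_cell <- vapply(seq_along(kept_idx), function(i) {
    in_cell <- dup_cells[presentk[i, dup_cells]]
    if (!length(in_cell)) return(0L)
    grp_a <- groups$members_a[[kept_idx[i]]]
    if (!length(grp_a)) return(0L)
    sum(grp_a %in% unlist(called_by_ct[in_cell], use.names = FALSE))
  }, integer(1))
  increment <- pmax(0L, n_a_cell - 1L)

  labels <- apply(presentk, 1, function(r) {
    paste(cell_types[r], collapse = "+")
  })
  agg_count <- tapply(rep(1L, length(labels)), labels, sum)
  agg_inc <- tapply(increment, labels, sum)
  cell_labels <- names(agg_count)
  memb <- t(vapply(strsplit(cell_labels, "+", fixed = TRUE),
                   function(s) cell_types %in% s, logical(length(cell_types))))
  colnames(memb) <- cell_types
  cells <- data.frame(cell = cell_labels, memb,
                      group_count = as.integer(agg_count),
                      paralog_increment = as.integer(agg_inc),
                      stringsAsFactors = FALSE, row.names = NULL,
                      check.names = FALSE)
  cells <- cells[order(-rowSums(memb), cells$cell), , drop = FALSE]
  rownames(cells) <- NULL
  assignment <- stats::setNames(labels, groups$group_id[keep])
  structure(cells, cell_types = cell_types, dup_cell_types = dup_cells,
            assignment = assignment,
            class = c("venn_partition", "data.frame"))
}

empty_venn_cells <- function(cell_types) {
  cells <- data.frame(cell = character(0), stringsAsFactors = FALSE)
  for (ct in cell_types) cells[[ct]] <- logical(0)
  cells$group_count <- integer(0)
  cells$paralog_increment <- integer(0)
  cells
}

#' Assemble a Venn partition from printed cell counts
#'
#' Builds a `"venn_partition"` object directly from per-cell counts (e.g. a
#' published Venn diagram with paralog counts in parentheses), so that the
#' partition-sum identity can be checked against printed totals.
#'
#' @param cells a data frame with columns `cell` (cell-type labels joined by
#'   `"+"`), `group_count`, and `paralog_increment`.
#' @param cell_types ordered character vector of all cell-type labels.
#' @param dup_cell_types labels belonging to the duplicated species.
#' @return A `"venn_partition"` data frame.
#' @export
#' @examples
#' p <- as_venn_partition(
#'   data.frame(cell = c("zHC+IHC+OHC", "zHC+IHC", "zHC+OHC", "zHC"),
#'              group_count = c(6659, 149, 322, 2831),
#'              paralog_increment = c(932, 25, 77, 0)),
#'   cell_types = c("zHC", "IHC", "OHC"), dup_cell_types = "zHC")
#' venn_totals(p)[["zHC"]]  # 10995
as_venn_partition <- function(cells, cell_types, dup_cell_types) {
  need <- c("cell", "group_count", "paralog_increment")
  miss <- setdiff(need, names(cells))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (anyDuplicated(cells$cell)) stop("duplicate cells", call. = FALSE)
  parts <- strsplit(cells$cell, "+", fixed = TRUE)
  unknown <- setdiff(unlist(parts), cell_types)
  if (length(unknown)) stop("unknown cell type(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  memb <- t(vapply(parts, function(s) cell_types %in% s,
                   logical(length(cell_types))))
  colnames(memb) <- cell_types
  out <- data.frame(cell = cells$cell, memb,
                    group_count = as.integer(cells$group_count),
                    paralog_increment = as.integer(cells$paralog_increment),
                    stringsAsFactors = FALSE, check.names = FALSE)
  structure(out, cell_types = cell_types,
            dup_cell_types = intersect(cell_types, dup_cell_types),
            assignment = NULL,
            class = c("venn_partition", "data.frame"))
}

#' Per-cell-type expressed totals from a Venn partition
#'
#' For each cell type `T`, sums `group_count` over the cells containing `T`;
#' for duplicated-species cell types the `paralog_increment` is added, since
#' the extra paralogs are expressed genes of that species.
#'
#' @param partition a `"venn_partition"` object.
#' @return Named numeric vector of totals, one per cell type.
#' @export
venn_totals <- function(partition) {
  cell_types <- attr(partition, "cell_types")
  dup <- attr(partition, "dup_cell_types")
  vapply(cell_types, function(ct) {
    m <- partition[[ct]]
    tot <- sum(partition$group_count[m])
    if (ct %in% dup) tot <- tot + sum(partition$paralog_increment[m])
    as.numeric(tot)
  }, numeric(1))
}

#' Genes uniquely expressed in a target cell type
#'
#' Selects genes called expressed in the target cell type whose abundance in
#' every reference cell type stays at or below `ref_max` RPKM (a gene with
#' no measurement in a reference is treated as not detected there). Result
#' is sorted by target RPKM, descending; ties break lexicographically by
#' gene identifier.
#'
#' @param expr long expression table.
#' @param target target cell-type label.
#' @param references character vector of reference cell-type labels.
#' @param rpkm_min,fdr_max presence cutoffs for the target call.
#' @param ref_max maximum reference abundance, RPKM; default 0.10.
#' @return Data frame with columns `gene`, `rpkm`, `fdr` (target values).
#' @export
unique_expression <- function(expr, target, references, rpkm_min = 0.1,
                              fdr_max = 0.10, ref_max = 0.10) {
  for (ct in c(target, references)) {
    if (!ct %in% expr$cell_type) {
      stop("cell type '", ct, "' absent from expression data", call. = FALSE)
    }
  }
  tgt <- expr[expr$cell_type == target, , drop = FALSE]
  tgt <- tgt[call_expressed(tgt$rpkm, tgt$fdr, rpkm_min, fdr_max), ,
             drop = FALSE]
  keep <- rep(TRUE, nrow(tgt))
  for (ct in references) {
    ref <- expr[expr$cell_type == ct, , drop = FALSE]
    ref_rpkm <- ref$rpkm[match(tgt$gene, ref$gene)]
    ref_rpkm[is.na(ref_rpkm)] <- 0
    keep <- keep & ref_rpkm <= ref_max
  }
  out <- tgt[keep, c("gene", "rpkm", "fdr"), drop = FALSE]
  out <- out[order(-out$rpkm, out$gene, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top-N genes by abundance
#'
#' Filters to rows at or above the abundance floor, sorts by RPKM descending
#' with lexicographic gene-identifier tie-breaking, and keeps at most `n`
#' rows.
#'
#' @param table data frame with `gene` and `rpkm` columns.
#' @param n maximum number of rows; default 200.
#' @param floor minimum RPKM (inclusive); default 0.10.
#' @return The ranked, truncated data frame.
#' @export
top_n <- function(table, n = 200, floor = 0.10) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  out <- table[!is.na(table$rpkm) & table$rpkm >= floor, , drop = FALSE]
  out <- out[order(-out$rpkm, out$gene, method = "radix"), , drop = FALSE]
  out <- head(out, n)
  rownames(out) <- NULL
  out
}

#' Ortholog groups above an abundance threshold in every cell type
#'
#' A group's abundance in a cell type is the maximum RPKM over its member
#' genes of the species measured there (zero if none measured). Groups are
#' kept when that abundance strictly exceeds `rpkm_min` in every listed cell
#' type — the strict inequality matches threshold tables defined as
#' "> x RPKM".
#'
#' @inheritParams venn_partition
#' @param rpkm_min threshold, RPKM; exceeded strictly.
#' @return Data frame with `group_id`, `relationship`, and one RPKM column
#'   per cell type, sorted by the first cell type's RPKM descending.
#' @export
threshold_intersection <- function(groups, expr, cell_types, cell_species,
                                   rpkm_min) {
  miss <- setdiff(cell_types, unique(expr$cell_type))
  if (length(miss)) stop("cell type(s) absent from expression data: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  vals <- vapply(cell_types, function(ct) {
    sp <- cell_species[[ct]]
    col <- if (sp == "a") "members_a" else "members_b"
    sub <- expr[expr$cell_type == ct, , drop = FALSE]
    vapply(groups[[col]], function(m) {
      r <- sub$rpkm[match(m, sub$gene)]
      r <- r[!is.na(r)]
      if (length(r)) max(r) else 0
    }, numeric(1))
  }, numeric(nrow(groups)))
  vals <- matrix(vals, nrow = nrow(groups),
                 dimnames = list(NULL, cell_types))
  keep <- rowSums(vals > rpkm_min) == length(cell_types)
  out <- data.frame(group_id = groups$group_id[keep],
                    relationship = groups$relationship[keep],
                    vals[keep, , drop = FALSE],
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- out[order(-out[[cell_types[1]]], out$group_id, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
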