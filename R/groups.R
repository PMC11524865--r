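#' Build ortholog groups from homology pairs
#'
#' Ortholog groups are the connected components of the bipartite gene graph
#' whose vertices are the species-A and species-B genes and whose edges are
#' the homology pairs. Component cardinalities determine the relationship
#' class: one gene on each side is one-to-one, more than one gene on exactly
#' one side is one-to-many, more than one on both sides is many-to-many.
#' Classification is derived purely from the graph; when the export's
#' `homology_label` disagrees with the derived class a warning is emitted and
#' the derived class wins.
#'
#' @param pairs a [gene_pairs()] table (or data frame with `gene_a`,
#'   `gene_b` columns).
#' @return A data frame of class `"ortholog_groups"`, one row per group, with
#'   columns `group_id`, `members_a` and `members_b` (list columns of gene
#'   identifiers), `n_a`, `n_b`, and `relationship`. The per-pair group
#'   assignment is attached as attribute `"pair_groups"` (integer row index
#'   into the group table, one per input pair).
#' @export
#' @examples
#' g <- build_groups(gene_pairs(c("z1", "z2", "z1"), c("m1", "m1", "m2")))
#' g$relationship  # "many-to-many"
build_groups <- function(pairs) {
  if (nrow(pairs) == 0) stop("empty pair collection", call. = FALSE)
  va <- paste0("A\r", pairs$gene_a)
  vb <- paste0("B\r", pairs$gene_b)
  g <- igraph::graph_from_data_frame(
    data.frame(from = va, to = vb, stringsAsFactors = FALSE),
    directed = FALSE
  )
  comp <- igraph::components(g)
  vnames <- igraph::V(g)$name
  side <- substr(vnames, 1, 1)
  gene <- substring(vnames, 3)
  memb <- comp$membership

  members_a <- split(gene[side == "A"], memb[side == "A"])
  members_b <- split(gene[side == "B"], memb[side == "B"])
  ids <- as.character(sort(as.integer(names(members_a))))
  members_a <- lapply(members_a[ids], sort)
  members_b <- lapply(members_b[ids], sort)
  n_a <- lengths(members_a)
  n_b <- lengths(members_b)
  relationship <- ifelse(n_a == 1 & n_b == 1, "one-to-one",
                         ifelse(n_a > 1 & n_b > 1, "many-to-many",
                                "one-to-many"))
  out <- data.frame(
    group_id = sprintf("og%05d", seq_along(ids)),
    n_a = as.integer(n_a),
    n_b = as.integer(n_b),
    relationship = relationship,
    stringsAsFactors = FALSE
  )
  out$members_a <- unname(members_a)
  out$members_b <- unname(members_b)

  pair_groups <- match(as.character(memb[match(va, vnames)]), ids)
  check_label_agreement(pairs, relationship[pair_groups])
  attr(out, "pair_groups") <- pair_groups
  class(out) <- c("ortholog_groups", "data.frame")
  out
}

# Cross-check free-text homology labels against the derived class; derived
# classification always wins.
check_label_agreement <- function(pairs, derived) {
  lab <- pairs$homology_label
  if (all(is.na(lab))) return(invisible())
  norm <- rep(NA_character_, length(lab))
  norm[grepl("one2one|one[-_ ]to[-_ ]one", lab, ignore.case = TRUE)] <-
    "one-to-one"
  norm[grepl("one2many|many2one|one[-_ ]to[-_ ]many|many[-_ ]to[-_ ]one",
             lab, ignore.case = TRUE)] <- "one-to-many"
  norm[grepl("many2many|many[-_ ]to[-_ ]many", lab, ignore.case = TRUE)] <-
    "many-to-many"
  bad <- !is.na(norm) & norm != derived
  if (any(bad)) {
    warning(sum(bad), " pair(s) have a homology_label disagreeing with the ",
            "graph-derived class; the derived class is used", call. = FALSE)
  }
  invisible()
}

#' Collapse redundant genes on one side of the ortholog groups
#'
#' In the duplicated-genome comparison, several species-A paralogs map to the
#' same species-B gene, so the species-B gene list contains redundant
#' entries. Collapsing a side returns each gene on that side exactly once.
#'
#' @param groups an `"ortholog_groups"` table from [build_groups()].
#' @param side `"a"` or `"b"`: which species' gene list to deduplicate.
#' @return Sorted character vector of distinct gene identifiers.
#' @export
collapse_redundant <- function(groups, side = c("b", "a")) {
  side <- match.arg(side)
  col <- if (side == "a") "members_a" else "members_b"
  sort(unique(unlist(groups[[col]], use.names = FALSE)))
}

#' Summarize ortholog relationship classes
#'
#' Counts, for each species, the genes falling in each relationship class,
#' together with per-species ortholog totals. The totals equal the number of
#' distinct genes per species appearing in any pair.
#'
#' @param groups an `"ortholog_groups"` table from [build_groups()].
#' @return An `"ortholog_summary"` data frame with columns `relationship`,
#'   `genes_a`, `genes_b`; the final row is the `total`.
#' @seealso [ortholog_summary()] to build one directly from printed class
#'   counts, [ortholog_fraction()].
#' @export
summarize_relationships <- function(groups) {
  classes <- c("one-to-one", "one-to-many", "many-to-many")
  ga <- vapply(classes, function(cl) {
    sum(groups$n_a[groups$relationship == cl])
  }, integer(1))
  gb <- vapply(classes, function(cl) {
    sum(groups$n_b[groups$relationship == cl])
  }, integer(1))
  ortholog_summary(one_to_one = unname(ga[1]),
                   one_to_many_a = unname(ga[2]),
                   one_to_many_b = unname(gb[2]),
                   many_to_many_a = unname(ga[3]),
                   many_to_many_b = unname(gb[3]))
}

#' Assemble a relationship summary from class counts
#'
#' Builds the per-species class-count table directly from printed counts
#' (e.g. a published classification table) rather than from a pair table.
#' One-to-one counts are shared by construction: each such group has exactly
#' one gene per species.
#'
#' @param one_to_one genes in one-to-one groups (same for both species).
#' @param one_to_many_a,one_to_many_b genes per species in one-to-many
#'   groups.
#' @param many_to_many_a,many_to_many_b genes per species in many-to-many
#'   groups.
#' @return An `"ortholog_summary"` data frame; the `total` row is the
#'   per-species sum over the three classes.
#' @export
#' @examples
#' s <- ortholog_summary(9864, 6723, 3425, 911, 237)
#' s[s$relationship == "total", ]  # 17498 / 13526
ortholog_summary <- function(one_to_one, one_to_many_a, one_to_many_b,
                             many_to_many_a, many_to_many_b) {
  counts <- c(one_to_one, one_to_many_a, one_to_many_b,
              many_to_many_a, many_to_many_b)
  if (any(counts < 0) || any(counts != trunc(counts))) {
    stop("class counts must be non-negative integers", call. = FALSE)
  }
  out <- data.frame(
    relationship = c("one-to-one", "one-to-many", "many-to-many", "total"),
    genes_a = c(one_to_one, one_to_many_a, many_to_many_a,
                one_to_one + one_to_many_a + many_to_many_a),
    genes_b = c(one_to_one, one_to_many_b, many_to_many_b,
                one_to_one + one_to_many_b + many_to_many_b),
    stringsAsFactors = FALSE
  )
  class(out) <- c("ortholog_summary", "data.frame")
  out
}

#' Fraction of protein-coding genes in selected ortholog classes
#'
#' Computes `100 * selected / protein_coding_total`. The full-precision
#' percentage is returned; for report output round with [round()] (R's
#' round-half-even), e.g. `round(ortholog_fraction(...))`.
#'
#' @param summary an `"ortholog_summary"` table.
#' @param protein_coding_total total protein-coding gene count for the
#'   species (must be positive and at least the selected count).
#' @param classes relationship classes to include; `NULL` (default) selects
#'   the ortholog total.
#' @param species `"a"` or `"b"`.
#' @return Percentage as a plain number (e.g. `39.30...`).
#' @export
#' @examples
#' s <- ortholog_summary(9864, 6723, 3425, 911, 237)
#' round(ortholog_fraction(s, 25098, classes = "one-to-one"))  # 39
ortholog_fraction <- function(summary, protein_coding_total, classes = NULL,
                              species = c("a", "b")) {
  species <- match.arg(species)
  if (!is.numeric(protein_coding_total) || length(protein_coding_total) != 1 ||
      is.na(protein_coding_total) || protein_coding_total <= 0) {
    stop("protein_coding_total must be a positive number", call. = FALSE)
  }
  col <- if (species == "a") "genes_a" else "genes_b"
  if (is.null(classes)) classes <- "total"
  bad <- setdiff(classes, summary$relationship)
  if (length(bad)) stop("unknown class(es): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  selected <- sum(summary[[col]][summary$relationship %in% classes])
  if (selected > protein_coding_total) {
    stop("selected count exceeds protein_coding_total", call. = FALSE)
  }
  100 * selected / protein_coding_total
}
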