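#' Construct a table of cross-species homology pairs
#'
#' A gene-pair table is the package's representation of a Biomart-style
#' ortholog export: one row per (species-A gene, species-B gene) homology
#' call, with optional per-pair confidence scores. Species A is, by
#' convention, the duplicated-genome species (zebrafish) and species B the
#' non-duplicated one (mouse), but identifiers are treated as opaque
#' case-sensitive strings throughout.
#'
#' @param gene_a,gene_b character vectors of gene identifiers.
#' @param goc,wga,pct_id numeric vectors of gene-order-conservation,
#'   whole-genome-alignment and percent-identity scores in \[0, 100\];
#'   `NA` marks a score absent from the export.
#' @param homology_label optional free-text annotation carried through from
#'   the source export (e.g. `"ortholog_one2one"`); never used for
#'   classification, only cross-checked.
#' @return A `data.frame` of class `"gene_pairs"` with the six canonical
#'   columns.
#' @seealso [read_homology_table()], [build_groups()], [flag_high_confidence()]
#' @export
#' @examples
#' gene_pairs(c("z1", "z2"), c("m1", "m1"), goc = c(80, NA), pct_id = c(60, 40))
gene_pairs <- function(gene_a, gene_b, goc = NA_real_, wga = NA_real_,
                       pct_id = NA_real_, homology_label = NA_character_) {
  n <- length(gene_a)
  if (length(gene_b) != n) {
    stop("gene_a and gene_b must have equal length", call. = FALSE)
  }
  df <- data.frame(
    gene_a = as.character(gene_a),
    gene_b = as.character(gene_b),
    goc = rep_len(as.numeric(goc), n),
    wga = rep_len(as.numeric(wga), n),
    pct_id = rep_len(as.numeric(pct_id), n),
    homology_label = rep_len(as.character(homology_label), n),
    stringsAsFactors = FALSE
  )
  validate_gene_pairs(df)
  class(df) <- c("gene_pairs", "data.frame")
  df
}

validate_gene_pairs <- function(df) {
  for (col in c("goc", "wga", "pct_id")) {
    x <- df[[col]]
    bad <- !is.na(x) & (x < 0 | x > 100)
    if (any(bad)) {
      stop(sprintf("%s scores outside [0, 100] in %d row(s)", col, sum(bad)),
           call. = FALSE)
    }
  }
  if (any(is.na(df$gene_a)) || any(is.na(df$gene_b)) ||
      any(!nzchar(df$gene_a)) || any(!nzchar(df$gene_b))) {
    stop("gene identifiers must be non-empty", call. = FALSE)
  }
  key <- paste(df$gene_a, df$gene_b, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    ex <- unique(paste0("(", df$gene_a[dup], ", ", df$gene_b[dup], ")"))
    stop("duplicate gene pairs: ", paste(head(ex, 10), collapse = ", "),
         if (length(ex) > 10) ", ..." else "", call. = FALSE)
  }
  invisible(df)
}

#' Read a Biomart-style homology export
#'
#' Parses a tab-delimited UTF-8 ortholog export with a header row into a
#' [gene_pairs()] table. Column names vary between exports, so a column map
#' translates the canonical field names to the names actually present.
#' Percent identity is directional in Biomart exports (query-to-target vs
#' target-to-query); exactly one column is mapped, and which one is the
#' caller's explicit choice.
#'
#' @param path path to a tab-delimited file with a header row.
#' @param columns named character vector mapping canonical field names
#'   (`gene_a`, `gene_b`, `goc`, `wga`, `pct_id`, `homology_label`) to the
#'   column names in the file. `gene_a` and `gene_b` are required; unmapped
#'   score fields are read as absent. Defaults assume canonical names.
#' @return A `"gene_pairs"` data frame. Blank score fields become `NA`
#'   (absent), never zero.
#' @export
read_homology_table <- function(path,
                                columns = c(gene_a = "gene_a",
                                            gene_b = "gene_b",
                                            goc = "goc",
                                            wga = "wga",
                                            pct_id = "pct_id",
                                            homology_label = "homology_label")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = c("", "NA"),
                    colClasses = "character", fileEncoding = "UTF-8")
  required <- c("gene_a", "gene_b")
  for (field in required) {
    if (!field %in% names(columns)) {
      stop("column map must include field '", field, "'", call. = FALSE)
    }
  }
  mapped <- columns[names(columns) %in%
                      c("gene_a", "gene_b", "goc", "wga", "pct_id",
                        "homology_label")]
  if (missing(columns)) {
    # default map: optional fields are only read when present in the header
    optional <- setdiff(names(mapped), required)
    mapped <- mapped[!(names(mapped) %in% optional & !mapped %in% names(raw))]
  }
  missing_cols <- mapped[!mapped %in% names(raw)]
  if (length(missing_cols)) {
    stop("mapped column(s) not present in file header: ",
         paste0("'", missing_cols, "' (field ", names(missing_cols), ")",
                collapse = ", "), call. = FALSE)
  }
  pick_num <- function(field) {
    if (field %in% names(mapped)) as.numeric(raw[[mapped[[field]]]])
    else rep(NA_real_, nrow(raw))
  }
  pick_chr <- function(field) {
    if (field %in% names(mapped)) as.character(raw[[mapped[[field]]]])
    else rep(NA_character_, nrow(raw))
  }
  gene_pairs(
    gene_a = raw[[mapped[["gene_a"]]]],
    gene_b = raw[[mapped[["gene_b"]]]],
    goc = pick_num("goc"),
    wga = pick_num("wga"),
    pct_id = pick_num("pct_id"),
    homology_label = pick_chr("homology_label")
  )
}

#' Flag high-confidence ortholog pairs
#'
#' A pair is high confidence when its gene-order-conservation score or its
#' whole-genome-alignment score reaches the synteny threshold (inclusive
#' "or"), and its percent identity reaches the identity threshold
#' (conjunctive). An absent score fails its clause rather than erroring,
#' since real exports contain blanks; the rule is therefore monotone in all
#' three scores.
#'
#' @param pairs a [gene_pairs()] table, or anything with numeric `goc`,
#'   `wga`, `pct_id` columns.
#' @param goc_min,wga_min,id_min thresholds in \[0, 100\]; defaults 75 / 75 /
#'   50.
#' @return Logical vector, one element per pair.
#' @export
#' @examples
#' p <- gene_pairs("z1", "m1", goc = 80, wga = 10, pct_id = 55)
#' flag_high_confidence(p)  # TRUE
flag_high_confidence <- function(pairs, goc_min = 75, wga_min = 75,
                                 id_min = 50) {
  for (thr in c(goc_min, wga_min, id_min)) {
    if (!is.numeric(thr) || length(thr) != 1 || is.na(thr) ||
        thr < 0 || thr > 100) {
      stop("thresholds must be single values in [0, 100]", call. = FALSE)
    }
  }
  pass <- function(x, m) !is.na(x) & x >= m
  (pass(pairs$goc, goc_min) | pass(pairs$wga, wga_min)) &
    pass(pairs$pct_id, id_min)
}
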