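#' Read a GMT gene-set file
#'
#' GMT is tab-delimited: set name, description, then member genes, one set
#' per line.
#'
#' @param path path to the GMT file.
#' @return Named list of character vectors (set members); descriptions in
#'   attribute `"descriptions"`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3
  if (any(short)) {
    stop("GMT line(s) with fewer than 3 fields: ",
         paste(which(short), collapse = ", "), call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(names(sets))) stop("duplicate set names", call. = FALSE)
  attr(sets, "descriptions") <- vapply(fields, `[[`, character(1), 2)
  sets
}

#' Gene-set collection with explicit background universe
#'
#' Gene sets are intersected with the universe; sets left empty are dropped
#' with a message. The universe is always an explicit input — typically the
#' orthologs measured in the cell types under study, not the whole genome,
#' to avoid expression-detection bias.
#'
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param universe character vector of background gene identifiers.
#' @return List of class `"gene_set_collection"` with elements `sets`
#'   (intersected) and `universe` (deduplicated).
#' @export
gene_set_collection <- function(sets, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe", call. = FALSE)
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("sets must be named", call. = FALSE)
  }
  inter <- lapply(sets, function(s) intersect(unique(s), universe))
  empty <- lengths(inter) == 0
  if (any(empty)) {
    message(sum(empty), " set(s) empty after universe intersection; dropped")
    inter <- inter[!empty]
  }
  if (!length(inter)) stop("no set overlaps the universe", call. = FALSE)
  structure(list(sets = inter, universe = universe),
            class = "gene_set_collection")
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the query list overlaps the set more
#' than expected by chance when drawing `|query|` genes without replacement
#' from the universe: the p-value is the upper-tail hypergeometric
#' probability of an overlap at least as large as observed (one-sided,
#' enrichment only). P-values are BH-adjusted across sets and the table is
#' sorted by p (ties by set name). Query genes outside the universe are
#' dropped with a message.
#'
#' @param query character vector of gene identifiers.
#' @param collection a [gene_set_collection()].
#' @return Data frame with columns `set`, `set_size`, `overlap`, `expected`,
#'   `p`, `adj_p`.
#' @export
#' @examples
#' gsc <- gene_set_collection(list(S = letters[1:5]), universe = letters[1:10])
#' hypergeom_enrich(letters[1:5], gsc)$p  # 1/choose(10, 5)
hypergeom_enrich <- function(query, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(as.character(query))
  outside <- setdiff(query, collection$universe)
  if (length(outside)) {
    message(length(outside), " query gene(s) outside the universe; dropped")
    query <- setdiff(query, outside)
  }
  if (!length(query)) {
    stop("query empty after universe intersection", call. = FALSE)
  }
  N <- length(collection$universe)
  K <- length(query)
  res <- lapply(names(collection$sets), function(nm) {
    s <- collection$sets[[nm]]
    m <- length(s)
    k <- length(intersect(query, s))
    data.frame(set = nm, set_size = m, overlap = k,
               expected = K * m / N,
               p = phyper(k - 1, m, N - m, K, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adj_p <- bh_adjust(out$p)
  out <- out[order(out$p, out$set, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
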