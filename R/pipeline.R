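#' Read and validate a pipeline run configuration
#'
#' The YAML mirrors the arguments of [run_pipeline()]; unknown keys are
#' rejected so that typos never silently fall back to defaults.
#'
#' @param path path to a YAML file.
#' @return A named list of validated configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

known_config_keys <- c(
  "pairs", "expr", "gmt", "universe_cell_types", "cell_types",
  "cell_species", "dup_species", "rpkm_min", "fdr_max", "goc_min",
  "wga_min", "id_min", "fc_min", "alpha", "ref_max", "top_n", "out_dir",
  "seed", "contrast", "query_cell"
)

validate_run_config <- function(cfg) {
  unknown <- setdiff(names(cfg), known_config_keys)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  num_ranges <- list(rpkm_min = c(0, Inf), fdr_max = c(0, 1),
                     goc_min = c(0, 100), wga_min = c(0, 100),
                     id_min = c(0, 100), fc_min = c(0, Inf),
                     alpha = c(0, 1), ref_max = c(0, Inf))
  for (k in names(num_ranges)) {
    if (!is.null(cfg[[k]])) {
      v <- cfg[[k]]
      if (!is.numeric(v) || v < num_ranges[[k]][1] || v > num_ranges[[k]][2]) {
        stop("configuration key '", k, "' out of range", call. = FALSE)
      }
    }
  }
  if (!is.null(cfg$cell_species)) {
    cfg$cell_species <- unlist(cfg$cell_species)
  }
  cfg
}

run_stage <- function(stage, expr_) {
  tryCatch(expr_, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the transcriptomic pipeline end to end
#'
#' classify -> presence calls -> Venn partition -> differential expression
#' -> enrichment, on in-memory inputs. Every stage error is re-raised with
#' the stage name. Output is a machine-readable summary; with `out_dir` the
#' component tables are also written as tab-delimited UTF-8 files plus a
#' JSON summary.
#'
#' @param pairs a [gene_pairs()] table.
#' @param expr long expression table (gene, cell_type, rpkm, fdr).
#' @param cell_types cell types for the Venn partition.
#' @param cell_species named species map for the cell types.
#' @param counts optional count matrix for the differential stage.
#' @param count_groups factor of conditions for `counts` (2 levels).
#' @param gene_sets optional named list of gene sets for enrichment; the
#'   universe is the duplicated-species genes measured in `query_cell`.
#' @param query_cell cell type whose uniquely/most expressed genes form the
#'   enrichment query; default first element of `cell_types`.
#' @param rpkm_min,fdr_max presence cutoffs.
#' @param goc_min,wga_min,id_min high-confidence score thresholds.
#' @param fc_min,alpha volcano thresholds for the differential stage.
#' @param n_top size of the ranked query list for enrichment; default 200.
#' @param out_dir optional output directory.
#' @return List of class `"orthoexpress_run"` with elements `summary`
#'   (relationship counts, high-confidence pair count, Venn cells and
#'   totals, DE counts, enrichment head), `groups`, `partition`, `de`,
#'   `enrichment`, and `log` (parameters used).
#' @export
run_pipeline <- function(pairs, expr, cell_types, cell_species,
                         counts = NULL, count_groups = NULL,
                         gene_sets = NULL, query_cell = cell_types[1],
                         rpkm_min = 0.1, fdr_max = 0.10,
                         goc_min = 75, wga_min = 75, id_min = 50,
                         fc_min = 1.0, alpha = 0.05, n_top = 200,
                         out_dir = NULL) {
  groups <- run_stage("classify", build_groups(pairs))
  hc <- run_stage("classify",
                  flag_high_confidence(pairs, goc_min, wga_min, id_min))
  summ <- run_stage("classify", summarize_relationships(groups))

  empty_expr <- nrow(expr) == 0
  if (empty_expr) {
    partition <- NULL
    totals <- setNames(numeric(length(cell_types)), cell_types)
  } else {
    partition <- run_stage("venn",
                           venn_partition(groups, expr, cell_types,
                                          cell_species, rpkm_min, fdr_max))
    totals <- venn_totals(partition)
  }

  de <- NULL
  de_counts <- list(n_up = 0L, n_down = 0L)
  if (!is.null(counts) && nrow(counts) > 0) {
    de <- run_stage("de", de_analysis(counts, count_groups, fc_min = fc_min,
                                      alpha = alpha))
    de_counts <- volcano_summary(de, fc_min = fc_min, alpha = alpha)
  }

  enr <- NULL
  if (!is.null(gene_sets) && !empty_expr) {
    enr <- run_stage("enrich", {
      sp <- cell_species[[query_cell]]
      measured <- unique(expr$gene[expr$cell_type == query_cell])
      sub <- expr[expr$cell_type == query_cell, , drop = FALSE]
      called <- sub[call_expressed(sub$rpkm, sub$fdr, rpkm_min, fdr_max), ,
                    drop = FALSE]
      query <- top_n(called, n = n_top, floor = rpkm_min)$gene
      gsc <- gene_set_collection(gene_sets, universe = measured)
      hypergeom_enrich(query, gsc)
    })
  }

  summary <- list(
    relationships = summ,
    n_high_confidence_pairs = sum(hc),
    venn_cells = if (!is.null(partition)) {
      partition[, c("cell", "group_count", "paralog_increment")]
    } else data.frame(cell = character(0), group_count = integer(0),
                      paralog_increment = integer(0)),
    expressed_totals = totals,
    de = de_counts,
    enrichment_top = if (!is.null(enr)) head(enr, 10) else NULL
  )
  log <- list(package = "orthoexpress",
              version = as.character(utils::packageVersion("orthoexpress")),
              parameters = list(rpkm_min = rpkm_min, fdr_max = fdr_max,
                                goc_min = goc_min, wga_min = wga_min,
                                id_min = id_min, fc_min = fc_min,
                                alpha = alpha, n_top = n_top,
                                cell_types = cell_types))
  out <- structure(list(summary = summary, groups = groups,
                        partition = partition, de = de, enrichment = enr,
                        log = log),
                   class = "orthoexpress_run")
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- run$groups
  gtab <- data.frame(group_id = g$group_id,
                     members_a = vapply(g$members_a, paste,
                                        character(1), collapse = ","),
                     members_b = vapply(g$members_b, paste,
                                        character(1), collapse = ","),
                     n_a = g$n_a, n_b = g$n_b,
                     relationship = g$relationship,
                     stringsAsFactors = FALSE)
  write_tsv(gtab, file.path(out_dir, "groups.tsv"))
  write_tsv(run$summary$relationships, file.path(out_dir, "relationships.tsv"))
  if (!is.null(run$partition)) {
    write_tsv(run$summary$venn_cells, file.path(out_dir, "venn_cells.tsv"))
  }
  if (!is.null(run$de)) write_tsv(run$de, file.path(out_dir, "de.tsv"))
  if (!is.null(run$enrichment)) {
    write_tsv(run$enrichment, file.path(out_dir, "enrichment.tsv"))
  }
  jsonlite::write_json(
    list(expressed_totals = as.list(run$summary$expressed_totals),
         de = run$summary$de,
         n_high_confidence_pairs = run$summary$n_high_confidence_pairs,
         log = run$log),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
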