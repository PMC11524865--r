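#' Simulation configuration
#'
#' One seeded configuration drives every synthetic generator. The defaults
#' emulate the structure of a teleost-vs-mammal ortholog comparison: a
#' duplicated "fish-like" genome in which a fraction of ancestral genes
#' retains both post-duplication copies (producing one-to-many and
#' many-to-many components), per-class confidence-score distributions, and
#' cell-type expression with planted Venn structure, log-normal RPKM given
#' presence, and replicated negative-binomial counts.
#'
#' The root seed is split hierarchically per sub-generator (homology,
#' expression, counts, recording), so adding one generator never perturbs
#' another's stream; identical seed and configuration give identical output.
#'
#' @param seed integer root seed (mandatory; no unseeded generation).
#' @param n_ancestral_genes ancestral gene count; default 3000.
#' @param duplicate_retention probability a fish gene retains both
#'   post-duplication copies; default 0.25.
#' @param dup_rate_b probability of a lineage-specific duplication on the
#'   non-duplicated side (source of many-to-many components); default 0.02.
#' @param orphan_rates per-species probability of no ortholog,
#'   `c(a = , b = )`; defaults 0.18 / 0.28.
#' @param hc_fraction fraction of pairs drawn to pass the high-confidence
#'   score rule; default 0.33.
#' @param score_missing_rate probability a goc/wga score is absent; default
#'   0.05.
#' @param cell_types labels of the simulated cell populations.
#' @param cell_species species of each cell type (`"a"`/`"b"`).
#' @param cell_probs named probabilities over Venn cells (cell-type labels
#'   joined by `"+"`); remaining mass is "expressed nowhere". The default
#'   plants a dominant all-hair-cell core, small two-way overlaps, and
#'   unique compartments.
#' @param paralog_coexpression probability each extra duplicated-species
#'   paralog beyond the first is itself expressed; default 0.35.
#' @param rpkm_meanlog,rpkm_sdlog log-normal RPKM parameters given presence;
#'   defaults 1.5 / 1.2.
#' @param nb_dispersion count-noise dispersion; default 0.1.
#' @param n_reps samples per group in the count matrix; default 5.
#' @param n_de planted differentially expressed genes; default 100.
#' @param de_log2fc absolute planted log2 effect; default 2.
#' @param count_scale counts per RPKM unit at unit depth; default 20.
#' @param nlc_truth [boltzmann_params()] generating recordings; default is
#'   an outer-hair-cell-like set (Qmax 1135 fC, slope factor 27 mV, Vhalf
#'   -54 mV, Clin 7.9 pF).
#' @param nlc_noise_sd capacitance noise SD, pF; default 0.05.
#' @param circuit list with `Rs`, `Rm` (Ohm) for raw-trace synthesis.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(seed,
                       n_ancestral_genes = 3000,
                       duplicate_retention = 0.25,
                       dup_rate_b = 0.02,
                       orphan_rates = c(a = 0.18, b = 0.28),
                       hc_fraction = 0.33,
                       score_missing_rate = 0.05,
                       cell_types = c("zHC", "zSC", "IHC", "OHC"),
                       cell_species = c(zHC = "a", zSC = "a",
                                        IHC = "b", OHC = "b"),
                       cell_probs = c("zHC+zSC+IHC+OHC" = 0.30,
                                      "zHC+IHC+OHC" = 0.22,
                                      "zHC+IHC" = 0.02,
                                      "zHC+OHC" = 0.03,
                                      "IHC+OHC" = 0.10,
                                      "zHC" = 0.12,
                                      "IHC" = 0.02,
                                      "OHC" = 0.03),
                       paralog_coexpression = 0.35,
                       rpkm_meanlog = 1.5,
                       rpkm_sdlog = 1.2,
                       nb_dispersion = 0.1,
                       n_reps = 5,
                       n_de = 100,
                       de_log2fc = 2,
                       count_scale = 20,
                       nlc_truth = boltzmann_params(Qmax = 1135,
                                                    slope_factor = 27,
                                                    Vhalf = -54, Clin = 7.9),
                       nlc_noise_sd = 0.05,
                       circuit = list(Rs = 10e6, Rm = 500e6)) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  probs <- c(duplicate_retention, dup_rate_b, orphan_rates, hc_fraction,
             score_missing_rate, cell_probs, paralog_coexpression)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must be in [0, 1]", call. = FALSE)
  }
  if (sum(cell_probs) > 1) stop("cell_probs must sum to at most 1",
                                call. = FALSE)
  structure(list(seed = as.integer(seed),
                 n_ancestral_genes = n_ancestral_genes,
                 duplicate_retention = duplicate_retention,
                 dup_rate_b = dup_rate_b,
                 orphan_rates = orphan_rates,
                 hc_fraction = hc_fraction,
                 score_missing_rate = score_missing_rate,
                 cell_types = cell_types,
                 cell_species = cell_species,
                 cell_probs = cell_probs,
                 paralog_coexpression = paralog_coexpression,
                 rpkm_meanlog = rpkm_meanlog,
                 rpkm_sdlog = rpkm_sdlog,
                 nb_dispersion = nb_dispersion,
                 n_reps = n_reps,
                 n_de = n_de,
                 de_log2fc = de_log2fc,
                 count_scale = count_scale,
                 nlc_truth = nlc_truth,
                 nlc_noise_sd = nlc_noise_sd,
                 circuit = circuit),
            class = "sim_config")
}

# Deterministic sub-seed derivation: a fixed LCG step on the root seed plus
# a salt hashed from the generator name; stays below 2^31.
derive_seed <- function(seed, salt) {
  h <- sum(utf8ToInt(salt) * seq_along(utf8ToInt(salt)))
  as.integer((as.double(seed) * 48271 + h * 9176) %% 2147483647)
}

#' Simulate a duplicated-genome homology table
#'
#' Each ancestral gene independently leaves 0, 1 or 2 descendant copies per
#' species: the duplicated species A retains both copies with probability
#' `duplicate_retention`, species B duplicates with the (small) probability
#' `dup_rate_b`, and each species loses the gene entirely at its orphan
#' rate. Every A-copy pairs with every B-copy of the same ancestral gene,
#' so components are complete bipartite and the true relationship class
#' follows from the copy numbers. Scores are drawn so that a configured
#' fraction of pairs passes the high-confidence rule by construction, with
#' occasional absent scores as in real exports.
#'
#' @param config a [sim_config()].
#' @return List with `pairs` (a [gene_pairs()] table) and `truth` (data
#'   frame: ancestral id, copies per species, true class, high-confidence
#'   label per pair).
#' @export
generate_homology <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "homology"))
  n <- config$n_ancestral_genes
  copies_a <- ifelse(runif(n) < config$orphan_rates[["a"]], 0L,
                     ifelse(runif(n) < config$duplicate_retention, 2L, 1L))
  copies_b <- ifelse(runif(n) < config$orphan_rates[["b"]], 0L,
                     ifelse(runif(n) < config$dup_rate_b, 2L, 1L))
  shared <- copies_a >= 1L & copies_b >= 1L
  true_class <- rep(NA_character_, n)
  true_class[shared & copies_a == 1L & copies_b == 1L] <- "one-to-one"
  true_class[shared & xor(copies_a > 1L, copies_b > 1L)] <- "one-to-many"
  true_class[shared & copies_a > 1L & copies_b > 1L] <- "many-to-many"

  rows <- which(shared)
  pair_list <- lapply(rows, function(i) {
    ga <- paste0("zg", sprintf("%05d", i),
                 if (copies_a[i] == 2L) c("a", "b") else "")
    gb <- paste0("mg", sprintf("%05d", i),
                 if (copies_b[i] == 2L) c("a", "b") else "")
    expand.grid(gene_a = ga, gene_b = gb, stringsAsFactors = FALSE)
  })
  pairs_df <- do.call(rbind, pair_list)
  ancestral <- rep(rows, vapply(pair_list, nrow, integer(1)))
  np <- nrow(pairs_df)

  hc <- runif(np) < config$hc_fraction
  goc <- wga <- pct_id <- numeric(np)
  # high-confidence pairs satisfy (goc>=75 | wga>=75) & pct_id>=50 by
  # construction; the rest violate one clause
  goc[hc] <- runif(sum(hc), 75, 100)
  wga[hc] <- runif(sum(hc), 40, 100)
  pct_id[hc] <- runif(sum(hc), 50, 100)
  lo <- !hc
  id_fail <- lo & runif(np) < 0.5
  goc[lo] <- runif(sum(lo), 0, 74.9)
  wga[lo] <- runif(sum(lo), 0, 74.9)
  pct_id[id_fail] <- runif(sum(id_fail), 0, 49.9)
  pct_id[lo & !id_fail] <- runif(sum(lo & !id_fail), 50, 100)
  # occasional blanks, only where the pass/fail status is unaffected:
  # drop goc on high-confidence pairs whose wga also passes, or wga on
  # low-confidence pairs (both synteny clauses already fail)
  drop_goc <- hc & wga >= 75 & runif(np) < config$score_missing_rate
  drop_wga <- lo & runif(np) < config$score_missing_rate
  goc[drop_goc] <- NA_real_
  wga[drop_wga] <- NA_real_

  pairs <- gene_pairs(pairs_df$gene_a, pairs_df$gene_b,
                      goc = goc, wga = wga, pct_id = pct_id)
  truth <- data.frame(ancestral = ancestral,
                      gene_a = pairs_df$gene_a, gene_b = pairs_df$gene_b,
                      true_class = true_class[ancestral],
                      high_confidence = hc, stringsAsFactors = FALSE)
  list(pairs = pairs, truth = truth)
}

#' Simulate cell-type expression with planted Venn structure
#'
#' Each ortholog group is assigned a Venn cell (a subset of cell types, or
#' "expressed nowhere") by sampling from `cell_probs`. Inside its cell, one
#' member gene of the appropriate species is expressed per cell type; each
#' additional duplicated-species paralog is co-expressed with probability
#' `paralog_coexpression` (the source of paralog increments). Present genes
#' draw RPKM from `0.1 + lognormal` with detection FDR below the cutoff;
#' absent genes sit below 0.1 RPKM, so presence calls at the default cutoff
#' recover the planted truth exactly. A replicated count matrix for the
#' first two duplicated-species cell types is generated with
#' negative-binomial noise, per-sample depth variation, and `n_de` planted
#' differential genes at `±de_log2fc`.
#'
#' @param groups an `"ortholog_groups"` table (e.g. built from
#'   [generate_homology()] output).
#' @param config a [sim_config()].
#' @return List with `expr` (long expression table), `counts` (matrix),
#'   `count_groups` (factor of sample conditions), and `truth` (planted
#'   cell per group, expressed genes, DE genes).
#' @export
generate_expression <- function(groups, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "expression"))
  ng <- nrow(groups)
  cts <- config$cell_types
  cell_names <- c(names(config$cell_probs), ".none")
  cell_p <- c(config$cell_probs, 1 - sum(config$cell_probs))
  cell_of <- sample(cell_names, ng, replace = TRUE, prob = cell_p)

  genes_a <- unique(unlist(groups$members_a, use.names = FALSE))
  genes_b <- unique(unlist(groups$members_b, use.names = FALSE))
  # start with everything absent; overwrite the planted-present entries
  expr <- expand.grid(gene = c(genes_a, genes_b), cell_type = cts,
                      stringsAsFactors = FALSE)
  sp_of_gene <- c(rep("a", length(genes_a)), rep("b", length(genes_b)))
  names(sp_of_gene) <- c(genes_a, genes_b)
  # a cell type only measures genes of its own species
  expr <- expr[sp_of_gene[expr$gene] ==
                 config$cell_species[expr$cell_type], , drop = FALSE]
  expr$rpkm <- runif(nrow(expr), 0, 0.095)
  expr$fdr <- runif(nrow(expr), 0, 1)
  rownames(expr) <- paste(expr$gene, expr$cell_type, sep = "\r")

  expressed_genes <- vector("list", ng)
  for (i in seq_len(ng)) {
    if (cell_of[i] == ".none") next
    in_cell <- strsplit(cell_of[i], "+", fixed = TRUE)[[1]]
    on <- character(0)
    for (ct in in_cell) {
      sp <- config$cell_species[[ct]]
      memb <- if (sp == "a") groups$members_a[[i]] else groups$members_b[[i]]
      on_ct <- memb[1]
      if (sp == "a" && length(memb) > 1) {
        extra <- memb[-1][runif(length(memb) - 1) <
                            config$paralog_coexpression]
        on_ct <- c(on_ct, extra)
      }
      key <- paste(on_ct, ct, sep = "\r")
      expr[key, "rpkm"] <- 0.1 + rlnorm(length(on_ct), config$rpkm_meanlog,
                                        config$rpkm_sdlog)
      expr[key, "fdr"] <- runif(length(on_ct), 0, 0.09)
      on <- union(on, on_ct)
    }
    expressed_genes[[i]] <- on
  }
  rownames(expr) <- NULL

  # count matrix for the first two duplicated-species cell types
  dup_cts <- cts[config$cell_species[cts] == "a"]
  if (length(dup_cts) < 2) stop("need two duplicated-species cell types ",
                                "for the count matrix", call. = FALSE)
  set.seed(derive_seed(config$seed, "counts"))
  ct_a <- dup_cts[1]; ct_b <- dup_cts[2]
  base <- expr[expr$cell_type == ct_a, c("gene", "rpkm")]
  mu0 <- pmax(config$count_scale * base$rpkm, 0.5)
  nde <- min(config$n_de, nrow(base))
  # plant effects on clearly expressed genes (>= 1 RPKM), not at the
  # detection floor where no test has power
  eligible <- which(base$rpkm >= 1)
  de_idx <- sample(eligible, min(nde, length(eligible)))
  fold <- rep(1, nrow(base))
  fold[de_idx] <- 2^(sample(c(-1, 1), length(de_idx), TRUE) *
                       config$de_log2fc)
  nr <- config$n_reps
  depth <- runif(2 * nr, 0.7, 1.3)
  mu <- cbind(matrix(rep(mu0 * fold, nr), ncol = nr),
              matrix(rep(mu0, nr), ncol = nr))
  mu <- sweep(mu, 2, depth, "*")
  counts <- matrix(rnbinom(length(mu), mu = mu,
                           size = 1 / config$nb_dispersion),
                   nrow = nrow(base),
                   dimnames = list(base$gene,
                                   paste0(rep(c(ct_a, ct_b), each = nr),
                                          "_rep", seq_len(nr))))
  count_groups <- factor(rep(c(ct_a, ct_b), each = nr),
                         levels = c(ct_a, ct_b))

  truth <- list(cell = setNames(cell_of, groups$group_id),
                expressed_genes = setNames(expressed_genes, groups$group_id),
                de_genes = base$gene[de_idx],
                de_log2fc = log2(fold[de_idx]))
  list(expr = expr, counts = counts, count_groups = count_groups,
       truth = truth)
}

#' Simulate a staircase NLC recording, optionally with raw two-sine traces
#'
#' Capacitance is evaluated from [nlc_curve()] at the staircase voltages
#' (default -120 to +60 mV in 4 mV steps) and Gaussian noise of SD
#' `nlc_noise_sd` is added. With `two_sine = TRUE`, a raw steady-state
#' current trace is synthesized per step from the three-element patch
#' circuit (`Rs` in series with parallel `Rm`, `Cm(V)`) under the summed
#' dual-sine command (10 mV at both frequencies), sampled so both
#' frequencies are DFT-bin aligned; these traces feed
#' [two_sine_capacitance()] end to end.
#'
#' @param config a [sim_config()] (`nlc_truth`, `nlc_noise_sd`, `circuit`).
#' @param v_start,v_end,v_step staircase, mV; defaults -120, 60, 4.
#' @param two_sine synthesize raw current traces per step; default FALSE.
#' @param fs sampling rate for raw traces, Hz; default 1e5.
#' @param f1,f2 stimulus frequencies, Hz; defaults 390.625, 781.25.
#' @param n_periods record length per step in periods of `f1`; default 4.
#' @param amp stimulus amplitude per sinusoid, mV; default 10.
#' @return A [recording()]; the generating truth is in
#'   `metadata$truth`, raw traces (if requested) in `metadata$segments`
#'   (per step: `voltage_V`, `current_A`).
#' @export
generate_recording <- function(config, v_start = -120, v_end = 60,
                               v_step = 4, two_sine = FALSE, fs = 1e5,
                               f1 = 390.625, f2 = 781.25, n_periods = 4,
                               amp = 10) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "recording"))
  V <- seq(v_start, v_end, by = v_step)
  truth <- config$nlc_truth
  cm_true <- nlc_curve(V, truth)
  cm <- cm_true + rnorm(length(V), 0, config$nlc_noise_sd)
  meta <- list(truth = truth, noise_sd = config$nlc_noise_sd,
               f1 = f1, f2 = f2, fs = fs)
  if (two_sine) {
    n <- round(n_periods * fs / f1)
    if (abs(n - n_periods * fs / f1) > 1e-9) {
      stop("fs/f1 must give an integer samples-per-period", call. = FALSE)
    }
    t <- seq_len(n) / fs
    Rs <- config$circuit$Rs; Rm <- config$circuit$Rm
    meta$segments <- lapply(seq_along(V), function(i) {
      cmF <- cm_true[i] * 1e-12
      v_ac <- amp * 1e-3 * (sin(2 * pi * f1 * t) + sin(2 * pi * f2 * t))
      i_t <- numeric(n)
      for (f in c(f1, f2)) {
        w <- 2 * pi * f
        Y <- 1 / (Rs + 1 / (1 / Rm + 1i * w * cmF))
        i_t <- i_t + amp * 1e-3 * Mod(Y) * sin(w * t + Arg(Y))
      }
      dc <- V[i] * 1e-3 / (Rs + Rm)
      list(voltage_V = v_ac + V[i] * 1e-3, current_A = i_t + dc)
    })
  }
  recording(voltage = V, capacitance = cm, metadata = meta)
}
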