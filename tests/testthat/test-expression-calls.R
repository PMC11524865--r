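make_expr <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  names(df) <- c("gene", "cell_type", "rpkm", "fdr")
  df
}

cs <- c(zHC = "a", zSC = "a", IHC = "b", OHC = "b")

test_that("presence call applies both cutoffs inclusively", {
  expect_true(call_expressed(0.5, 0.01))
  expect_false(call_expressed(0.09, 0.01))   # below the 0.1 RPKM cutoff
  expect_false(call_expressed(5.0, 0.5))     # FDR above 0.10
  expect_true(call_expressed(0.1, 0.10))     # thresholds themselves count
  expect_equal(call_expressed(c(1, NA), c(0.01, 0.01)), c(TRUE, FALSE))
})

test_that("group presence uses any-member semantics, all-member on request", {
  g <- build_groups(gene_pairs(c("z1", "z2"), c("m1", "m1")))
  expr <- make_expr(gene = c("z1", "z2", "m1"),
                    cell_type = c("zHC", "zHC", "IHC"),
                    rpkm = c(5, 0.01, 2), fdr = c(0.01, 0.01, 0.01))
  expect_true(group_presence(g, expr, "zHC", cs))
  expect_false(group_presence(g, expr, "zHC", cs, semantics = "all"))
  expect_error(group_presence(g, expr, "OHC", cs), "absent")
  none <- make_expr(gene = "z1", cell_type = "zHC", rpkm = 0.01, fdr = 0.5)
  expect_false(group_presence(g, none, "zHC", cs))
})

test_that("toy paralog group lands in the right Venn cell with increment", {
  g <- build_groups(gene_pairs(c("za1", "za2"), c("mb1", "mb1")))
  expr <- make_expr(gene = c("za1", "za2", "mb1", "mb1"),
                    cell_type = c("zHC", "zHC", "IHC", "OHC"),
                    rpkm = c(3, 2, 1, 0.01), fdr = c(0.01, 0.01, 0.01, 0.01))
  p <- venn_partition(g, expr, c("zHC", "IHC", "OHC"), cs)
  expect_equal(nrow(p), 1)
  expect_equal(p$cell, "zHC+IHC")
  expect_equal(p$group_count, 1L)
  expect_equal(p$paralog_increment, 1L)
})

test_that("nothing above cutoff gives an empty partition with zero totals", {
  g <- build_groups(gene_pairs("z1", "m1"))
  expr <- make_expr(gene = c("z1", "m1", "m1"),
                    cell_type = c("zHC", "IHC", "OHC"),
                    rpkm = c(0.01, 0.05, 0.02), fdr = c(0.9, 0.9, 0.9))
  p <- venn_partition(g, expr, c("zHC", "IHC", "OHC"), cs)
  expect_equal(nrow(p), 0)
  expect_equal(unname(venn_totals(p)), c(0, 0, 0))
})

test_that("Venn cells are disjoint, exhaustive and order-invariant", {
  set.seed(11)
  cfg <- sim_config(seed = 61, n_ancestral_genes = 300)
  hom <- generate_homology(cfg)
  g <- build_groups(hom$pairs)
  ex <- generate_expression(g, cfg)
  cts <- c("zHC", "IHC", "OHC")
  p <- venn_partition(g, ex$expr, cts, cs)

  # oracle: independent per-group subset assignment by direct row scans
  called <- ex$expr[call_expressed(ex$expr$rpkm, ex$expr$fdr), ]
  subset_of <- vapply(seq_len(nrow(g)), function(i) {
    present <- vapply(cts, function(ct) {
      memb <- if (cs[[ct]] == "a") g$members_a[[i]] else g$members_b[[i]]
      any(called$gene %in% memb & called$cell_type == ct)
    }, logical(1))
    paste(cts[present], collapse = "+")
  }, character(1))
  expected <- table(subset_of[subset_of != ""])
  got <- setNames(p$group_count, p$cell)
  expect_equal(got[names(expected)], as.vector(expected),
               ignore_attr = TRUE)
  expect_equal(sum(p$group_count), sum(subset_of != ""))

  # partition-sum identity per cell type
  tot <- venn_totals(p)
  for (ct in cts) {
    m <- p[[ct]]
    manual <- sum(p$group_count[m]) +
      if (cs[[ct]] == "a") sum(p$paralog_increment[m]) else 0
    expect_equal(unname(tot[ct]), manual)
  }

  # invariance to group and expression row order
  g2 <- g[sample(nrow(g)), ]
  class(g2) <- class(g)
  e2 <- ex$expr[sample(nrow(ex$expr)), ]
  p2 <- venn_partition(g2, e2, cts, cs)
  expect_equal(p2[order(p2$cell), c("cell", "group_count",
                                    "paralog_increment")],
               p[order(p$cell), c("cell", "group_count",
                                  "paralog_increment")],
               ignore_attr = TRUE)
})

test_that("printed Venn cells reproduce the expressed totals identity", {
  p <- as_venn_partition(
    data.frame(cell = c("zHC+IHC+OHC", "zHC+IHC", "zHC+OHC", "zHC",
                        "IHC+OHC", "IHC", "OHC"),
               group_count = c(6659, 149, 322, 2831, 1594, 145, 288),
               paralog_increment = c(932, 25, 77, 0, 0, 0, 0)),
    cell_types = c("zHC", "IHC", "OHC"), dup_cell_types = "zHC")
  tot <- venn_totals(p)
  expect_identical(unname(tot["zHC"]), 10995)
  expect_identical(unname(tot["IHC"]), 8547)
  expect_identical(unname(tot["OHC"]), 8863)
})

test_that("unique expression excludes genes detected in any reference", {
  expr <- make_expr(gene = c("g1", "g2", "g3", "g1", "g2", "g3"),
                    cell_type = c(rep("zHC", 3), rep("zSC", 3)),
                    rpkm = c(50, 50, 0.05, 0.05, 50, 0.01),
                    fdr = rep(0.01, 6))
  u <- unique_expression(expr, "zHC", "zSC")
  expect_equal(u$gene, "g1")
  # brute-force scan on a random table
  set.seed(12)
  n <- 200
  rnd <- make_expr(gene = rep(sprintf("g%03d", 1:n), 2),
                   cell_type = rep(c("zHC", "zSC"), each = n),
                   rpkm = round(rlnorm(2 * n, 0, 2), 3),
                   fdr = round(runif(2 * n), 3))
  u2 <- unique_expression(rnd, "zHC", "zSC")
  tgt <- rnd[rnd$cell_type == "zHC", ]
  ref <- rnd[rnd$cell_type == "zSC", ]
  manual <- tgt$gene[tgt$rpkm >= 0.1 & tgt$fdr <= 0.10 &
                       ref$rpkm[match(tgt$gene, ref$gene)] <= 0.10]
  expect_equal(sort(u2$gene), sort(manual))
  expect_equal(u2$rpkm, sort(u2$rpkm, decreasing = TRUE))
  # by construction disjoint from the reference-expressed set
  ref_expressed <- ref$gene[ref$rpkm > 0.10]
  expect_length(intersect(u2$gene, ref_expressed), 0)
})

test_that("top-N ranks by abundance with lexicographic ties and a floor", {
  tab <- data.frame(gene = c("e", "a", "c", "b", "d"),
                    rpkm = c(5, 3, 3, 1, 0.05), stringsAsFactors = FALSE)
  expect_equal(top_n(tab, n = 3)$gene, c("e", "a", "c"))
  expect_equal(top_n(tab, n = 10)$gene, c("e", "a", "c", "b"))  # floor drops d
  expect_equal(top_n(tab, n = 2)$gene, c("e", "a"))
  expect_error(top_n(tab, n = 0), ">= 1")
})

test_that("threshold intersection is strict in every listed cell type", {
  g <- build_groups(gene_pairs(c("z1", "z2"), c("m1", "m2")))
  expr <- make_expr(gene = c("z1", "m1", "m1", "z2", "m2", "m2"),
                    cell_type = rep(c("zHC", "IHC", "OHC"), 2),
                    rpkm = c(11, 12, 13, 10, 15, 15),
                    fdr = rep(0.01, 6))
  out <- threshold_intersection(g, expr, c("zHC", "IHC", "OHC"), cs,
                                rpkm_min = 10)
  expect_equal(nrow(out), 1)       # the 10.0-exactly group is excluded
  expect_equal(out$zHC, 11)
  # random fixture vs brute-force scan
  set.seed(13)
  cfg <- sim_config(seed = 62, n_ancestral_genes = 200)
  gg <- build_groups(generate_homology(cfg)$pairs)
  ee <- generate_expression(gg, cfg)$expr
  got <- threshold_intersection(gg, ee, c("zHC", "IHC", "OHC"), cs, 2)
  manual <- vapply(seq_len(nrow(gg)), function(i) {
    all(vapply(c("zHC", "IHC", "OHC"), function(ct) {
      memb <- if (cs[[ct]] == "a") gg$members_a[[i]] else gg$members_b[[i]]
      r <- ee$rpkm[ee$cell_type == ct & ee$gene %in% memb]
      length(r) > 0 && max(r) > 2
    }, logical(1)))
  }, logical(1))
  expect_equal(sort(got$group_id), sort(gg$group_id[manual]))
})
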