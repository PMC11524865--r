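# Independent oracles used across the suite. These deliberately share no
# code with the package: components by breadth-first search, BH by the
# literal step-up formula, hypergeometric tails by subset enumeration,
# admittance by direct circuit evaluation.

# Connected components of the bipartite pair graph by BFS over an adjacency
# list; returns a data.frame of per-component size and class.
bf_component_classes <- function(gene_a, gene_b) {
  na <- paste0("A:", gene_a)
  nb <- paste0("B:", gene_b)
  nodes <- unique(c(na, nb))
  adj <- split(c(nb, na), c(na, nb))
  seen <- setNames(rep(FALSE, length(nodes)), nodes)
  comps <- list()
  for (start in nodes) {
    if (seen[[start]]) next
    queue <- start
    comp <- character(0)
    seen[[start]] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, v)
      for (w in adj[[v]]) {
        if (!seen[[w]]) { seen[[w]] <- TRUE; queue <- c(queue, w) }
      }
    }
    comps[[length(comps) + 1]] <- comp
  }
  do.call(rbind, lapply(comps, function(comp) {
    n_a <- sum(startsWith(comp, "A:"))
    n_b <- sum(startsWith(comp, "B:"))
    cls <- if (n_a == 1 && n_b == 1) "one-to-one"
    else if (n_a > 1 && n_b > 1) "many-to-many"
    else "one-to-many"
    data.frame(n_a = n_a, n_b = n_b, relationship = cls,
               stringsAsFactors = FALSE)
  }))
}

# Random bipartite pair table: up to max_pairs distinct pairs over small
# gene pools so that multi-gene components arise often.
random_pairs <- function(max_pairs = 50) {
  n <- sample.int(max_pairs, 1)
  ga <- paste0("z", sample.int(max(2, n %/% 2), n, replace = TRUE))
  gb <- paste0("m", sample.int(max(2, n %/% 2), n, replace = TRUE))
  keep <- !duplicated(paste(ga, gb))
  gene_pairs(ga[keep], gb[keep])
}

# Literal Benjamini-Hochberg step-up: p_(i) * n / i with a cumulative
# minimum from the largest p down, capped at 1.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  stepped <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(stepped)))
  pmin(adj, 1)[order(o)]
}

# Upper-tail hypergeometric by enumeration: probability that a uniformly
# random K-subset of 1..N overlaps 1..m in at least k_obs elements.
hyper_oracle <- function(N, m, K, k_obs) {
  hits <- 0
  subsets <- utils::combn(N, K)
  for (j in seq_len(ncol(subsets))) {
    if (sum(subsets[, j] <= m) >= k_obs) hits <- hits + 1
  }
  hits / ncol(subsets)
}

# Steady-state voltage/current traces of the series-Rs, parallel-(Rm, Cm)
# circuit under a summed two-sine command (SI units).
circuit_traces <- function(Rs, Rm, Cm, fs = 1e5, n = 1024,
                           f1 = 390.625, f2 = 781.25, amp_mV = 10,
                           v_hold_mV = 0) {
  t <- seq_len(n) / fs
  v <- rep(v_hold_mV * 1e-3, n)
  i <- rep(v_hold_mV * 1e-3 / (Rs + Rm), n)
  for (f in c(f1, f2)) {
    w <- 2 * pi * f
    Y <- 1 / (Rs + 1 / (1 / Rm + 1i * w * Cm))
    v <- v + amp_mV * 1e-3 * sin(w * t)
    i <- i + amp_mV * 1e-3 * Mod(Y) * sin(w * t + Arg(Y))
  }
  list(voltage = v, current = i)
}

# Trapezoid quadrature on a uniform grid.
trapz <- function(x, y) {
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

fig8_params <- function() {
  boltzmann_params(Qmax = 1135, slope_factor = 27, Vhalf = -54, Clin = 7.9)
}

write_lines_tmp <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
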