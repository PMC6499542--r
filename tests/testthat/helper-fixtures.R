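# Shared fixture builders and independent brute-force oracles.

# Small expression matrix with explicit values; populations A, B, ...
make_em <- function(values, pops, unit = "count", order = NULL,
                    is_neuronal = NULL) {
  smp <- colnames(values)
  ExpressionMatrix(values,
                   sample_population = stats::setNames(pops, smp),
                   sample_order = if (!is.null(order))
                     stats::setNames(order, smp),
                   is_neuronal = if (!is.null(is_neuronal))
                     stats::setNames(is_neuronal, smp),
                   unit = unit)
}

# Random dm_collection over P populations and n_genes genes; each pair is
# distinguished independently with probability p_on.
random_dmc <- function(n_genes, n_pop, p_on = 0.3) {
  px <- celldiv:::pair_index(sprintf("P%d", seq_len(n_pop)))
  pairs <- matrix(stats::runif(n_genes * px$n_pairs) < p_on, n_genes,
                  px$n_pairs,
                  dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                  px$labels))
  lfc <- matrix(stats::rexp(n_genes * px$n_pairs) + pairs * 3, n_genes,
                px$n_pairs, dimnames = dimnames(pairs))
  celldiv:::new_dm_collection(pairs, lfc, sprintf("P%d", seq_len(n_pop)),
                              px$i, px$j, px$labels)
}

# Brute-force DEF: explicit double loop over the square matrix.
bf_def <- function(square_dm) {
  p <- nrow(square_dm)
  hits <- 0L
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) hits <- hits + (square_dm[i, j] != 0)
  }
  hits / (p * (p - 1) / 2)
}

# Exhaustive minimal set-cover size reaching a combined-DEF target.
exhaustive_min_cover <- function(dmc, target) {
  ids <- rownames(dmc$pairs)
  for (k in seq_along(ids)) {
    sets <- utils::combn(ids, k, simplify = FALSE)
    for (s in sets) {
      if (combined_def(dmc, s) >= target) return(k)
    }
  }
  Inf
}

# Dirichlet-multinomial sampler (independent of the package generators).
rdirmult <- function(n_samples, pi, phi, coverage_mean) {
  t(sapply(seq_len(n_samples), function(i) {
    w <- stats::rgamma(length(pi), phi * pi)
    n <- stats::rpois(1, coverage_mean)
    if (n == 0) return(rep(0L, length(pi)))
    stats::rmultinom(1, n, w / sum(w))[, 1]
  }))
}

# Null expression matrix for length-bias calibration: two groups drawn from
# one distribution, values already on the log2 scale (no transform applied).
null_length_em <- function(n_genes, n_rep = 2) {
  base <- stats::runif(n_genes, 2, 8)
  v <- matrix(base + stats::rnorm(n_genes * 2 * n_rep, 0, 0.5), n_genes,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              c(paste0("a", seq_len(n_rep)),
                                paste0("b", seq_len(n_rep)))))
  v[v < 0] <- 0
  make_em(v, rep(c("A", "B"), each = n_rep), unit = "log2fpkm1")
}

# Gene table with lengths spread across log10 bins.
spread_gene_table <- function(genes) {
  gene_table(genes, round(10^stats::runif(length(genes), 3.2, 5.8)))
}
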