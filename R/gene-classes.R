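# OFF-state noise, family over-representation, expression-pattern
# orthogonality, and the pan-neuronal filter.

#' Per-gene OFF-state noise
#'
#' For each gene, the OFF set is the samples where expression falls below
#' `off_thresh` (FPKM < 1 by default, i.e. essentially silent), and the OFF
#' noise is the sample standard deviation (n - 1 denominator) of expression
#' over that set, on the linear FPKM scale. Genes with fewer than `min_off`
#' OFF samples get `NA` (no meaningful OFF state).
#'
#' @param em An [ExpressionMatrix()] with unit `"fpkm"`.
#' @param off_thresh OFF-state expression cutoff (default 1 FPKM).
#' @param min_off Minimum OFF-set size; default 10% of samples (at least 2).
#' @return A data.frame with columns `gene`, `off_noise`, `n_off`,
#'   `max_expr`, `mean_expr`.
#' @export
off_noise <- function(em, off_thresh = 1,
                      min_off = max(2L, ceiling(0.1 * ncol(em$values)))) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (em$unit != "fpkm")
    stop("off_noise expects FPKM values", call. = FALSE)
  v <- em$values
  off <- v < off_thresh
  n_off <- rowSums(off)
  noise <- vapply(seq_len(nrow(v)), function(g) {
    if (n_off[g] < min_off) return(NA_real_)
    stats::sd(v[g, off[g, ]])
  }, numeric(1))
  data.frame(gene = rownames(v), off_noise = noise, n_off = n_off,
             max_expr = apply(v, 1L, max), mean_expr = rowMeans(v),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Low- and high-OFF-noise gene classes
#'
#' Splits genes into a low-OFF-noise class (noise strictly below `low_max`)
#' and a high-OFF-noise class (noise strictly above `high_min`), both
#' restricted to genes with at least a moderate ON expression level
#' (`max_expr >= min_max_expr`) so that "quietly OFF" is judged only for
#' genes that are convincingly ON somewhere.
#'
#' @param stats Output of [off_noise()].
#' @param low_max Upper bound (exclusive) for the low-noise class
#'   (default 0.2).
#' @param high_min Lower bound (exclusive) for the high-noise class
#'   (default 0.3).
#' @param min_max_expr Minimum maximum expression (default 20 FPKM).
#' @return List with character vectors `low` and `high`.
#' @export
select_noise_classes <- function(stats, low_max = 0.2, high_min = 0.3,
                                 min_max_expr = 20) {
  if (low_max <= 0 || high_min <= 0 || low_max >= high_min)
    stop("need 0 < low_max < high_min", call. = FALSE)
  ok <- !is.na(stats$off_noise) & stats$max_expr >= min_max_expr
  list(low = stats$gene[ok & stats$off_noise < low_max],
       high = stats$gene[ok & stats$off_noise > high_min])
}

#' Gene-family over-representation (hypergeometric)
#'
#' Upper-tail hypergeometric test of the overlap between a gene list and
#' each family: p = P[X >= overlap] where X counts family members in a
#' random draw of `|list|` genes from the universe.
#'
#' @param gene_list Character vector, a subset of `universe`.
#' @param universe Character vector of all eligible genes.
#' @param fams A `gene_families` list (members are intersected with the
#'   universe).
#' @param sig_thresh Significance threshold on p (default 1e-5).
#' @return A data.frame with one row per family: `family`, `overlap`,
#'   `family_size`, `list_size`, `universe_size`, `p`, `significant`,
#'   sorted by p.
#' @export
enrichment <- function(gene_list, universe, fams, sig_thresh = 1e-5) {
  gene_list <- unique(gene_list)
  universe <- unique(universe)
  if (!all(gene_list %in% universe))
    stop("gene list is not a subset of the universe", call. = FALSE)
  n_u <- length(universe)
  n_l <- length(gene_list)
  res <- lapply(names(fams), function(nm) {
    fam <- intersect(fams[[nm]], universe)
    k <- length(intersect(fam, gene_list))
    p <- stats::phyper(k - 1, length(fam), n_u - length(fam), n_l,
                       lower.tail = FALSE)
    data.frame(family = nm, overlap = k, family_size = length(fam),
               list_size = n_l, universe_size = n_u, p = p,
               significant = p < sig_thresh, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$p), , drop = FALSE]
}

#' Orthogonality of a gene set's expression patterns
#'
#' Mean over all unordered gene pairs of (1 - Pearson correlation) of their
#' population-mean expression patterns (log2(x + 1) scale): 0 for a fully
#' redundant family, around 1 for independent patterns, up to 2 for
#' anticorrelated ones. Genes with constant patterns (undefined correlation)
#' are excluded.
#'
#' @param pm A `PopulationMatrix` (log-transformed here if not already).
#' @param genes Gene ids to evaluate (>= 2 usable after exclusions).
#' @return Mean pairwise decorrelation, a single number in [0, 2].
#' @export
orthogonality <- function(pm, genes) {
  stopifnot(inherits(pm, "PopulationMatrix"))
  v <- if (pm$log2) pm$values else log2p1(pm$values)
  v <- v[genes, , drop = FALSE]
  keep <- apply(v, 1L, stats::sd) > 0
  v <- v[keep, , drop = FALSE]
  if (nrow(v) < 2L)
    stop("fewer than 2 genes with non-constant patterns", call. = FALSE)
  cc <- stats::cor(t(v))
  mean(1 - cc[upper.tri(cc)])
}

#' Orthogonality Z-score against a random-set null
#'
#' Compares a family's orthogonality to the distribution over random
#' same-size gene sets drawn (without replacement) from a universe.
#' Families smaller than `min_size` within the universe are skipped, since
#' the null variance grows sharply for small sets.
#'
#' @param pm A `PopulationMatrix`.
#' @param family Gene ids of the family.
#' @param universe Gene ids defining the null sampling pool.
#' @param n_draws Number of null draws (default 1000).
#' @param min_size Minimum family size within the universe (default 50).
#' @param seed Integer seed for the null draws.
#' @return A list of class `orthogonality_result` with `family_size`,
#'   `observed`, `null_mean`, `null_sd`, `z`, `ci99` (empirical 0.5%/99.5%
#'   quantiles), `n_draws`, `seed`; or, for a too-small family, a list with
#'   `skipped = TRUE` and a `reason`.
#' @export
orthogonality_z <- function(pm, family, universe, n_draws = 1000L,
                            min_size = 50L, seed = 1L) {
  fam <- intersect(family, universe)
  if (length(fam) < min_size) {
    return(structure(list(skipped = TRUE,
                          reason = sprintf("family size %d below minimum %d",
                                           length(fam), min_size),
                          family_size = length(fam)),
                     class = "orthogonality_result"))
  }
  obs <- orthogonality(pm, fam)
  null <- with_stream(seed, "orthogonality_null", {
    vapply(seq_len(n_draws), function(i) {
      orthogonality(pm, sample(universe, length(fam)))
    }, numeric(1))
  })
  structure(
    list(skipped = FALSE, family_size = length(fam), observed = obs,
         null_mean = mean(null), null_sd = stats::sd(null),
         z = (obs - mean(null)) / stats::sd(null),
         ci99 = stats::quantile(null, c(0.005, 0.995), names = FALSE),
         n_draws = n_draws, seed = seed),
    class = "orthogonality_result"
  )
}

#' Default orthogonality universe: genes expressed somewhere
#'
#' Genes whose maximum population-mean expression reaches `min_expr`
#' (1 FPKM by default), the pool from which random null sets are drawn.
#'
#' @param pm A `PopulationMatrix` on the linear scale.
#' @param min_expr Expression floor (default 1).
#' @return Character vector of gene ids.
#' @export
expressed_universe <- function(pm, min_expr = 1) {
  stopifnot(inherits(pm, "PopulationMatrix"))
  v <- pm$values
  if (pm$log2) min_expr <- log2p1(min_expr)
  rownames(v)[apply(v, 1L, max) >= min_expr]
}

#' Pan-neuronal gene filter
#'
#' Selects genes expressed consistently across all neuronal populations and
#' at most weakly in nonneuronal ones. Writing NE for the vector of
#' neuronal population means and NNE for the nonneuronal one (replicate-
#' averaged FPKM), a gene passes iff all seven conditions hold (all strict):
#' (1) mean NE > 20; (2) min NE > 5; (3) mean NE > max NNE;
#' (4) min NE > mean NNE; (5) mean NE > 4 x mean NNE;
#' (6) mean NE > mean NNE + 2 x sd NNE; (7) mean NE - 2 x sd NE > mean NNE.
#' Standard deviations are across populations.
#'
#' @param pm A `PopulationMatrix` of FPKM means (linear scale) whose
#'   `is_neuronal` flags mark the neuronal populations.
#' @param detail If `TRUE`, return the per-gene logical condition matrix
#'   instead of the passing gene set.
#' @return Character vector of pan-neuronal gene ids, or (with
#'   `detail = TRUE`) a logical gene x condition matrix with a `pass`
#'   column.
#' @export
pan_neuronal <- function(pm, detail = FALSE) {
  stopifnot(inherits(pm, "PopulationMatrix"))
  if (pm$log2)
    stop("pan_neuronal expects linear-scale FPKM population means",
         call. = FALSE)
  if (!any(pm$is_neuronal) || !any(!pm$is_neuronal))
    stop("need at least one neuronal and one nonneuronal population",
         call. = FALSE)
  ne <- pm$values[, pm$is_neuronal, drop = FALSE]
  nne <- pm$values[, !pm$is_neuronal, drop = FALSE]
  mean_ne <- rowMeans(ne); min_ne <- apply(ne, 1L, min)
  sd_ne <- apply(ne, 1L, stats::sd)
  mean_nne <- rowMeans(nne); max_nne <- apply(nne, 1L, max)
  sd_nne <- apply(nne, 1L, stats::sd)
  # single nonneuronal/neuronal population: sd undefined, treated as 0
  sd_ne[is.na(sd_ne)] <- 0
  sd_nne[is.na(sd_nne)] <- 0

  cond <- cbind(
    c1 = mean_ne > 20,
    c2 = min_ne > 5,
    c3 = mean_ne > max_nne,
    c4 = min_ne > mean_nne,
    c5 = mean_ne > 4 * mean_nne,
    c6 = mean_ne > mean_nne + 2 * sd_nne,
    c7 = mean_ne - 2 * sd_ne > mean_nne
  )
  rownames(cond) <- rownames(pm$values)
  if (detail) return(cbind(cond, pass = rowSums(cond) == ncol(cond)))
  rownames(cond)[rowSums(cond) == ncol(cond)]
}
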