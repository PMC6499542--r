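# Gene-length binning and length-resolved summaries of diversity metrics,
# plus the between- vs within-group fold-change test per length bin.

#' Logarithmic gene-length bins
#'
#' Bin index = floor(bins_per_log * log10(length in bp)), four bins per
#' decade by default, so bin 16 covers 10-17.8 kb and bins >= 20 cover
#' genes of 100 kb and longer.
#'
#' @param gt A [gene_table()] (lengths >= 1 bp).
#' @param bins_per_log Bins per factor-of-10 of length (default 4).
#' @return A `length_bins` object: list with `bin` (named integer per
#'   gene), `bins_per_log`, and `genes` split by bin.
#' @export
length_bins <- function(gt, bins_per_log = 4L) {
  if (any(gt$length < 1)) stop("gene lengths must be >= 1 bp", call. = FALSE)
  bin <- floor(bins_per_log * log10(gt$length))
  names(bin) <- gt$gene
  structure(
    list(bin = bin, bins_per_log = bins_per_log,
         genes = split(gt$gene, bin)),
    class = "length_bins"
  )
}

#' Lower length bound (bp) of each bin index
#' @param bins A `length_bins`.
#' @param bin Integer bin indices.
#' @return Numeric lower bounds in bp.
#' @export
bin_lower_bp <- function(bins, bin) 10^(bin / bins$bins_per_log)

#' Summarize a per-gene metric within length bins
#'
#' @param metric Named numeric vector (gene -> value); `NA`/`NaN` values
#'   are excluded. Infinite values are kept (they propagate to the mean).
#' @param bins A `length_bins`.
#' @return A data.frame with one row per non-empty bin: `bin`,
#'   `length_from_bp`, `n`, `mean`, `median`.
#' @export
binned_metric <- function(metric, bins) {
  stopifnot(inherits(bins, "length_bins"))
  rows <- lapply(names(bins$genes), function(b) {
    vals <- metric[intersect(bins$genes[[b]], names(metric))]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) return(NULL)
    data.frame(bin = as.integer(b),
               length_from_bp = bin_lower_bp(bins, as.integer(b)),
               n = length(vals), mean = mean(vals),
               median = stats::median(vals))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out[order(out$bin), , drop = FALSE]
}

#' Fraction of expressed genes that are long, per population
#'
#' For each population: the number of expressed genes (mean expression
#' strictly above `expr_thresh`) at least `length_thresh` bp long, divided
#' by the number of all expressed genes. With `weighted = TRUE`, the
#' expression-weighted share of long genes instead.
#'
#' @param pm A `PopulationMatrix` on the linear scale.
#' @param gt A [gene_table()].
#' @param length_thresh Long-gene cutoff in bp (default 100 kb).
#' @param expr_thresh Expression cutoff (default 1).
#' @param weighted Use the expression-weighted share.
#' @return Named numeric vector per population (`NA` where no gene is
#'   expressed).
#' @export
long_gene_fraction <- function(pm, gt, length_thresh = 1e5, expr_thresh = 1,
                               weighted = FALSE) {
  stopifnot(inherits(pm, "PopulationMatrix"))
  if (length_thresh <= 0 || expr_thresh < 0)
    stop("invalid thresholds", call. = FALSE)
  len <- gt$length[match(rownames(pm$values), gt$gene)]
  if (anyNA(len)) stop("gene lengths missing", call. = FALSE)
  long <- len >= length_thresh
  apply(pm$values, 2L, function(x) {
    expr <- x > expr_thresh
    if (!any(expr)) return(NA_real_)
    if (weighted) sum(x[expr & long]) / sum(x[expr])
    else sum(expr & long) / sum(expr)
  })
}

#' Between- vs within-group fold-change test per length bin
#'
#' Asks, per length bin, whether two populations differ in expression more
#' than their replicates do. For each gene the between-group statistic is
#' the absolute difference of group means (log2(x + 1) scale) and the
#' within-group statistics are the absolute replicate differences, pooled
#' from both groups; each is standardized by the standard error factor of
#' its contrast (sqrt(1/n_a + 1/n_b) for the mean difference, sqrt(2) for
#' a replicate pair) so that under the null of no group difference both
#' have the same distribution. A one-sided Mann-Whitney test per bin asks
#' whether between-group fold-changes are stochastically larger, with
#' Benjamini-Hochberg adjustment across bins. Bins with fewer than
#' `min_genes` genes are excluded.
#'
#' @param em An [ExpressionMatrix()]; both populations need >= 2
#'   replicates.
#' @param pop_a,pop_b Population labels to compare.
#' @param bins A `length_bins` over (at least) the matrix genes.
#' @param alpha Significance level after adjustment (default 0.05).
#' @param min_genes Minimum genes per bin (default 10).
#' @param long_thresh_bp Long-gene boundary for the summary fractions
#'   (default 100 kb).
#' @return A `length_bias_result`: list with `bins` (data.frame: `bin`,
#'   `length_from_bp`, `n_genes`, `p`, `q`, `significant`),
#'   `frac_long_significant`, `frac_short_significant`, `alpha`.
#' @export
length_bias_test <- function(em, pop_a, pop_b, bins, alpha = 0.05,
                             min_genes = 10L, long_thresh_bp = 1e5) {
  stopifnot(inherits(em, "ExpressionMatrix"), inherits(bins, "length_bins"))
  sa <- em$samples$sample[em$samples$population == pop_a]
  sb <- em$samples$sample[em$samples$population == pop_b]
  if (length(sa) < 2L || length(sb) < 2L)
    stop("both populations need >= 2 replicates", call. = FALSE)
  v <- em$values
  if (!em$unit %in% c("log2fpkm1", "log2cpm1")) v <- log2p1(v)
  va <- v[, sa, drop = FALSE]
  vb <- v[, sb, drop = FALSE]

  between <- abs(rowMeans(va) - rowMeans(vb)) /
    sqrt(1 / length(sa) + 1 / length(sb))
  within_of <- function(m) {
    cmb <- utils::combn(ncol(m), 2L)
    w <- abs(m[, cmb[1L, ], drop = FALSE] - m[, cmb[2L, ], drop = FALSE]) /
      sqrt(2)
    w
  }
  wa <- within_of(va)
  wb <- within_of(vb)

  res <- lapply(names(bins$genes), function(b) {
    g <- intersect(bins$genes[[b]], rownames(v))
    if (length(g) < min_genes) return(NULL)
    p <- stats::wilcox.test(between[g], c(wa[g, ], wb[g, ]),
                            alternative = "greater", exact = FALSE)$p.value
    data.frame(bin = as.integer(b),
               length_from_bp = bin_lower_bp(bins, as.integer(b)),
               n_genes = length(g), p = p)
  })
  tab <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(tab) || nrow(tab) == 0L)
    stop("no bin has enough genes", call. = FALSE)
  tab <- tab[order(tab$bin), , drop = FALSE]
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  tab$significant <- tab$q < alpha
  long <- tab$length_from_bp >= long_thresh_bp
  structure(
    list(bins = tab,
         frac_long_significant = if (any(long)) mean(tab$significant[long])
                                 else NA_real_,
         frac_short_significant = if (any(!long)) mean(tab$significant[!long])
                                  else NA_real_,
         alpha = alpha),
    class = "length_bias_result"
  )
}
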