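# NNLS decomposition of query expression profiles against reference
# cluster panels: informative-gene selection, quantile normalization,
# purity scoring and split-half cross-validation.

#' One-way ANOVA F statistic per gene
#'
#' Between-class mean square over within-class mean square of expression
#' across populations, the usual screen for genes that vary across classes.
#' Values are placed on the log2(x + 1) scale unless already log.
#'
#' @param em An [ExpressionMatrix()]; at least 2 populations and at least
#'   2 replicates overall beyond the population count.
#' @return Named numeric vector of F statistics; `Inf` where the
#'   within-class variance is zero but the between-class variance is not.
#' @export
anova_f <- function(em) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  pops <- populations(em)
  v <- em$values
  if (!em$unit %in% c("log2fpkm1", "log2cpm1")) v <- log2p1(v)
  grp <- em$samples$population
  k <- length(pops)
  n <- ncol(v)
  if (k < 2L || n - k < 1L)
    stop("need >= 2 populations and residual degrees of freedom",
         call. = FALSE)
  means <- sapply(pops, function(p) rowMeans(v[, grp == p, drop = FALSE]))
  if (is.null(dim(means)))
    means <- matrix(means, nrow = 1, dimnames = list(rownames(v), pops))
  nrep <- as.integer(table(grp)[pops])
  grand <- rowSums(means * rep(nrep, each = nrow(v))) / n
  ss_between <- rowSums(sweep(means, 1L, grand)^2 *
                          rep(nrep, each = nrow(v)))
  ss_within <- rowSums((v - means[, match(grp, pops), drop = FALSE])^2)
  f <- (ss_between / (k - 1)) / (ss_within / (n - k))
  f[ss_between == 0 & ss_within == 0] <- 0
  names(f) <- rownames(v)
  f
}

#' Select informative, non-redundant genes for decomposition
#'
#' Walks genes in descending F order (from the primary dataset) and accepts
#' a candidate only if its Differentiation Matrix is sufficiently different
#' -- Jaccard index strictly below `jaccard_max` -- from every previously
#' accepted gene's DM, in every supplied dataset. This avoids stacking the
#' panel with genes that all separate the same (easily separated) cell
#' classes. Two genes whose DMs are both empty are treated as redundant
#' (Jaccard 1).
#'
#' @param f Named per-gene F statistics from the primary dataset.
#' @param dms A `dm_collection` or list of them (one per dataset); genes
#'   must be common to all.
#' @param jaccard_max Jaccard threshold (default 0.5); `1` disables the
#'   redundancy filter (plain top-n by F).
#' @param n_genes Number of genes to select (default 500).
#' @return Character vector of selected gene ids, in acceptance order.
#' @export
select_decomposition_genes <- function(f, dms, jaccard_max = 0.5,
                                       n_genes = 500L) {
  if (inherits(dms, "dm_collection")) dms <- list(dms)
  if (length(dms) == 0L) stop("no Differentiation Matrices supplied",
                              call. = FALSE)
  genes <- names(sort(f, decreasing = TRUE))
  for (d in dms) {
    if (!all(genes %in% rownames(d$pairs)))
      stop("genes missing from a dm_collection", call. = FALSE)
  }
  mats <- lapply(dms, function(d) d$pairs[genes, , drop = FALSE])

  selected <- integer(0)
  for (g in seq_along(genes)) {
    ok <- TRUE
    for (m in mats) {
      row_g <- m[g, ]
      for (s in selected) {
        row_s <- m[s, ]
        inter <- sum(row_g & row_s)
        uni <- sum(row_g | row_s)
        jac <- if (uni == 0L) 1 else inter / uni
        if (jac >= jaccard_max) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (jaccard_max >= 1) ok <- TRUE
    if (ok) selected <- c(selected, g)
    if (length(selected) >= n_genes) break
  }
  genes[selected]
}

#' Quantile-normalize a profile to a target distribution
#'
#' Replaces the value at each rank of `query` by the target value at the
#' same rank, so the output's sorted values equal the sorted target
#' exactly. Tied query values all receive the mean of the target values at
#' the tied ranks. Idempotent: normalizing an already-normalized profile is
#' a no-op (up to tie averaging).
#'
#' @param query Numeric vector.
#' @param target Numeric vector of the same length (any order; sorted
#'   internally).
#' @return Numeric vector, same length and names as `query`.
#' @export
quantile_normalize_to <- function(query, target) {
  if (length(query) != length(target))
    stop("query and target lengths differ", call. = FALSE)
  qs <- sort(target)
  ord <- order(query)
  out <- numeric(length(query))
  sorted_q <- query[ord]
  # walk runs of tied query values; each run gets the mean target value
  i <- 1L
  n <- length(query)
  while (i <= n) {
    j <- i
    while (j < n && sorted_q[j + 1L] == sorted_q[i]) j <- j + 1L
    out[ord[i:j]] <- mean(qs[i:j])
    i <- j + 1L
  }
  names(out) <- names(query)
  out
}

#' Build a reference panel from cluster-average profiles
#'
#' Stores the gene x cluster matrix of log2-scale cluster means restricted
#' to the selected genes, together with the target quantile distribution:
#' the element-wise mean of the sorted per-cluster profiles (so queries can
#' be mapped onto the panel's value distribution before decomposition).
#'
#' @param pm A `PopulationMatrix` of reference cluster means (log2 scale;
#'   transformed here if not).
#' @param genes Informative genes to keep (default all).
#' @return A `reference_panel`: list with `profiles` (gene x cluster),
#'   `clusters`, `genes`, `target` (sorted reference distribution).
#' @export
reference_panel <- function(pm, genes = NULL) {
  stopifnot(inherits(pm, "PopulationMatrix"))
  v <- if (pm$log2) pm$values else log2p1(pm$values)
  genes <- genes %||% rownames(v)
  v <- v[genes, , drop = FALSE]
  target <- rowMeans(apply(v, 2L, sort))
  structure(
    list(profiles = v, clusters = colnames(v), genes = genes,
         target = target),
    class = "reference_panel"
  )
}

#' Non-negative least-squares decomposition of a query profile
#'
#' Solves min || A x - b ||_2 subject to x >= 0, where A is the panel's
#' gene x cluster matrix and b the (quantile-normalized) query profile.
#' The purity score is the largest coefficient divided by the coefficient
#' sum -- near 1 when the query matches a single reference cluster.
#'
#' @param panel A [reference_panel()].
#' @param query Named numeric vector over the panel genes (a gene x query
#'   matrix is accepted for multiple queries), or an `ExpressionMatrix`.
#' @param normalize Quantile-normalize each query to the panel target
#'   first (default `TRUE`).
#' @return A data.frame with one row per query: cluster coefficients,
#'   `residual_norm`, `purity` (`NA` when all coefficients are zero), plus
#'   attribute `"coefficients"` (cluster x query matrix).
#' @export
nnls_decompose <- function(panel, query, normalize = TRUE) {
  stopifnot(inherits(panel, "reference_panel"))
  q <- if (inherits(query, "ExpressionMatrix")) query$values else query
  if (is.null(dim(q))) q <- matrix(q, ncol = 1,
                                   dimnames = list(names(q), "query"))
  if (!all(panel$genes %in% rownames(q)))
    stop("query lacks panel genes", call. = FALSE)
  q <- q[panel$genes, , drop = FALSE]

  a <- panel$profiles
  zero_col <- colSums(a != 0) == 0L
  if (any(zero_col))
    warning("all-zero reference profiles, coefficients forced to 0: ",
            paste(panel$clusters[zero_col], collapse = ", "), call. = FALSE)
  a_fit <- a[, !zero_col, drop = FALSE]

  coefs <- matrix(0, length(panel$clusters), ncol(q),
                  dimnames = list(panel$clusters, colnames(q)))
  resid <- numeric(ncol(q))
  for (k in seq_len(ncol(q))) {
    b <- q[, k]
    if (normalize) b <- quantile_normalize_to(b, panel$target)
    if (all(b == 0) || ncol(a_fit) == 0L) {
      resid[k] <- sqrt(sum(b^2))
      next
    }
    fit <- pracma::lsqnonneg(a_fit, b)
    coefs[!zero_col, k] <- fit$x
    resid[k] <- sqrt(max(fit$resid.norm, 0))
  }
  tot <- colSums(coefs)
  purity <- ifelse(tot > 0, apply(coefs, 2L, max) / tot, NA_real_)
  out <- data.frame(query = colnames(q), t(coefs),
                    residual_norm = resid, purity = purity,
                    check.names = FALSE, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "coefficients") <- coefs
  out
}

#' Split-half decomposition cross-validation
#'
#' Splits each population's replicates into two halves by acquisition-order
#' parity, builds a reference panel from half B's population means (top
#' `n_genes` by cross-population variance), and decomposes each half-A
#' population mean against it. A well-separated dataset yields purity near
#' 1 for every population; populations that are transcriptionally confusable
#' share their coefficients and drop in purity.
#'
#' @param em An [ExpressionMatrix()]; populations with fewer than 2
#'   replicates are excluded with a warning.
#' @param n_genes Panel size (default 500).
#' @param normalize Quantile-normalize half-A profiles to the panel target.
#' @return List with `purity` (named per population), `mean_purity`, and
#'   the full `decomposition` table.
#' @export
cross_validate <- function(em, n_genes = 500L, normalize = TRUE) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  pops <- populations(em)
  counts <- table(em$samples$population)[pops]
  drop <- names(counts)[counts < 2L]
  if (length(drop)) {
    warning("excluding singleton populations: ",
            paste(drop, collapse = ", "), call. = FALSE)
    keep <- em$samples$sample[!em$samples$population %in% drop]
    em <- subset_samples(em, keep)
    pops <- populations(em)
  }

  rank_in_pop <- stats::ave(em$samples$order, em$samples$population,
                            FUN = function(x) rank(x, ties.method = "first"))
  half_a <- em$samples$sample[rank_in_pop %% 2L == 1L]
  half_b <- em$samples$sample[rank_in_pop %% 2L == 0L]
  pm_a <- population_means(subset_samples(em, half_a), log_transform = TRUE)
  pm_b <- population_means(subset_samples(em, half_b), log_transform = TRUE)

  v <- pm_b$values
  sel <- names(sort(apply(v, 1L, stats::var),
                    decreasing = TRUE))[seq_len(min(n_genes, nrow(v)))]
  panel <- reference_panel(pm_b, sel)
  dec <- nnls_decompose(panel, pm_a$values[sel, , drop = FALSE],
                        normalize = normalize)
  purity <- stats::setNames(dec$purity, dec$query)
  list(purity = purity, mean_purity = mean(purity, na.rm = TRUE),
       decomposition = dec)
}

#' Subset an ExpressionMatrix to selected samples
#' @param em An [ExpressionMatrix()].
#' @param samples Sample ids to keep.
#' @return An `ExpressionMatrix`.
#' @export
subset_samples <- function(em, samples) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  idx <- match(samples, em$samples$sample)
  if (anyNA(idx)) stop("unknown samples", call. = FALSE)
  ExpressionMatrix(
    em$values[, idx, drop = FALSE],
    sample_population = stats::setNames(em$samples$population[idx],
                                        em$samples$sample[idx]),
    sample_order = stats::setNames(em$samples$order[idx],
                                   em$samples$sample[idx]),
    is_neuronal = stats::setNames(em$samples$is_neuronal[idx],
                                  em$samples$sample[idx]),
    unit = em$unit
  )
}
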