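# DEF / FCR diversity metrics and greedy combinatorial-code search over
# Differentiation Matrices.

#' Differentially expressed fraction (DEF)
#'
#' The fraction of unordered population pairs a gene distinguishes: the
#' number of 1 entries in its Differentiation Matrix (off-diagonal, counted
#' once per pair) divided by P(P-1)/2.
#'
#' @param dm Either a `dm_collection` (returns a named vector, one DEF per
#'   gene) or a single symmetric binary P x P matrix.
#' @return DEF value(s) in [0, 1].
#' @export
def_score <- function(dm) {
  if (inherits(dm, "dm_collection")) {
    return(rowMeans(dm$pairs))
  }
  if (!is.matrix(dm) || nrow(dm) != ncol(dm) || nrow(dm) < 2L)
    stop("need a square P x P matrix with P >= 2", call. = FALSE)
  p <- nrow(dm)
  sum(dm[upper.tri(dm)] != 0) / (p * (p - 1) / 2)
}

#' Fold-change ratio (FCR)
#'
#' Mean absolute log2 fold-change over distinguished pairs divided by the
#' mean over undistinguished pairs: a signal-to-noise measure of how robust
#' a gene's pair distinctions are. `NaN` when the gene distinguishes no pair
#' (no signal to rate); `Inf` when every pair is distinguished or the
#' undistinguished pairs have mean fold-change zero.
#'
#' @param dm A `dm_collection`, or a single square binary matrix.
#' @param lfc For the single-matrix form, a symmetric matrix of absolute
#'   log2 fold-changes; ignored for a `dm_collection` (which carries its
#'   own).
#' @return FCR value(s); `NaN` / `Inf` as described.
#' @export
fcr_score <- function(dm, lfc = NULL) {
  if (inherits(dm, "dm_collection")) {
    if (is.null(dm$lfc)) stop("dm_collection carries no fold-changes",
                              call. = FALSE)
    on <- dm$pairs
    alfc <- abs(dm$lfc)
    n_on <- rowSums(on)
    n_off <- ncol(on) - n_on
    num <- rowSums(alfc * on) / n_on
    den <- rowSums(alfc * !on) / n_off
    out <- num / den
    out[n_on == 0L] <- NaN
    out[n_on > 0L & (n_off == 0L | den == 0)] <- Inf
    names(out) <- rownames(on)
    return(out)
  }
  if (is.null(lfc)) stop("supply 'lfc' for the matrix form", call. = FALSE)
  ut <- upper.tri(dm)
  on <- dm[ut] != 0
  if (!any(on)) return(NaN)
  if (all(on) || mean(abs(lfc[ut])[!on]) == 0) return(Inf)
  mean(abs(lfc[ut])[on]) / mean(abs(lfc[ut])[!on])
}

#' Per-gene DEF and FCR table
#'
#' @param dmc A `dm_collection` with fold-changes.
#' @return A data.frame with columns `gene`, `def`, `fcr`,
#'   `n_distinguished`, `n_pairs`.
#' @export
diversity_scores <- function(dmc) {
  stopifnot(inherits(dmc, "dm_collection"))
  data.frame(
    gene = rownames(dmc$pairs),
    def = unname(def_score(dmc)),
    fcr = unname(fcr_score(dmc)),
    n_distinguished = unname(rowSums(dmc$pairs)),
    n_pairs = ncol(dmc$pairs),
    stringsAsFactors = FALSE
  )
}

#' Top genes by DEF or FCR
#'
#' Ranks genes for "top n" lists. For FCR, genes with infinite FCR are
#' placed first (ordered among themselves by DEF, descending) followed by
#' finite FCR in descending order; genes with undefined FCR (DEF = 0) are
#' never selected. For DEF, plain descending order.
#'
#' @param scores Output of [diversity_scores()].
#' @param by `"fcr"` or `"def"`.
#' @param n Number of genes to return.
#' @return Character vector of gene ids.
#' @export
top_genes <- function(scores, by = c("fcr", "def"), n = 1000L) {
  by <- match.arg(by)
  if (by == "def") {
    ord <- order(-scores$def, scores$gene)
  } else {
    s <- scores[!is.nan(scores$fcr), , drop = FALSE]
    inf <- s[is.infinite(s$fcr), , drop = FALSE]
    fin <- s[is.finite(s$fcr), , drop = FALSE]
    ids <- c(inf$gene[order(-inf$def, inf$gene)],
             fin$gene[order(-fin$fcr, fin$gene)])
    return(utils::head(ids, n))
  }
  utils::head(scores$gene[ord], n)
}

#' Combined DEF of a gene set
#'
#' DEF of the element-wise logical OR of the genes' Differentiation
#' Matrices: the fraction of pairs distinguished by at least one gene in
#' the set.
#'
#' @param dmc A `dm_collection`.
#' @param genes Gene ids or indices (default: all genes in `dmc`).
#' @return A single DEF value in [0, 1].
#' @export
combined_def <- function(dmc, genes = NULL) {
  stopifnot(inherits(dmc, "dm_collection"))
  m <- if (is.null(genes)) dmc$pairs else dmc$pairs[genes, , drop = FALSE]
  if (nrow(m) == 0L) stop("empty gene set", call. = FALSE)
  mean(colSums(m) > 0L)
}

#' Greedy combinatorial-code search
#'
#' Selects a small set of genes whose combined Differentiation Matrix
#' distinguishes at least a target fraction of population pairs. The first
#' pick is the candidate with the highest individual DEF; each subsequent
#' pick maximizes the marginal gain in combined DEF, irrespective of its
#' individual DEF. Ties are broken by higher individual DEF, then by
#' lexicographic gene id, making the result deterministic. The search stops
#' when the combined DEF reaches `threshold` or no candidate adds coverage.
#'
#' @param dmc A `dm_collection`.
#' @param candidates Gene ids to search over (default all).
#' @param threshold Target combined DEF in (0, 1].
#' @return A `code_result`: list with `genes` (ordered picks),
#'   `combined_def` (after each addition), `threshold`, `achieved`.
#' @export
greedy_code <- function(dmc, candidates = NULL, threshold = 0.99) {
  stopifnot(inherits(dmc, "dm_collection"))
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]", call. = FALSE)
  candidates <- candidates %||% rownames(dmc$pairs)
  if (length(candidates) == 0L) stop("empty candidate set", call. = FALSE)
  m <- dmc$pairs[candidates, , drop = FALSE]
  ids <- rownames(m)
  indiv <- rowSums(m)
  n_pairs <- ncol(m)

  covered <- rep(FALSE, n_pairs)
  picked <- character(0)
  traj <- numeric(0)
  avail <- rep(TRUE, nrow(m))
  repeat {
    gain <- rowSums(m[, !covered, drop = FALSE] & TRUE)  # marginal new pairs
    gain[!avail] <- -1L
    best <- max(gain)
    if (best <= 0) break
    cand <- which(gain == best)
    cand <- cand[order(-indiv[cand], ids[cand])]
    pick <- cand[1L]
    avail[pick] <- FALSE
    covered <- covered | m[pick, ]
    picked <- c(picked, ids[pick])
    traj <- c(traj, mean(covered))
    if (traj[length(traj)] >= threshold) break
  }
  structure(
    list(genes = picked, combined_def = traj, threshold = threshold,
         achieved = length(traj) > 0 && traj[length(traj)] >= threshold),
    class = "code_result"
  )
}

#' @export
print.code_result <- function(x, ...) {
  cat(sprintf("code_result: %d genes, combined DEF %.4f (threshold %.2f, %s)\n",
              length(x$genes),
              if (length(x$combined_def)) max(x$combined_def) else 0,
              x$threshold,
              if (x$achieved) "achieved" else "not achieved"))
  invisible(x)
}

#' DEF of a partition (Gini-Simpson identity)
#'
#' A gene whose expression partitions populations into discrete classes
#' distinguishes exactly the between-class pairs, and its DEF equals
#' (P^2 - sum n_k^2) / (P^2 - P) -- the Gini-Simpson diversity index of the
#' class sizes, rescaled to unordered pairs.
#'
#' @param partition Vector of class labels, one per population.
#' @return DEF in [0, 1].
#' @export
gini_simpson_def <- function(partition) {
  p <- length(partition)
  if (p < 2L) stop("need >= 2 populations", call. = FALSE)
  nk <- table(partition)
  (p^2 - sum(nk^2)) / (p^2 - p)
}
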