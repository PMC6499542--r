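# Pairwise differential expression across populations and per-gene
# Differentiation Matrices.
#
# The model is a one-factor linear model per gene (population as the only
# factor) with a pooled residual variance, shrunk towards a common prior by
# empirical Bayes: gene-wise variances are treated as draws from a scaled
# inverse-chi-square prior (d0, s0^2) whose hyperparameters are estimated by
# method of moments on the log variances, and the moderated variance is the
# usual weighted combination (d0*s0^2 + d*s^2) / (d0 + d).

#' Fit the one-factor population model per gene
#'
#' Values are placed on the log2(x + 1) scale (unless already log) and a
#' linear model with population as the only factor is fit to every gene,
#' giving population means, a pooled residual variance per gene, and
#' empirical-Bayes moderated variances. Hyperparameters (prior df `d0`,
#' prior variance `s0^2`) are estimated by matching moments of the log
#' residual variances against the scaled-F distribution they follow under
#' the prior; genes with zero residual variance are excluded from the
#' moment fit but still receive a moderated variance.
#'
#' @param em An [ExpressionMatrix()]; at least two populations and at least
#'   one population with two or more replicates.
#' @param max_replicates If set, restrict each population to its most
#'   recently acquired `max_replicates` replicates (by `order`) before
#'   fitting, the convention used to equalize power across populations.
#' @param prior_df,prior_var Optional overrides for the estimated
#'   hyperparameters; `prior_df = 0` disables moderation entirely and
#'   `prior_df = Inf` pins every variance at `prior_var`.
#' @return A `group_fit` object: list with `means` (gene x population, log2
#'   scale), `s2` (residual variance), `df_residual`, `df_prior`,
#'   `var_prior`, `s2_post`, `n_replicates` per population, `populations`,
#'   `genes`.
#' @export
fit_group_model <- function(em, max_replicates = NULL, prior_df = NULL,
                            prior_var = NULL) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  pops <- populations(em)
  if (length(pops) < 2L) stop("need >= 2 populations", call. = FALSE)

  keep <- unlist(lapply(pops, function(p) {
    rows <- which(em$samples$population == p)
    if (!is.null(max_replicates) && length(rows) > max_replicates)
      rows <- rows[order(em$samples$order[rows],
                         decreasing = TRUE)][seq_len(max_replicates)]
    rows
  }))
  v <- em$values[, keep, drop = FALSE]
  grp <- em$samples$population[keep]
  if (!em$unit %in% c("log2fpkm1", "log2cpm1")) v <- log2p1(v)

  n <- ncol(v)
  d <- n - length(pops)
  if (d <= 0L)
    stop("no residual degrees of freedom: all populations singleton",
         call. = FALSE)

  means <- sapply(pops, function(p) rowMeans(v[, grp == p, drop = FALSE]))
  if (is.null(dim(means)))
    means <- matrix(means, nrow = 1, dimnames = list(rownames(v), pops))
  n_rep <- stats::setNames(as.integer(table(grp)[pops]), pops)
  rss <- rowSums((v - means[, match(grp, pops), drop = FALSE])^2)
  s2 <- rss / d

  if (is.null(prior_df) || is.null(prior_var)) {
    hp <- fit_variance_prior(s2, d)
    prior_df <- prior_df %||% hp$df_prior
    prior_var <- prior_var %||% hp$var_prior
  }
  s2_post <- if (is.infinite(prior_df)) {
    rep(prior_var, length(s2))
  } else {
    (prior_df * prior_var + d * s2) / (prior_df + d)
  }

  structure(
    list(means = means, s2 = s2, df_residual = d, df_prior = prior_df,
         var_prior = prior_var, s2_post = s2_post, n_replicates = n_rep,
         populations = pops, genes = rownames(v)),
    class = "group_fit"
  )
}

#' Method-of-moments fit of the variance prior
#'
#' Under a scaled inverse-chi-square prior, the observed gene variances are
#' s0^2 times F(d, d0) variates, so z = log(s2) has mean and variance
#' expressible through digamma/trigamma functions of d/2 and d0/2. Matching
#' the empirical variance of z gives d0 (via a Newton inversion of the
#' trigamma function) and the empirical mean then gives s0^2.
#'
#' @param s2 Gene-wise residual variances (positive entries are used).
#' @param d Residual degrees of freedom.
#' @return List with `df_prior` (possibly `Inf`) and `var_prior`.
#' @export
fit_variance_prior <- function(s2, d) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 2L)
    stop("need at least 2 positive variances to fit the prior", call. = FALSE)
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  ebar <- mean(e)
  evar <- stats::var(e) * (length(e) - 1) / length(e)
  excess <- evar - trigamma(d / 2)
  if (excess <= 0) {
    # no detectable spread of true variances: infinitely strong prior
    return(list(df_prior = Inf, var_prior = exp(ebar)))
  }
  d0 <- 2 * trigamma_inverse(excess)
  s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  list(df_prior = d0, var_prior = s02)
}

# Newton inversion of trigamma on (0, Inf); x > 0.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Moderated-t contrasts for every unordered population pair
#'
#' For each pair (i, j): log2 fold-change delta = mean_i - mean_j, moderated
#' t = delta / sqrt(s2_post * (1/n_i + 1/n_j)), two-sided p from a
#' t-distribution on d0 + d degrees of freedom, and Benjamini-Hochberg
#' q-values computed across genes (by default within each pair).
#'
#' @param fit A `group_fit` from [fit_group_model()].
#' @param bh Scope of the Benjamini-Hochberg adjustment: `"per_pair"`
#'   (default) adjusts across genes within each population pair; `"global"`
#'   adjusts across all genes and pairs jointly.
#' @return A `pairwise_de` object: list with gene x pair matrices `lfc`,
#'   `t`, `p`, `q`; `populations`; `pair_i`; `pair_j`; `pair_labels`.
#' @export
pairwise_contrasts <- function(fit, bh = c("per_pair", "global")) {
  stopifnot(inherits(fit, "group_fit"))
  bh <- match.arg(bh)
  px <- pair_index(fit$populations)
  n <- fit$n_replicates
  df_total <- fit$df_prior + fit$df_residual

  lfc <- fit$means[, px$i, drop = FALSE] - fit$means[, px$j, drop = FALSE]
  sefac <- sqrt(1 / n[px$i] + 1 / n[px$j])
  se <- sqrt(fit$s2_post) %o% sefac
  tt <- lfc / se
  tt[lfc == 0] <- 0  # 0/0 when a gene is constant and fully shrunk
  p <- 2 * stats::pt(-abs(tt), df = df_total)
  p[!is.finite(tt)] <- 0
  q <- if (bh == "per_pair") {
    matrix(apply(p, 2L, stats::p.adjust, method = "BH"), nrow(p), ncol(p))
  } else {
    matrix(stats::p.adjust(p, method = "BH"), nrow(p), ncol(p))
  }
  dn <- list(fit$genes, px$labels)
  dimnames(lfc) <- dimnames(tt) <- dimnames(p) <- dimnames(q) <- dn

  structure(
    list(lfc = lfc, t = tt, p = p, q = q, populations = fit$populations,
         pair_i = px$i, pair_j = px$j, pair_labels = px$labels),
    class = "pairwise_de"
  )
}

#' Differentiation Matrices from pairwise tests
#'
#' A gene distinguishes a pair of populations when its absolute log2
#' fold-change strictly exceeds `lfc_thresh` and its q-value is strictly
#' below `q_thresh`. The result stores, per gene, the symmetric binary
#' population x population matrix in flattened pair form.
#'
#' @param de A `pairwise_de` from [pairwise_contrasts()].
#' @param lfc_thresh Absolute log2 fold-change threshold (default 2).
#' @param q_thresh q-value threshold (default 0.05).
#' @return A `dm_collection`: list with logical gene x pair matrix `pairs`,
#'   numeric `lfc`, `populations`, `pair_i`, `pair_j`, `pair_labels`.
#' @export
build_dm <- function(de, lfc_thresh = 2, q_thresh = 0.05) {
  stopifnot(inherits(de, "pairwise_de"))
  if (lfc_thresh <= 0 || q_thresh <= 0)
    stop("thresholds must be positive", call. = FALSE)
  new_dm_collection(abs(de$lfc) > lfc_thresh & de$q < q_thresh,
                    abs(de$lfc), de$populations, de$pair_i, de$pair_j,
                    de$pair_labels)
}

#' Differentiation Matrices from cluster-average profiles
#'
#' For reference datasets where only cluster averages are available (no
#' replicate structure), a pair is distinguished when the absolute
#' difference of log2 cluster means strictly exceeds `lfc_thresh`
#' (default 1).
#'
#' @param pm A `PopulationMatrix` on the log2(x + 1) scale (transformed here
#'   if not already).
#' @param lfc_thresh Absolute log2 fold-change threshold (default 1).
#' @return A `dm_collection`.
#' @export
build_dm_from_means <- function(pm, lfc_thresh = 1) {
  stopifnot(inherits(pm, "PopulationMatrix"))
  v <- if (pm$log2) pm$values else log2p1(pm$values)
  px <- pair_index(colnames(v))
  lfc <- abs(v[, px$i, drop = FALSE] - v[, px$j, drop = FALSE])
  dimnames(lfc) <- list(rownames(v), px$labels)
  new_dm_collection(lfc > lfc_thresh, lfc, colnames(v), px$i, px$j,
                    px$labels)
}

new_dm_collection <- function(pairs, lfc, populations, pair_i, pair_j,
                              pair_labels) {
  structure(
    list(pairs = pairs, lfc = lfc, populations = populations,
         pair_i = pair_i, pair_j = pair_j, pair_labels = pair_labels),
    class = "dm_collection"
  )
}

#' @export
print.dm_collection <- function(x, ...) {
  cat(sprintf("dm_collection: %d genes x %d population pairs (%d populations)\n",
              nrow(x$pairs), ncol(x$pairs), length(x$populations)))
  invisible(x)
}

#' Expand one gene's Differentiation Matrix to square form
#'
#' @param dmc A `dm_collection`.
#' @param gene Gene id or row index.
#' @return A symmetric 0/1 integer matrix with zero diagonal.
#' @export
dm_matrix <- function(dmc, gene) {
  stopifnot(inherits(dmc, "dm_collection"))
  p <- length(dmc$populations)
  m <- matrix(0L, p, p, dimnames = list(dmc$populations, dmc$populations))
  on <- dmc$pairs[gene, ]
  m[cbind(dmc$pair_i[on], dmc$pair_j[on])] <- 1L
  m[cbind(dmc$pair_j[on], dmc$pair_i[on])] <- 1L
  m
}

#' Write a dm_collection to a pair of TSV files
#'
#' The distinguished-pair indicator matrix goes to `path` (genes x pair
#' columns, 0/1, with a `gene` id column); absolute fold-changes, when
#' present, go to the same path with suffix `.lfc`.
#'
#' @param dmc A `dm_collection`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_dm_collection <- function(dmc, path) {
  stopifnot(inherits(dmc, "dm_collection"))
  tab <- data.frame(gene = rownames(dmc$pairs), dmc$pairs * 1L,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(dmc$lfc)) {
    utils::write.table(
      data.frame(gene = rownames(dmc$pairs), dmc$lfc,
                 check.names = FALSE, stringsAsFactors = FALSE),
      paste0(path, ".lfc"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a dm_collection written by [write_dm_collection()]
#'
#' @param path TSV path; a companion `.lfc` file is read when present.
#' @return A `dm_collection`.
#' @export
load_dm_collection <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  pairs <- as.matrix(tab[, -1L, drop = FALSE]) != 0
  rownames(pairs) <- tab$gene
  labels <- colnames(pairs)
  pops <- unique(unlist(strsplit(labels, "|", fixed = TRUE)))
  px <- pair_index(pops)
  if (!identical(px$labels, labels))
    stop("pair columns are not in canonical order", call. = FALSE)
  lfc <- NULL
  if (file.exists(paste0(path, ".lfc"))) {
    lt <- utils::read.delim(paste0(path, ".lfc"), check.names = FALSE,
                            stringsAsFactors = FALSE)
    lfc <- as.matrix(lt[, -1L, drop = FALSE])
    rownames(lfc) <- lt$gene
  }
  new_dm_collection(pairs, lfc, pops, px$i, px$j, px$labels)
}

#' Subset a dm_collection to selected genes
#' @param dmc A `dm_collection`.
#' @param genes Gene ids or indices.
#' @return A `dm_collection` over the selected genes.
#' @export
dm_subset <- function(dmc, genes) {
  new_dm_collection(dmc$pairs[genes, , drop = FALSE],
                    if (!is.null(dmc$lfc)) dmc$lfc[genes, , drop = FALSE],
                    dmc$populations, dmc$pair_i, dmc$pair_j, dmc$pair_labels)
}
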