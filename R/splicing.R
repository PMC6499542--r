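# Alternative-donor branch usage: donor units, branch probabilities,
# Dirichlet-multinomial likelihood-ratio test, and splice DEF.
#
# The unit of testing is the set of junctions sharing one donor site
# ("donor unit", m >= 2 acceptors). Acceptor usage within a unit is modeled
# per sample as Dirichlet-multinomial with mean usage pi (on the simplex)
# and concentration phi shared between groups; differential usage between
# two groups of samples is a likelihood-ratio test of group-specific pi
# against shared pi, on m - 1 degrees of freedom.

#' Group junctions into alternative-donor units
#'
#' Junctions sharing (chrom, strand, donor position) form one unit;
#' acceptors are ordered by ascending genomic position and per-sample
#' counts collected into a sample x acceptor matrix (absent records are
#' zero). Units with a single acceptor are dropped: they carry no
#' alternative-usage information.
#'
#' @param jt A [junction_table()].
#' @param samples Sample ids defining the row order (default: all samples
#'   present in `jt`, sorted).
#' @return List of `donor_unit` objects: each a list with `chrom`,
#'   `strand`, `donor`, `acceptors`, `counts` (sample x acceptor matrix),
#'   `gene`, `id`.
#' @export
group_junctions_by_donor <- function(jt, samples = NULL) {
  stopifnot(inherits(jt, "junction_table"))
  samples <- samples %||% sort(unique(jt$sample))
  key <- paste(jt$chrom, jt$strand, jt$donor, sep = ":")
  units <- lapply(split(seq_len(nrow(jt)), key), function(rows) {
    sub <- jt[rows, , drop = FALSE]
    acceptors <- sort(unique(sub$acceptor))
    if (length(acceptors) < 2L) return(NULL)
    cnt <- matrix(0, length(samples), length(acceptors),
                  dimnames = list(samples, as.character(acceptors)))
    cnt[cbind(match(sub$sample, samples),
              match(sub$acceptor, acceptors))] <- sub$count
    gene <- unique(sub$gene[!is.na(sub$gene)])
    structure(
      list(chrom = sub$chrom[1L], strand = sub$strand[1L],
           donor = sub$donor[1L], acceptors = acceptors, counts = cnt,
           gene = if (length(gene) == 1L) gene else NA_character_,
           id = paste(sub$chrom[1L], sub$strand[1L], sub$donor[1L],
                      sep = ":")),
      class = "donor_unit"
    )
  })
  units <- units[!vapply(units, is.null, logical(1))]
  names(units) <- vapply(units, `[[`, character(1), "id")
  units
}

#' Per-sample branch probabilities of a donor unit
#'
#' p_i = count_i / total for each acceptor, per sample; samples whose total
#' junctional reads at the donor do not exceed `min_reads` are untestable
#' and get `NA`.
#'
#' @param unit A `donor_unit`.
#' @param min_reads Read-total prerequisite; testable means total >
#'   `min_reads` (default 10).
#' @return Sample x acceptor matrix of branch probabilities (`NA` rows for
#'   untestable samples).
#' @export
branch_probabilities <- function(unit, min_reads = 10) {
  tot <- rowSums(unit$counts)
  p <- unit$counts / tot
  p[tot <= min_reads, ] <- NA_real_
  p
}

#' Dirichlet-multinomial log-likelihood
#'
#' Log-likelihood of per-sample acceptor count vectors under a
#' Dirichlet-multinomial with parameters alpha = phi * pi, dropping the
#' multinomial coefficient (constant across the hypotheses compared here):
#' sum over samples of log Gamma(phi) - log Gamma(n + phi) +
#' sum_i [log Gamma(y_i + phi pi_i) - log Gamma(phi pi_i)].
#'
#' @param counts Sample x acceptor count matrix (a single vector is
#'   accepted).
#' @param pi Mean usage vector on the simplex.
#' @param phi Concentration, > 0.
#' @return Log-likelihood (scalar).
#' @export
dirmult_loglik <- function(counts, pi, phi) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  if (!is.finite(phi) || phi <= 0 || any(!is.finite(pi)) || any(pi < 0))
    stop("non-finite or invalid Dirichlet-multinomial parameters",
         call. = FALSE)
  alpha <- phi * pi
  n <- rowSums(counts)
  sum(lgamma(phi) - lgamma(n + phi)) +
    sum(lgamma(sweep(counts, 2L, alpha, "+")) -
          rep(lgamma(alpha), each = nrow(counts)))
}

# Shared MLE machinery ------------------------------------------------------

# additive log-ratio transform (last category reference) and inverse
alr <- function(pi) log(pi[-length(pi)] / pi[length(pi)])
alr_inv <- function(theta) {
  e <- exp(c(theta, 0))
  e / sum(e)
}

# moment estimate of pi from pooled counts, kept off the simplex boundary
pi_moment <- function(counts, eps = 1e-3) {
  p <- colSums(counts) + eps
  p / sum(p)
}

# Per-category and per-total digamma sums entering the score equations:
# A_i = sum_s [digamma(y_si + alpha_i) - digamma(alpha_i)],
# B   = sum_s [digamma(phi) - digamma(n_s + phi)].
dirmult_score_parts <- function(counts, pi, phi) {
  alpha <- phi * pi
  n <- rowSums(counts)
  a <- colSums(digamma(sweep(counts, 2L, alpha, "+"))) -
    nrow(counts) * digamma(alpha)
  b <- nrow(counts) * digamma(phi) - sum(digamma(n + phi))
  list(a = a, b = b)
}

fit_dirmult_null <- function(counts, phi_init = 10, maxit = 500L) {
  m <- ncol(counts)
  start <- c(alr(pi_moment(counts)), log(phi_init))
  fn <- function(theta) {
    -dirmult_loglik(counts, alr_inv(theta[seq_len(m - 1L)]),
                    exp(theta[m]))
  }
  gr <- function(theta) {
    pi <- alr_inv(theta[seq_len(m - 1L)])
    phi <- exp(theta[m])
    sp <- dirmult_score_parts(counts, pi, phi)
    abar <- sum(sp$a * pi)
    -c(phi * pi[-m] * (sp$a[-m] - abar), phi * (sp$b + abar))
  }
  opt <- stats::optim(start, fn, gr, method = "L-BFGS-B",
                      lower = c(rep(-25, m - 1L), log(1e-4)),
                      upper = c(rep(25, m - 1L), log(1e6)),
                      control = list(maxit = maxit))
  list(pi = alr_inv(opt$par[seq_len(m - 1L)]), phi = exp(opt$par[m]),
       loglik = -opt$value, converged = opt$convergence == 0L)
}

# Usage fit with the concentration held fixed (nuisance estimated under
# the null): optimizes pi only, on the alr scale.
fit_dirmult_pi <- function(counts, phi, maxit = 500L) {
  m <- ncol(counts)
  start <- alr(pi_moment(counts))
  fn <- function(theta) -dirmult_loglik(counts, alr_inv(theta), phi)
  gr <- function(theta) {
    pi <- alr_inv(theta)
    sp <- dirmult_score_parts(counts, pi, phi)
    abar <- sum(sp$a * pi)
    -(phi * pi[-m] * (sp$a[-m] - abar))
  }
  opt <- stats::optim(start, fn, gr, method = "L-BFGS-B",
                      lower = rep(-25, m - 1L), upper = rep(25, m - 1L),
                      control = list(maxit = maxit))
  list(pi = alr_inv(opt$par), loglik = -opt$value,
       converged = opt$convergence == 0L)
}

#' Dirichlet-multinomial likelihood-ratio test for differential usage
#'
#' Tests whether two groups of samples use a donor unit's acceptors with
#' different mean proportions. Null: one shared usage vector pi and
#' concentration phi, fit jointly by bounded quasi-Newton maximum
#' likelihood on transformed parameters. Alternative: group-specific
#' pi_a, pi_b with the same phi -- the concentration is a nuisance
#' parameter estimated once under the null and held fixed, which keeps the
#' test calibrated at small replicate numbers (re-estimating phi under the
#' alternative lets group splits absorb overdispersion and inflates the
#' statistic). LRT = 2(ll_alt - ll_null) is referred to a chi-square with
#' m - 1 degrees of freedom. Samples whose read total does not exceed
#' `min_reads` are dropped (not zero-filled); the pair is untestable when
#' either group loses all its samples. PSI vectors are computed from
#' pooled counts per group; `max_dpsi` is the largest absolute
#' per-acceptor difference.
#'
#' @param counts_a,counts_b Sample x acceptor count matrices for the two
#'   groups (equal acceptor sets, same order).
#' @param min_reads Per-sample read-total prerequisite (default 10,
#'   strict).
#' @return A `branch_test` list: `testable`, `lrt`, `p`, `df`, `psi_a`,
#'   `psi_b`, `max_dpsi`, `phi`, `pi_a`, `pi_b`, `n_a`, `n_b`, and
#'   `reason` when untestable.
#' @export
dirmult_lrt <- function(counts_a, counts_b, min_reads = 10) {
  if (is.null(dim(counts_a))) counts_a <- matrix(counts_a, nrow = 1)
  if (is.null(dim(counts_b))) counts_b <- matrix(counts_b, nrow = 1)
  if (ncol(counts_a) != ncol(counts_b))
    stop("acceptor sets differ between groups", call. = FALSE)
  m <- ncol(counts_a)
  a <- counts_a[rowSums(counts_a) > min_reads, , drop = FALSE]
  b <- counts_b[rowSums(counts_b) > min_reads, , drop = FALSE]
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(structure(list(testable = FALSE,
                          reason = "no sample exceeds the read prerequisite",
                          lrt = NA_real_, p = NA_real_, df = m - 1L,
                          psi_a = NULL, psi_b = NULL,
                          max_dpsi = NA_real_),
                     class = "branch_test"))
  }
  null_fit <- fit_dirmult_null(rbind(a, b))
  fit_a <- fit_dirmult_pi(a, null_fit$phi)
  fit_b <- fit_dirmult_pi(b, null_fit$phi)
  if (!null_fit$converged || !fit_a$converged || !fit_b$converged) {
    return(structure(list(testable = FALSE,
                          reason = "optimizer did not converge",
                          lrt = NA_real_, p = NA_real_, df = m - 1L,
                          psi_a = NULL, psi_b = NULL,
                          max_dpsi = NA_real_),
                     class = "branch_test"))
  }
  lrt <- max(0, 2 * (fit_a$loglik + fit_b$loglik - null_fit$loglik))
  psi_a <- colSums(a) / sum(a)
  psi_b <- colSums(b) / sum(b)
  structure(
    list(testable = TRUE, lrt = lrt,
         p = stats::pchisq(lrt, df = m - 1L, lower.tail = FALSE),
         df = m - 1L, psi_a = psi_a, psi_b = psi_b,
         max_dpsi = max(abs(psi_a - psi_b)), phi = null_fit$phi,
         pi_a = fit_a$pi, pi_b = fit_b$pi,
         n_a = nrow(a), n_b = nrow(b)),
    class = "branch_test"
  )
}

#' Pairwise differential-usage tests for all donor units
#'
#' Runs [dirmult_lrt()] for every donor unit and every unordered pair of
#' populations.
#'
#' @param units List of `donor_unit` from [group_junctions_by_donor()].
#' @param sample_population Named character vector mapping sample id to
#'   population.
#' @param min_reads Read prerequisite per sample (default 10).
#' @param bh Also compute BH-adjusted p-values across donors within each
#'   pair (`FALSE` by default: the differentiation rule uses raw p).
#' @return A data.frame with one row per donor x pair: `donor`, `gene`,
#'   `pair`, `pop_i`, `pop_j`, `testable`, `lrt`, `p`, `max_dpsi` (and
#'   `q` when `bh = TRUE`).
#' @export
splice_pairwise_tests <- function(units, sample_population, min_reads = 10,
                                  bh = FALSE) {
  pops <- unique(unname(sample_population))
  px <- pair_index(pops)
  rows <- list()
  for (u in units) {
    smp <- rownames(u$counts)
    pop_of <- sample_population[smp]
    for (k in seq_len(px$n_pairs)) {
      pa <- pops[px$i[k]]; pb <- pops[px$j[k]]
      res <- dirmult_lrt(u$counts[pop_of == pa, , drop = FALSE],
                         u$counts[pop_of == pb, , drop = FALSE],
                         min_reads = min_reads)
      rows[[length(rows) + 1L]] <- data.frame(
        donor = u$id, gene = u$gene, pair = px$labels[k],
        pop_i = pa, pop_j = pb, testable = res$testable,
        lrt = res$lrt, p = res$p, max_dpsi = res$max_dpsi,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (bh) {
    out$q <- stats::ave(out$p, out$pair, FUN = function(p) {
      q <- p
      q[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
      q
    })
  }
  out
}

#' Splice Differentiation Matrices per donor unit
#'
#' A donor distinguishes a population pair when the pair is testable, the
#' Dirichlet-multinomial p-value is strictly below `p_thresh`, and the
#' maximum absolute PSI difference strictly exceeds `dpsi_thresh`.
#' Untestable pairs count as undistinguished.
#'
#' @param tests Output of [splice_pairwise_tests()].
#' @param p_thresh p-value threshold (default 0.05); applied to the `q`
#'   column instead when `use_bh = TRUE` and present.
#' @param dpsi_thresh Maximum delta-PSI threshold (default 0.1).
#' @param use_bh Use BH-adjusted p-values when available.
#' @return A `dm_collection` over donor units (no fold-changes; FCR does
#'   not apply).
#' @export
splice_dm <- function(tests, p_thresh = 0.05, dpsi_thresh = 0.1,
                      use_bh = FALSE) {
  pvals <- if (use_bh && "q" %in% names(tests)) tests$q else tests$p
  hit <- tests$testable & !is.na(pvals) & pvals < p_thresh &
    tests$max_dpsi > dpsi_thresh
  donors <- unique(tests$donor)
  pops <- unique(c(tests$pop_i, tests$pop_j))
  px <- pair_index(pops)
  m <- matrix(FALSE, length(donors), px$n_pairs,
              dimnames = list(donors, px$labels))
  m[cbind(match(tests$donor, donors), match(tests$pair, px$labels))] <- hit
  dmc <- new_dm_collection(m, NULL, pops, px$i, px$j, px$labels)
  attr(dmc, "gene") <- stats::setNames(
    tests$gene[!duplicated(tests$donor)], tests$donor[!duplicated(tests$donor)])
  dmc
}

#' Per-gene combined splice DEF
#'
#' A pair of populations is distinguished by a gene when any of the gene's
#' donor units distinguishes it: the gene's splice DEF is the DEF of the
#' OR over its donors' Differentiation Matrices.
#'
#' @param donor_dm A `dm_collection` over donor units (from
#'   [splice_dm()]).
#' @param gene_of Named character vector donor id -> gene id; defaults to
#'   the mapping attached by [splice_dm()].
#' @return Named numeric vector: splice DEF per gene.
#' @export
gene_splice_def <- function(donor_dm, gene_of = NULL) {
  stopifnot(inherits(donor_dm, "dm_collection"))
  gene_of <- gene_of %||% attr(donor_dm, "gene")
  if (is.null(gene_of)) stop("no donor-to-gene mapping available",
                             call. = FALSE)
  donors <- rownames(donor_dm$pairs)
  genes <- gene_of[donors]
  ok <- !is.na(genes)
  grp <- split(which(ok), genes[ok])
  vapply(grp, function(rows) {
    mean(colSums(donor_dm$pairs[rows, , drop = FALSE]) > 0L)
  }, numeric(1))
}
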