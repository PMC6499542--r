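# Seeded generators for expression matrices and junction tables with known
# ground truth. The defaults emulate the statistical structure the
# analyses assume: ON/OFF marker genes with near-silent OFF states, long
# "effector" genes with graded expression differences across populations,
# and housekeeping genes with no population structure; junction tables
# carry group-specific Dirichlet-multinomial acceptor usage.

#' Gene-class specification for the expression simulator
#'
#' @param name Class label recorded in the truth table.
#' @param n Number of genes.
#' @param type `"on_off_marker"` (ON in a random population subset, near
#'   zero elsewhere), `"graded"` (log-normal population means,
#'   independently per population), or `"constant"` (one mean everywhere).
#' @param length_meanlog,length_sdlog Log-normal parameters of gene length
#'   in bp.
#' @param on_mean Mean FPKM in the ON state (markers), the log-normal
#'   median across populations (graded), or the flat mean (constant).
#' @param on_fraction Probability a population is ON (markers only; at
#'   least one ON and one OFF population are enforced).
#' @param off_mean OFF-state leak mean in FPKM (markers; small but nonzero
#'   so OFF noise is near, not exactly, zero).
#' @param spread_log2 Population-to-population SD of log2 mean expression
#'   (graded class).
#' @param dispersion Negative-binomial dispersion (variance =
#'   mu + mu^2 * dispersion).
#' @return A `gene_class_spec` list.
#' @export
gene_class_spec <- function(name, n, type = c("on_off_marker", "graded",
                                              "constant"),
                            length_meanlog = log(1e4), length_sdlog = 0.6,
                            on_mean = 50, on_fraction = 0.2,
                            off_mean = 0.01, spread_log2 = 3,
                            dispersion = 0.05) {
  type <- match.arg(type)
  if (n < 0 || on_fraction < 0 || on_fraction > 1 || dispersion < 0 ||
      on_mean < 0 || off_mean < 0)
    stop("invalid gene-class specification", call. = FALSE)
  structure(list(name = name, n = as.integer(n), type = type,
                 length_meanlog = length_meanlog,
                 length_sdlog = length_sdlog, on_mean = on_mean,
                 on_fraction = on_fraction, off_mean = off_mean,
                 spread_log2 = spread_log2, dispersion = dispersion),
            class = "gene_class_spec")
}

#' Simulation configuration
#'
#' The default configuration emulates a profiled-population study at desk
#' scale: 12 populations x 3 replicates; 80 ON/OFF marker genes (short, ON
#' at 100 FPKM in ~15% of populations, OFF leak 0.01 FPKM), 80 long graded
#' effector genes (length centered at 150 kb, log2 spread 3 across
#' populations), and 840 housekeeping genes; a quarter of the populations
#' nonneuronal; library sizes log-normal around 5 million reads.
#'
#' @param n_populations,n_replicates Populations and replicates per
#'   population.
#' @param classes List of [gene_class_spec()] objects.
#' @param frac_nonneuronal Fraction of populations flagged nonneuronal.
#' @param libsize_meanlog,libsize_sdlog Log-normal library-size
#'   parameters.
#' @param seed Master seed; all randomness derives from it through named
#'   streams.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_populations = 12L, n_replicates = 3L,
                       classes = NULL, frac_nonneuronal = 0.25,
                       libsize_meanlog = log(5e6), libsize_sdlog = 0.2,
                       seed = 1L) {
  if (n_populations < 2L || n_replicates < 1L ||
      frac_nonneuronal < 0 || frac_nonneuronal >= 1)
    stop("invalid simulation configuration", call. = FALSE)
  classes <- classes %||% list(
    gene_class_spec("marker", 80L, "on_off_marker",
                    length_meanlog = log(5e3), length_sdlog = 0.5,
                    on_mean = 100, on_fraction = 0.15, off_mean = 0.01,
                    dispersion = 0.05),
    gene_class_spec("effector", 80L, "graded",
                    length_meanlog = log(1.5e5), length_sdlog = 0.4,
                    on_mean = 20, spread_log2 = 3, dispersion = 0.1),
    gene_class_spec("housekeeping", 840L, "constant",
                    length_meanlog = log(1e4), length_sdlog = 0.6,
                    on_mean = 50, dispersion = 0.05)
  )
  for (cl in classes) {
    if (!inherits(cl, "gene_class_spec"))
      stop("classes must be gene_class_spec objects", call. = FALSE)
  }
  structure(list(n_populations = as.integer(n_populations),
                 n_replicates = as.integer(n_replicates), classes = classes,
                 frac_nonneuronal = frac_nonneuronal,
                 libsize_meanlog = libsize_meanlog,
                 libsize_sdlog = libsize_sdlog, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a count matrix with known ground truth
#'
#' Per-gene, per-population mean FPKM values are drawn according to the
#' gene class; expected counts scale the FPKM by gene length (kb) and
#' library size (millions), and observed counts are negative binomial with
#' the class dispersion. Fully deterministic given the configuration seed.
#'
#' @param cfg A [sim_config()].
#' @return List with `counts` (an [ExpressionMatrix()], unit `"count"`),
#'   `gene_table` (with a `class` column), and `truth` (list: `class`,
#'   `on_populations` per marker gene, `mean_fpkm` gene x population,
#'   `length`, `is_neuronal` per population).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  p <- cfg$n_populations
  r <- cfg$n_replicates
  pops <- sprintf("pop%02d", seq_len(p))
  n_genes <- sum(vapply(cfg$classes, `[[`, integer(1), "n"))
  genes <- sprintf("g%04d", seq_len(n_genes))
  cls <- rep(vapply(cfg$classes, `[[`, character(1), "name"),
             vapply(cfg$classes, `[[`, integer(1), "n"))

  lens <- with_stream(cfg$seed, "lengths", {
    unlist(lapply(cfg$classes, function(cl) {
      pmax(200, round(stats::rlnorm(cl$n, cl$length_meanlog,
                                    cl$length_sdlog)))
    }))
  })
  names(lens) <- genes

  on_pops <- vector("list", n_genes)
  names(on_pops) <- genes
  mean_fpkm <- with_stream(cfg$seed, "means", {
    mm <- matrix(0, n_genes, p, dimnames = list(genes, pops))
    g0 <- 0L
    for (cl in cfg$classes) {
      idx <- g0 + seq_len(cl$n)
      if (cl$type == "on_off_marker") {
        for (g in idx) {
          k <- stats::rbinom(1L, p - 2L, cl$on_fraction) + 1L  # 1..P-1 ON
          on <- sample(p, k)
          mm[g, ] <- cl$off_mean
          mm[g, on] <- cl$on_mean
          on_pops[[g]] <- pops[sort(on)]
        }
      } else if (cl$type == "graded") {
        # cap at two decades above the class median: keeps single extreme
        # genes from dominating a sample's library and distorting every
        # other gene's FPKM (real FPKM distributions are similarly bounded)
        mm[idx, ] <- pmin(
          cl$on_mean * 2^matrix(stats::rnorm(cl$n * p, 0, cl$spread_log2),
                                cl$n, p),
          100 * cl$on_mean)
      } else {
        mm[idx, ] <- cl$on_mean
      }
      g0 <- g0 + cl$n
    }
    mm
  })

  n_smp <- p * r
  smp <- sprintf("%s_r%d", rep(pops, each = r), rep(seq_len(r), p))
  libsize <- with_stream(cfg$seed, "libsize", {
    stats::rlnorm(n_smp, cfg$libsize_meanlog, cfg$libsize_sdlog)
  })

  disp <- rep(vapply(cfg$classes, `[[`, numeric(1), "dispersion"),
              vapply(cfg$classes, `[[`, integer(1), "n"))
  pop_of <- rep(seq_len(p), each = r)
  counts <- with_stream(cfg$seed, "counts", {
    mu <- mean_fpkm[, pop_of, drop = FALSE] * (lens / 1000) *
      rep(libsize / 1e6, each = n_genes)
    cm <- matrix(stats::rnbinom(length(mu), mu = mu,
                                size = rep(1 / pmax(disp, 1e-8),
                                           ncol(mu))),
                 n_genes, n_smp)
    dimnames(cm) <- list(genes, smp)
    cm
  })

  n_nonneuro <- round(cfg$frac_nonneuronal * p)
  is_neuro_pop <- rep(TRUE, p)
  if (n_nonneuro > 0)
    is_neuro_pop[with_stream(cfg$seed, "neuronal",
                             sample(p, n_nonneuro))] <- FALSE
  names(is_neuro_pop) <- pops

  em <- ExpressionMatrix(
    counts,
    sample_population = stats::setNames(pops[pop_of], smp),
    sample_order = stats::setNames(seq_len(n_smp), smp),
    is_neuronal = stats::setNames(is_neuro_pop[pop_of], smp),
    unit = "count"
  )
  gt <- gene_table(genes, lens, class = cls)
  list(counts = em, gene_table = gt,
       truth = list(class = stats::setNames(cls, genes),
                    on_populations = on_pops, mean_fpkm = mean_fpkm,
                    length = lens, is_neuronal = is_neuro_pop))
}

#' Simulate junction tables with Dirichlet-multinomial acceptor usage
#'
#' Each donor unit gets `m` acceptors (2 or 3) and a usage regime:
#' `"shared"` donors use one usage vector in every population (the null
#' case); `"all_or_none"` donors draw, per population, a usage vector near
#' a random simplex vertex, producing the strongly bimodal branch
#' probabilities characteristic of real alternative donors. Per sample,
#' coverage is Poisson and acceptor counts are Dirichlet-multinomial with
#' concentration `phi`.
#'
#' @param cfg A [sim_config()] (populations, replicates, seed).
#' @param n_donors Number of donor units.
#' @param frac_all_or_none Fraction of donors in the all-or-none regime.
#' @param phi Dirichlet-multinomial concentration.
#' @param coverage_mean Mean junctional read total per sample.
#' @param m_choices Acceptor counts to sample from (default 2:3).
#' @return List with `junctions` (a [junction_table()]) and `truth`
#'   (per donor: `regime`, `m`, `pi` population x acceptor usage, `phi`,
#'   `gene`).
#' @export
simulate_junctions <- function(cfg, n_donors = 50L, frac_all_or_none = 0.5,
                               phi = 20, coverage_mean = 50,
                               m_choices = 2:3) {
  stopifnot(inherits(cfg, "sim_config"))
  if (n_donors < 1L || frac_all_or_none < 0 || frac_all_or_none > 1 ||
      phi <= 0 || coverage_mean <= 0)
    stop("invalid junction simulation spec", call. = FALSE)
  p <- cfg$n_populations
  r <- cfg$n_replicates
  pops <- sprintf("pop%02d", seq_len(p))
  smp <- sprintf("%s_r%d", rep(pops, each = r), rep(seq_len(r), p))
  pop_of <- rep(seq_len(p), each = r)

  with_stream(cfg$seed, "junctions", {
    regime <- rep("shared", n_donors)
    regime[sample(n_donors, round(frac_all_or_none * n_donors))] <-
      "all_or_none"
    rows <- list()
    truth <- list()
    for (d in seq_len(n_donors)) {
      m <- sample(m_choices, 1L)
      donor_pos <- 1e4 * d
      acceptors <- donor_pos + 1000L * seq_len(m)
      if (regime[d] == "shared") {
        base <- as.numeric(stats::rgamma(m, 2)) + 0.2
        pi_pop <- matrix(base / sum(base), p, m, byrow = TRUE)
      } else {
        pi_pop <- t(vapply(seq_len(p), function(i) {
          v <- rep(0.02 / (m - 1), m)
          v[sample(m, 1L)] <- 0.98
          v
        }, numeric(m)))
      }
      gene <- sprintf("sg%03d", d)
      for (s in seq_along(smp)) {
        n_reads <- stats::rpois(1L, coverage_mean)
        if (n_reads == 0L) next
        alpha <- phi * pi_pop[pop_of[s], ]
        w <- stats::rgamma(m, alpha)
        if (sum(w) == 0) w <- rep(1, m)
        cnt <- stats::rmultinom(1L, n_reads, w / sum(w))[, 1L]
        keep <- cnt > 0
        if (!any(keep)) next
        rows[[length(rows) + 1L]] <- data.frame(
          sample = smp[s], chrom = "chr1", strand = "+",
          donor = donor_pos, acceptor = acceptors[keep],
          count = cnt[keep], gene = gene, stringsAsFactors = FALSE)
      }
      truth[[sprintf("chr1:+:%d", donor_pos)]] <-
        list(regime = regime[d], m = m, pi = pi_pop, phi = phi,
             gene = gene)
    }
    tab <- do.call(rbind, rows)
    list(junctions = junction_table(tab$sample, tab$chrom, tab$strand,
                                    tab$donor, tab$acceptor, tab$count,
                                    tab$gene),
         truth = truth)
  })
}
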