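test_that("OFF noise is the n-1 standard deviation over OFF samples", {
  v <- matrix(c(0, 0.6, 0.6, 50,
                0, 0, 0, 80,
                5, 8, 2, 40), 3, 4, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), sprintf("s%d", 1:4)))
  em <- make_em(v, c("A", "A", "B", "B"), unit = "fpkm")
  st <- off_noise(em, min_off = 2)
  expect_equal(st$off_noise[1], sd(c(0, 0.6, 0.6)))
  expect_equal(st$off_noise[2], 0)
  expect_true(is.na(st$off_noise[3]))  # no sample below 1 FPKM
  expect_equal(st$n_off, c(3, 3, 0))
  expect_equal(st$max_expr, c(50, 80, 40))
  expect_error(off_noise(make_em(v, c("A", "A", "B", "B"))), "FPKM")
})

test_that("noise classes split on strict bounds with an expression floor", {
  st <- data.frame(
    gene = sprintf("g%d", 1:6),
    off_noise = c(0.1, 0.25, 0.5, 0.5, 0.2, NA),
    n_off = 5, max_expr = c(100, 100, 100, 5, 100, 100),
    mean_expr = 10, stringsAsFactors = FALSE)
  cl <- select_noise_classes(st, min_max_expr = 20)
  expect_equal(cl$low, "g1")          # 0.1 < 0.2, expressed
  expect_equal(cl$high, "g3")         # 0.5 > 0.3, expressed
  # g2 in the gap, g4 below the expression floor, g5 at the bound, g6 NA
  expect_false(any(c("g2", "g4", "g5", "g6") %in% unlist(cl)))
  expect_error(select_noise_classes(st, low_max = 0.4, high_min = 0.3))
})

test_that("enrichment p is the exact hypergeometric upper tail", {
  fams <- structure(list(f = c("g1", "g2")), class = "gene_families")
  uni <- sprintf("g%d", 1:4)
  res <- enrichment(c("g1", "g2"), uni, fams, sig_thresh = 1e-5)
  expect_equal(res$p, 1 / 6)  # choose(2,2)*choose(2,0)/choose(4,2)
  expect_false(res$significant)
  expect_equal(res$overlap, 2)

  # zero overlap includes the whole tail: p = 1
  fams0 <- structure(list(f = c("g3", "g4")), class = "gene_families")
  expect_equal(enrichment(c("g1", "g2"), uni, fams0)$p, 1)

  expect_error(enrichment(c("g9"), uni, fams), "subset")

  # brute-force tail sum oracle on random small universes
  set.seed(17)
  for (i in 1:20) {
    n_u <- sample(8:30, 1)
    uni <- sprintf("u%d", seq_len(n_u))
    fam <- sample(uni, sample(2:6, 1))
    lst <- sample(uni, sample(3:7, 1))
    k <- length(intersect(fam, lst))
    p_bf <- sum(vapply(k:min(length(fam), length(lst)), function(x) {
      choose(length(fam), x) * choose(n_u - length(fam), length(lst) - x) /
        choose(n_u, length(lst))
    }, numeric(1)))
    res <- enrichment(lst, uni, structure(list(f = fam),
                                          class = "gene_families"))
    expect_equal(res$p, p_bf, tolerance = 1e-12)
  }
})

test_that("orthogonality spans [0, 2] and is affine invariant", {
  pops <- sprintf("P%d", 1:8)
  base <- seq(1, 8)
  v <- rbind(g1 = base, g2 = 2 * base + 3,      # identical pattern shape
             g3 = 9 - base,                     # anticorrelated
             g4 = rep(5, 8))                    # constant: excluded
  colnames(v) <- pops
  pm <- population_matrix(v, log2 = TRUE)
  expect_equal(orthogonality(pm, c("g1", "g2")), 0)
  expect_equal(orthogonality(pm, c("g1", "g3")), 2)
  expect_error(orthogonality(pm, c("g1", "g4")), "fewer than 2")

  # many independent random patterns: mean decorrelation near 1
  set.seed(19)
  n <- 60; p <- 40
  vr <- matrix(rnorm(n * p, 5, 2), n, p,
               dimnames = list(sprintf("r%d", 1:n), sprintf("P%d", 1:p)))
  vr[vr < 0] <- 0
  pmr <- population_matrix(vr, log2 = TRUE)
  ortho <- orthogonality(pmr, rownames(vr))
  se <- 1 / sqrt(p - 3) / sqrt(choose(n, 2) / n)  # generous SE bound
  expect_lt(abs(ortho - 1), 3 * max(se, 0.05))

  # affine rescaling per gene leaves the value unchanged
  vr2 <- vr * rep(runif(n, 0.5, 2), p) + rep(runif(n, 0, 3), p)
  pmr2 <- population_matrix(vr2, log2 = TRUE)
  expect_equal(orthogonality(pmr2, rownames(vr)), ortho, tolerance = 1e-12)
})

test_that("orthogonality Z-scores flag redundant families and skip small ones", {
  set.seed(23)
  n <- 300; p <- 20
  v <- matrix(abs(rnorm(n * p, 5, 2)), n, p,
              dimnames = list(sprintf("g%d", 1:n), sprintf("P%d", 1:p)))
  # a redundant family: near-duplicates of one pattern
  fam <- sprintf("g%d", 1:60)
  v[fam, ] <- rep(v["g1", ], each = 60) +
    matrix(rnorm(60 * p, 0, 0.05), 60, p)
  pm <- population_matrix(v, log2 = TRUE)
  uni <- rownames(v)

  res <- orthogonality_z(pm, fam, uni, n_draws = 200, seed = 5)
  expect_false(res$skipped)
  expect_lt(res$z, -5)
  expect_equal(res$z, (res$observed - res$null_mean) / res$null_sd)

  # family drawn from the null itself: modest |Z|
  fam_null <- sample(setdiff(uni, fam), 60)
  res2 <- orthogonality_z(pm, fam_null, setdiff(uni, fam), n_draws = 200,
                          seed = 6)
  expect_lt(abs(res2$z), 3.5)

  expect_true(orthogonality_z(pm, sprintf("g%d", 1:49), uni)$skipped)
})

test_that("expressed universe applies the population-mean floor", {
  v <- matrix(c(0.5, 0.2, 3, 0.1, 1, 0.9), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("A", "B")))
  pm <- population_matrix(v)
  expect_equal(expressed_universe(pm, 1), c("g2", "g3"))
})

test_that("the pan-neuronal filter applies all seven conditions strictly", {
  # base: NE = 100 in all neuronal pops, NNE = 10
  ne_pops <- sprintf("N%d", 1:10); nne_pops <- sprintf("M%d", 1:10)
  v <- matrix(0, 4, 20, dimnames = list(sprintf("g%d", 1:4),
                                        c(ne_pops, nne_pops)))
  v["g1", ] <- c(rep(100, 10), rep(10, 10))      # passes everything
  v["g2", ] <- c(rep(20, 10), rep(0, 10))        # mean NE = 20: fails (1)
  v["g3", ] <- c(rep(100, 10), rep(30, 10))      # 100 <= 4*30: fails (5)
  v["g4", ] <- 0                                  # fails most
  pm <- population_matrix(v, is_neuronal = stats::setNames(
    rep(c(TRUE, FALSE), each = 10), colnames(v)))
  expect_equal(pan_neuronal(pm), "g1")
  det <- pan_neuronal(pm, detail = TRUE)
  expect_false(det["g2", "c1"]); expect_true(all(det["g2", c("c2", "c3",
                                                             "c4", "c5",
                                                             "c6", "c7")]))
  expect_false(det["g3", "c5"]); expect_true(det["g3", "c1"])

  # raising a nonneuronal value can only shrink the result set
  v2 <- v; v2["g1", "M1"] <- 500
  pm2 <- population_matrix(v2, is_neuronal = stats::setNames(
    rep(c(TRUE, FALSE), each = 10), colnames(v2)))
  expect_true(all(pan_neuronal(pm2) %in% pan_neuronal(pm)))

  expect_error(pan_neuronal(population_matrix(v)), "nonneuronal")
})
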