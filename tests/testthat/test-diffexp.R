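test_that("constant genes get a positive moderated variance floor", {
  set.seed(1)
  v <- matrix(2^rnorm(60, 5) , 10, 6,
              dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:6)))
  v[1, ] <- 32  # identical everywhere: s2 = 0
  em <- make_em(v, rep(c("A", "B"), each = 3), unit = "log2fpkm1")
  fit <- fit_group_model(em)
  expect_equal(fit$s2[1], 0, ignore_attr = TRUE)
  expect_gt(fit$s2_post[1], 0)
  expect_equal(fit$s2_post[1],
               fit$df_prior * fit$var_prior / (fit$df_prior + fit$df_residual),
               ignore_attr = TRUE)
})

test_that("with a zero prior the moderated t equals the pooled t-test", {
  set.seed(42)
  for (i in 1:100) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    v <- matrix(abs(rnorm(n1 + n2, 10, 2)), 1, n1 + n2,
                dimnames = list("g1", sprintf("s%d", seq_len(n1 + n2))))
    em <- make_em(v, rep(c("A", "B"), c(n1, n2)), unit = "log2fpkm1")
    fit <- fit_group_model(em, prior_df = 0, prior_var = 1)
    de <- pairwise_contrasts(fit)
    tt <- t.test(v[1, 1:n1], v[1, n1 + seq_len(n2)], var.equal = TRUE)
    expect_equal(unname(de$t[1, 1]), unname(tt$statistic), tolerance = 1e-10)
    expect_equal(unname(de$p[1, 1]), tt$p.value, tolerance = 1e-10)
  }
})

test_that("fold-changes are antisymmetric and equal means give p = 1", {
  set.seed(7)
  v <- matrix(2^rnorm(36, 4), 6, 6,
              dimnames = list(sprintf("g%d", 1:6), sprintf("s%d", 1:6)))
  v[1, ] <- 16
  em <- make_em(v, rep(c("A", "B", "C"), each = 2), unit = "log2fpkm1")
  de <- pairwise_contrasts(fit_group_model(em))
  expect_equal(unname(de$t[1, ]), rep(0, 3))
  expect_equal(unname(de$p[1, ]), rep(1, 3))
  # antisymmetry: delta(i,j) = -(delta computed from swapped means)
  fit <- fit_group_model(em)
  expect_equal(de$lfc[, "A|B"], fit$means[, "A"] - fit$means[, "B"])
  expect_equal(de$lfc[, "B|C"], -(fit$means[, "C"] - fit$means[, "B"]))
})

test_that("variance-prior hyperparameters are recovered from simulation", {
  set.seed(11)
  n_genes <- 2000; d0 <- 4; s02 <- 0.05
  n_rep <- 4
  s2_true <- d0 * s02 / rchisq(n_genes, df = d0)
  v <- matrix(10 + rnorm(n_genes * 2 * n_rep, 0, sqrt(s2_true)), n_genes,
              dimnames = list(sprintf("g%d", seq_len(n_genes)),
                              sprintf("s%d", seq_len(2 * n_rep))))
  v[v < 0] <- 0
  em <- make_em(v, rep(c("A", "B"), each = n_rep), unit = "log2fpkm1")
  fit <- fit_group_model(em)
  expect_lt(abs(fit$df_prior - d0) / d0, 0.25)
  expect_lt(abs(fit$var_prior - s02) / s02, 0.25)

  # independent cross-check of the moment fit against limma's
  skip_if_not_installed("limma")
  sq <- limma::squeezeVar(fit$s2, df = fit$df_residual)
  expect_equal(fit$df_prior, sq$df.prior, tolerance = 0.02)
  expect_equal(fit$var_prior, sq$var.prior, tolerance = 0.02)
  # and the moderation formula itself, using limma's prior exactly
  expect_equal((sq$df.prior * sq$var.prior + fit$df_residual * fit$s2) /
                 (sq$df.prior + fit$df_residual),
               sq$var.post, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("q-values match a brute-force Benjamini-Hochberg recomputation", {
  set.seed(3)
  v <- matrix(2^rnorm(200 * 4, 4), 200, 4,
              dimnames = list(sprintf("g%d", 1:200), sprintf("s%d", 1:4)))
  em <- make_em(v, rep(c("A", "B"), each = 2), unit = "log2fpkm1")
  de <- pairwise_contrasts(fit_group_model(em))
  p <- de$p[, 1]
  n <- length(p)
  ord <- order(p)
  bh <- rev(cummin(rev(p[ord] * n / seq_len(n))))
  bh <- pmin(bh, 1)
  expect_equal(unname(de$q[ord, 1]), unname(bh))
  expect_true(all(de$q >= de$p))
})

test_that("the DM rule applies strict thresholds", {
  px <- celldiv:::pair_index(c("A", "B"))
  mk <- function(lfc, q) {
    de <- structure(list(
      lfc = matrix(lfc, 1, 1, dimnames = list("g1", px$labels)),
      t = matrix(1, 1, 1), p = matrix(q, 1, 1),
      q = matrix(q, 1, 1, dimnames = list("g1", px$labels)),
      populations = c("A", "B"), pair_i = px$i, pair_j = px$j,
      pair_labels = px$labels), class = "pairwise_de")
    build_dm(de)$pairs[1, 1]
  }
  expect_false(mk(2.0, 0.01))   # |lfc| = 2 exactly: not > 2
  expect_true(mk(5, 0.04))
  expect_false(mk(5, 0.06))
  expect_false(mk(-5, 0.05))    # q = 0.05 exactly: not < 0.05
  expect_true(mk(-5, 0.049))
})

test_that("cluster-mean DMs use the |logFC| > 1 rule and are monotone", {
  pm <- population_matrix(
    matrix(c(1, 2.5, 1, 1, 1, 2.01), 3, 2, byrow = FALSE,
           dimnames = list(c("g1", "g2", "g3"), c("A", "B"))),
    log2 = TRUE)
  # g1: |1 - 1| = 0; g2: |2.5 - 1| = 1.5 > 1; g3: |1 - 2.01| = 1.01 > 1
  dmc <- build_dm_from_means(pm, lfc_thresh = 1)
  expect_equal(unname(dmc$pairs[, 1]), c(FALSE, TRUE, TRUE))
  # raising the threshold never turns a 0 into a 1
  for (th in c(1.2, 1.5, 3)) {
    expect_true(all(build_dm_from_means(pm, th)$pairs <= dmc$pairs))
  }
})

test_that("replicate-based and mean-based DMs agree when separation is huge", {
  set.seed(9)
  p <- 5; r <- 3
  means <- matrix(2^(sample(0:8, 40, replace = TRUE)), 8, p,
                  dimnames = list(sprintf("g%d", 1:8), sprintf("P%d", 1:p)))
  noise <- matrix(rnorm(8 * p * r, 0, 1e-3), 8, p * r)
  v <- log2(means + 1)[, rep(1:p, each = r)] + noise
  v[v < 0] <- 0
  dimnames(v) <- list(rownames(means), sprintf("s%d", seq_len(p * r)))
  em <- make_em(v, rep(sprintf("P%d", 1:p), each = r), unit = "log2fpkm1")
  dm_rep <- build_dm(pairwise_contrasts(fit_group_model(em)),
                     lfc_thresh = 2, q_thresh = 0.05)
  pm <- population_matrix(log2(means + 1), log2 = TRUE)
  dm_mean <- build_dm_from_means(pm, lfc_thresh = 2)
  expect_equal(dm_rep$pairs, dm_mean$pairs)
})

test_that("symmetry and zero diagonal hold in the square expansion", {
  set.seed(2)
  dmc <- random_dmc(20, 6)
  for (g in c(1, 7, 20)) {
    m <- dm_matrix(dmc, g)
    expect_equal(m, t(m))
    expect_equal(unname(diag(m)), rep(0L, 6))
  }
})
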