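test_that("junctions group by donor; single-acceptor donors are dropped", {
  jt <- junction_table(
    sample = c("s1", "s1", "s1", "s2", "s1", "s1", "s1"),
    chrom = "chr1",
    strand = c("+", "+", "+", "+", "+", "-", "-"),
    donor = c(100, 100, 500, 100, 900, 900, 900),
    acceptor = c(300, 200, 700, 200, 1100, 1100, 1300),
    count = c(5, 3, 8, 4, 2, 6, 7))
  units <- group_junctions_by_donor(jt)
  # donor 100+ has 2 acceptors; 500+ only one (dropped); 900 splits by strand
  expect_setequal(names(units), c("chr1:+:100", "chr1:-:900"))
  u <- units[["chr1:+:100"]]
  expect_equal(u$acceptors, c(200, 300))   # ascending position
  expect_equal(u$counts["s1", ], c("200" = 3, "300" = 5))
  expect_equal(u$counts["s2", ], c("200" = 4, "300" = 0))  # zero-filled
  # mixed strands at one position are separate units
  expect_equal(group_junctions_by_donor(jt)[["chr1:-:900"]]$acceptors,
               c(1100, 1300))
})

test_that("branch probabilities require more than 10 reads", {
  u <- structure(list(
    chrom = "chr1", strand = "+", donor = 1,
    acceptors = c(10, 20),
    counts = matrix(c(30, 10, 7, 3, 0, 40), 3, 2, byrow = TRUE,
                    dimnames = list(c("s1", "s2", "s3"), c("10", "20"))),
    gene = "g", id = "chr1:+:1"), class = "donor_unit")
  p <- branch_probabilities(u)
  expect_equal(unname(p["s1", ]), c(0.75, 0.25))
  expect_true(all(is.na(p["s2", ])))       # total exactly 10: untestable
  expect_equal(unname(p["s3", ]), c(0, 1))
})

test_that("the Dirichlet-multinomial log-likelihood matches hand values", {
  # single sample, y = (1, 0), pi = (1/2, 1/2), phi = 2:
  # log[ G(2)/G(3) * G(1+1)/G(1) * G(0+1)/G(1) ] = log(1/2)
  expect_equal(dirmult_loglik(c(1, 0), c(0.5, 0.5), 2), log(0.5))

  # permutation symmetry
  set.seed(4)
  y <- matrix(rpois(12, 15), 4, 3)
  pi <- c(0.2, 0.5, 0.3)
  perm <- c(3, 1, 2)
  expect_equal(dirmult_loglik(y, pi, 7),
               dirmult_loglik(y[, perm], pi[perm], 7))

  # phi -> infinity approaches the multinomial log-likelihood
  ll_inf <- dirmult_loglik(y, pi, 1e8)
  ll_multi <- sum(y %*% log(pi))  # multinomial coefficient dropped
  expect_equal(ll_inf, ll_multi, tolerance = 1e-4)

  expect_error(dirmult_loglik(y, pi, -1), "invalid")
})

test_that("identical groups give a null LRT; separated groups are detected", {
  set.seed(9)
  cnt <- rdirmult(3, c(0.5, 0.5), 10, 60)
  r <- dirmult_lrt(cnt, cnt)
  expect_true(r$testable)
  expect_lt(r$lrt, 1e-4)
  expect_gt(r$p, 0.99)
  expect_equal(r$max_dpsi, 0)

  a <- matrix(rep(c(100, 0), 3), 3, 2, byrow = TRUE)
  b <- matrix(rep(c(0, 100), 3), 3, 2, byrow = TRUE)
  r2 <- dirmult_lrt(a, b)
  expect_true(r2$testable)
  expect_lt(r2$p, 0.05)
  expect_equal(r2$max_dpsi, 1)

  # the read prerequisite: both groups all at/below 10 reads -> untestable
  low <- matrix(rep(c(5, 5), 3), 3, 2, byrow = TRUE)
  r3 <- dirmult_lrt(low, low)
  expect_false(r3$testable)
  # failing samples are dropped, not zero-filled
  mix <- rbind(c(5, 5), c(40, 20))
  r4 <- dirmult_lrt(mix, cnt)
  expect_true(r4$testable)
  expect_equal(r4$n_a, 1)
})

test_that("the splice DM rule needs significance and delta-PSI together", {
  tests <- data.frame(
    donor = rep(c("d1", "d2", "d3", "d4"), each = 1),
    gene = c("gA", "gA", "gB", "gB"),
    pair = "A|B", pop_i = "A", pop_j = "B",
    testable = c(TRUE, TRUE, TRUE, FALSE),
    lrt = 1, p = c(0.04, 0.001, 0.2, NA),
    max_dpsi = c(0.3, 0.05, 0.5, NA), stringsAsFactors = FALSE)
  dm <- splice_dm(tests)
  expect_equal(unname(dm$pairs[, 1]), c(TRUE, FALSE, FALSE, FALSE))

  gdef <- gene_splice_def(dm)
  expect_equal(gdef[["gA"]], 1)  # d1 distinguishes the only pair
  expect_equal(gdef[["gB"]], 0)
})

test_that("gene splice DEF is the union over the gene's donors", {
  px <- celldiv:::pair_index(sprintf("P%d", 1:4))
  pairs <- matrix(FALSE, 3, 6,
                  dimnames = list(c("d1", "d2", "d3"), px$labels))
  pairs["d1", "P1|P2"] <- TRUE
  pairs["d2", "P3|P4"] <- TRUE
  pairs["d3", c("P1|P2", "P1|P3")] <- TRUE
  dmc <- celldiv:::new_dm_collection(pairs, NULL, sprintf("P%d", 1:4),
                                     px$i, px$j, px$labels)
  gdef <- gene_splice_def(dmc, gene_of = c(d1 = "gX", d2 = "gX", d3 = "gY"))
  expect_equal(gdef[["gX"]], 2 / 6)   # disjoint pair sets {12}, {34}
  expect_equal(gdef[["gY"]], 2 / 6)
  # OR monotonicity: gene DEF >= each donor DEF
  expect_gte(gdef[["gX"]], max(def_score(dmc)[c("d1", "d2")]))

  # brute force over random fixtures
  set.seed(25)
  for (i in 1:10) {
    dmr <- random_dmc(9, 5)
    rownames(dmr$pairs) <- sprintf("d%d", 1:9)
    gmap <- setNames(sample(c("g1", "g2", "g3"), 9, replace = TRUE),
                     rownames(dmr$pairs))
    gd <- gene_splice_def(dmr, gene_of = gmap)
    for (g in unique(gmap)) {
      rows <- names(gmap)[gmap == g]
      expect_equal(gd[[g]],
                   bf_def(Reduce(`|`, lapply(rows, function(d)
                     dm_matrix(dmr, d) > 0)) * 1L))
    }
  }
})

test_that("simulated all-or-none donors give bimodal branch probabilities", {
  cfg <- sim_config(n_populations = 6, n_replicates = 2, seed = 3)
  js <- simulate_junctions(cfg, n_donors = 30, frac_all_or_none = 1,
                           phi = 20, coverage_mean = 60)
  units <- group_junctions_by_donor(js$junctions)
  probs <- unlist(lapply(units, function(u) {
    p <- branch_probabilities(u)
    p[!is.na(p)]
  }))
  expect_gt(mean(probs <= 0.1 | probs >= 0.9), 0.8)
})

test_that("low coverage makes most donor units untestable", {
  cfg <- sim_config(n_populations = 4, n_replicates = 2, seed = 5)
  js <- simulate_junctions(cfg, n_donors = 20, coverage_mean = 5)
  units <- group_junctions_by_donor(js$junctions)
  frac_na <- mean(unlist(lapply(units, function(u) {
    rowMeans(is.na(branch_probabilities(u)))
  })))
  expect_gt(frac_na, 0.9)
})
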