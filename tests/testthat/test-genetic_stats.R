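# Band-sharing similarity, allele frequencies, PIC, gene diversity,
# Nei's standard distance, chi-square.

test_that("per-marker sharing follows the set rule and channels", {
  expect_equal(marker_share(c(2, 2), c(2, 3), "codominant")$score, 0.5)
  expect_equal(marker_share(c(2, 3), c(2, 3), "codominant")$score, 1.0)
  expect_equal(marker_share(c(2, 3), c(2, 4), "codominant")$score, 0.5)
  expect_equal(marker_share(c(2, 2), c(3, 3), "codominant")$score, 0)
  expect_equal(marker_share(c(2, 2), c(3, 3), "codominant")$channel,
               "mismatch")
  expect_equal(marker_share(c(1, 1), c(1, 1), "dominant"),
               list(score = 1, channel = "positive"))
  expect_equal(marker_share(c(0, 0), c(0, 0), "dominant"),
               list(score = 1, channel = "null"))
  expect_equal(marker_share(c(1, 1), c(0, 0), "dominant"),
               list(score = 0, channel = "mismatch"))
  expect_equal(marker_share(c(NA, NA), c(1, 1), "dominant")$channel,
               "excluded")
  expect_error(marker_share(c(0, 1), c(1, 1), "dominant"), "dominant")
})

test_that("GS reproduces the hand-counted 19-marker pair and bounds", {
  g <- hand_counted_pair()
  expect_equal(gs_pair(g, 1, 2), 14 / 19)
  expect_equal(gs_pair(g, "X", "X"), 1)
  # all markers mismatched -> 0
  panel <- marker_panel(c("R1", "S1"), c("dominant", "codominant"))
  g0 <- genotype_matrix(rbind(c(1L, 2L), c(0L, 3L)),
                        rbind(c(1L, 2L), c(0L, 4L)), panel, c("u", "v"))
  expect_equal(gs_pair(g0, 1, 2), 0)
})

test_that("GS requires a shared non-missing marker", {
  panel <- marker_panel(c("R1", "R2"), c("dominant", "dominant"))
  a <- rbind(c(1L, NA), c(NA, 1L))
  g <- genotype_matrix(a, a, panel, c("u", "v"))
  expect_error(gs_pair(g, 1, 2), "non-missing")
})

test_that("GD matrix is the GS complement: symmetric, zero diagonal, [0,1]", {
  set.seed(11)
  g <- random_genotypes(n_acc = 7, p_missing = 0.1)
  gd <- gd_matrix(g)
  expect_equal(gd, t(gd))
  expect_equal(unname(diag(gd)), rep(0, 7))
  expect_true(all(gd >= 0 & gd <= 1))
  # duplicated accessions sit at distance zero
  g2 <- genotype_matrix(g$a[c(1, 1), ], g$b[c(1, 1), ], g$panel, c("p", "q"))
  expect_equal(gd_matrix(g2)["p", "q"], 0)
})

test_that("matrix GS agrees with a brute-force per-marker recount", {
  set.seed(23)
  for (rep in 1:10) {
    g <- random_genotypes(n_acc = 6, n_dom = 4, n_cod = 3,
                          p_missing = if (rep %% 2) 0 else 0.15)
    gs <- gs_matrix(g)
    for (i in 1:5) for (j in (i + 1):6)
      expect_equal(gs[i, j], oracle_gs(g, i, j))
  }
})

test_that("allele frequencies count copies and sum to one", {
  panel <- marker_panel(c("S1", "R1"), c("codominant", "dominant"))
  a <- rbind(c(2L, 1L), c(2L, 1L), c(2L, 1L), c(2L, 0L))
  b <- rbind(c(3L, 1L), c(3L, 1L), c(3L, 1L), c(3L, 0L))
  g <- genotype_matrix(a, b, panel, paste0("a", 1:4))
  fr <- allele_freqs(g, rep("G", 4))
  expect_equal(fr$freqs$G$S1[c("2", "3")], c("2" = 0.5, "3" = 0.5))
  expect_equal(unname(fr$freqs$G$R1["1"]), 0.75)
  set.seed(5)
  g2 <- random_genotypes(n_acc = 8, p_missing = 0.2)
  fr2 <- allele_freqs(g2, rep(c("x", "y"), each = 4))
  for (grp in names(fr2$freqs))
    for (f in fr2$freqs[[grp]])
      if (!is.null(f)) expect_equal(sum(f), 1)
})

test_that("PIC matches its closed forms and diversity bound", {
  expect_equal(pic(0.5, "dominant"), 0.5)
  expect_equal(pic(c("0" = 0.25, "1" = 0.75), "dominant"), 2 * 0.75 * 0.25)
  expect_equal(pic(c(0.5, 0.5), "codominant"), 0.375)
  expect_equal(pic(1.0, "codominant"), 0)
  expect_error(pic(numeric(0), "codominant"), "empty")
  set.seed(31)
  for (i in 1:25) {
    p <- as.vector(stats::rgamma(sample(2:6, 1), 1)); p <- p / sum(p)
    expect_lte(pic(p, "codominant"), 1 - sum(p^2) + 1e-12)
  }
  # dominant PIC maximal at p = 0.5
  ps <- seq(0.05, 0.95, by = 0.05)
  vals <- vapply(ps, pic, 0, kind = "dominant")
  expect_equal(ps[which.max(vals)], 0.5)
})

test_that("gene diversity averages per-locus heterozygosity", {
  panel <- marker_panel(c("S1", "S2"), c("codominant", "codominant"))
  # locus 1: both accessions 1/2 -> freqs (.5,.5); locus 2 fixed
  a <- rbind(c(1L, 1L), c(1L, 1L)); b <- rbind(c(2L, 1L), c(2L, 1L))
  g <- genotype_matrix(a, b, panel, c("u", "v"))
  fr <- allele_freqs(g, rep("G", 2))
  expect_equal(gene_diversity(fr, "G"), (0.5 + 0) / 2)
  # direct per-locus value for (0.5, 0.25, 0.25)
  f <- c(0.5, 0.25, 0.25)
  expect_equal(1 - sum(f^2), 0.625)
  # monomorphic everywhere -> 0
  a0 <- matrix(1L, 2, 2)
  g0 <- genotype_matrix(a0, a0, panel, c("u", "v"))
  expect_equal(gene_diversity(allele_freqs(g0, rep("G", 2)), "G"), 0)
  expect_error(gene_diversity(fr, "nope"), "unknown group")
})

test_that("Nei distance is zero on identity, matches the one-locus case,
           and flags disjoint profiles", {
  panel <- marker_panel("S1", "codominant")
  mk <- function(calls) {
    a <- matrix(vapply(calls, `[`, 0L, 1L), ncol = 1)
    b <- matrix(vapply(calls, `[`, 0L, 2L), ncol = 1)
    genotype_matrix(a, b, panel, sprintf("i%d", seq_along(calls)))
  }
  # rows 1-2 form group A fixed on allele 1; rows 3-4 group B at (0.5, 0.5)
  g <- mk(list(c(1L, 1L), c(1L, 1L), c(1L, 2L), c(1L, 2L)))
  fr <- allele_freqs(g, c("A", "A", "B", "B"))
  expect_equal(fr$freqs$A$S1, c("1" = 1, "2" = 0))
  expect_equal(fr$freqs$B$S1, c("1" = 0.5, "2" = 0.5))
  nd <- nei_distance(fr, "A", "B")
  expect_equal(nd$I, 0.5 / sqrt(0.5), tolerance = 1e-12)
  expect_equal(nd$D, -log(0.5 / sqrt(0.5)), tolerance = 1e-12)
  expect_equal(nei_distance(fr, "A", "A")$D, 0)
  # disjoint alleles -> infinite with flag
  g2 <- mk(list(c(1L, 1L), c(2L, 2L)))
  fr2 <- allele_freqs(g2, c("A", "B"))
  nd2 <- nei_distance(fr2, "A", "B")
  expect_true(nd2$infinite)
  expect_identical(nd2$D, Inf)
})

test_that("Nei distance grows along an interpolation away from identity", {
  # direct frequency profiles via a constructed table
  set.seed(13)
  p <- c(0.7, 0.2, 0.1); q <- c(0.1, 0.3, 0.6)
  ts <- seq(0, 1, by = 0.25)
  dists <- vapply(ts, function(t) {
    ft <- (1 - t) * p + t * q
    jx <- sum(p^2); jy <- sum(ft^2); jxy <- sum(p * ft)
    -log(jxy / sqrt(jx * jy))
  }, 0)
  expect_true(all(diff(dists) > 0))
  expect_equal(dists[1], 0)
})

test_that("chi-square matches a textbook recomputation and known cases", {
  expect_equal(chisq_independence(matrix(c(5, 5, 5, 5), 2))$statistic, 0)
  r <- chisq_independence(matrix(c(10, 0, 0, 10), 2))
  expect_equal(r$statistic, 20)
  expect_equal(r$df, 1L)
  expect_error(chisq_independence(matrix(c(1, 2), 1)), "at least 2")
  expect_error(chisq_independence(matrix(c(0, 0, 1, 2), 2)),
               "zero row or column")
  set.seed(99)
  for (i in 1:20) {
    r <- sample(2:4, 1); cc <- sample(2:4, 1)
    tab <- matrix(rpois(r * cc, 8) + 1, nrow = r)
    got <- chisq_independence(tab)
    want <- oracle_chisq(tab)
    expect_equal(got$statistic, want$statistic)
    expect_equal(got$df, want$df)
  }
})

test_that("diversity table reports combined and per-kind values", {
  set.seed(77)
  g <- random_genotypes(n_acc = 10, n_dom = 6, n_cod = 4)
  dt <- diversity_table(g, rep(c("n", "s"), each = 5))
  expect_equal(nrow(dt), 2L)
  expect_true(all(c("D_all", "D_dominant", "D_codominant") %in% names(dt)))
  expect_true(all(dt$D_all >= 0 & dt$D_all < 1))
  # dominant-marker diversity is capped at 0.5 under two-state coding
  expect_true(all(dt$D_dominant <= 0.5))
})
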