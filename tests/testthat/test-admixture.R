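# Gibbs sampler contracts, Evanno delta-K arithmetic, run alignment,
# population assignment.

small_sim <- function(seed = 3, K = 2, F = 0.3) {
  sp <- sim_spec(K_true = K, n_per_pop = 12, n_dominant = 30,
                 n_codominant = 6, drift_F = F, master_seed = seed)
  gen_admixed_genotypes(sp)
}

test_that("K = 1 collapses to a single certain population", {
  sim <- small_sim()
  r <- run_admixture(sim$genotypes,
                     admixture_config(1, burn_in = 20, n_iter = 30, seed = 1))
  expect_equal(unname(r$Q[, 1]), rep(1, nrow(r$Q)))
  expect_true(is.finite(r$lnPD))
})

test_that("sampler state stays on the simplex and runs are reproducible", {
  sim <- small_sim()
  cfg <- admixture_config(3, burn_in = 40, n_iter = 60, seed = 99)
  r1 <- run_admixture(sim$genotypes, cfg)
  expect_equal(unname(rowSums(r1$Q)), rep(1, nrow(r1$Q)), tolerance = 1e-9)
  for (pm in r1$P)
    expect_equal(unname(rowSums(pm)), rep(1, nrow(pm)), tolerance = 1e-9)
  r2 <- run_admixture(sim$genotypes, cfg)
  expect_identical(r1$Q, r2$Q)
  expect_identical(r1$ll_trace, r2$ll_trace)
  expect_error(run_admixture(sim$genotypes,
                             admixture_config(1000, burn_in = 5, n_iter = 5)),
               "exceeds")
})

test_that("two separated populations are recovered with low Q error", {
  sim <- small_sim(seed = 7, F = 0.35)
  r <- run_admixture(sim$genotypes,
                     admixture_config(2, burn_in = 150, n_iter = 250,
                                      seed = 11))
  err <- min(mean(abs(r$Q - sim$truth$Q)),
             mean(abs(r$Q[, 2:1] - sim$truth$Q)))
  expect_lt(err, 0.12)
})

test_that("stronger drift gives better ancestry recovery on matched seeds", {
  errs <- vapply(c(0.05, 0.15, 0.35), function(F) {
    sim <- small_sim(seed = 5, F = F)
    r <- run_admixture(sim$genotypes,
                       admixture_config(2, burn_in = 120, n_iter = 200,
                                        seed = 13))
    min(mean(abs(r$Q - sim$truth$Q)),
        mean(abs(r$Q[, 2:1] - sim$truth$Q)))
  }, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("delta-K follows the Evanno formula with undefined endpoints", {
  runs <- c(lapply(c(-5010, -4990), fake_run, K = 2),
            lapply(c(-4010, -3990), fake_run, K = 3),
            lapply(c(-3910, -3890), fake_run, K = 4))
  dk <- delta_k(runs)
  # mean L = (-5000, -4000, -3900); sd at K=3 is sd(c(-4010,-3990))
  expect_equal(dk$mean_lnPD, c(-5000, -4000, -3900))
  expect_equal(dk$deltaK[2], abs(-3900 + 8000 - 5000) / sd(c(-4010, -3990)))
  expect_true(is.na(dk$deltaK[1]) && is.na(dk$deltaK[3]))
  # exactly linear mean L -> interior delta K of 0
  lin <- c(lapply(c(-5010, -4990), fake_run, K = 2),
           lapply(c(-4510, -4490), fake_run, K = 3),
           lapply(c(-4010, -3990), fake_run, K = 4))
  expect_equal(delta_k(lin)$deltaK[2], 0)
  # zero run-to-run sd -> infinite, flagged
  flat <- c(lapply(c(-5000, -5000), fake_run, K = 2),
            lapply(c(-4000, -4000), fake_run, K = 3),
            lapply(c(-3900, -3900), fake_run, K = 4))
  dkf <- delta_k(flat)
  expect_identical(dkf$deltaK[2], Inf)
  expect_true(dkf$sd_zero[2])
  expect_error(delta_k(runs[1:4]), "3 K values")
  expect_error(delta_k(runs[c(1, 3, 5)]), "2 runs")
})

test_that("alignment undoes column permutations and preserves row sums", {
  set.seed(42)
  Q <- matrix(rgamma(30, 1), 10, 3); Q <- Q / rowSums(Q)
  rownames(Q) <- paste0("a", 1:10)
  mkrun <- function(Qm, lnPD) structure(
    list(Q = Qm, P = list(M = matrix(1 / 3, 3, 2)), lnPD = lnPD,
         K = 3L, seed = 0L), class = "admixture_run")
  perms <- list(c(2, 3, 1), c(3, 1, 2), 1:3)
  runs <- lapply(seq_along(perms), function(i)
    mkrun(Q[, perms[[i]]], lnPD = -100 - i))
  al <- align_runs(runs)
  # all runs are column permutations of one Q: after alignment they are
  # identical (pairwise distance zero) and equal the reference run
  ref <- al$runs[[al$reference]]$Q
  for (r in al$runs) expect_equal(unname(r$Q), unname(ref),
                                  tolerance = 1e-12)
  expect_equal(unname(al$consensus), unname(ref), tolerance = 1e-12)
  # the reference is still a column permutation of the generating Q
  matched <- vapply(seq_len(ncol(ref)), function(j)
    min(apply(Q, 2, function(col) max(abs(col - ref[, j])))), 0)
  expect_true(all(matched < 1e-12))
  expect_equal(unname(rowSums(al$consensus)), rep(1, 10), tolerance = 1e-9)
  # two identical runs with swapped columns (K = 2)
  Q2 <- cbind(c(.9, .1, .5), c(.1, .9, .5))
  rownames(Q2) <- paste0("b", 1:3)
  r1 <- structure(list(Q = Q2, P = list(), lnPD = -10, K = 2L, seed = 0L),
                  class = "admixture_run")
  r2 <- r1; r2$Q <- Q2[, 2:1]; r2$lnPD <- -11
  al2 <- align_runs(list(r1, r2))
  expect_equal(al2$consensus, Q2)
})

test_that("assignment applies the strict 0.6 rule and admixed naming", {
  q <- rbind(c(0.7, 0.1, 0.1, 0.1),
             c(0.5, 0.4, 0.05, 0.05),
             c(0.6, 0.3, 0.05, 0.05))
  rownames(q) <- c("hi", "mid", "edge")
  asg <- assign_populations(q)
  expect_equal(asg$label, c("Pop1", "Pop1/2", "Pop1/2"))
  expect_equal(asg$admixed, c(FALSE, TRUE, TRUE))
  expect_error(assign_populations(q, threshold = 0.4), "threshold")
  expect_error(assign_populations(q, threshold = 1.2), "threshold")
  expect_error(assign_populations(q * 2), "sum to 1")
})

test_that("consensus is invariant under relabelling of input runs", {
  set.seed(31)
  sim <- small_sim(seed = 9)
  runs <- admixture_scan(sim$genotypes, k_range = 2, n_runs = 3,
                         burn_in = 40, n_iter = 60, master_seed = 2)
  al <- align_runs(runs)
  flipped <- lapply(runs, function(r) { r$Q <- r$Q[, 2:1]; r })
  al_f <- align_runs(flipped)
  d1 <- sum(abs(al$consensus - al_f$consensus))
  d2 <- sum(abs(al$consensus - al_f$consensus[, 2:1]))
  expect_lt(min(d1, d2), 1e-9)
})
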