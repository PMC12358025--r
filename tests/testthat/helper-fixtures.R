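# Fixture builders and independent oracles used across the suite.

# random mixed-panel genotype matrix (valid calls, optional missingness)
random_genotypes <- function(n_acc = 6, n_dom = 5, n_cod = 4,
                             max_alleles = 5, p_missing = 0) {
  kinds <- c(rep("dominant", n_dom), rep("codominant", n_cod))
  panel <- marker_panel(sprintf("M%02d", seq_along(kinds)), kinds)
  L <- length(kinds)
  a <- matrix(NA_integer_, n_acc, L)
  b <- matrix(NA_integer_, n_acc, L)
  for (m in seq_len(L)) {
    if (kinds[m] == "dominant") {
      band <- rbinom(n_acc, 1, 0.5)
      a[, m] <- band; b[, m] <- band
    } else {
      J <- sample(2:max_alleles, 1)
      a[, m] <- sample.int(J, n_acc, replace = TRUE)
      b[, m] <- sample.int(J, n_acc, replace = TRUE)
    }
  }
  if (p_missing > 0) {
    drop <- matrix(runif(n_acc * L) < p_missing, n_acc, L)
    # keep at least one call per accession pair by never blanking marker 1
    drop[, 1] <- FALSE
    a[drop] <- NA_integer_; b[drop] <- NA_integer_
  }
  genotype_matrix(a, b, panel, sprintf("A%02d", seq_len(n_acc)))
}

# the worked 19-marker pair: 12 dominant (6 both-present, 3 both-absent,
# 3 mismatched) + 7 codominant (4 identical, 2 half-shared, 1 disjoint)
# -> GS = (6 + 4 + 2*0.5 + 3)/19 = 14/19
hand_counted_pair <- function() {
  panel <- marker_panel(c(sprintf("R%02d", 1:12), sprintf("S%02d", 1:7)),
                        c(rep("dominant", 12), rep("codominant", 7)))
  a1 <- c(rep(1, 6), rep(0, 3), rep(1, 3), 2, 3, 4, 5, 2, 2, 2)
  b1 <- c(rep(1, 6), rep(0, 3), rep(1, 3), 2, 3, 4, 5, 2, 2, 2)
  a2 <- c(rep(1, 6), rep(0, 3), rep(0, 3), 2, 3, 4, 5, 2, 2, 3)
  b2 <- c(rep(1, 6), rep(0, 3), rep(0, 3), 2, 3, 4, 5, 3, 3, 3)
  genotype_matrix(rbind(a1, a2), rbind(b1, b2), panel, c("X", "Y"))
}

# independent per-pair GS recount: set arithmetic from first principles
oracle_gs <- function(g, i, j) {
  num <- 0; den <- 0
  for (m in seq_len(ncol(g$a))) {
    gi <- c(g$a[i, m], g$b[i, m]); gj <- c(g$a[j, m], g$b[j, m])
    if (anyNA(gi) || anyNA(gj)) next
    den <- den + 1
    if (g$panel$kind[m] == "dominant") {
      num <- num + as.numeric(gi[1] == gj[1])
    } else {
      A <- unique(gi); B <- unique(gj)
      num <- num + length(intersect(A, B)) / max(length(A), length(B))
    }
  }
  num / den
}

# textbook Pearson chi-square recomputation
oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  list(statistic = sum((tab - E)^2 / E),
       df = (nrow(tab) - 1) * (ncol(tab) - 1))
}

# fabricate an admixture_run with a given lnPD (for delta-K arithmetic)
fake_run <- function(K, lnPD) {
  structure(list(Q = matrix(1 / K, 2, K,
                            dimnames = list(c("a", "b"), NULL)),
                 P = list(), lnPD = lnPD, K = as.integer(K), seed = 0L),
            class = "admixture_run")
}

# small three-marker cytoplasm key fixture
fixture_key <- function() {
  cytoplasm_key(
    markers = c("Cp1", "Cp2", "Cp3"),
    pattern_map = list(Cp1 = c("420" = "A", "280+140" = "B"),
                       Cp2 = c("510" = "A", "350+160" = "B"),
                       Cp3 = c("390" = "A", "240+150" = "B")),
    type_map = c("A/A/A" = "Ia", "B/A/A" = "Ib",
                 "A/B/A" = "Ic", "B/B/B" = "III"))
}
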