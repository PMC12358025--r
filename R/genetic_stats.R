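#' Per-marker band-sharing score between two genotype calls
#'
#' For a dominant marker the two accessions either share the band (1,
#' "positive" channel), share its absence (1, "null" channel) or mismatch
#' (0). For a codominant marker the score is `|A int B| / max(|A|, |B|)` over
#' the two distinct-allele sets, so a homozygote 2/2 against a heterozygote
#' 2/3 scores 0.5, identical heterozygotes score 1 and disjoint genotypes 0.
#'
#' @param gi,gj length-2 numeric vectors giving each call's allele pair
#'   (dominant: `c(1,1)` or `c(0,0)`).
#' @param kind `"dominant"` or `"codominant"`.
#' @return A list with `score` (0, 0.5-type fractions, or 1) and `channel`
#'   (`"positive"`, `"null"`, `"mismatch"`, or `"excluded"` when either call
#'   is missing).
#' @export
marker_share <- function(gi, gj, kind) {
  if (anyNA(gi) || anyNA(gj))
    return(list(score = NA_real_, channel = "excluded"))
  kind <- match.arg(kind, c("dominant", "codominant"))
  if (kind == "dominant") {
    if (gi[1] != gi[2] || gj[1] != gj[2] ||
        !gi[1] %in% c(0, 1) || !gj[1] %in% c(0, 1))
      stop("dominant calls must be 1/1 or 0/0")
    if (gi[1] == gj[1])
      return(list(score = 1, channel = if (gi[1] == 1) "positive" else "null"))
    return(list(score = 0, channel = "mismatch"))
  }
  A <- unique(gi); B <- unique(gj)
  score <- length(intersect(A, B)) / max(length(A), length(B))
  list(score = score,
       channel = if (score > 0) "positive" else "mismatch")
}

# vectorised codominant share of one call (a1,b1) against vectors (av,bv)
share_codom_vec <- function(a1, b1, av, bv) {
  s1 <- 1L + (a1 != b1)
  s2 <- 1L + (av != bv)
  inter <- (a1 == av | a1 == bv) +
    ((b1 != a1) & (b1 == av | b1 == bv))
  inter / pmax(s1, s2)
}

#' Band-sharing genetic similarity between two accessions
#'
#' `GS = (N11 + N00) / n`, where `N11` sums positive-band sharing over all
#' markers (SSR heterozygote sharing contributes fractions), `N00` counts
#' shared dominant-band absences, and `n` is the number of mutually
#' non-missing markers (19 for the full 12 RAPD + 7 SSR panel with complete
#' data).
#'
#' @param g a [genotype_matrix()].
#' @param i,j accession IDs or indices.
#' @return GS in `[0, 1]`.
#' @export
gs_pair <- function(g, i, j) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.character(i)) i <- match(i, g$accessions)
  if (is.character(j)) j <- match(j, g$accessions)
  ok <- !is.na(g$a[i, ]) & !is.na(g$a[j, ])
  if (!any(ok)) stop("no mutually non-missing markers between accessions ",
                     g$accessions[i], " and ", g$accessions[j])
  dom <- g$panel$kind == "dominant"
  score <- numeric(ncol(g$a))
  dd <- ok & dom
  score[dd] <- as.numeric(g$a[i, dd] == g$a[j, dd])
  cc <- ok & !dom
  if (any(cc))
    score[cc] <- share_codom_vec(g$a[i, cc], g$b[i, cc],
                                 g$a[j, cc], g$b[j, cc])
  sum(score[ok]) / sum(ok)
}

#' Pairwise genetic similarity matrix
#'
#' @param g a [genotype_matrix()] with at least two accessions.
#' @return Symmetric matrix of GS values, unit diagonal.
#' @export
gs_matrix <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- length(g$accessions)
  if (n < 2L) stop("need at least 2 accessions")
  dom <- g$panel$kind == "dominant"
  gs <- diag(1, n)
  a <- g$a; b <- g$b
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    sc <- matrix(0, length(js), ncol(a))
    ok <- !is.na(a[i, ])[col(sc)] & !is.na(a[js, , drop = FALSE])
    for (m in which(dom))
      sc[, m] <- as.numeric(a[js, m] == a[i, m])
    for (m in which(!dom))
      sc[, m] <- share_codom_vec(a[i, m], b[i, m], a[js, m], b[js, m])
    sc[!ok] <- 0
    denom <- rowSums(ok)
    if (any(denom == 0L))
      stop("no mutually non-missing markers between accession ",
           g$accessions[i], " and ", g$accessions[js[denom == 0L][1]])
    gs[i, js] <- gs[js, i] <- rowSums(sc) / denom
  }
  dimnames(gs) <- list(g$accessions, g$accessions)
  gs
}

#' Pairwise genetic distance matrix (GD = 1 - GS)
#'
#' @param g a [genotype_matrix()].
#' @return Symmetric distance matrix with zero diagonal.
#' @export
gd_matrix <- function(g) 1 - gs_matrix(g)

#' Per-group, per-marker allele frequencies
#'
#' Codominant markers are counted over 2n gene copies; dominant markers over
#' the two-state 1/1 vs 0/0 codes (no Hardy-Weinberg back-estimation — the
#' frequencies describe the coded data). Frequency vectors share one allele
#' universe per marker across groups, so they line up for between-group
#' statistics.
#'
#' @param g a [genotype_matrix()].
#' @param grouping character/factor of group labels, one per accession (in
#'   accession order), or a named vector keyed by accession ID.
#' @return An object of class `allele_freq_table`: per group a list of
#'   per-marker frequency vectors (`NULL` where the group has no calls),
#'   plus `alleles` (universe per marker), `n` (accessions per group) and
#'   `n_copies` (gene copies behind each vector).
#' @export
allele_freqs <- function(g, grouping) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!is.null(names(grouping))) grouping <- grouping[g$accessions]
  grouping <- as.character(grouping)
  if (length(grouping) != length(g$accessions))
    stop("grouping must cover every accession")
  if (anyNA(grouping)) stop("grouping has missing labels")
  L <- nrow(g$panel)
  universe <- vector("list", L)
  for (m in seq_len(L)) {
    if (g$panel$kind[m] == "dominant") {
      universe[[m]] <- c(0L, 1L)
    } else {
      obs <- c(g$a[, m], g$b[, m])
      obs <- obs[!is.na(obs)]
      hi <- if (!is.na(g$panel$n_alleles[m])) g$panel$n_alleles[m]
            else if (length(obs)) max(obs) else 1L
      universe[[m]] <- seq_len(hi)
    }
  }
  groups <- unique(grouping)
  freqs <- n_copies <- stats::setNames(vector("list", length(groups)), groups)
  for (grp in groups) {
    rows <- which(grouping == grp)
    fl <- vector("list", L); nc <- integer(L)
    for (m in seq_len(L)) {
      copies <- c(g$a[rows, m], g$b[rows, m])
      copies <- copies[!is.na(copies)]
      nc[m] <- length(copies)
      if (nc[m] == 0L) { fl[m] <- list(NULL); next }
      cnt <- tabulate(match(copies, universe[[m]]),
                      nbins = length(universe[[m]]))
      f <- cnt / sum(cnt)
      names(f) <- as.character(universe[[m]])
      fl[[m]] <- f
    }
    names(fl) <- g$panel$name
    freqs[[grp]] <- fl
    n_copies[[grp]] <- stats::setNames(nc, g$panel$name)
  }
  structure(list(freqs = freqs, alleles = universe,
                 n = table(grouping)[groups], n_copies = n_copies,
                 markers = g$panel$name, kinds = g$panel$kind),
            class = "allele_freq_table")
}

#' Polymorphic information content of a marker
#'
#' Codominant markers use Botstein's PIC,
#' `1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`. Dominant (presence/absence)
#' markers use the two-state form `2p(1-p)` on the band-presence frequency,
#' whose maximum is 0.5.
#'
#' @param freqs numeric allele-frequency vector summing to 1. For dominant
#'   markers either the two-state vector `c(absent, present)` (named "0","1"
#'   as produced by [allele_freqs()]) or a single band-presence frequency.
#' @param kind `"dominant"` or `"codominant"`.
#' @return PIC value.
#' @export
pic <- function(freqs, kind) {
  # Botstein cross-product term without a double loop:
  # sum_{i<j} 2 p_i^2 p_j^2 = (sum p^2)^2 - sum p^4
  kind <- match.arg(kind, c("dominant", "codominant"))
  if (!length(freqs)) stop("empty frequency vector")
  if (kind == "dominant") {
    p <- if (length(freqs) == 1L) freqs
         else if (!is.null(names(freqs)) && "1" %in% names(freqs)) freqs[["1"]]
         else freqs[2L]
    if (p < 0 || p > 1) stop("band frequency outside [0, 1]")
    return(unname(2 * p * (1 - p)))
  }
  if (abs(sum(freqs) - 1) > 1e-6) stop("frequencies must sum to 1")
  p2 <- sum(freqs^2)
  p4 <- sum(freqs^4)
  unname(1 - p2 - (p2^2 - p4))
}

#' Gene diversity (expected heterozygosity) within a group
#'
#' Per-locus `h = 1 - sum(p_i^2)` averaged over loci with data. The default
#' is the plug-in (uncorrected) estimator; `unbiased = TRUE` applies the
#' small-sample factor `m/(m-1)` with `m` gene copies.
#'
#' @param freqs an [allele_freqs()] table.
#' @param group group label present in `freqs`.
#' @param unbiased apply the sample-size correction (default `FALSE`).
#' @return Mean gene diversity `D`.
#' @export
gene_diversity <- function(freqs, group, unbiased = FALSE) {
  stopifnot(inherits(freqs, "allele_freq_table"))
  if (!group %in% names(freqs$freqs)) stop("unknown group: ", group)
  fl <- freqs$freqs[[group]]
  nc <- freqs$n_copies[[group]]
  h <- vapply(seq_along(fl), function(m) {
    f <- fl[[m]]
    if (is.null(f)) return(NA_real_)
    hm <- 1 - sum(f^2)
    if (unbiased && nc[m] > 1L) hm <- hm * nc[m] / (nc[m] - 1L)
    hm
  }, 0)
  mean(h, na.rm = TRUE)
}

#' Nei's (1972) standard genetic distance between two groups
#'
#' `Jx = mean_l sum(p^2)`, `Jy = mean_l sum(q^2)`, `Jxy = mean_l sum(p q)`;
#' the normalised identity is `I = Jxy / sqrt(Jx Jy)` and `D = -ln I`.
#' Groups with no shared alleles give `I = 0` and `D = Inf` (flagged).
#'
#' @param freqs an [allele_freqs()] table.
#' @param group_a,group_b group labels.
#' @return A list with `D`, `I` and logical `infinite`.
#' @export
nei_distance <- function(freqs, group_a, group_b) {
  stopifnot(inherits(freqs, "allele_freq_table"))
  for (grp in c(group_a, group_b))
    if (!grp %in% names(freqs$freqs)) stop("unknown group: ", grp)
  fa <- freqs$freqs[[group_a]]; fb <- freqs$freqs[[group_b]]
  shared <- which(!vapply(fa, is.null, TRUE) & !vapply(fb, is.null, TRUE))
  if (!length(shared)) stop("groups share no locus with data")
  jx <- mean(vapply(shared, function(m) sum(fa[[m]]^2), 0))
  jy <- mean(vapply(shared, function(m) sum(fb[[m]]^2), 0))
  jxy <- mean(vapply(shared, function(m) sum(fa[[m]] * fb[[m]]), 0))
  I <- jxy / sqrt(jx * jy)
  if (jxy <= 0)
    return(list(D = Inf, I = 0, infinite = TRUE))
  list(D = max(0, -log(I)), I = I, infinite = FALSE)
}

#' Pearson chi-square test of independence on a contingency table
#'
#' Plain Pearson statistic `sum((O - E)^2 / E)` without continuity
#' correction, with `df = (r - 1)(c - 1)`.
#'
#' @param tab numeric matrix of counts, at least 2x2.
#' @return A list with `statistic`, `df` and `p_value`.
#' @export
chisq_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("contingency table needs at least 2 rows and 2 columns")
  if (any(tab < 0)) stop("negative counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row or column margin")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Diversity summary table per group
#'
#' Gene diversity per group computed on all markers and on the dominant-only
#' and codominant-only subsets (the layout of a combined / RAPD-only /
#' SSR-only diversity table).
#'
#' @param g a [genotype_matrix()].
#' @param grouping group labels as in [allele_freqs()].
#' @param unbiased passed to [gene_diversity()].
#' @return `data.frame` with columns `group`, `n`, `D_all`, `D_dominant`,
#'   `D_codominant`.
#' @export
diversity_table <- function(g, grouping, unbiased = FALSE) {
  f_all <- allele_freqs(g, grouping)
  dom <- g$panel$kind == "dominant"
  f_dom <- if (any(dom)) allele_freqs(subset_markers(g, which(dom)), grouping)
  f_cod <- if (any(!dom)) allele_freqs(subset_markers(g, which(!dom)), grouping)
  groups <- names(f_all$freqs)
  data.frame(
    group = groups,
    n = as.integer(f_all$n[groups]),
    D_all = vapply(groups, gene_diversity, 0, freqs = f_all,
                   unbiased = unbiased),
    D_dominant = if (any(dom))
      vapply(groups, gene_diversity, 0, freqs = f_dom, unbiased = unbiased)
      else NA_real_,
    D_codominant = if (any(!dom))
      vapply(groups, gene_diversity, 0, freqs = f_cod, unbiased = unbiased)
      else NA_real_,
    row.names = NULL, stringsAsFactors = FALSE)
}
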