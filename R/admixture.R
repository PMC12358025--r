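#' Configuration for the admixture-model Gibbs sampler
#'
#' Defaults follow the standard protocol for small marker panels: 5000
#' burn-in sweeps, 5000 collected sweeps, 20 replicate runs per K, and the
#' correlated allele-frequency (F-) model.
#'
#' @param K number of ancestral clusters (>= 1).
#' @param burn_in burn-in sweeps (default 5000).
#' @param n_iter collected sweeps (default 5000).
#' @param n_runs replicate runs per K for multi-run scans (default 20).
#' @param frequency_model `"correlated"` (F-model with ancestral frequencies
#'   and per-cluster drift) or `"independent"` (flat Dirichlet per cluster).
#' @param alpha initial symmetric Dirichlet parameter for ancestry
#'   proportions (default 1).
#' @param infer_alpha update alpha by a Metropolis step each sweep (uniform
#'   prior on (0, 10); default `TRUE`). With `FALSE` alpha stays fixed.
#' @param seed integer RNG seed for a single run.
#' @return A list of class `admixture_config`.
#' @export
admixture_config <- function(K, burn_in = 5000L, n_iter = 5000L,
                             n_runs = 20L,
                             frequency_model = c("correlated", "independent"),
                             alpha = 1, infer_alpha = TRUE, seed = 1L) {
  frequency_model <- match.arg(frequency_model)
  if (K < 1L) stop("K must be >= 1")
  if (burn_in < 1L || n_iter < 1L) stop("burn_in and n_iter must be positive")
  structure(list(K = as.integer(K), burn_in = as.integer(burn_in),
                 n_iter = as.integer(n_iter), n_runs = as.integer(n_runs),
                 frequency_model = frequency_model, alpha = alpha,
                 infer_alpha = isTRUE(infer_alpha), seed = as.integer(seed)),
            class = "admixture_config")
}

# encode a genotype_matrix as 0-based allele index matrices for the sampler;
# dominant 0/0 and 1/1 codes become a two-allele locus, matching the way the
# pseudo-homozygote coding enters the likelihood.
encode_for_sampler <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  L <- nrow(g$panel)
  A <- g$a; B <- g$b
  J <- integer(L)
  for (m in seq_len(L)) {
    if (g$panel$kind[m] == "dominant") {
      J[m] <- 2L
    } else {
      obs <- suppressWarnings(max(c(g$b[, m], 1L), na.rm = TRUE))
      J[m] <- max(obs, g$panel$n_alleles[m], na.rm = TRUE)
      A[, m] <- A[, m] - 1L
      B[, m] <- B[, m] - 1L
    }
  }
  A[is.na(A)] <- -1L; B[is.na(B)] <- -1L
  storage.mode(A) <- "integer"; storage.mode(B) <- "integer"
  list(A = A, B = B, J = J)
}

#' Run the admixture-model Gibbs sampler once
#'
#' Alternates (a) cluster-of-origin assignment for every gene copy, (b)
#' cluster allele-frequency updates from Dirichlet counts (correlated model:
#' drift around sampled ancestral frequencies; independent model: flat
#' Dirichlet), and (c) per-individual ancestry updates under a symmetric
#' Dirichlet whose parameter alpha is itself updated by a Metropolis step
#' (unless `infer_alpha = FALSE`). The log data probability is estimated
#' from the collected sweeps as `mean(logL) - var(logL)/2`.
#'
#' @param g a [genotype_matrix()] (dominant markers consumed as their
#'   1/1 / 0/0 coding).
#' @param cfg an [admixture_config()].
#' @return An object of class `admixture_run`: `Q` (accessions x K, rows sum
#'   to 1), `P` (per-locus cluster x allele posterior-mean frequencies),
#'   `lnPD`, `ll_trace`, `F` (final drift values), `K`, `seed`.
#' @export
run_admixture <- function(g, cfg) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(cfg, "admixture_config"))
  if (cfg$K > length(g$accessions))
    stop("K exceeds the number of accessions")
  if (any(rowSums(!is.na(g$a)) == 0L))
    stop("accession with all calls missing")
  enc <- encode_for_sampler(g)
  set.seed(cfg$seed)
  res <- .gibbs_core(enc$A, enc$B, enc$J, cfg$K, cfg$burn_in, cfg$n_iter,
                     cfg$frequency_model == "correlated", cfg$alpha,
                     cfg$infer_alpha, 1.0)
  Q <- res$Q / rowSums(res$Q)   # guard tiny accumulation error
  rownames(Q) <- g$accessions
  colnames(Q) <- paste0("Pop", seq_len(cfg$K))
  ll <- res$ll_trace
  lnPD <- mean(ll) - if (length(ll) > 1L) stats::var(ll) / 2 else 0
  names(res$P) <- g$panel$name
  structure(list(Q = Q, P = res$P, lnPD = lnPD, ll_trace = ll,
                 F = res$F, alpha = res$alpha, K = cfg$K, seed = cfg$seed,
                 frequency_model = cfg$frequency_model),
            class = "admixture_run")
}

#' @export
print.admixture_run <- function(x, ...) {
  cat("admixture_run: K =", x$K, " lnP(D) =", format(x$lnPD),
      " seed =", x$seed, "\n")
  invisible(x)
}

#' Replicate admixture runs over a range of K
#'
#' Expands one master seed deterministically into per-run seeds and runs the
#' sampler `n_runs` times for every K.
#'
#' @param g a [genotype_matrix()].
#' @param k_range integer vector of K values (default 1:10).
#' @param n_runs runs per K (default 20).
#' @param burn_in,n_iter sweep counts per run (defaults 5000/5000).
#' @param frequency_model,infer_alpha passed to [admixture_config()].
#' @param master_seed master RNG seed.
#' @return List of `admixture_run` objects (grouped by K in order).
#' @export
admixture_scan <- function(g, k_range = 1:10, n_runs = 20L,
                           burn_in = 5000L, n_iter = 5000L,
                           frequency_model = "correlated",
                           infer_alpha = TRUE, master_seed = 1L) {
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max - 1L,
                      length(k_range) * n_runs)
  runs <- vector("list", length(seeds))
  idx <- 0L
  for (K in k_range) {
    for (r in seq_len(n_runs)) {
      idx <- idx + 1L
      cfg <- admixture_config(K, burn_in = burn_in, n_iter = n_iter,
                              frequency_model = frequency_model,
                              infer_alpha = infer_alpha, seed = seeds[idx])
      runs[[idx]] <- run_admixture(g, cfg)
    }
  }
  runs
}

#' Evanno delta-K table from replicate runs
#'
#' For each K with both neighbours present,
#' `deltaK = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd L(K)`; the
#' endpoints are undefined (`NA`). A zero run-to-run standard deviation
#' yields `Inf` with `sd_zero` flagged.
#'
#' @param runs list of `admixture_run` objects covering >= 3 consecutive K
#'   values with >= 2 runs each.
#' @return `data.frame` with columns `K`, `n_runs`, `mean_lnPD`, `sd_lnPD`,
#'   `L1` (first difference), `L2` (|second difference|), `deltaK`,
#'   `sd_zero`.
#' @export
delta_k <- function(runs) {
  Ks <- vapply(runs, `[[`, 0L, "K")
  ln <- vapply(runs, `[[`, 0, "lnPD")
  ks <- sort(unique(Ks))
  if (length(ks) < 3L) stop("need at least 3 K values")
  if (any(diff(ks) != 1L)) stop("K values must be consecutive")
  if (any(table(Ks) < 2L)) stop("need at least 2 runs per K")
  mu <- vapply(ks, function(k) mean(ln[Ks == k]), 0)
  sdv <- vapply(ks, function(k) stats::sd(ln[Ks == k]), 0)
  nk <- as.integer(table(Ks)[as.character(ks)])
  m <- length(ks)
  L1 <- c(NA, diff(mu))
  L2 <- rep(NA_real_, m)
  dK <- rep(NA_real_, m)
  for (i in 2:(m - 1L)) {
    L2[i] <- abs(mu[i + 1L] - 2 * mu[i] + mu[i - 1L])
    dK[i] <- if (sdv[i] == 0) Inf else L2[i] / sdv[i]
  }
  data.frame(K = ks, n_runs = nk, mean_lnPD = mu, sd_lnPD = sdv,
             L1 = L1, L2 = L2, deltaK = dK,
             sd_zero = !is.na(L2) & sdv == 0)
}

# all permutations of 1:k as a list (k! entries)
all_perms <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- all_perms(k - 1L)
  out <- vector("list", k * length(sub))
  i <- 0L
  for (p in sub)
    for (pos in 0:(k - 1L)) {
      i <- i + 1L
      out[[i]] <- append(p, k, after = pos)
    }
  out
}

# best column permutation of Q onto ref (min summed squared difference);
# exhaustive for K <= 8, greedy column matching beyond.
match_columns <- function(Q, ref) {
  K <- ncol(Q)
  if (K <= 8L) {
    best <- NULL; best_d <- Inf
    for (p in all_perms(K)) {
      dd <- sum((Q[, p, drop = FALSE] - ref)^2)
      if (dd < best_d) { best_d <- dd; best <- p }
    }
    return(best)
  }
  perm <- integer(K); used <- rep(FALSE, K)
  for (k in seq_len(K)) {
    cost <- vapply(seq_len(K), function(j)
      if (used[j]) Inf else sum((Q[, j] - ref[, k])^2), 0)
    perm[k] <- which.min(cost); used[perm[k]] <- TRUE
  }
  perm
}

#' Align replicate runs of equal K and form a consensus ancestry matrix
#'
#' Cluster labels are arbitrary per run, so each run's columns are permuted
#' to minimise the summed squared difference to a reference (the run with
#' the highest lnP(D)); the consensus Q is the mean of the aligned matrices.
#'
#' @param runs list of `admixture_run` objects sharing K and accession
#'   order.
#' @return A list with `runs` (aligned), `consensus` (mean Q),
#'   `permutations`.
#' @export
align_runs <- function(runs) {
  Ks <- vapply(runs, `[[`, 0L, "K")
  if (length(unique(Ks)) != 1L) stop("runs must share K")
  accs <- rownames(runs[[1L]]$Q)
  for (r in runs)
    if (!identical(rownames(r$Q), accs))
      stop("runs must share the accession set and order")
  ref_idx <- which.max(vapply(runs, `[[`, 0, "lnPD"))
  ref <- runs[[ref_idx]]$Q
  perms <- vector("list", length(runs))
  aligned <- runs
  for (i in seq_along(runs)) {
    p <- match_columns(runs[[i]]$Q, ref)
    perms[[i]] <- p
    Qi <- runs[[i]]$Q[, p, drop = FALSE]
    colnames(Qi) <- colnames(ref)
    aligned[[i]]$Q <- Qi
    aligned[[i]]$P <- lapply(runs[[i]]$P,
                             function(pm) pm[p, , drop = FALSE])
  }
  consensus <- Reduce(`+`, lapply(aligned, `[[`, "Q")) / length(aligned)
  list(runs = aligned, consensus = consensus, permutations = perms,
       reference = ref_idx)
}

#' Assign accessions to populations from a consensus ancestry matrix
#'
#' An accession whose largest membership strictly exceeds the threshold is
#' assigned to that population ("PopX"); otherwise it is labelled admixed
#' from its two largest components in descending membership order
#' ("PopX/Y").
#'
#' @param q ancestry matrix with rows summing to 1.
#' @param threshold assignment cutoff in `(0.5, 1]` (default 0.6, strict
#'   `>`).
#' @return `data.frame` with columns `accession`, `label`, `max_membership`,
#'   `admixed`.
#' @export
assign_populations <- function(q, threshold = 0.6) {
  if (threshold <= 0.5 || threshold > 1)
    stop("threshold must be in (0.5, 1]")
  q <- as.matrix(q)
  if (any(abs(rowSums(q) - 1) > 1e-6)) stop("Q rows must sum to 1")
  lab <- character(nrow(q)); mx <- numeric(nrow(q)); adm <- logical(nrow(q))
  for (i in seq_len(nrow(q))) {
    o <- order(q[i, ], decreasing = TRUE)
    mx[i] <- q[i, o[1L]]
    if (mx[i] > threshold) {
      lab[i] <- paste0("Pop", o[1L])
    } else {
      lab[i] <- paste0("Pop", o[1L], "/", o[2L])
      adm[i] <- TRUE
    }
  }
  data.frame(accession = rownames(q) %||% as.character(seq_len(nrow(q))),
             label = lab, max_membership = mx, admixed = adm,
             stringsAsFactors = FALSE, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
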