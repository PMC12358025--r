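# Synthetic germplasm generator: K ancestral populations with correlated
# (drifted) allele frequencies, Dirichlet admixture, ancestry-linked
# cytoplasm haplotypes, and a bimodal seed-length distribution with a
# seed-size/fruit-weight correlation.

rdirichlet_vec <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) <= 0) x <- rep(1, length(alpha))
  x / sum(x)
}

#' Specification for a synthetic germplasm dataset
#'
#' Defaults describe two well-defined ancestral populations of 50
#' accessions each genotyped at 100 dominant and 20 codominant loci with
#' modest drift (F = 0.05) and no admixture; one population is small-seeded
#' (mean 6.0 mm), the other large-seeded (mean 11.0 mm), straddling the
#' 9.0 mm cut, and fruit weight tracks seed length with correlation 0.823.
#'
#' @param K_true number of ancestral populations.
#' @param n_per_pop accession count per population (recycled to `K_true`).
#' @param n_dominant,n_codominant locus counts by marker kind.
#' @param alleles_per_ssr length-2 range of allele counts for codominant
#'   loci.
#' @param drift_F per-population drift in (0, 0.5) (recycled).
#' @param admixture_alpha symmetric Dirichlet parameter for ancestry
#'   proportions, or `NULL` for pure (unadmixed) populations.
#' @param cytoplasm_map cytoplasm type per population, from
#'   `c("Ia","Ib","Ic","III")` (recycled).
#' @param cytoplasm_mixing probability that an accession's maternal lineage
#'   departs from its majority ancestry (default 0).
#' @param seed_class_map `"large"`/`"small"` per population (recycled).
#' @param seed_length_params list with `large` and `small`, each
#'   `c(mean, sd)` in mm; the class means must straddle 9.0 when both
#'   classes are requested.
#' @param trait_corr target seed-length/fruit-weight correlation.
#' @param master_seed integer seed; every generated table is a deterministic
#'   function of the spec.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(K_true = 2L, n_per_pop = 50L,
                     n_dominant = 100L, n_codominant = 20L,
                     alleles_per_ssr = c(4L, 8L),
                     drift_F = 0.05, admixture_alpha = NULL,
                     cytoplasm_map = c("Ia", "Ic", "Ib", "III"),
                     cytoplasm_mixing = 0,
                     seed_class_map = c("small", "large"),
                     seed_length_params = list(large = c(11.0, 1.0),
                                               small = c(6.0, 1.0)),
                     trait_corr = 0.823, master_seed = 1L) {
  K_true <- as.integer(K_true)
  if (K_true < 1L) stop("K_true must be >= 1")
  n_per_pop <- rep_len(as.integer(n_per_pop), K_true)
  if (any(n_per_pop < 1L)) stop("n_per_pop must be positive")
  if (n_dominant + n_codominant < 1L) stop("need at least one locus")
  drift_F <- rep_len(drift_F, K_true)
  if (any(drift_F <= 0 | drift_F >= 0.5)) stop("drift_F must be in (0, 0.5)")
  cytoplasm_map <- rep_len(cytoplasm_map, K_true)
  if (any(!cytoplasm_map %in% c("Ia", "Ib", "Ic", "III")))
    stop("cytoplasm_map entries must be Ia/Ib/Ic/III")
  seed_class_map <- rep_len(seed_class_map, K_true)
  if (any(!seed_class_map %in% c("large", "small")))
    stop("seed_class_map entries must be 'large' or 'small'")
  if (all(c("large", "small") %in% seed_class_map) &&
      !(seed_length_params$large[1] >= 9.0 && seed_length_params$small[1] < 9.0))
    stop("class seed-length means must straddle the 9.0 mm cut")
  structure(list(K_true = K_true, n_per_pop = n_per_pop,
                 n_dominant = as.integer(n_dominant),
                 n_codominant = as.integer(n_codominant),
                 alleles_per_ssr = as.integer(alleles_per_ssr),
                 drift_F = drift_F, admixture_alpha = admixture_alpha,
                 cytoplasm_map = cytoplasm_map,
                 cytoplasm_mixing = cytoplasm_mixing,
                 seed_class_map = seed_class_map,
                 seed_length_params = seed_length_params,
                 trait_corr = trait_corr,
                 master_seed = as.integer(master_seed)),
            class = "sim_spec")
}

#' Generate admixed genotypes with known ground truth
#'
#' Ancestral allele frequencies are drawn from a flat Dirichlet (Beta(1,1)
#' band probabilities for dominant loci); population frequencies follow the
#' correlated-frequency drift model `Dir(pA (1-F)/F)`; ancestry proportions
#' are either degenerate (pure populations) or symmetric
#' `Dirichlet(alpha)`; codominant genotypes arise from two independent
#' allele draws through the ancestry mixture, dominant markers from one
#' two-state draw recorded as 1/1 or 0/0.
#'
#' @param spec a [sim_spec()].
#' @return A list with `genotypes` (a [genotype_matrix()]) and `truth`
#'   (`Q`, `pop_of_origin` = majority-ancestry population, `ancestral_freq`,
#'   `pop_freq`, `spec`).
#' @export
gen_admixed_genotypes <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$master_seed)
  K <- spec$K_true
  n <- sum(spec$n_per_pop)
  Ld <- spec$n_dominant; Lc <- spec$n_codominant; L <- Ld + Lc
  kinds <- c(rep("dominant", Ld), rep("codominant", Lc))
  mnames <- c(sprintf("R%03d", seq_len(Ld)),
              if (Lc) sprintf("S%03d", seq_len(Lc)))
  J <- integer(L)
  anc <- vector("list", L); popf <- vector("list", L)
  for (m in seq_len(L)) {
    J[m] <- if (kinds[m] == "dominant") 2L else
      sample(spec$alleles_per_ssr[1]:spec$alleles_per_ssr[2], 1L)
    pa <- rdirichlet_vec(rep(1, J[m]))
    anc[[m]] <- pa
    pk <- matrix(0, K, J[m])
    for (k in seq_len(K))
      pk[k, ] <- rdirichlet_vec(pa * (1 - spec$drift_F[k]) / spec$drift_F[k])
    popf[[m]] <- pk
  }
  home <- rep(seq_len(K), spec$n_per_pop)
  Q <- matrix(0, n, K)
  if (is.null(spec$admixture_alpha)) {
    Q[cbind(seq_len(n), home)] <- 1
  } else {
    for (i in seq_len(n))
      Q[i, ] <- rdirichlet_vec(rep(spec$admixture_alpha, K))
  }
  accs <- sprintf("ACC%03d", seq_len(n))
  rownames(Q) <- accs; colnames(Q) <- paste0("Pop", seq_len(K))
  a <- matrix(NA_integer_, n, L); b <- matrix(NA_integer_, n, L)
  for (i in seq_len(n)) {
    for (m in seq_len(L)) {
      mix <- as.vector(Q[i, ] %*% popf[[m]])
      if (kinds[m] == "dominant") {
        band <- stats::rbinom(1L, 1L, mix[2L])
        a[i, m] <- b[i, m] <- band
      } else {
        pair <- sort(sample.int(J[m], 2L, replace = TRUE, prob = mix))
        a[i, m] <- pair[1L]; b[i, m] <- pair[2L]
      }
    }
  }
  panel <- marker_panel(mnames, kinds,
                        n_alleles = ifelse(kinds == "dominant", 2L, J))
  g <- genotype_matrix(a, b, panel, accs)
  pop_of_origin <- max.col(Q, ties.method = "first")
  list(genotypes = g,
       truth = list(Q = Q, pop_of_origin = pop_of_origin,
                    ancestral_freq = stats::setNames(anc, mnames),
                    pop_freq = stats::setNames(popf, mnames),
                    spec = spec))
}

#' Generate CAPS cytoplasm calls linked to ancestry
#'
#' Each accession's cytoplasm type is the type mapped to its
#' majority-ancestry population (maternal lineage follows ancestry), with
#' an optional mixing probability of drawing a different type. Emits a
#' three-marker key whose letter tuples distinguish the four types, plus
#' pattern calls consistent with that key.
#'
#' @param truth the `truth` element of [gen_admixed_genotypes()] output.
#' @param spec the same [sim_spec()].
#' @return A list with `calls` (pattern matrix), `key` (a
#'   [cytoplasm_key()]) and `types` (true type per accession).
#' @export
gen_cytoplasm <- function(truth, spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$master_seed + 1L)
  type_tuples <- c(Ia = "A/A/A", Ib = "B/A/A", Ic = "A/B/A", III = "B/B/B")
  pattern_map <- list(
    Cp1 = c("420" = "A", "280+140" = "B"),
    Cp2 = c("510" = "A", "350+160" = "B"),
    Cp3 = c("390" = "A", "240+150" = "B"))
  key <- cytoplasm_key(names(pattern_map), pattern_map,
                       stats::setNames(names(type_tuples), type_tuples))
  types <- spec$cytoplasm_map[truth$pop_of_origin]
  if (spec$cytoplasm_mixing > 0) {
    flip <- stats::runif(length(types)) < spec$cytoplasm_mixing
    all_types <- c("Ia", "Ib", "Ic", "III")
    types[flip] <- vapply(types[flip], function(tp)
      sample(setdiff(all_types, tp), 1L), "")
  }
  # invert letter -> pattern per marker
  letter_to_pattern <- lapply(pattern_map, function(pm)
    stats::setNames(names(pm), pm))
  accs <- rownames(truth$Q)
  calls <- matrix(NA_character_, length(accs), length(key$markers),
                  dimnames = list(accs, key$markers))
  for (i in seq_along(accs)) {
    tup <- strsplit(type_tuples[[types[i]]], "/", fixed = TRUE)[[1L]]
    for (mi in seq_along(key$markers))
      calls[i, mi] <- letter_to_pattern[[mi]][tup[mi]]
  }
  list(calls = calls, key = key,
       types = stats::setNames(types, accs))
}

#' Generate a 16-trait morphology table and accession metadata
#'
#' Seed lengths are Gaussian per seed class (truncated positive); fruit
#' weight is built to the target correlation with seed length; the
#' remaining traits are Gaussian (or ordinal) with class-specific means, so
#' the two classes form separable morphological groups.
#'
#' @param truth the `truth` element of [gen_admixed_genotypes()] output.
#' @param spec the same [sim_spec()].
#' @return A list with `traits` (matrix, 16 columns), `meta`
#'   (accession metadata `data.frame`) and `intended_class` (the class each
#'   accession was generated from; boundary draws may classify otherwise).
#' @export
gen_traits <- function(truth, spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$master_seed + 2L)
  accs <- rownames(truth$Q)
  n <- length(accs)
  cls <- spec$seed_class_map[truth$pop_of_origin]
  pars <- spec$seed_length_params
  mu <- vapply(cls, function(cc) pars[[cc]][1], 0)
  sd <- vapply(cls, function(cc) pars[[cc]][2], 0)
  slen <- stats::rnorm(n, mu, sd)
  while (any(slen <= 0)) {
    bad <- slen <= 0
    slen[bad] <- stats::rnorm(sum(bad), mu[bad], sd[bad])
  }
  swid <- pmax(0.5, slen * 0.42 + stats::rnorm(n, 0, 0.3))
  rho <- spec$trait_corr
  zlen <- as.vector(scale(slen))
  fw <- 600 + 450 * (rho * zlen + sqrt(1 - rho^2) * stats::rnorm(n))
  fw <- pmax(5, fw)
  big <- cls == "large"
  flower_p <- ifelse(big, 0.85, 0.45)   # P(andromonoecious)
  flower <- vapply(flower_p, function(p)
    sample(c(2, 0, 1), 1L, prob = c(p, 0.9 - p + 0.05, 0.05)), 0)
  tr <- cbind(
    seed_length = slen,
    seed_width = swid,
    leaf_length = stats::rnorm(n, ifelse(big, 14, 9), 1.5),
    leaf_width = stats::rnorm(n, ifelse(big, 15, 10), 1.5),
    petiole_length = stats::rnorm(n, ifelse(big, 12, 8), 1.2),
    internode_length = stats::rnorm(n, ifelse(big, 11, 7), 1.0),
    flower_type = flower,
    fruit_weight = fw,
    fruit_length = pmax(2, stats::rnorm(n, ifelse(big, 18, 7), 2.5)),
    fruit_diameter = pmax(1, stats::rnorm(n, ifelse(big, 11, 5), 1.5)),
    flesh_thickness = pmax(0.2, stats::rnorm(n, ifelse(big, 2.8, 1.1), 0.4)),
    flesh_colour = sample(1:5, n, replace = TRUE),
    exocarp_colour = sample(1:5, n, replace = TRUE),
    exocarp_dots = sample(0:2, n, replace = TRUE),
    fruit_groove = sample(0:2, n, replace = TRUE),
    brix = pmax(1, stats::rnorm(n, ifelse(big, 8.5, 3.5), 1.2)))
  rownames(tr) <- accs
  meta <- data.frame(id = accs,
                     region_group = paste0("Pop", truth$pop_of_origin),
                     seed_length_mm = slen, seed_width_mm = swid,
                     horticultural_group = NA_character_,
                     stringsAsFactors = FALSE)
  list(traits = tr, meta = meta,
       intended_class = stats::setNames(cls, accs))
}

#' African seed-size contingency table
#'
#' The 4 x 2 table of African accessions by region and seed class
#' (Northern Africa, Sudan, Western Africa, Southern Africa x large/small):
#' 97 accessions, column totals 57 large and 40 small.
#'
#' @return Integer matrix with region row names and `large`/`small`
#'   columns.
#' @export
fixture_table1 <- function() {
  matrix(c(37L, 1L,
           17L, 21L,
           2L, 10L,
           1L, 8L),
         nrow = 4L, byrow = TRUE,
         dimnames = list(c("Northern Africa", "Sudan", "Western Africa",
                           "Southern Africa"),
                         c("large", "small")))
}
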