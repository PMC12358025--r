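# Orchestration: configuration-driven end-to-end analysis producing the
# report bundle (similarity/diversity tables, tree, ordination, admixture
# consensus and delta-K, cytoplasm crosstab, seed-class chi-square).

# FNV-1a 32-bit hash of a character scalar; cheap stable config fingerprint.
# The xor only touches the low byte, so keep it in integer range by hand.
fnv1a <- function(s) {
  bytes <- utf8ToInt(s) %% 256
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # h * 16777619 mod 2^32 in 16-bit pieces to stay exact in doubles
    h0 <- h %% 65536; h1 <- (h - h0) / 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h0 <- h %% 65536
  sprintf("%04x%04x", as.integer((h - h0) / 65536), as.integer(h0))
}

#' Pipeline configuration
#'
#' Defaults encode the standard protocol: K scanned over 1-10 with 20 runs
#' each at 5000/5000 burn-in/collected sweeps, assignment threshold 0.6,
#' seed-length cut 9.0 mm. Supply either a [sim_spec()] (`sim`) or input
#' file paths.
#'
#' @param sim a [sim_spec()], or `NULL` to read files.
#' @param genotypes,panel,metadata,traits,caps_calls,key_file input paths
#'   (used when `sim` is `NULL`; `traits`/`caps_calls`/`key_file` optional).
#' @param stages character subset of
#'   `c("stats","tree","pcoa","admixture","cytoplasm","traits")`.
#' @param k_range K values for the admixture scan.
#' @param n_runs,burn_in,n_iter admixture sampler effort.
#' @param frequency_model `"correlated"` or `"independent"`.
#' @param threshold population-assignment cutoff.
#' @param pcoa_axes ordination axes to keep.
#' @param n_clusters_morph trait-tree cut size.
#' @param master_seed seed governing every stochastic stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_spec(),
                            genotypes = NULL, panel = NULL, metadata = NULL,
                            traits = NULL, caps_calls = NULL, key_file = NULL,
                            stages = c("stats", "tree", "pcoa", "admixture",
                                       "cytoplasm", "traits"),
                            k_range = 1:10, n_runs = 20L,
                            burn_in = 5000L, n_iter = 5000L,
                            frequency_model = "correlated",
                            threshold = 0.6, pcoa_axes = 2L,
                            n_clusters_morph = 4L, master_seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(sim)) {
    for (p in c(genotypes, panel, metadata))
      if (!file.exists(p)) stop("input file not found: ", p)
  }
  structure(list(sim = sim, genotypes = genotypes, panel = panel,
                 metadata = metadata, traits = traits,
                 caps_calls = caps_calls, key_file = key_file,
                 stages = stages, k_range = k_range,
                 n_runs = as.integer(n_runs), burn_in = as.integer(burn_in),
                 n_iter = as.integer(n_iter),
                 frequency_model = frequency_model,
                 threshold = threshold, pcoa_axes = as.integer(pcoa_axes),
                 n_clusters_morph = as.integer(n_clusters_morph),
                 master_seed = as.integer(master_seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes data loading/simulation, then the requested stages in order:
#' band-sharing statistics and diversity, UPGMA tree, principal coordinate
#' analysis, admixture scan with delta-K/alignment/assignment, cytoplasm
#' typing with crosstab, and seed/trait analysis. All randomness derives
#' from `cfg$master_seed`, so a rerun with the same configuration is
#' identical. A failing stage aborts with the stage named; completed
#' results are retained in the error's `partial` attribute.
#'
#' @param cfg a [pipeline_config()].
#' @param verbose print stage log lines (default `FALSE`).
#' @return A list of class `report_bundle`; always carries `config_hash`
#'   and `master_seed`, plus one element per executed stage.
#' @export
run_pipeline <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  bundle <- list(config_hash = fnv1a(paste(deparse(cfg), collapse = "\n")),
                 master_seed = cfg$master_seed)
  say <- function(...) if (verbose) message("[melondiv] ", ...)
  run_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      err <- simpleError(paste0("stage '", name, "' failed: ",
                                conditionMessage(e)))
      attr(err, "partial") <- bundle
      stop(err)
    })
    say(name, " done in ", sprintf("%.2f s", proc.time()[["elapsed"]] - t0))
    out
  }

  dat <- run_stage("data", {
    if (!is.null(cfg$sim)) {
      spec <- cfg$sim
      spec$master_seed <- cfg$master_seed
      sim <- gen_admixed_genotypes(spec)
      cy <- gen_cytoplasm(sim$truth, spec)
      tr <- gen_traits(sim$truth, spec)
      list(g = sim$genotypes, truth = sim$truth, meta = tr$meta,
           traits = tr$traits, caps = cy$calls, key = cy$key,
           true_types = cy$types)
    } else {
      panel <- read_marker_panel(cfg$panel)
      g <- read_genotypes(cfg$genotypes, panel)
      meta <- read_metadata(cfg$metadata)
      list(g = g, truth = NULL, meta = meta,
           traits = if (!is.null(cfg$traits)) read_trait_table(cfg$traits),
           caps = if (!is.null(cfg$caps_calls)) read_caps_calls(cfg$caps_calls),
           key = if (!is.null(cfg$key_file)) read_cytoplasm_key(cfg$key_file))
    }
  })
  bundle$validation <- validate_dataset(dat$g, dat$meta)
  grouping <- stats::setNames(dat$meta$region_group, dat$meta$id)

  if ("stats" %in% cfg$stages) {
    bundle$gs <- run_stage("stats", gs_matrix(dat$g))
    bundle$gd <- 1 - bundle$gs
    bundle$diversity <- diversity_table(dat$g, grouping[dat$g$accessions])
    fr <- allele_freqs(dat$g, grouping[dat$g$accessions])
    groups <- names(fr$freqs)
    if (length(groups) > 1L) {
      nd <- matrix(0, length(groups), length(groups),
                   dimnames = list(groups, groups))
      for (i in seq_along(groups))
        for (j in seq_along(groups))
          if (i < j)
            nd[i, j] <- nd[j, i] <- nei_distance(fr, groups[i], groups[j])$D
      bundle$nei_group_distance <- nd
    }
  }
  if ("tree" %in% cfg$stages) {
    if (is.null(bundle$gd)) bundle$gd <- gd_matrix(dat$g)
    bundle$tree <- run_stage("tree", upgma(bundle$gd))
    bundle$newick <- to_newick(bundle$tree)
  }
  if ("pcoa" %in% cfg$stages) {
    if (is.null(bundle$gd)) bundle$gd <- gd_matrix(dat$g)
    bundle$pcoa <- run_stage("pcoa", pcoa(bundle$gd, cfg$pcoa_axes))
  }
  if ("admixture" %in% cfg$stages) {
    adm <- run_stage("admixture", {
      runs <- admixture_scan(dat$g, k_range = cfg$k_range,
                             n_runs = cfg$n_runs, burn_in = cfg$burn_in,
                             n_iter = cfg$n_iter,
                             frequency_model = cfg$frequency_model,
                             master_seed = cfg$master_seed)
      Ks <- vapply(runs, `[[`, 0L, "K")
      dk <- if (length(unique(Ks)) >= 3L && cfg$n_runs >= 2L)
        delta_k(runs)
      best_k <- if (!is.null(dk) && any(!is.na(dk$deltaK)))
        dk$K[which.max(dk$deltaK)] else max(Ks)
      al <- align_runs(runs[Ks == best_k])
      list(runs = runs, delta_k = dk, best_k = best_k,
           consensus_Q = al$consensus,
           assignments = assign_populations(al$consensus, cfg$threshold))
    })
    bundle$admixture <- adm
  }
  if ("cytoplasm" %in% cfg$stages && !is.null(dat$caps) &&
      !is.null(dat$key)) {
    bundle$cytoplasm <- run_stage("cytoplasm", {
      types <- classify_cytoplasm(dat$caps, dat$key)
      list(types = types,
           crosstab = cytoplasm_crosstab(types, dat$meta))
    })
  }
  if ("traits" %in% cfg$stages) {
    bundle$seed <- run_stage("traits-seed", {
      tab <- seed_class_table(dat$meta)
      chi <- if (nrow(tab) >= 2L && all(colSums(tab) > 0) &&
                 all(rowSums(tab) > 0))
        chisq_independence(tab)
      list(table = tab, chisq = chi)
    })
    if (!is.null(dat$traits))
      bundle$morphology <- run_stage("traits-morph", {
        mc <- morph_cluster(dat$traits, cfg$n_clusters_morph)
        pca <- trait_pca(mc$standardized, cfg$pcoa_axes)
        list(clusters = mc$labels, tree = mc$tree, pca = pca)
      })
  }
  if (!is.null(dat$truth)) bundle$truth <- dat$truth
  if (!is.null(dat$true_types)) bundle$true_cytoplasm <- dat$true_types
  class(bundle) <- "report_bundle"
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("report_bundle (config ", x$config_hash, ", seed ", x$master_seed,
      "):\n  stages: ",
      paste(setdiff(names(x), c("config_hash", "master_seed")),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
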