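#' Construct a marker panel definition
#'
#' A panel describes the markers scored on a set of accessions: each marker is
#' either dominant (a presence/absence band, e.g. RAPD, coded as the
#' pseudo-homozygotes 1/1 and 0/0) or codominant (multi-allelic, e.g. SSR,
#' with alleles labelled by fragment-size rank, 1 = smallest).
#'
#' @param name character vector of unique marker names.
#' @param kind character vector, each element `"dominant"` or `"codominant"`.
#' @param chromosome optional character vector of chromosome labels (`NA`
#'   allowed).
#' @param n_alleles optional integer vector giving the number of allele labels
#'   for codominant markers; `NA` means "infer from the data". Dominant
#'   markers always have the implicit two-state band.
#' @return A `data.frame` of class `marker_panel`.
#' @export
marker_panel <- function(name, kind, chromosome = NA_character_,
                         n_alleles = NA_integer_) {
  name <- as.character(name)
  kind <- as.character(kind)
  if (anyDuplicated(name))
    stop("duplicated marker names: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  bad <- !kind %in% c("dominant", "codominant")
  if (any(bad))
    stop("unknown marker kind: ", paste(unique(kind[bad]), collapse = ", "))
  n_alleles <- as.integer(n_alleles)
  panel <- data.frame(name = name, kind = kind,
                      chromosome = rep_len(as.character(chromosome), length(name)),
                      n_alleles = rep_len(n_alleles, length(name)),
                      stringsAsFactors = FALSE)
  if (any(!is.na(panel$n_alleles) & panel$kind == "codominant" &
          panel$n_alleles < 1L))
    stop("codominant markers need at least one allele label")
  panel$n_alleles[panel$kind == "dominant"] <- 2L
  class(panel) <- c("marker_panel", "data.frame")
  panel
}

#' Construct a genotype matrix
#'
#' Stores unordered diploid calls for a set of accessions over a mixed
#' dominant/codominant marker panel. Dominant markers admit only the
#' pseudo-homozygote codes 1/1 (band present) and 0/0 (band absent);
#' codominant calls are unordered allele pairs stored sorted. A call with
#' both alleles `NA` is missing.
#'
#' @param allele_a,allele_b integer matrices (accessions x markers) holding
#'   the two allele indices per call; pairs are canonicalised so that
#'   `allele_a <= allele_b`.
#' @param panel a [marker_panel()] with one row per column of `allele_a`.
#' @param accessions character vector of unique accession IDs.
#' @return An object of class `genotype_matrix` with elements `a`, `b`,
#'   `panel`, `accessions`.
#' @export
genotype_matrix <- function(allele_a, allele_b, panel, accessions) {
  a <- as.matrix(allele_a); b <- as.matrix(allele_b)
  storage.mode(a) <- "integer"; storage.mode(b) <- "integer"
  accessions <- as.character(accessions)
  if (!inherits(panel, "marker_panel")) stop("`panel` must be a marker_panel")
  if (nrow(a) != length(accessions) || !all(dim(a) == dim(b)))
    stop("allele matrices must be rectangular with one row per accession")
  if (ncol(a) != nrow(panel))
    stop("panel declares ", nrow(panel), " markers but calls have ",
         ncol(a), " columns")
  if (anyDuplicated(accessions))
    stop("duplicated accession IDs: ",
         paste(unique(accessions[duplicated(accessions)]), collapse = ", "))
  if (any(xor(is.na(a), is.na(b))))
    stop("half-missing calls: both alleles must be present or both NA")
  # canonical sorted pairs
  swap <- !is.na(a) & a > b
  if (any(swap)) { tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp }
  for (m in seq_len(nrow(panel))) {
    am <- a[, m]; bm <- b[, m]
    ok <- !is.na(am)
    if (panel$kind[m] == "dominant") {
      if (any(ok & (am != bm | !(am %in% c(0L, 1L)))))
        stop("marker ", panel$name[m],
             ": dominant calls must be 1/1 or 0/0 (heterozygote impossible)")
    } else {
      if (any(ok & am < 1L))
        stop("marker ", panel$name[m], ": allele labels must be >= 1")
      if (!is.na(panel$n_alleles[m]) && any(ok & bm > panel$n_alleles[m]))
        stop("marker ", panel$name[m], ": allele label exceeds panel's ",
             panel$n_alleles[m])
    }
  }
  rownames(a) <- rownames(b) <- accessions
  colnames(a) <- colnames(b) <- panel$name
  structure(list(a = a, b = b, panel = panel, accessions = accessions),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$accessions), "accessions x",
      nrow(x$panel), "markers (", sum(x$panel$kind == "dominant"),
      "dominant,", sum(x$panel$kind == "codominant"), "codominant )\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(length(x$accessions), nrow(x$panel))

#' Subset the markers of a genotype matrix
#'
#' @param g a [genotype_matrix()].
#' @param markers integer/logical/character index into the panel.
#' @return A `genotype_matrix` restricted to the selected markers.
#' @export
subset_markers <- function(g, markers) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.character(markers)) markers <- match(markers, g$panel$name)
  if (anyNA(markers)) stop("unknown marker name in subset")
  panel <- g$panel[markers, , drop = FALSE]
  class(panel) <- c("marker_panel", "data.frame")
  genotype_matrix(g$a[, markers, drop = FALSE], g$b[, markers, drop = FALSE],
                  panel, g$accessions)
}

parse_genotype_tokens <- function(tokens, marker, kind, file = "<genotypes>") {
  a <- rep(NA_integer_, length(tokens)); b <- a
  tokens <- trimws(tokens)
  filled <- !(is.na(tokens) | tokens %in% c(".", "", "NA", "./."))
  if (any(filled)) {
    parts <- strsplit(tokens[filled], "/", fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad))
      stop(file, ", marker ", marker, ": malformed genotype token '",
           tokens[filled][bad][1], "' (expected 'a/b' or '.')")
    va <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
    vb <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
    if (anyNA(va) || anyNA(vb))
      stop(file, ", marker ", marker, ": non-numeric allele token")
    a[filled] <- va; b[filled] <- vb
  }
  list(a = a, b = b)
}

#' Read a marker panel from a delimited file
#'
#' Expects columns `name` and `kind` and optionally `chromosome` and
#' `n_alleles`.
#'
#' @param path path to a TSV/CSV file.
#' @param sep field separator (default tab).
#' @return A [marker_panel()].
#' @export
read_marker_panel <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("name", "kind") %in% names(df)))
    stop(path, ": panel file needs 'name' and 'kind' columns")
  marker_panel(df$name, df$kind,
               chromosome = if ("chromosome" %in% names(df)) df$chromosome else NA,
               n_alleles = if ("n_alleles" %in% names(df)) df$n_alleles else NA)
}

#' Read genotype calls from a delimited file
#'
#' One row per accession; the first column holds the accession ID, remaining
#' columns hold `a/b` genotype tokens (`.` for missing) under marker-name
#' headers matching the panel.
#'
#' @param path path to the genotype table.
#' @param panel a [marker_panel()] declaring each marker's kind.
#' @param sep field separator (default tab).
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, panel, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop(path, ": expected an ID column plus marker columns")
  ids <- df[[1L]]
  missing_cols <- setdiff(panel$name, names(df)[-1L])
  if (length(missing_cols))
    stop(path, ": markers missing from file: ",
         paste(missing_cols, collapse = ", "))
  n <- length(ids); L <- nrow(panel)
  a <- matrix(NA_integer_, n, L); b <- matrix(NA_integer_, n, L)
  for (m in seq_len(L)) {
    parsed <- parse_genotype_tokens(df[[panel$name[m]]], panel$name[m],
                                    panel$kind[m], file = path)
    a[, m] <- parsed$a; b[, m] <- parsed$b
  }
  genotype_matrix(a, b, panel, ids)
}

#' Write genotype calls to a delimited file
#'
#' Inverse of [read_genotypes()]: emits `a/b` tokens and `.` for missing.
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, sep = "\t") {
  stopifnot(inherits(g, "genotype_matrix"))
  tok <- matrix(".", nrow(g$a), ncol(g$a))
  ok <- !is.na(g$a)
  tok[ok] <- paste0(g$a[ok], "/", g$b[ok])
  df <- data.frame(accession = g$accessions, tok, stringsAsFactors = FALSE)
  names(df) <- c("accession", g$panel$name)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read accession metadata
#'
#' Expects columns `id`, `region_group`, `seed_length_mm`, `seed_width_mm`
#' and optionally `horticultural_group`.
#'
#' @param path path to a TSV/CSV file.
#' @param sep field separator (default tab).
#' @return A `data.frame` with one row per accession.
#' @export
read_metadata <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("id", "region_group", "seed_length_mm", "seed_width_mm")
  if (!all(need %in% names(df)))
    stop(path, ": metadata needs columns ", paste(need, collapse = ", "))
  if (!"horticultural_group" %in% names(df))
    df$horticultural_group <- NA_character_
  bad <- !is.na(df$seed_length_mm) & df$seed_length_mm <= 0
  if (any(bad)) stop(path, ": non-positive seed length for ",
                     paste(df$id[bad], collapse = ", "))
  df
}

#' Read a quantitative trait table
#'
#' First column is the accession ID; remaining columns are named
#' quantitative/ordinal traits.
#'
#' @param path path to a TSV/CSV file.
#' @param sep field separator (default tab).
#' @return A numeric matrix with accession IDs as row names.
#' @export
read_trait_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  m
}

#' Cross-check a genotype matrix against accession metadata
#'
#' Report-only validation: never throws for data problems, it lists them.
#'
#' @param g a [genotype_matrix()].
#' @param meta metadata `data.frame` as from [read_metadata()].
#' @return A `data.frame` of class `validation_report` with columns
#'   `severity` (`"warning"`/`"error"`), `item`, `message`; zero rows iff the
#'   dataset is consistent.
#' @export
validate_dataset <- function(g, meta) {
  stopifnot(inherits(g, "genotype_matrix"))
  sev <- character(); item <- character(); msg <- character()
  add <- function(s, it, m) {
    sev <<- c(sev, s); item <<- c(item, it); msg <<- c(msg, m)
  }
  dup <- unique(meta$id[duplicated(meta$id)])
  for (d in dup) add("error", d, "duplicated accession ID in metadata")
  for (acc in setdiff(g$accessions, meta$id))
    add("warning", acc, "accession missing from metadata")
  for (acc in setdiff(meta$id, g$accessions))
    add("warning", acc, "metadata row without genotype calls")
  all_missing <- colSums(!is.na(g$a)) == 0L
  for (m in g$panel$name[all_missing])
    add("warning", m, "marker with all calls missing")
  rep <- data.frame(severity = sev, item = item, message = msg,
                    stringsAsFactors = FALSE)
  class(rep) <- c("validation_report", "data.frame")
  rep
}

#' Write a distance matrix in square PHYLIP format
#'
#' A count line followed by one row per taxon: a 10-character name field then
#' the distances. Names longer than 10 characters are truncated; a collision
#' after truncation is an error.
#'
#' @param d symmetric numeric matrix with row names, zero diagonal.
#' @param path output path.
#' @param digits decimal digits written (default 6).
#' @return `path`, invisibly.
#' @export
write_distance_phylip <- function(d, path, digits = 6) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix not symmetric")
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("T", seq_len(nrow(d)))
  short <- substr(labs, 1L, 10L)
  if (anyDuplicated(short))
    stop("taxon names collide after truncation to 10 characters: ",
         paste(unique(short[duplicated(short)]), collapse = ", "))
  lines <- c(sprintf("%5d", nrow(d)),
             vapply(seq_len(nrow(d)), function(i) {
               paste0(formatC(short[i], width = -10),
                      paste(formatC(d[i, ], format = "f", digits = digits),
                            collapse = " "))
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read a square PHYLIP distance matrix
#'
#' @param path path written by [write_distance_phylip()] or by PHYLIP tools.
#' @return A symmetric numeric matrix with taxon names as dimnames.
#' @export
read_distance_phylip <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1L]))
  labs <- character(n)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    row <- lines[i + 1L]
    labs[i] <- trimws(substr(row, 1L, 10L))
    d[i, ] <- as.numeric(strsplit(trimws(substr(row, 11L, nchar(row))),
                                  "[[:space:]]+")[[1L]])
  }
  dimnames(d) <- list(labs, labs)
  d
}

#' Load and validate a complete genotype dataset
#'
#' Convenience wrapper: reads the marker panel, genotype calls and
#' accession metadata, and attaches the cross-check report from
#' [validate_dataset()].
#'
#' @param genotype_path genotype table (see [read_genotypes()]).
#' @param metadata_path accession metadata (see [read_metadata()]).
#' @param panel_path marker panel (see [read_marker_panel()]).
#' @param sep field separator for all three files (default tab).
#' @return A list with `genotypes` (a [genotype_matrix()]), `metadata` and
#'   `validation` (a `validation_report`).
#' @export
load_dataset <- function(genotype_path, metadata_path, panel_path,
                         sep = "\t") {
  panel <- read_marker_panel(panel_path, sep = sep)
  g <- read_genotypes(genotype_path, panel, sep = sep)
  meta <- read_metadata(metadata_path, sep = sep)
  list(genotypes = g, metadata = meta,
       validation = validate_dataset(g, meta))
}
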