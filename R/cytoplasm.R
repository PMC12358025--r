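#' Construct a cytoplasm-typing key
#'
#' Maps CAPS digestion patterns to haplotype letters per marker, and
#' complete letter tuples across markers to cytoplasm types (Ia/Ib/Ic/III).
#'
#' @param markers character vector of CAPS marker names.
#' @param pattern_map named list: per marker, a named character vector
#'   mapping an observed fragment-pattern label to an allele letter.
#' @param type_map named character vector: names are complete letter tuples
#'   joined by `/` in marker order (e.g. `"A/A/A"`), values are cytoplasm
#'   types.
#' @return A list of class `cytoplasm_key`.
#' @export
cytoplasm_key <- function(markers, pattern_map, type_map) {
  markers <- as.character(markers)
  if (!setequal(names(pattern_map), markers))
    stop("pattern_map must have one entry per declared marker")
  pattern_map <- pattern_map[markers]
  n_mark <- length(markers)
  for (key in names(type_map)) {
    parts <- strsplit(key, "/", fixed = TRUE)[[1L]]
    if (length(parts) != n_mark)
      stop("type_map key '", key, "' is not a complete tuple over ",
           n_mark, " markers")
  }
  bad <- !type_map %in% c("Ia", "Ib", "Ic", "III")
  if (any(bad))
    stop("cytoplasm types must be Ia/Ib/Ic/III; got ",
         paste(unique(type_map[bad]), collapse = ", "))
  structure(list(markers = markers,
                 pattern_map = lapply(pattern_map, function(x)
                   stats::setNames(as.character(x), names(x))),
                 type_map = stats::setNames(as.character(type_map),
                                            names(type_map))),
            class = "cytoplasm_key")
}

#' Read a cytoplasm-typing key from YAML
#'
#' Expected schema: top-level `markers` (list), `pattern_map` (marker ->
#' pattern label -> letter) and `type_map` (either a map from `"A/A/A"`
#' tuple strings to types, or a list of `{alleles: [..], type: ..}`
#' entries).
#'
#' @param path YAML file path.
#' @return A [cytoplasm_key()].
#' @export
read_cytoplasm_key <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$markers) || is.null(y$pattern_map) || is.null(y$type_map))
    stop(path, ": key needs 'markers', 'pattern_map' and 'type_map'")
  tm <- y$type_map
  if (is.list(tm) && is.list(tm[[1L]]) && !is.null(tm[[1L]]$alleles)) {
    keys <- vapply(tm, function(e) paste(e$alleles, collapse = "/"), "")
    tm <- stats::setNames(vapply(tm, `[[`, "", "type"), keys)
  } else {
    tm <- unlist(tm)
  }
  pm <- lapply(y$pattern_map, unlist)
  cytoplasm_key(unlist(y$markers), pm, tm)
}

#' Write a cytoplasm key to YAML
#'
#' @param key a [cytoplasm_key()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cytoplasm_key <- function(key, path) {
  stopifnot(inherits(key, "cytoplasm_key"))
  yaml::write_yaml(list(markers = key$markers,
                        pattern_map = lapply(key$pattern_map, as.list),
                        type_map = as.list(key$type_map)), path)
  invisible(path)
}

#' Read CAPS pattern calls from a delimited file
#'
#' First column `accession`, one column per CAPS marker holding the
#' observed fragment-pattern label (empty or `.` for missing).
#'
#' @param path TSV path.
#' @param sep field separator.
#' @return A character matrix, accessions as row names, markers as columns.
#' @export
read_caps_calls <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m[m %in% c("", ".")] <- NA_character_
  m
}

#' Classify accessions into cytoplasm types
#'
#' Pure lookup: each accession's observed pattern at each key marker is
#' translated to its haplotype letter, and the complete letter tuple is
#' looked up in the key's type map. A tuple absent from the map yields
#' `"unclassified"`; an accession with a missing marker call is
#' unclassified with its reason recorded; a pattern label unknown to the
#' key is an error (it indicates a mis-keyed dataset, not biology).
#'
#' @param calls character matrix as from [read_caps_calls()] (accessions x
#'   key markers).
#' @param key a [cytoplasm_key()].
#' @return `data.frame` with columns `accession`, `tuple`, `type`,
#'   `reason` (`NA` unless unclassified).
#' @export
classify_cytoplasm <- function(calls, key) {
  stopifnot(inherits(key, "cytoplasm_key"))
  calls <- as.matrix(calls)
  miss_m <- setdiff(key$markers, colnames(calls))
  if (length(miss_m))
    stop("calls lack key marker(s): ", paste(miss_m, collapse = ", "))
  accs <- rownames(calls)
  type <- character(length(accs)); tuple <- character(length(accs))
  reason <- rep(NA_character_, length(accs))
  for (i in seq_along(accs)) {
    letters_i <- character(length(key$markers))
    ok <- TRUE
    for (mi in seq_along(key$markers)) {
      m <- key$markers[mi]
      pat <- calls[i, m]
      if (is.na(pat)) {
        reason[i] <- paste0("missing call at ", m)
        ok <- FALSE; break
      }
      letter <- key$pattern_map[[m]][pat]
      if (is.na(letter))
        stop("accession ", accs[i], ": pattern '", pat,
             "' unknown for marker ", m)
      letters_i[mi] <- letter
    }
    if (!ok) { type[i] <- "unclassified"; tuple[i] <- NA_character_; next }
    tuple[i] <- paste(letters_i, collapse = "/")
    tp <- key$type_map[tuple[i]]
    if (is.na(tp)) {
      type[i] <- "unclassified"
      reason[i] <- paste0("tuple ", tuple[i], " absent from key")
    } else type[i] <- unname(tp)
  }
  data.frame(accession = accs, tuple = tuple, type = type, reason = reason,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cross-tabulate cytoplasm types by group and seed class
#'
#' Counts accessions by region/group and seed class for each cytoplasm
#' type (the layout of a geography x seed-size x cytoplasm table).
#' Accessions without metadata are excluded and reported.
#'
#' @param types `data.frame` from [classify_cytoplasm()].
#' @param meta metadata `data.frame` with `id`, `region_group`,
#'   `seed_length_mm`.
#' @return A list with `table` (3-way `table`: group x seed class x type)
#'   and `excluded` (accession IDs lacking metadata).
#' @export
cytoplasm_crosstab <- function(types, meta) {
  idx <- match(types$accession, meta$id)
  excluded <- types$accession[is.na(idx)]
  keep <- !is.na(idx)
  grp <- meta$region_group[idx[keep]]
  cls <- classify_seed(meta$seed_length_mm[idx[keep]])
  tp <- types$type[keep]
  tab <- table(group = grp, seed_class = cls, type = tp)
  list(table = tab, excluded = excluded)
}
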