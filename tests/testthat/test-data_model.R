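# Readers, genotype container invariants, validation, PHYLIP serialization.

write_fixture_files <- function(dir) {
  panel <- data.frame(name = c("R01", "R02", "S01", "S02"),
                      kind = c("dominant", "dominant",
                               "codominant", "codominant"))
  write.table(panel, file.path(dir, "panel.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  geno <- data.frame(accession = c("a1", "a2", "a3", "a4"),
                     R01 = c("1/1", "0/0", "1/1", "0/0"),
                     R02 = c("1/1", "1/1", "0/0", "0/0"),
                     S01 = c("2/2", "3/7", "7/3", "."),
                     S02 = c("1/2", "2/2", "1/1", "2/3"),
                     stringsAsFactors = FALSE)
  write.table(geno, file.path(dir, "geno.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  meta <- data.frame(id = c("a1", "a2", "a3", "a4"),
                     region_group = c("N", "N", "S", "S"),
                     seed_length_mm = c(10.2, 11.0, 6.1, 5.2),
                     seed_width_mm = c(4.5, 4.8, 2.5, 2.2))
  write.table(meta, file.path(dir, "meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  dir
}

test_that("loading a mixed panel gives the declared shape and sorted pairs", {
  dir <- write_fixture_files(withr::local_tempdir())
  panel <- read_marker_panel(file.path(dir, "panel.tsv"))
  g <- read_genotypes(file.path(dir, "geno.tsv"), panel)
  expect_equal(dim(g), c(4L, 4L))
  expect_equal(sum(g$panel$kind == "dominant"), 2L)
  expect_equal(sum(g$panel$kind == "codominant"), 2L)
  # "3/7" is a heterozygote pair; "7/3" canonicalises to the same call
  expect_equal(c(g$a["a2", "S01"], g$b["a2", "S01"]), c(3L, 7L))
  expect_equal(c(g$a["a3", "S01"], g$b["a3", "S01"]), c(3L, 7L))
  # missing cell flagged
  expect_true(is.na(g$a["a4", "S01"]))
  # one-call loader bundles matrix, metadata and a clean validation report
  ds <- load_dataset(file.path(dir, "geno.tsv"), file.path(dir, "meta.tsv"),
                     file.path(dir, "panel.tsv"))
  expect_identical(ds$genotypes$a, g$a)
  expect_equal(nrow(ds$validation), 0L)
})

test_that("impossible dominant heterozygotes and ragged input are rejected", {
  panel <- marker_panel("R01", "dominant")
  expect_error(genotype_matrix(matrix(0L), matrix(1L), panel, "a1"),
               "dominant")
  expect_error(genotype_matrix(matrix(2L), matrix(2L), panel, "a1"),
               "dominant")
  expect_error(marker_panel("M", "semi-dominant"), "unknown marker kind")
  # half-missing call
  expect_error(genotype_matrix(matrix(NA_integer_), matrix(1L), panel, "a1"),
               "missing")
  # duplicate accessions
  p2 <- marker_panel(c("R01", "R02"), c("dominant", "dominant"))
  expect_error(genotype_matrix(matrix(1L, 2, 2), matrix(1L, 2, 2), p2,
                               c("a1", "a1")), "duplicated")
})

test_that("genotype write/read round-trip is the identity", {
  set.seed(42)
  g <- random_genotypes(n_acc = 8, p_missing = 0.1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, path)
  g2 <- read_genotypes(path, g$panel)
  expect_identical(g2$a, g$a)
  expect_identical(g2$b, g$b)
  expect_identical(g2$accessions, g$accessions)
})

test_that("dataset validation reports problems without throwing", {
  dir <- write_fixture_files(withr::local_tempdir())
  panel <- read_marker_panel(file.path(dir, "panel.tsv"))
  g <- read_genotypes(file.path(dir, "geno.tsv"), panel)
  meta <- read_metadata(file.path(dir, "meta.tsv"))
  expect_equal(nrow(validate_dataset(g, meta)), 0L)
  # one accession absent from metadata -> one warning entry
  rep1 <- validate_dataset(g, meta[meta$id != "a3", ])
  expect_equal(nrow(rep1), 1L)
  expect_equal(rep1$severity, "warning")
  expect_equal(rep1$item, "a3")
  # duplicated metadata ID -> error entry
  rep2 <- validate_dataset(g, rbind(meta, meta[1, ]))
  expect_true(any(rep2$severity == "error" & rep2$item == "a1"))
})

test_that("square PHYLIP serialization round-trips and guards name collisions", {
  z <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  path <- withr::local_tempfile(fileext = ".phy")
  write_distance_phylip(z, path)
  lines <- readLines(path)
  expect_equal(as.integer(trimws(lines[1])), 3L)
  expect_equal(length(lines), 4L)
  expect_equal(unname(read_distance_phylip(path)), unname(z))

  set.seed(7)
  x <- matrix(runif(25), 5, 5); d <- (x + t(x)) / 2; diag(d) <- 0
  rownames(d) <- colnames(d) <- paste0("taxon", 1:5)
  write_distance_phylip(d, path)
  expect_equal(read_distance_phylip(path), d, tolerance = 1e-6)

  long <- d
  rownames(long) <- colnames(long) <-
    paste0("very_long_name_", c("a", "a", "b", "c", "d"))
  expect_error(write_distance_phylip(long, path), "truncation")
})

test_that("the shipped example dataset loads and classifies cleanly", {
  ext <- function(f) system.file("extdata", f, package = "melondiv")
  ds <- load_dataset(ext("example_genotypes.tsv"),
                     ext("example_metadata.tsv"),
                     ext("example_panel.tsv"))
  expect_equal(dim(ds$genotypes), c(12L, 9L))
  expect_equal(nrow(ds$validation), 0L)
  key <- read_cytoplasm_key(ext("example_cytoplasm_key.yaml"))
  calls <- read_caps_calls(ext("example_caps_calls.tsv"))
  types <- classify_cytoplasm(calls, key)
  expect_true(all(types$type %in% c("Ia", "Ib", "Ic", "III")))
})
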