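#' Tabular readers and writers (phenotype, pedigree, Ct, results)
#'
#' Plain-text table IO with strict validation. Pedigree files are CSV with
#' columns `animal`, `sire`, `dam`, `sex`; `"0"` (or empty) marks an
#' unknown parent and is read as `NA`. Phenotype files are CSV with at
#' least `bird_id`, `sex`, `initial_bw`, `final_bw`, `total_fi`,
#' `test_days` (grams and days). Ct tables are CSV with `sample_id`,
#' `group`, `gene`, `ct_target`, `ct_reference`.
#'
#' @param path file path.
#' @name table_io
NULL

#' @rdname table_io
#' @export
read_phenotypes <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("bird_id", "sex", "initial_bw", "final_bw", "total_fi", "test_days")
  miss <- setdiff(need, names(df))
  if (length(miss)) .fail("phenotype file missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (any(df$initial_bw <= 0 | df$final_bw <= 0))
    .fail("phenotype file: non-positive body weight")
  if (any(df$test_days <= 0)) .fail("phenotype file: non-positive test_days")
  df
}

#' @rdname table_io
#' @param x data.frame to write.
#' @export
write_phenotypes <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_pedigree <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(animal = "character", sire = "character",
                                dam = "character"))
  need <- c("animal", "sire", "dam", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss)) .fail("pedigree file missing column(s): %s",
                          paste(miss, collapse = ", "))
  df$sire[df$sire %in% c("0", "", "NA")] <- NA_character_
  df$dam[df$dam %in% c("0", "", "NA")] <- NA_character_
  if (anyDuplicated(df$animal)) .fail("pedigree: duplicated animal id")
  df
}

#' @rdname table_io
#' @export
write_pedigree <- function(x, path) {
  x$sire[is.na(x$sire)] <- "0"
  x$dam[is.na(x$dam)] <- "0"
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_ct_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "gene", "ct_target", "ct_reference")
  miss <- setdiff(need, names(df))
  if (length(miss)) .fail("Ct file missing column(s): %s",
                          paste(miss, collapse = ", "))
  df
}

#' Write / read a results table (tab-separated, lossless round-trip)
#'
#' Generic TSV serialization used for every per-SNP result table. Comment
#' lines starting with `#` carry provenance headers and are skipped on
#' read. Character fields containing tabs or newlines are rejected: they
#' cannot round-trip.
#'
#' @param x data.frame of results.
#' @param path file path.
#' @param header optional character vector written as `#`-prefixed lines.
#' @export
write_results_table <- function(x, path, header = NULL) {
  chr <- vapply(x, is.character, logical(1))
  for (cn in names(x)[chr])
    if (any(grepl("[\t\n]", x[[cn]])))
      .fail("results table: field '%s' contains tab or newline", cn)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
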