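## Small readers/writers for the package's plain-text interchange formats.

#' Read a single-record FASTA file
#'
#' @param path FASTA path.
#' @return named character vector of sequences (names from headers).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Read / write a variant table as TSV
#'
#' Columns: `cds_pos` (1-based base position in the CDS), `ref`, `alt`,
#' `filter`; extra columns are carried through.
#'
#' @param path TSV path.
#' @return data.frame of variant records.
#' @export
read_variants_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cds_pos", "ref", "alt")
  if (!all(need %in% names(d))) {
    stop("variant TSV must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(d$filter)) d$filter <- "PASS"
  d
}

#' @rdname read_variants_tsv
#' @param variants data.frame of variant records.
#' @export
write_variants_tsv <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a fitted expected-count regression model as JSON
#'
#' @param path JSON path.
#' @return `read_regression_model` returns a `regression_model`.
#' @export
read_regression_model <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(slope = d$slope, intercept = d$intercept, R = d$R,
                 n_points = d$n_points),
            class = "regression_model")
}

#' @rdname read_regression_model
#' @param model a `regression_model`.
#' @export
write_regression_model <- function(model, path) {
  stopifnot(inherits(model, "regression_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
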