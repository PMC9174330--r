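## CDS validation, SNV consequence classification, unique-variant tallies,
## and the mutability -> expected-count regression.

#' Validate a coding sequence against its protein sequence
#'
#' A CDS is valid when it (1) begins with ATG, (2) ends with a stop
#' codon, (3) has length a multiple of 3 with no internal stop, and
#' (4) translates to `protein_seq` (when one is supplied).
#'
#' @param cds DNA string.
#' @param protein_seq amino acid string to check the translation against,
#'   or `NULL` to skip rule (4).
#' @return list with elements `ok` (logical) and `violations`
#'   (character vector, empty when valid). Violations are data, not
#'   errors.
#' @export
validate_cds <- function(cds, protein_seq = NULL) {
  cds <- toupper(cds)
  violations <- character(0)
  if (grepl("[^ACGT]", cds)) {
    violations <- c(violations, "contains non-ACGT characters")
    return(list(ok = FALSE, violations = violations))
  }
  if (nchar(cds) %% 3L != 0L) {
    violations <- c(violations, "length is not a multiple of 3")
    return(list(ok = FALSE, violations = violations))
  }
  codons <- codon_split(cds)
  n <- length(codons)
  if (n < 2L) {
    violations <- c(violations, "fewer than 2 codons")
    return(list(ok = FALSE, violations = violations))
  }
  aa <- translate_codon(codons)
  if (codons[1] != "ATG") {
    violations <- c(violations, "does not begin with ATG")
  }
  if (aa[n] != "*") {
    violations <- c(violations, "does not end with a stop codon")
  }
  if (any(aa[-n] == "*")) {
    violations <- c(violations, "internal stop codon")
  }
  if (!is.null(protein_seq) &&
      paste(aa[-n], collapse = "") != toupper(protein_seq)) {
    violations <- c(violations, "translation does not match protein sequence")
  }
  list(ok = length(violations) == 0L, violations = violations)
}

#' Construct a transcript object
#'
#' Bundles a validated CDS with its protein sequence and (optionally) its
#' per-codon consequence-partitioned mutability. Protein sites are
#' 1-based codon indices; the stop codon occupies CDS positions
#' `3L+1 .. 3L+3` and maps to no site.
#'
#' @param cds valid CDS string.
#' @param protein_seq amino acid string; derived from `cds` when `NULL`.
#' @param transcript_id,protein_id identifiers carried into outputs.
#' @param matrix optional `mutation_matrix`; when given, the per-codon
#'   mutability table is computed and attached.
#' @param boundary flank policy at CDS termini (see [codon_mutability()]).
#' @return an object of class `transcript`: a list with fields
#'   `transcript_id`, `protein_id`, `cds`, `protein_seq`, `L`,
#'   `mutability` (may be `NULL`).
#' @export
transcript <- function(cds, protein_seq = NULL, transcript_id = "tx",
                       protein_id = "protein", matrix = NULL,
                       boundary = "zero") {
  cds <- toupper(cds)
  if (is.null(protein_seq)) protein_seq <- translate_cds(cds)
  v <- validate_cds(cds, protein_seq)
  if (!v$ok) stop("invalid CDS: ", paste(v$violations, collapse = "; "))
  mut <- if (!is.null(matrix)) {
    transcript_mutability(cds, matrix, boundary = boundary)
  }
  structure(
    list(transcript_id = transcript_id, protein_id = protein_id,
         cds = cds, protein_seq = protein_seq, L = nchar(protein_seq),
         mutability = mut),
    class = "transcript"
  )
}

#' @export
print.transcript <- function(x, ...) {
  cat("<transcript>", x$transcript_id, "/", x$protein_id,
      "-", x$L, "amino acid sites\n")
  invisible(x)
}

#' Classify a single-nucleotide variant by coding consequence
#'
#' Mutates the codon containing the given CDS base, translates, and
#' reports the consequence class. Changes within the stop codon map to no
#' protein site (`site` is `NA`).
#'
#' @param tx a `transcript`.
#' @param cds_position 1-based base position within the CDS.
#' @param alt alternate base, different from the reference base.
#' @return list with `class` (one of `"synonymous"`, `"missense"`,
#'   `"nonsense"`, `"stop_loss"`), `site` (1-based protein position or
#'   `NA` for the stop codon), `ref_aa`, `alt_aa`, `ref`, `alt`.
#' @export
classify_snv <- function(tx, cds_position, alt) {
  stopifnot(inherits(tx, "transcript"))
  n <- nchar(tx$cds)
  if (cds_position < 1L || cds_position > n) {
    stop("cds_position out of range 1..", n)
  }
  alt <- toupper(alt)
  if (!alt %in% DNA_BASES) stop("'alt' must be one of A, C, G, T")
  ref <- substr(tx$cds, cds_position, cds_position)
  if (alt == ref) stop("'alt' equals the reference base at position ",
                       cds_position)
  j <- ceiling(cds_position / 3)
  codon <- substr(tx$cds, 3L * j - 2L, 3L * j)
  offset <- cds_position - (3L * j - 3L)
  alt_codon <- codon
  substr(alt_codon, offset, offset) <- alt
  cls <- classify_codon_change(codon, alt_codon)
  list(class = cls, site = if (j <= tx$L) j else NA_integer_,
       ref_aa = translate_codon(codon), alt_aa = translate_codon(alt_codon),
       ref = ref, alt = alt, codon = codon, alt_codon = alt_codon)
}

#' Tally unique qualifying SNVs per protein site
#'
#' Keeps records whose FILTER is `PASS`, collapses duplicate
#' (position, ref, alt) triples to one, rejects records whose stated
#' reference base disagrees with the CDS (with a warning), classifies the
#' survivors, and counts unique synonymous and missense variants per
#' site. Nonsense and stop-loss changes are classified but counted in
#' neither bucket. Two distinct nucleotide changes causing the same amino
#' acid substitution count as two variants.
#'
#' @param tx a `transcript`.
#' @param variants data.frame with columns `cds_pos`, `ref`, `alt`,
#'   `filter` (missing `filter` column is treated as all-PASS).
#' @return data.frame of class `site_variant_counts` with columns `site`
#'   (1..L), `n_syn`, `n_mis`.
#' @export
tally_variants <- function(tx, variants) {
  stopifnot(inherits(tx, "transcript"))
  out <- data.frame(site = seq_len(tx$L), n_syn = 0L, n_mis = 0L)
  class(out) <- c("site_variant_counts", "data.frame")
  if (is.null(variants) || nrow(variants) == 0L) return(out)
  if (is.null(variants$filter)) variants$filter <- "PASS"
  v <- variants[variants$filter == "PASS", , drop = FALSE]
  if (nrow(v) == 0L) return(out)
  v$ref <- toupper(v$ref); v$alt <- toupper(v$alt)
  v <- v[!duplicated(v[c("cds_pos", "ref", "alt")]), , drop = FALSE]
  # drop non-SNV alleles (multiallelic records must be pre-decomposed)
  snv <- nchar(v$ref) == 1L & nchar(v$alt) == 1L &
    v$ref %in% DNA_BASES & v$alt %in% DNA_BASES & v$ref != v$alt
  v <- v[snv, , drop = FALSE]
  cds_ref <- substring(tx$cds, v$cds_pos, v$cds_pos)
  mismatch <- cds_ref != v$ref
  if (any(mismatch)) {
    warning(sum(mismatch), " variant record(s) rejected: ",
            "reference base disagrees with the CDS")
    v <- v[!mismatch, , drop = FALSE]
  }
  for (i in seq_len(nrow(v))) {
    cl <- classify_snv(tx, v$cds_pos[i], v$alt[i])
    if (is.na(cl$site)) next
    if (cl$class == "missense") {
      out$n_mis[cl$site] <- out$n_mis[cl$site] + 1L
    } else if (cl$class == "synonymous") {
      out$n_syn[cl$site] <- out$n_syn[cl$site] + 1L
    }
  }
  out
}

#' Fit the mutability -> observed-count regression
#'
#' Ordinary least squares of per-transcript observed unique synonymous
#' variant counts on per-transcript total synonymous mutability. Because
#' synonymous variation is under minimal selection, the fitted line
#' represents the expected number of unique variants for a given
#' mutability in the absence of constraint; expected missense counts are
#' obtained by plugging missense mutability into the same line.
#'
#' @param mu numeric vector of per-transcript total mutability, or a
#'   data.frame with columns `mu` and `n_obs`.
#' @param n_obs observed unique variant counts (same length as `mu`).
#' @return object of class `regression_model`: list with `slope`
#'   (count per unit mutability), `intercept` (count), `R` (Pearson
#'   correlation of the points), `n_points`.
#' @export
fit_expected_count_model <- function(mu, n_obs = NULL) {
  if (is.data.frame(mu)) {
    n_obs <- mu$n_obs
    mu <- mu$mu
  }
  if (length(mu) != length(n_obs)) stop("'mu' and 'n_obs' lengths differ")
  if (length(mu) < 3L) stop("need at least 3 points to fit the model")
  if (stats::var(mu) == 0) stop("degenerate design: no variance in mutability")
  fit <- stats::lm(n_obs ~ mu)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         R = stats::cor(mu, n_obs),
         n_points = length(mu)),
    class = "regression_model"
  )
}

#' @export
print.regression_model <- function(x, ...) {
  cat(sprintf(
    "<regression_model> y-hat = %.4g * mu + %.4g  (R = %.3f, n = %d)\n",
    x$slope, x$intercept, x$R, x$n_points))
  invisible(x)
}

#' Predict an expected unique-variant count from mutability
#'
#' @param model a `regression_model`.
#' @param mu total mutability (per generation).
#' @return predicted count (real-valued, may be negative; see
#'   [expected_missense_count()] for the floored version).
#' @export
predict_expected_count <- function(model, mu) {
  stopifnot(inherits(model, "regression_model"))
  model$slope * mu + model$intercept
}

#' Expected number of unique missense variants for a transcript
#'
#' Plugs the transcript's total missense mutability into the regression
#' fitted on synonymous data. Predictions at or below 0 are floored at 0,
#' in which case the protein cannot be scored.
#'
#' @param tx a `transcript` with an attached mutability table.
#' @param model a `regression_model`.
#' @param class consequence class whose mutability is plugged in
#'   (`"missense"` for scoring, `"synonymous"` for the control score).
#' @return `t_e`, a non-negative real number (not rounded), with
#'   attribute `scorable` (FALSE when the raw prediction was <= 0).
#' @export
expected_missense_count <- function(tx, model,
                                    class = c("missense", "synonymous")) {
  stopifnot(inherits(tx, "transcript"))
  class <- match.arg(class)
  if (is.null(tx$mutability)) {
    stop("transcript has no mutability table; construct it with a matrix")
  }
  mu <- total_mutability(tx$mutability, class)
  raw <- predict_expected_count(model, mu)
  t_e <- max(0, raw)
  attr(t_e, "scorable") <- raw > 0
  t_e
}
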