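## Trinucleotide mutability model: a 64 x 3 table of per-generation
## substitution probabilities keyed by sequence context, and its reduction
## to per-codon mutability partitioned by coding consequence.

#' Construct a trinucleotide mutation matrix
#'
#' A mutation matrix stores, for each of the 64 trinucleotide contexts
#' `XYZ`, the per-generation probability of the central base `Y` mutating
#' to each of the three alternate bases `Y'` (192 entries in total).
#'
#' @param prob named numeric vector of probabilities; names are
#'   `"XYZ>W"` where `XYZ` is the context and `W` the alternate central
#'   base. Missing entries default to 0. All values must be >= 0.
#' @param scaling_constant unitless multiplier applied to every entry at
#'   construction (default 1). Downstream COSMIS scores are invariant to
#'   it; it only matters when absolute per-generation rates are needed.
#' @return an object of class `mutation_matrix`: a named numeric vector
#'   with exactly 192 entries and attribute `scaling_constant`.
#' @examples
#' m <- mutation_matrix(c("ACG>A" = 1e-8, "ACG>T" = 2e-8))
#' m[["ACG>A"]]
#' @export
mutation_matrix <- function(prob = numeric(0), scaling_constant = 1) {
  keys <- mutation_matrix_keys()
  if (is.null(names(prob)) && length(prob) > 0) {
    stop("'prob' must be a named vector with names like \"ACG>T\"")
  }
  unknown <- setdiff(names(prob), keys)
  if (length(unknown)) {
    stop("invalid mutation keys: ", paste(utils::head(unknown, 5), collapse = ", "))
  }
  if (any(prob < 0)) stop("mutation probabilities must be >= 0")
  if (!is.numeric(scaling_constant) || scaling_constant < 0) {
    stop("'scaling_constant' must be a non-negative number")
  }
  full <- stats::setNames(numeric(length(keys)), keys)
  full[names(prob)] <- prob * scaling_constant
  structure(full, scaling_constant = scaling_constant,
            class = "mutation_matrix")
}

## The 192 valid (context, alt) keys, alphabetical by context then alt.
mutation_matrix_keys <- function() {
  ctx <- all_trinucleotides()
  keys <- lapply(ctx, function(c3) {
    y <- substr(c3, 2, 2)
    paste0(c3, ">", setdiff(DNA_BASES, y))
  })
  unlist(keys)
}

#' Uniform mutation matrix
#'
#' Every one of the 192 context-specific substitution probabilities is set
#' to the same value `q`. Useful as a context-free baseline and in tests
#' where consequence partitions have simple closed forms.
#'
#' @param q probability per substitution per generation.
#' @return a `mutation_matrix`.
#' @export
uniform_mutation_matrix <- function(q = 1e-8) {
  keys <- mutation_matrix_keys()
  mutation_matrix(stats::setNames(rep(q, length(keys)), keys))
}

#' Rescale a mutation matrix by a positive constant
#'
#' @param m a `mutation_matrix`.
#' @param c positive multiplier.
#' @return a `mutation_matrix` with every entry multiplied by `c`.
#' @export
rescale_mutation_matrix <- function(m, c) {
  stopifnot(inherits(m, "mutation_matrix"), is.numeric(c), c > 0)
  structure(unclass(m) * c,
            scaling_constant = attr(m, "scaling_constant") * c,
            class = "mutation_matrix")
}

#' Estimate a mutation matrix from context occurrence and mutation counts
#'
#' The probability of context `XYZ` mutating to `XY'Z` is the number of
#' observed `Y -> Y'` mutations in context `XYZ` divided by the total
#' number of occurrences of `XYZ` (e.g., tabulated over intergenic
#' sequence), optionally multiplied by a proportionality constant that
#' converts the ratio to a per-generation rate. Contexts with no observed
#' mutations get probability 0.
#'
#' @param occurrences named integer vector: context -> occurrence count.
#' @param mutation_counts named integer vector: `"XYZ>W"` -> mutation
#'   count, or a data.frame with columns `context`, `alt`, `count`.
#' @param scaling_constant per-generation proportionality constant
#'   (default 1).
#' @return a `mutation_matrix`.
#' @export
estimate_mutation_matrix <- function(occurrences, mutation_counts,
                                     scaling_constant = 1) {
  if (is.data.frame(mutation_counts)) {
    mutation_counts <- stats::setNames(
      mutation_counts$count,
      paste0(mutation_counts$context, ">", mutation_counts$alt)
    )
  }
  if (any(occurrences < 0) || any(mutation_counts < 0)) {
    stop("counts must be non-negative")
  }
  ctx_of <- substr(names(mutation_counts), 1, 3)
  occ <- occurrences[ctx_of]
  bad <- is.na(occ) | occ == 0
  if (any(bad & mutation_counts > 0)) {
    stop("mutation count reported for context with zero occurrences: ",
         paste(unique(ctx_of[bad & mutation_counts > 0]), collapse = ", "))
  }
  if (any(mutation_counts > occ, na.rm = TRUE)) {
    stop("mutation count exceeds occurrence count for context: ",
         paste(unique(ctx_of[which(mutation_counts > occ)]), collapse = ", "))
  }
  prob <- ifelse(bad, 0, mutation_counts / occ)
  mutation_matrix(stats::setNames(prob, names(mutation_counts)),
                  scaling_constant = scaling_constant)
}

#' Look up substitution probabilities
#'
#' @param m a `mutation_matrix`.
#' @param context character vector of trinucleotide contexts.
#' @param alt character vector of alternate central bases (recycled).
#' @return numeric vector of probabilities.
#' @export
mutation_probability <- function(m, context, alt) {
  stopifnot(inherits(m, "mutation_matrix"))
  unname(unclass(m)[paste0(context, ">", alt)])
}

#' Per-codon mutability partitioned by coding consequence
#'
#' Enumerates the 9 single-nucleotide changes of a codon, looks up each
#' probability under its trinucleotide context (the codon base plus its
#' immediate neighbors in the coding sequence), classifies the change
#' against the standard genetic code, and sums probabilities into
#' synonymous / missense / nonsense buckets. Changes that destroy a stop
#' codon (stop loss) are classified but contribute to none of the three
#' buckets.
#'
#' @param codon a DNA 3-mer.
#' @param m a `mutation_matrix`.
#' @param left_flank,right_flank the CDS bases immediately before the
#'   first and after the third codon position, or `NA` at a CDS boundary.
#' @param boundary what to do when a flank is absent: `"zero"` (the
#'   affected single-base changes contribute 0) or `"require"` (error).
#' @return named numeric triple `c(u_syn, u_mis, u_non)`.
#' @examples
#' m <- uniform_mutation_matrix(1e-8)
#' codon_mutability("TGG", m, "A", "A")  # 0 syn, 7 mis, 2 non
#' @export
codon_mutability <- function(codon, m, left_flank = NA, right_flank = NA,
                             boundary = c("zero", "require")) {
  boundary <- match.arg(boundary)
  codon <- toupper(codon)
  if (!grepl("^[ACGT]{3}$", codon)) {
    stop("'codon' must be a DNA 3-mer without ambiguity codes")
  }
  if (boundary == "require" && (is.na(left_flank) || is.na(right_flank))) {
    stop("flanking base(s) absent and boundary policy is \"require\"")
  }
  bases <- strsplit(codon, "")[[1]]
  ext <- c(left_flank, bases, right_flank)  # positions 0..4
  nbr <- codon_snv_neighbors(codon)
  ctx_l <- ext[nbr$pos]        # base to the left of mutated position
  ctx_r <- ext[nbr$pos + 2L]   # base to the right
  p <- ifelse(is.na(ctx_l) | is.na(ctx_r), 0,
              mutation_probability(m, paste0(ctx_l, nbr$ref, ctx_r), nbr$alt))
  u <- c(
    u_syn = sum(p[nbr$class == "synonymous"]),
    u_mis = sum(p[nbr$class == "missense"]),
    u_non = sum(p[nbr$class == "nonsense"])
  )
  u
}

#' Enumerate every single-nucleotide change of a coding sequence
#'
#' One row per possible SNV (3 alternates at each CDS base, stop codon
#' included), with its trinucleotide-context mutation probability and
#' coding consequence. This is the workhorse behind
#' [transcript_mutability()] and the synthetic variant generator.
#'
#' @param cds a valid CDS string.
#' @param m a `mutation_matrix`.
#' @param boundary flank policy at the CDS termini (`"zero"` or
#'   `"require"`); see [codon_mutability()].
#' @return data.frame with columns `site` (codon index; `L + 1` for the
#'   stop codon), `cds_pos`, `ref`, `alt`, `class`, `prob`.
#' @export
enumerate_cds_snvs <- function(cds, m, boundary = c("zero", "require")) {
  boundary <- match.arg(boundary)
  cds <- toupper(cds)
  bases <- strsplit(cds, "")[[1]]
  n <- length(bases)
  codons <- codon_split(cds)
  pos <- rep(seq_len(n), each = 3L)
  ref <- bases[pos]
  alt <- unlist(lapply(bases, function(b) setdiff(DNA_BASES, b)),
                use.names = FALSE)
  lf <- c(NA, bases)[pos]              # base to the left (NA at position 1)
  rf <- c(bases, NA)[pos + 1L]         # base to the right (NA at position n)
  if (boundary == "require" && (is.na(lf[1]) || is.na(rf[length(rf)]))) {
    stop("flanking base(s) absent and boundary policy is \"require\"")
  }
  site <- (pos - 1L) %/% 3L + 1L
  offset <- pos - 3L * (site - 1L)
  ref_codon <- codons[site]
  alt_codon <- ref_codon
  substr(alt_codon, offset, offset) <- alt
  prob <- ifelse(is.na(lf) | is.na(rf), 0,
                 mutation_probability(m, paste0(lf, ref, rf), alt))
  data.frame(site = site, cds_pos = pos, ref = ref, alt = alt,
             class = classify_codon_change(ref_codon, alt_codon),
             prob = prob, stringsAsFactors = FALSE)
}

#' Per-codon mutability table for a full coding sequence
#'
#' Applies [codon_mutability()] to every codon of a validated CDS, taking
#' each codon's trinucleotide contexts from the concatenated coding
#' sequence itself. The terminal stop codon encodes no amino acid site
#' and is excluded from the table (it still supplies the right flank of
#' the last coding codon).
#'
#' @param cds a valid CDS (see [validate_cds()]).
#' @param m a `mutation_matrix`.
#' @param boundary flank policy at the two CDS termini; see
#'   [codon_mutability()].
#' @return a data.frame of class `codon_mutability_table` with columns
#'   `site`, `codon`, `u_syn`, `u_mis`, `u_non`, one row per amino acid
#'   site, and attributes `mu_syn`, `mu_mis`, `mu_non` (column totals).
#' @export
transcript_mutability <- function(cds, m, boundary = "zero") {
  cds <- toupper(cds)
  v <- validate_cds(cds)
  if (!v$ok) {
    stop("invalid CDS: ", paste(v$violations, collapse = "; "))
  }
  codons <- codon_split(cds)
  L <- length(codons) - 1L  # stop codon excluded
  snvs <- enumerate_cds_snvs(cds, m, boundary = boundary)
  snvs <- snvs[snvs$site <= L, , drop = FALSE]
  bucket <- function(cls) {
    s <- snvs[snvs$class == cls, , drop = FALSE]
    v <- numeric(L)
    if (nrow(s)) {
      agg <- tapply(s$prob, s$site, sum)
      v[as.integer(names(agg))] <- agg
    }
    v
  }
  out <- data.frame(site = seq_len(L), codon = codons[seq_len(L)],
                    u_syn = bucket("synonymous"), u_mis = bucket("missense"),
                    u_non = bucket("nonsense"), stringsAsFactors = FALSE)
  structure(out,
            mu_syn = sum(out$u_syn), mu_mis = sum(out$u_mis),
            mu_non = sum(out$u_non),
            class = c("codon_mutability_table", "data.frame"))
}

#' Total mutability of a transcript by consequence class
#'
#' @param tab a `codon_mutability_table`.
#' @param class one of `"synonymous"`, `"missense"`, `"nonsense"`.
#' @return total mutability (per generation).
#' @export
total_mutability <- function(tab, class = c("synonymous", "missense",
                                            "nonsense")) {
  class <- match.arg(class)
  col <- switch(class, synonymous = "u_syn", missense = "u_mis",
                nonsense = "u_non")
  sum(tab[[col]])
}

#' Read / write a mutation matrix as TSV
#'
#' The on-disk format has columns `context`, `alt`, `probability` and one
#' row per (context, alternate) pair; probabilities round-trip as decimal
#' strings.
#'
#' @param path file path.
#' @return `read_mutation_matrix` returns a `mutation_matrix`.
#' @export
read_mutation_matrix <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c("character", "character", "numeric"))
  mutation_matrix(stats::setNames(d$probability, paste0(d$context, ">", d$alt)))
}

#' @rdname read_mutation_matrix
#' @param m a `mutation_matrix` to write.
#' @export
write_mutation_matrix <- function(m, path) {
  stopifnot(inherits(m, "mutation_matrix"))
  keys <- names(m)
  d <- data.frame(context = substr(keys, 1, 3), alt = substr(keys, 5, 5),
                  probability = format(unclass(m), digits = 17, trim = TRUE,
                                       scientific = FALSE),
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
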