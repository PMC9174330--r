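## Genetic-code helpers shared across modules. The code table itself comes
## from Biostrings (standard nuclear code, table 1).

DNA_BASES <- c("A", "C", "G", "T")

#' Translate a codon (or vector of codons) with the standard genetic code
#'
#' @param codon character vector of DNA 3-mers (uppercase ACGT).
#' @return character vector of one-letter amino acids, `"*"` for stop.
#' @keywords internal
translate_codon <- function(codon) {
  aa <- unname(Biostrings::GENETIC_CODE[codon])
  if (anyNA(aa)) {
    stop("invalid codon(s): ", paste(codon[is.na(aa)], collapse = ", "))
  }
  aa
}

#' Translate a CDS into its amino acid sequence
#'
#' The terminal stop codon, if present, is dropped from the returned string.
#'
#' @param cds a DNA string with length a multiple of 3.
#' @return single amino acid string (no stop symbol).
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L) {
    stop("CDS length is not a multiple of 3")
  }
  codons <- codon_split(cds)
  aa <- translate_codon(codons)
  if (length(aa) && aa[length(aa)] == "*") {
    aa <- aa[-length(aa)]
  }
  paste(aa, collapse = "")
}

## Split a CDS string into codons.
codon_split <- function(cds) {
  n <- nchar(cds) %/% 3L
  substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

## Classify a single codon change. Returns one of
## "synonymous", "missense", "nonsense", "stop_loss".
classify_codon_change <- function(ref_codon, alt_codon) {
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  ifelse(ref_aa == alt_aa, "synonymous",
    ifelse(alt_aa == "*", "nonsense",
      ifelse(ref_aa == "*", "stop_loss", "missense")
    )
  )
}

## All 64 trinucleotide contexts, alphabetical.
all_trinucleotides <- function() {
  g <- expand.grid(z = DNA_BASES, y = DNA_BASES, x = DNA_BASES,
                   stringsAsFactors = FALSE)
  sort(paste0(g$x, g$y, g$z))
}

## The 9 single-nucleotide neighbors of a codon: data.frame with columns
## pos (1:3), ref, alt, alt_codon, class.
codon_snv_neighbors <- function(codon) {
  bases <- strsplit(codon, "")[[1]]
  out <- vector("list", 9L)
  k <- 0L
  for (pos in 1:3) {
    for (alt in setdiff(DNA_BASES, bases[pos])) {
      mutated <- bases
      mutated[pos] <- alt
      k <- k + 1L
      out[[k]] <- data.frame(
        pos = pos, ref = bases[pos], alt = alt,
        alt_codon = paste(mutated, collapse = ""),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  res$class <- classify_codon_change(rep(codon, nrow(res)), res$alt_codon)
  res
}
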