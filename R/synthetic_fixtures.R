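## Fully synthetic toy proteins (sequence, CDS, 3D coordinates) and
## variant tables with known constraint structure, so the whole scoring
## pipeline can be exercised without any external data.

#' Specification of a synthetic toy protein
#'
#' @param L number of amino acid sites (>= 2).
#' @param geometry `"ideal_helix"` (C-alpha rise 1.5 A per residue, 100
#'   degree turn), `"random_coil"` (3.8 A random walk), or
#'   `"two_chain_dimer"` (two copies of the helix with a controllable
#'   inter-chain gap).
#' @param codon_profile `"uniform"` (uniform over synonymous codons) or
#'   `"gc_skewed"` (weight doubling per G/C in the codon; exercises the
#'   context dependence of the mutability model).
#' @param constraint_profile per-site retention fraction `f_j` in
#'   `[0, 1]`; 1 = neutral, 0 = fully depleted. Recycled to length `L`.
#' @param t_e_true expected total number of missense variant placements
#'   drawn by the generator.
#' @param t_e_syn_true analogous synonymous total; `NULL` (default)
#'   scales `t_e_true` by the transcript's synonymous/missense
#'   mutability ratio, i.e. neutral counts proportional to mutability.
#' @param seed RNG seed for sequence, structure and variant generation.
#' @param dimer_gap closest C-beta approach between the two chains in
#'   Angstrom (default 5, so facing residues form inter-chain contacts
#'   at the 8 A threshold).
#' @return object of class `toy_protein_spec`.
#' @export
toy_protein_spec <- function(L, geometry = c("ideal_helix", "random_coil",
                                             "two_chain_dimer"),
                             codon_profile = c("uniform", "gc_skewed"),
                             constraint_profile = 1, t_e_true = 2 * L,
                             t_e_syn_true = NULL, seed = 42,
                             dimer_gap = 5) {
  geometry <- match.arg(geometry)
  codon_profile <- match.arg(codon_profile)
  if (L < 2) stop("'L' must be >= 2")
  f <- rep_len(constraint_profile, L)
  if (any(f < 0 | f > 1)) stop("retention fractions must lie in [0, 1]")
  if (t_e_true < 0) stop("'t_e_true' must be >= 0")
  structure(list(L = L, geometry = geometry, codon_profile = codon_profile,
                 constraint_profile = f, t_e_true = t_e_true,
                 t_e_syn_true = t_e_syn_true, seed = seed,
                 dimer_gap = dimer_gap),
            class = "toy_protein_spec")
}

## Reverse genetic code: amino acid -> codons.
codons_for_aa <- function(aa) {
  names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == aa]
}

#' Deterministic toy protein and coding sequences
#'
#' The first residue is always methionine; the rest are drawn uniformly
#' over the 20 amino acids. Codons are back-translated per the spec's
#' codon usage profile and a stop codon is appended.
#'
#' @param spec a `toy_protein_spec`.
#' @return list with `protein_seq` and `cds` (both strings).
#' @export
toy_sequences <- function(spec) {
  stopifnot(inherits(spec, "toy_protein_spec"))
  set.seed(spec$seed)
  aas <- setdiff(sort(unique(Biostrings::GENETIC_CODE)), "*")
  protein <- c("M", sample(aas, spec$L - 1L, replace = TRUE))
  pick_codon <- function(aa) {
    cands <- codons_for_aa(aa)
    w <- if (spec$codon_profile == "gc_skewed") {
      2^vapply(strsplit(cands, ""), function(b) sum(b %in% c("G", "C")),
               numeric(1))
    } else {
      rep(1, length(cands))
    }
    if (length(cands) == 1L) cands else sample(cands, 1L, prob = w)
  }
  codons <- vapply(protein, pick_codon, "")
  stop_codon <- pick_codon("*")
  list(protein_seq = paste(protein, collapse = ""),
       cds = paste(c(codons, stop_codon), collapse = ""))
}

#' Idealized 3D coordinates for a toy protein
#'
#' Helical geometries use a C-alpha radius of 2.3 A, a rise of 1.5 A per
#' residue and a 100 degree turn, with C-beta atoms displaced radially
#' to 3.8 A, so that i/i+-1, i/i+-3 and i/i+-4 contacts exist at the 8 A
#' threshold. The dimer places a second copy parallel to the first with
#' closest C-beta approach `dimer_gap`.
#'
#' @param spec a `toy_protein_spec`.
#' @param protein_seq amino acid string (glycines get no C-beta).
#' @return data.frame with columns `chain`, `resnum`, `aa`, `atom`
#'   (`"CA"`/`"CB"`), `x`, `y`, `z`.
#' @export
toy_coordinates <- function(spec, protein_seq) {
  aa <- strsplit(protein_seq, "")[[1]]
  L <- length(aa)
  helix <- function() {
    theta <- (seq_len(L) - 1L) * 100 * pi / 180
    list(ca = cbind(2.3 * cos(theta), 2.3 * sin(theta),
                    1.5 * seq_len(L)),
         cb = cbind(3.8 * cos(theta), 3.8 * sin(theta),
                    1.5 * seq_len(L)))
  }
  coil <- function() {
    set.seed(spec$seed + 101)
    dirs <- matrix(stats::rnorm(3 * L), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    ca <- apply(3.8 * dirs, 2, cumsum)
    if (L == 1L) ca <- matrix(ca, ncol = 3)
    off <- matrix(stats::rnorm(3 * L), ncol = 3)
    off <- 1.5 * off / sqrt(rowSums(off^2))
    list(ca = ca, cb = ca + off)
  }
  one_chain <- function(xyz, chain, shift = c(0, 0, 0)) {
    rows <- lapply(seq_len(L), function(i) {
      atoms <- if (aa[i] == "G") "CA" else c("CA", "CB")
      coords <- rbind(xyz$ca[i, ], xyz$cb[i, ])[seq_along(atoms), ,
                                                drop = FALSE]
      data.frame(chain = chain, resnum = i, aa = aa[i], atom = atoms,
                 x = coords[, 1] + shift[1], y = coords[, 2] + shift[2],
                 z = coords[, 3] + shift[3], stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  if (spec$geometry == "random_coil") {
    return(one_chain(coil(), "A"))
  }
  h <- helix()
  out <- one_chain(h, "A")
  if (spec$geometry == "two_chain_dimer") {
    # axis separation = 2 x C-beta radius + gap; chain B rotated 180
    # degrees so its C-betas face chain A
    d <- 2 * 3.8 + spec$dimer_gap
    hb <- list(ca = cbind(-h$ca[, 1], h$ca[, 2], h$ca[, 3]),
               cb = cbind(-h$cb[, 1], h$cb[, 2], h$cb[, 3]))
    out <- rbind(out, one_chain(hb, "B", shift = c(d, 0, 0)))
  }
  out
}

## Minimal fixed-width PDB writer for CA/CB-only toy models.
write_toy_pdb <- function(coords, path, bfactor = 90) {
  aa3 <- names(AA3TO1)[match(coords$aa, AA3TO1)]
  lines <- sprintf(
    "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(coords)),
    sprintf(" %-3s", coords$atom), aa3, coords$chain, coords$resnum,
    coords$x, coords$y, coords$z, 1.00, bfactor,
    substr(coords$atom, 1, 1)
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Generate the full toy-protein fixture set
#'
#' Writes the four files every downstream reader consumes: the protein
#' FASTA, the matched CDS FASTA, a PDB structure, and the residue-level
#' mapping TSV.
#'
#' @param spec a `toy_protein_spec`.
#' @param dir output directory (created if missing).
#' @param bfactor per-residue confidence written to the B-factor column
#'   (default 90, i.e. a confidently predicted model).
#' @return list with the four file `paths` plus the in-memory
#'   `protein_seq`, `cds` and `coords`.
#' @export
make_toy_protein <- function(spec, dir = tempfile("toyprot"),
                             bfactor = 90) {
  stopifnot(inherits(spec, "toy_protein_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- toy_sequences(spec)
  coords <- toy_coordinates(spec, seqs$protein_seq)
  paths <- list(
    protein_fasta = file.path(dir, "protein.fasta"),
    cds_fasta = file.path(dir, "cds.fasta"),
    structure_pdb = file.path(dir, "structure.pdb"),
    mapping_tsv = file.path(dir, "mapping.tsv")
  )
  writeLines(c(">toy_protein", seqs$protein_seq), paths$protein_fasta)
  writeLines(c(">toy_cds", seqs$cds), paths$cds_fasta)
  write_toy_pdb(coords, paths$structure_pdb, bfactor = bfactor)
  res <- unique(coords[, c("chain", "resnum")])
  utils::write.table(
    data.frame(protein_pos = res$resnum, chain = res$chain,
               resnum = res$resnum),
    paths$mapping_tsv, sep = "\t", quote = FALSE, row.names = FALSE
  )
  c(list(paths = paths), seqs, list(coords = coords, spec = spec))
}

#' Simulate an observed variant table under known constraint
#'
#' Draws `round(t_e_true)` missense placements over sites from the
#' multinomial defined by the normalized missense mutability of the toy
#' CDS, thins each site's placements by its retention fraction `f_j`,
#' assigns surviving placements to distinct nucleotide changes within
#' the codon (weighted by per-change mutability, without replacement, so
#' the unique-variant tally preserves the drawn site counts until a
#' codon's changes are exhausted), and collapses to unique SNVs.
#' Synonymous variants are drawn analogously with `f = 1` everywhere.
#'
#' @param spec a `toy_protein_spec`.
#' @param matrix a `mutation_matrix`.
#' @param cds the toy CDS; `NULL` regenerates it from the spec's seed.
#' @return data.frame with columns `cds_pos`, `ref`, `alt`, `filter`
#'   (all `"PASS"`), `class`, sorted by position. Attribute `truth`
#'   holds the per-site retention fractions.
#' @export
simulate_observed_variants <- function(spec, matrix, cds = NULL) {
  stopifnot(inherits(spec, "toy_protein_spec"))
  if (is.null(cds)) cds <- toy_sequences(spec)$cds
  L <- spec$L
  snvs <- enumerate_cds_snvs(cds, matrix)
  snvs <- snvs[snvs$site <= L, , drop = FALSE]
  set.seed(spec$seed + 1L)

  draw_class <- function(cls, total, f) {
    s <- snvs[snvs$class == cls & snvs$prob > 0, , drop = FALSE]
    u <- numeric(L)
    agg <- tapply(s$prob, s$site, sum)
    u[as.integer(names(agg))] <- agg
    if (sum(u) <= 0 || round(total) < 1) {
      return(s[0, c("cds_pos", "ref", "alt"), drop = FALSE])
    }
    k <- stats::rmultinom(1, round(total), u / sum(u))[, 1]
    k <- stats::rbinom(L, k, f)
    picked <- lapply(which(k > 0), function(j) {
      sj <- s[s$site == j, , drop = FALSE]
      take <- min(k[j], nrow(sj))  # saturation: codon SNVs exhausted
      idx <- if (nrow(sj) == 1L) 1L else {
        sample(nrow(sj), take, prob = sj$prob)
      }
      sj[idx, c("cds_pos", "ref", "alt"), drop = FALSE]
    })
    do.call(rbind, c(list(s[0, c("cds_pos", "ref", "alt")]), picked))
  }

  mis <- draw_class("missense", spec$t_e_true, spec$constraint_profile)
  t_syn <- spec$t_e_syn_true
  if (is.null(t_syn)) {
    u_mis <- sum(snvs$prob[snvs$class == "missense"])
    u_syn <- sum(snvs$prob[snvs$class == "synonymous"])
    t_syn <- spec$t_e_true * u_syn / u_mis
  }
  syn <- draw_class("synonymous", t_syn, 1)
  out <- rbind(
    if (nrow(mis)) cbind(mis, class = "missense"),
    if (nrow(syn)) cbind(syn, class = "synonymous")
  )
  if (is.null(out)) {
    out <- data.frame(cds_pos = integer(0), ref = character(0),
                      alt = character(0), class = character(0))
  }
  out$filter <- rep("PASS", nrow(out))
  out <- out[order(out$cds_pos, out$alt),
             c("cds_pos", "ref", "alt", "filter", "class")]
  rownames(out) <- NULL
  # duplicates cannot arise within a class (sampling without
  # replacement), but collapse defensively to mirror the tally path
  out <- out[!duplicated(out[c("cds_pos", "ref", "alt")]), , drop = FALSE]
  structure(out, truth = spec$constraint_profile)
}
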