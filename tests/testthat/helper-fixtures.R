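# Shared fixtures and independent oracles for the test suite.

# Literal standard genetic code, written out independently of the
# package (and of Biostrings) so consequence classification can be
# checked against a second source.
ORACLE_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

BASES <- c("A", "C", "G", "T")

# Brute-force consequence classification of every SNV of a codon,
# using only the literal code table above.
oracle_codon_snvs <- function(codon) {
  b <- strsplit(codon, "")[[1]]
  out <- list()
  for (pos in 1:3) {
    for (alt in BASES[BASES != b[pos]]) {
      mut <- b
      mut[pos] <- alt
      alt_codon <- paste(mut, collapse = "")
      ref_aa <- ORACLE_CODE[[codon]]
      alt_aa <- ORACLE_CODE[[alt_codon]]
      cls <- if (ref_aa == alt_aa) "synonymous"
      else if (alt_aa == "*") "nonsense"
      else if (ref_aa == "*") "stop_loss"
      else "missense"
      out[[length(out) + 1]] <- data.frame(
        pos = pos, ref = b[pos], alt = alt, alt_codon = alt_codon,
        class = cls, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

all_codons <- function() {
  g <- expand.grid(BASES, BASES, BASES, stringsAsFactors = FALSE)
  paste0(g[[3]], g[[2]], g[[1]])
}

# Hand-built structure model from a coordinate table (chain, resnum,
# aa, x, y, z); confidence defaults to 90.
fake_model <- function(df, source_kind = "experimental",
                       resolution = NA_real_) {
  df$inscode <- ""
  if (is.null(df$confidence)) df$confidence <- 90
  df$sidechain_complete <- TRUE
  structure(df, source_kind = source_kind, resolution = resolution,
            class = c("structure_model", "data.frame"))
}

# Identity mapping for a fake model.
identity_mapping <- function(model) {
  residue_mapping(data.frame(protein_pos = model$resnum,
                             chain = model$chain, resnum = model$resnum))
}

# Hand-built contact_sets object from a named list of member vectors.
fake_contact_sets <- function(members, coords = NULL, radius = 8) {
  sites <- as.integer(names(members))
  if (is.null(coords)) coords <- cbind(sites, 0, 0)
  structure(list(sites = sites, members = members, coords = coords,
                 radius = radius),
            class = "contact_sets")
}

# A small random mutability table (u > 0) for property tests.
random_mutability <- function(L, seed) {
  set.seed(seed)
  structure(
    data.frame(site = seq_len(L), codon = "NNN",
               u_syn = stats::runif(L), u_mis = stats::runif(L),
               u_non = stats::runif(L)),
    class = c("codon_mutability_table", "data.frame"))
}

# Standard toy protein used by several engine tests.
toy_pipeline <- function(L = 50, seed = 7, t_e_true = 100,
                         geometry = "ideal_helix", ...) {
  m <- uniform_mutation_matrix(1e-8)
  spec <- toy_protein_spec(L = L, seed = seed, t_e_true = t_e_true,
                           geometry = geometry, ...)
  fx <- make_toy_protein(spec)
  mod <- parse_structure(fx$paths$structure_pdb)
  map <- read_residue_mapping(fx$paths$mapping_tsv)
  list(matrix = m, spec = spec, fx = fx,
       tx = transcript(fx$cds, matrix = m),
       model = mod, mapping = map,
       cs = build_contact_sets(mod, map, 8))
}
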