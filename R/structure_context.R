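## Structure parsing, residue-level mapping, contact sets, structure
## selection/confidence filters, interface detection and spatial
## clustering of flagged sites.

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M", SEC = "U", PYL = "O"
)

#' Parse a protein structure into a residue table
#'
#' Reads a PDB or mmCIF file (via bio3d), collapses alternate locations
#' to the highest-occupancy conformer, and reduces each residue to one
#' representative coordinate: the C-beta atom, or the C-alpha atom for
#' glycines (and, when `cbeta_fallback = TRUE`, for residues whose
#' C-beta is missing; such residues are flagged). Residues with neither
#' atom are omitted with a warning. For predicted models the per-residue
#' confidence (pLDDT) is read from the B-factor column.
#'
#' @param path path to a `.pdb` or `.cif` file.
#' @param chains chain identifiers to keep; `NULL` keeps all.
#' @param source_kind `"experimental"`, `"homology"`, or `"predicted"`.
#' @param resolution resolution in Angstrom, or `NA` when not applicable.
#' @param cbeta_fallback use C-alpha when a non-glycine residue lacks a
#'   C-beta (default TRUE, with a warning); if FALSE such residues are
#'   dropped.
#' @return object of class `structure_model`: a data.frame with columns
#'   `chain`, `resnum`, `inscode`, `aa` (one-letter), `x`, `y`, `z`,
#'   `confidence`, `sidechain_complete`, plus attributes `source_kind`
#'   and `resolution`.
#' @export
parse_structure <- function(path, chains = NULL,
                            source_kind = c("experimental", "homology",
                                            "predicted"),
                            resolution = NA_real_, cbeta_fallback = TRUE) {
  source_kind <- match.arg(source_kind)
  if (!file.exists(path)) stop("structure file not found: ", path)
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE)) {
    bio3d::read.cif(path)
  } else {
    bio3d::read.pdb(path)
  }
  atoms <- pdb$atom
  atoms <- atoms[atoms$type == "ATOM" | atoms$resid %in% names(AA3TO1), ,
                 drop = FALSE]
  if (!is.null(chains)) {
    if (length(chains) == 0L) stop("empty chain selection")
    atoms <- atoms[atoms$chain %in% chains, , drop = FALSE]
    if (nrow(atoms) == 0L) stop("no atoms left after chain selection")
  }
  if (nrow(atoms) == 0L) stop("no protein atoms in ", path)
  if (is.null(atoms$insert)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  if (is.null(atoms$o)) atoms$o <- 1
  atoms$o[is.na(atoms$o)] <- 1
  key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
  res_keys <- unique(key)
  rows <- lapply(res_keys, function(k) {
    ra <- atoms[key == k, , drop = FALSE]
    # collapse altloc: keep highest occupancy, ties by altloc identifier
    if (!is.null(ra$alt) && any(!is.na(ra$alt) & ra$alt != "")) {
      per_atom <- split(seq_len(nrow(ra)), ra$elety)
      keep <- vapply(per_atom, function(ii) {
        ii[order(-ra$o[ii], ra$alt[ii])][1]
      }, integer(1))
      ra <- ra[sort(keep), , drop = FALSE]
    }
    aa <- AA3TO1[ra$resid[1]]
    rep <- representative_coordinate(ra, unname(aa),
                                     cbeta_fallback = cbeta_fallback)
    if (is.null(rep)) return(NULL)
    data.frame(chain = ra$chain[1], resnum = ra$resno[1],
               inscode = ra$insert[1],
               aa = if (is.na(aa)) "X" else unname(aa),
               x = rep$xyz[1], y = rep$xyz[2], z = rep$xyz[3],
               confidence = ra$b[ra$elety == "CA"][1],
               sidechain_complete = !rep$fallback_used,
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0) {
    warning(dropped, " residue(s) omitted: no C-beta or C-alpha atom")
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (any(!out$sidechain_complete & out$aa != "G")) {
    warning(sum(!out$sidechain_complete & out$aa != "G"),
            " non-glycine residue(s) lack a C-beta; using C-alpha")
  }
  rownames(out) <- NULL
  structure(out, source_kind = source_kind, resolution = resolution,
            class = c("structure_model", "data.frame"))
}

#' Representative coordinate of a residue
#'
#' C-beta when present; C-alpha for glycine; C-alpha as a flagged
#' fallback for non-glycines missing a C-beta (when enabled); otherwise
#' `NULL` (residue unusable).
#'
#' @param res_atoms data.frame of the residue's atom records with at
#'   least columns `elety`, `x`, `y`, `z`.
#' @param aa one-letter amino acid code of the residue.
#' @param cbeta_fallback allow the C-alpha fallback for non-glycines.
#' @return `NULL`, or a list with `xyz` (length-3 numeric) and
#'   `fallback_used` (TRUE when a non-glycine fell back to C-alpha).
#' @export
representative_coordinate <- function(res_atoms, aa, cbeta_fallback = TRUE) {
  get_xyz <- function(name) {
    i <- which(res_atoms$elety == name)
    if (length(i) == 0L) return(NULL)
    as.numeric(res_atoms[i[1], c("x", "y", "z")])
  }
  cb <- get_xyz("CB")
  ca <- get_xyz("CA")
  if (!is.na(aa) && aa == "G") {
    if (!is.null(ca)) return(list(xyz = ca, fallback_used = FALSE))
    return(NULL)
  }
  if (!is.null(cb)) return(list(xyz = cb, fallback_used = FALSE))
  if (cbeta_fallback && !is.null(ca)) {
    return(list(xyz = ca, fallback_used = TRUE))
  }
  NULL
}

#' Read a residue-level sequence/structure mapping
#'
#' Two-column (plus optional insertion code) TSV with columns
#' `protein_pos` and `chain:resnum` (or separate `chain` and `resnum`
#' columns), standing in for a SIFTS-style residue-level cross-reference.
#'
#' @param path TSV path.
#' @return data.frame of class `residue_mapping` with columns
#'   `protein_pos`, `chain`, `resnum`.
#' @export
read_residue_mapping <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("chain" %in% names(d) && "resnum" %in% names(d)) {
    out <- data.frame(protein_pos = as.integer(d$protein_pos),
                      chain = as.character(d$chain),
                      resnum = as.integer(d$resnum),
                      stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(d[[2]], ":", fixed = TRUE)
    out <- data.frame(protein_pos = as.integer(d[[1]]),
                      chain = vapply(parts, `[`, "", 1),
                      resnum = as.integer(vapply(parts, `[`, "", 2)),
                      stringsAsFactors = FALSE)
  }
  residue_mapping(out)
}

#' Construct / validate a residue mapping
#'
#' @param df data.frame with columns `protein_pos`, `chain`, `resnum`.
#' @return the validated data.frame with class `residue_mapping`.
#' @export
residue_mapping <- function(df) {
  stopifnot(all(c("protein_pos", "chain", "resnum") %in% names(df)))
  key <- paste(df$chain, df$resnum)
  if (anyDuplicated(key)) stop("mapping is not injective: duplicated ",
                               "structure residue(s)")
  per_chain <- split(df$protein_pos, df$chain)
  if (any(vapply(per_chain, anyDuplicated, integer(1)) > 0)) {
    stop("mapping is not injective: a protein position maps twice ",
         "within one chain")
  }
  structure(df, class = c("residue_mapping", "data.frame"))
}

#' Build 3D contact sets for every mapped residue
#'
#' The contact set of index site `r` contains `r` itself plus every
#' mapped residue whose representative coordinate lies strictly within
#' `radius` Angstrom of `r`'s. For oligomers, residues from all chains
#' mapping to the same protein are pooled: members are recorded by
#' protein position with multiplicity (a position can appear once per
#' chain), and the index coordinate of a position resolved in several
#' chains is taken from the first chain in file order.
#'
#' @param model a `structure_model`.
#' @param mapping a `residue_mapping`; model residues without a mapping
#'   entry are ignored.
#' @param radius contact threshold in Angstrom (default 8; strict `<`).
#' @return object of class `contact_sets`: list with `sites` (sorted
#'   unique protein positions), `members` (list of integer vectors with
#'   multiplicity, parallel to `sites`), `coords` (index-site coordinate
#'   matrix), and `radius`.
#' @export
build_contact_sets <- function(model, mapping, radius = 8) {
  stopifnot(inherits(model, "structure_model"))
  if (nrow(model) == 0L) {
    return(structure(list(sites = integer(0), members = list(),
                          coords = matrix(numeric(0), ncol = 3),
                          radius = radius),
                     class = "contact_sets"))
  }
  m <- merge(as.data.frame(model), as.data.frame(mapping),
             by = c("chain", "resnum"))
  if (nrow(m) == 0L) stop("mapping covers none of the model's residues")
  # preserve chain file order for index-residue choice
  chain_order <- unique(model$chain)
  m <- m[order(match(m$chain, chain_order), m$protein_pos), , drop = FALSE]
  xyz <- as.matrix(m[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  sites <- sort(unique(m$protein_pos))
  idx_row <- vapply(sites, function(s) which(m$protein_pos == s)[1],
                    integer(1))
  members <- lapply(seq_along(sites), function(i) {
    r <- idx_row[i]
    hit <- which(d[r, ] < radius)           # includes r itself (distance 0)
    sort(m$protein_pos[hit])
  })
  structure(list(sites = sites,
                 members = stats::setNames(members, sites),
                 coords = xyz[idx_row, , drop = FALSE],
                 radius = radius),
            class = "contact_sets")
}

#' @export
print.contact_sets <- function(x, ...) {
  cat("<contact_sets>", length(x$sites), "index sites, radius",
      x$radius, "A\n")
  invisible(x)
}

#' Contact set sizes
#'
#' @param cs a `contact_sets` object.
#' @return named integer vector of |S_r| (members counted with
#'   multiplicity, self included).
#' @export
contact_set_sizes <- function(cs) {
  vapply(cs$members, length, integer(1))
}

#' Fraction of long-range contacts per index site
#'
#' A contact is long-range when the member lies more than
#' `separation_threshold` residues from the index site along the 1D
#' sequence. Sites whose contact set holds only themselves have an
#' undefined fraction (`NA`), not 0.
#'
#' @param cs a `contact_sets` object.
#' @param separation_threshold 1D separation defining long range
#'   (default 15 residues).
#' @return named numeric vector over index sites, values in `[0, 1]` or
#'   `NA`.
#' @export
long_range_contact_fraction <- function(cs, separation_threshold = 15) {
  vapply(seq_along(cs$sites), function(i) {
    r <- cs$sites[i]
    others <- cs$members[[i]][cs$members[[i]] != r]
    if (length(others) == 0L) return(NA_real_)
    mean(abs(others - r) > separation_threshold)
  }, numeric(1)) |> stats::setNames(cs$sites)
}

#' Filter a predicted structure by per-residue confidence
#'
#' Residues with pLDDT <= `min_plddt` are removed (strict `>` is
#' required to keep a residue) before contact sets are built; the whole
#' model is rejected when fewer than `min_fraction` of its residues
#' survive.
#'
#' @param model a `structure_model` with `source_kind = "predicted"` and
#'   confidence values present.
#' @param min_plddt confidence cutoff (default 50, exclusive).
#' @param min_fraction minimum surviving fraction (default 1/3).
#' @return the filtered `structure_model`, or `NULL` when rejected.
#' @export
filter_predicted_model <- function(model, min_plddt = 50,
                                   min_fraction = 1 / 3) {
  stopifnot(inherits(model, "structure_model"))
  if (anyNA(model$confidence)) {
    stop("predicted model has residues with missing confidence values")
  }
  keep <- model$confidence > min_plddt
  if (mean(keep) < min_fraction) return(NULL)
  out <- model[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)$source_kind <- attr(model, "source_kind")
  attributes(out)$resolution <- attr(model, "resolution")
  class(out) <- class(model)
  out
}

#' Select the best structure among candidates
#'
#' Experimental structures are filtered to resolution better than 5
#' Angstrom, coverage of at least one third of the reference sequence
#' and resolved sidechains, then ranked by number of residues resolved
#' and, at ties, by best (lowest) resolution. If none qualifies,
#' homology models with sequence identity >= 25% and coverage >= 1/3 are
#' ranked by coverage. Failing that, a predicted model is accepted if it
#' passes [filter_predicted_model()]. `NULL` is a valid outcome.
#'
#' @param candidates list of candidate lists, each with fields `model`
#'   (a `structure_model`), `coverage` (fraction of the reference
#'   sequence), `resolution` (Angstrom or `NA`), `source_kind`,
#'   `n_resolved` (residue count; defaults to `nrow(model)`),
#'   `sequence_identity` (fraction, homology models only),
#'   `sidechains_resolved` (logical, default TRUE).
#' @param max_resolution,min_coverage,min_identity filter thresholds.
#' @return the chosen candidate (list as supplied), or `NULL`.
#' @export
select_best_structure <- function(candidates, max_resolution = 5,
                                  min_coverage = 1 / 3,
                                  min_identity = 0.25) {
  if (length(candidates) == 0L) return(NULL)
  get <- function(c, f, default = NA) {
    if (!is.null(c[[f]])) c[[f]] else default
  }
  kind <- vapply(candidates, function(c) get(c, "source_kind", ""), "")
  n_res <- vapply(candidates, function(c) {
    n <- get(c, "n_resolved")
    if (is.na(n)) nrow(c$model) else n
  }, numeric(1))
  cover <- vapply(candidates, function(c) get(c, "coverage", 0), numeric(1))
  resol <- vapply(candidates, function(c) get(c, "resolution"), numeric(1))
  sidec <- vapply(candidates, function(c) {
    isTRUE(get(c, "sidechains_resolved", TRUE))
  }, logical(1))

  exp_ok <- which(kind == "experimental" & !is.na(resol) &
                    resol < max_resolution & cover >= min_coverage & sidec)
  if (length(exp_ok)) {
    best <- exp_ok[order(-n_res[exp_ok], resol[exp_ok])][1]
    return(candidates[[best]])
  }
  ident <- vapply(candidates, function(c) get(c, "sequence_identity"),
                  numeric(1))
  hom_ok <- which(kind == "homology" & !is.na(ident) &
                    ident >= min_identity & cover >= min_coverage)
  if (length(hom_ok)) {
    best <- hom_ok[order(-cover[hom_ok])][1]
    return(candidates[[best]])
  }
  pred <- which(kind == "predicted")
  for (i in pred) {
    filtered <- filter_predicted_model(candidates[[i]]$model)
    if (!is.null(filtered)) {
      out <- candidates[[i]]
      out$model <- filtered
      return(out)
    }
  }
  NULL
}

#' Detect oligomeric interface sites
#'
#' A position is an interface site when its contact set in the oligomer
#' is strictly larger than in the monomer (partner-chain contacts add
#' members; intra-chain contacts are unchanged).
#'
#' @param monomer_cs,oligomer_cs `contact_sets` built from the monomeric
#'   and oligomeric structure of the same protein. Both must cover the
#'   same positions.
#' @return sorted integer vector of interface protein positions.
#' @export
detect_interface_sites <- function(monomer_cs, oligomer_cs) {
  if (!setequal(monomer_cs$sites, oligomer_cs$sites)) {
    stop("monomer and oligomer contact sets cover different positions")
  }
  mono <- contact_set_sizes(monomer_cs)
  olig <- contact_set_sizes(oligomer_cs)[names(mono)]
  sort(monomer_cs$sites[olig > mono])
}

#' Spatial clustering of flagged sites vs. random site sets
#'
#' Compares the mean pairwise distance between the representative
#' coordinates of flagged sites with the same statistic over random
#' equally-sized subsets of all resolved sites. A ratio below 1 means
#' the flagged sites are more spatially clustered than expected by
#' chance.
#'
#' @param cs a `contact_sets` object (supplies resolved positions and
#'   their coordinates).
#' @param flagged_sites integer vector of >= 2 structure-resolved
#'   protein positions.
#' @param n_perm number of random subsets (default 1000).
#' @param seed RNG seed (required; no implicit global state).
#' @return list with `ratio` (observed / mean permuted mean pairwise
#'   distance), `p` (fraction of permutations with statistic <= observed,
#'   with add-one smoothing), `observed`, `n_perm`.
#' @export
spatial_clustering_ratio <- function(cs, flagged_sites, n_perm = 1000,
                                     seed) {
  if (missing(seed)) stop("'seed' is required")
  flagged_sites <- unique(flagged_sites)
  if (length(flagged_sites) < 2L) stop("need at least 2 flagged sites")
  if (!all(flagged_sites %in% cs$sites)) {
    stop("flagged site(s) not structure-resolved")
  }
  mean_pairdist <- function(idx) mean(stats::dist(cs$coords[idx, ,
                                                            drop = FALSE]))
  obs <- mean_pairdist(match(flagged_sites, cs$sites))
  k <- length(flagged_sites)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    mean_pairdist(sample(length(cs$sites), k))
  }, numeric(1))
  list(ratio = obs / mean(perm),
       p = (sum(perm <= obs) + 1) / (n_perm + 1),
       observed = obs, n_perm = n_perm)
}

#' Write contact sets as TSV
#'
#' One row per (index site, member) pair with the member's protein
#' position and the distance between representative coordinates.
#'
#' @param cs a `contact_sets` object.
#' @param path output path.
#' @export
write_contact_sets <- function(cs, path) {
  rows <- lapply(seq_along(cs$sites), function(i) {
    data.frame(index_pos = cs$sites[i], member_pos = cs$members[[i]])
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
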