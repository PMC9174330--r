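test_that("toy PDB files parse into one representative coordinate per residue", {
  tp <- toy_pipeline(L = 20, seed = 4)
  mod <- tp$model
  expect_s3_class(mod, "structure_model")
  expect_equal(nrow(mod), 20)
  expect_equal(mod$resnum, 1:20)
  # glycines use C-alpha (radius 2.3), others C-beta (radius 3.8);
  # PDB coordinates carry 3 decimals
  rad <- sqrt(mod$x^2 + mod$y^2)
  expect_lt(max(abs(rad[mod$aa == "G"] - 2.3)), 1e-3)
  expect_lt(max(abs(rad[mod$aa != "G"] - 3.8)), 1e-3)
  expect_equal(unique(mod$confidence), 90)
})

test_that("representative coordinates follow the C-beta / glycine rule", {
  atoms <- data.frame(elety = c("CA", "CB"), x = c(0, 1), y = c(0, 2),
                      z = c(0, 3))
  expect_equal(representative_coordinate(atoms, "A")$xyz, c(1, 2, 3))
  gly <- data.frame(elety = "CA", x = 0, y = 0, z = 0)
  expect_equal(representative_coordinate(gly, "G")$xyz, c(0, 0, 0))
  # non-glycine missing C-beta: flagged fallback or NULL
  r <- representative_coordinate(gly, "L", cbeta_fallback = TRUE)
  expect_true(r$fallback_used)
  expect_null(representative_coordinate(gly, "L", cbeta_fallback = FALSE))
  expect_null(representative_coordinate(
    data.frame(elety = "N", x = 0, y = 0, z = 0), "L"))
})

test_that("parse_structure drops residues with no usable atom and warns", {
  pdb <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00 90.00           C",
    "ATOM      2  CB  ALA A   1       1.000   0.000   0.000  1.00 90.00           C",
    "ATOM      3  CA  GLY A   2       3.000   0.000   0.000  1.00 80.00           C",
    "ATOM      4  N   LEU A   3       6.000   0.000   0.000  1.00 70.00           N",
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, path)
  expect_warning(mod <- parse_structure(path), "omitted")
  expect_equal(nrow(mod), 2)
  expect_equal(mod$x, c(1, 3))  # ALA C-beta, GLY C-alpha
  expect_error(parse_structure(path, chains = character(0)), "empty chain")
})

test_that("contact sets use strict Euclidean distance with self-inclusion", {
  mod <- fake_model(data.frame(
    chain = "A", resnum = 1:3, aa = "A", x = c(0, 5, 10), y = 0, z = 0))
  cs <- build_contact_sets(mod, identity_mapping(mod), radius = 8)
  expect_equal(cs$members, list(`1` = c(1L, 2L), `2` = 1:3, `3` = 2:3),
               ignore_attr = TRUE)
  # exactly 8.000 A apart is NOT a contact
  mod2 <- fake_model(data.frame(
    chain = "A", resnum = 1:2, aa = "A", x = c(0, 8), y = 0, z = 0))
  cs2 <- build_contact_sets(mod2, identity_mapping(mod2), radius = 8)
  expect_equal(cs2$members[["1"]], 1L)
  expect_equal(contact_set_sizes(cs2), c(`1` = 1L, `2` = 1L))
})

test_that("contact relation is symmetric, self-inclusive and radius-monotone", {
  set.seed(88)
  n <- 40
  mod <- fake_model(data.frame(
    chain = "A", resnum = 1:n, aa = "A",
    x = runif(n, 0, 25), y = runif(n, 0, 25), z = runif(n, 0, 25)))
  map <- identity_mapping(mod)
  cs6 <- build_contact_sets(mod, map, 6)
  cs8 <- build_contact_sets(mod, map, 8)
  cs10 <- build_contact_sets(mod, map, 10)
  for (i in seq_len(n)) {
    expect_true(i %in% cs8$members[[i]])
    expect_true(all(cs6$members[[i]] %in% cs8$members[[i]]))
    expect_true(all(cs8$members[[i]] %in% cs10$members[[i]]))
    for (j in cs8$members[[i]]) {
      expect_true(i %in% cs8$members[[j]])
    }
  }
  # brute-force all-pairs oracle
  xyz <- as.matrix(mod[, c("x", "y", "z")])
  for (i in seq_len(n)) {
    want <- sort(which(vapply(seq_len(n), function(j) {
      sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < 8
    }, logical(1))))
    expect_equal(cs8$members[[i]], want)
  }
})

test_that("long-range contact fractions handle self-only sets as undefined", {
  cs <- fake_contact_sets(list(`20` = c(20L, 21L, 18L, 60L),
                               `50` = c(50L, 49L, 51L),
                               `70` = 70L,
                               `5` = c(5L, 30L, 80L)))
  lr <- long_range_contact_fraction(cs, 15)
  expect_equal(unname(lr), c(1 / 3, 0, NA, 1))
})

test_that("structure selection ranks by residues resolved then resolution", {
  cand <- function(kind, n, res = NA, cov = 0.8, ident = NA, side = TRUE) {
    list(model = fake_model(data.frame(
      chain = "A", resnum = seq_len(2), aa = "A", x = 0, y = 0, z = 0)),
      source_kind = kind, n_resolved = n, resolution = res,
      coverage = cov, sequence_identity = ident,
      sidechains_resolved = side)
  }
  a <- cand("experimental", 200, 2.0)
  b <- cand("experimental", 180, 1.0)
  expect_identical(select_best_structure(list(a, b))$n_resolved, 200)
  # tie on residues resolved -> best resolution wins
  c1 <- cand("experimental", 200, 1.5)
  expect_identical(select_best_structure(list(a, c1))$resolution, 1.5)
  # filters: resolution must beat 5 A, coverage >= 1/3, sidechains present
  expect_null(select_best_structure(list(cand("experimental", 300, 6.0))))
  expect_null(select_best_structure(list(
    cand("experimental", 300, 2.0, cov = 0.2))))
  expect_null(select_best_structure(list(
    cand("experimental", 300, 2.0, side = FALSE))))
  # homology fallback needs identity >= 25%, ranked by coverage
  h1 <- cand("homology", 100, cov = 0.5, ident = 0.30)
  h2 <- cand("homology", 100, cov = 0.7, ident = 0.28)
  h3 <- cand("homology", 100, cov = 0.9, ident = 0.20)
  pick <- select_best_structure(list(cand("experimental", 300, 6.0), h1, h2, h3))
  expect_identical(pick$coverage, 0.7)
})

test_that("predicted models are filtered by strict pLDDT > 50 and 1/3 rule", {
  mk <- function(conf) {
    fake_model(data.frame(chain = "A", resnum = seq_along(conf), aa = "A",
                          x = seq_along(conf), y = 0, z = 0,
                          confidence = conf), source_kind = "predicted")
  }
  kept <- filter_predicted_model(mk(c(rep(90, 60), rep(40, 40))))
  expect_equal(nrow(kept), 60)
  expect_null(filter_predicted_model(mk(c(rep(90, 20), rep(40, 80)))))
  # boundary exactly 50 is removed
  kept <- filter_predicted_model(mk(c(rep(50, 50), rep(51, 50))))
  expect_equal(nrow(kept), 50)
  expect_true(all(kept$confidence > 50))
  # predicted model accepted through selection when >= 1/3 passes
  p <- list(model = mk(c(rep(90, 40), rep(30, 60))),
            source_kind = "predicted", coverage = 1, n_resolved = 100)
  pick <- select_best_structure(list(p))
  expect_equal(nrow(pick$model), 40)
})

test_that("interface sites have strictly larger oligomer contact sets", {
  mono <- fake_contact_sets(list(`1` = c(1L, 2L), `2` = c(1L, 2L)))
  olig <- fake_contact_sets(list(`1` = c(1L, 2L, 2L), `2` = c(1L, 2L)))
  expect_equal(detect_interface_sites(mono, olig), 1L)
  bad <- fake_contact_sets(list(`1` = 1L))
  expect_error(detect_interface_sites(mono, bad), "different positions")
})

test_that("a helix dimer yields facing interface residues with extra contacts", {
  tp <- toy_pipeline(L = 30, seed = 3, geometry = "two_chain_dimer")
  olig <- tp$cs
  modA <- tp$model[tp$model$chain == "A", ]
  attributes(modA)$source_kind <- "experimental"
  class(modA) <- class(tp$model)
  mapA <- tp$mapping[tp$mapping$chain == "A", ]
  mono <- build_contact_sets(modA, mapA, 8)
  iface <- detect_interface_sites(mono, olig)
  expect_gt(length(iface), 3)
  expect_lt(length(iface), 30)
  # oligomer dominance for every site, strict only at the interface
  expect_true(all(contact_set_sizes(olig) >= contact_set_sizes(mono)))
  # interface residues are the ones whose C-beta points toward chain B
  xA <- modA$x[match(iface, modA$resnum)]
  expect_true(all(xA > 0))
  expect_false(any(modA$resnum[modA$x < -3] %in% iface))
})

test_that("spatial clustering ratio detects clustered flagged sites", {
  tp <- toy_pipeline(L = 60, seed = 21)
  # flagged sites at one helix end are mutually close
  r <- spatial_clustering_ratio(tp$cs, flagged_sites = 1:8,
                                n_perm = 1000, seed = 5)
  expect_lt(r$ratio, 1)
  expect_lt(r$p, 0.05)
  # full set: every permutation is the whole set, ratio exactly 1
  r_full <- spatial_clustering_ratio(tp$cs, flagged_sites = tp$cs$sites,
                                     n_perm = 10, seed = 5)
  expect_identical(r_full$ratio, 1)
  # determinism
  r2 <- spatial_clustering_ratio(tp$cs, flagged_sites = 1:8,
                                 n_perm = 1000, seed = 5)
  expect_identical(r, r2)
  expect_error(spatial_clustering_ratio(tp$cs, 3L, 10, seed = 1),
               "at least 2")
})

test_that("residue mappings must be injective per chain", {
  expect_error(residue_mapping(data.frame(
    protein_pos = c(1, 2), chain = "A", resnum = c(5, 5))), "injective")
  expect_error(residue_mapping(data.frame(
    protein_pos = c(3, 3), chain = "A", resnum = c(5, 6))), "injective")
  # the same protein position in two chains is fine (oligomer)
  ok <- residue_mapping(data.frame(
    protein_pos = c(1, 1), chain = c("A", "B"), resnum = c(1, 1)))
  expect_s3_class(ok, "residue_mapping")
})
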