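test_that("normalized site probabilities sum to one and ignore scale", {
  tab <- random_mutability(10, seed = 1)
  tab$u_mis <- rep(1, 10)
  expect_equal(normalized_site_probabilities(tab, "missense"), rep(0.1, 10))
  tab$u_mis <- c(1, 3, rep(0, 8))
  p <- normalized_site_probabilities(tab, "missense")
  expect_equal(p[1:2], c(0.25, 0.75))
  tab2 <- tab
  tab2$u_mis <- tab$u_mis * 1e7
  expect_equal(normalized_site_probabilities(tab2, "missense"), p)
  tab$u_mis <- rep(0, 10)
  expect_error(normalized_site_probabilities(tab, "missense"),
               "unscorable")
})

test_that("COSMIS Z and empirical p follow their defining formulas", {
  expect_equal(cosmis_score(10, 20, 4), -2.5)
  expect_equal(cosmis_score(24, 20, 4), 1.0)
  expect_equal(cosmis_score(20, 20, 4), 0)
  expect_true(is.na(cosmis_score(5, 5, 0)))
  expect_equal(empirical_p_value(0, 10000), 1 / 10001)
  expect_equal(empirical_p_value(10000, 10000), 1)
  expect_lt(empirical_p_value(99, 10000), 0.01)
  expect_gte(empirical_p_value(100, 10000), 0.01)
  expect_error(empirical_p_value(11, 10), "K")
})

test_that("a contact set spanning all sites has a degenerate null", {
  L <- 20
  cs <- fake_contact_sets(list(`1` = seq_len(L)))
  sims <- simulate_contact_set_counts(rep(1 / L, L), t_e = 37.4, cs,
                                      N = 500, seed = 3)
  expect_true(all(sims == 37))  # round(t_e) trials, total is fixed
  ns <- null_summary(sims, m_o = 30)
  expect_equal(ns$m_e, 37)
  expect_equal(ns$m_sigma, 0)
  expect_true(is.na(cosmis_score(ns$m_o, ns$m_e, ns$m_sigma)))
})

test_that("simulated contact-set counts match binomial marginals", {
  L <- 100
  cs <- fake_contact_sets(list(`1` = 1:10))
  sims <- simulate_contact_set_counts(rep(1 / L, L), t_e = 200, cs,
                                      N = 10000, seed = 11)
  m_e <- mean(sims)
  m_sig <- sd(as.vector(sims))
  expect_equal(m_e, 200 * 0.1, tolerance = 3 * m_sig / sqrt(10000) / 20)
  expect_equal(m_sig, sqrt(200 * 0.1 * 0.9), tolerance = 0.05)
  # determinism: same seed, bit-identical
  sims2 <- simulate_contact_set_counts(rep(1 / L, L), t_e = 200, cs,
                                       N = 10000, seed = 11)
  expect_identical(sims, sims2)
})

test_that("oligomer multiplicity doubles a duplicated member's contribution", {
  L <- 10
  p <- rep(1 / L, L)
  cs_dup <- fake_contact_sets(list(`1` = c(1L, 2L, 2L)))
  cs_plain <- fake_contact_sets(list(`1` = c(1L, 2L)))
  s1 <- simulate_contact_set_counts(p, 50, cs_dup, N = 2000, seed = 4)
  s2 <- simulate_contact_set_counts(p, 50, cs_plain, N = 2000, seed = 4)
  # same seed, same site draws: difference is exactly one extra copy of
  # site 2's count, which averages t_e / L
  expect_gt(mean(s1), mean(s2))
  expect_equal(mean(s1 - s2), 5, tolerance = 0.3)
})

test_that("score_protein produces a complete, reproducible site table", {
  tp <- toy_pipeline(L = 40, seed = 13, t_e_true = 80)
  v <- simulate_observed_variants(tp$spec, tp$matrix)
  cnt <- tally_variants(tp$tx, v)
  sc <- score_protein(tp$tx, cnt, tp$cs, t_e = 80, N = 2000, seed = 21)
  expect_equal(nrow(sc), 40)
  expect_equal(sc$pos, 1:40)
  expect_true(all(sc$status == "ok"))
  expect_equal(sc$cosmis, (sc$m_o - sc$m_e) / sc$m_sigma)
  expect_true(all(sc$p_value > 0 & sc$p_value <= 1))
  expect_equal(sc$high_confidence, sc$p_value < 0.01)
  sc2 <- score_protein(tp$tx, cnt, tp$cs, t_e = 80, N = 2000, seed = 21)
  expect_identical(sc, sc2)
  # unresolved sites get a status, not silence
  cs_part <- tp$cs
  keep <- 1:30
  cs_part$sites <- cs_part$sites[keep]
  cs_part$members <- cs_part$members[keep]
  cs_part$coords <- cs_part$coords[keep, ]
  sc3 <- score_protein(tp$tx, cnt, cs_part, t_e = 80, N = 500, seed = 1)
  expect_equal(sc3$status[31:40], rep("unresolved", 10))
  expect_true(all(is.na(sc3$cosmis[31:40])))
})

test_that("p is non-decreasing and Z strictly increasing in the observed count", {
  L <- 30
  cs <- fake_contact_sets(list(`1` = 1:6))
  sims <- simulate_contact_set_counts(rep(1 / L, L), 60, cs, N = 5000,
                                      seed = 8)
  m_range <- 0:30
  res <- t(vapply(m_range, function(mo) {
    ns <- null_summary(sims, mo)
    c(p = empirical_p_value(ns$K, ns$N),
      z = cosmis_score(ns$m_o, ns$m_e, ns$m_sigma))
  }, c(p = 0, z = 0)))
  expect_true(all(diff(res[, "p"]) >= 0))
  expect_true(all(diff(res[, "z"]) > 0))
})

test_that("score_protein rejects an unscorable expected count", {
  tp <- toy_pipeline(L = 10, seed = 2)
  cnt <- tally_variants(tp$tx, NULL)
  expect_error(score_protein(tp$tx, cnt, tp$cs, t_e = 0, N = 10, seed = 1),
               "unscorable")
  neg <- structure(list(slope = 1, intercept = -10, R = 0.9, n_points = 5),
                   class = "regression_model")
  expect_error(score_protein(tp$tx, cnt, tp$cs, model = neg, N = 10,
                             seed = 1), "unscorable")
})

test_that("synonymous control uses the same machinery on the synonymous class", {
  tp <- toy_pipeline(L = 60, seed = 19, t_e_true = 150)
  v <- simulate_observed_variants(tp$spec, tp$matrix)
  cnt <- tally_variants(tp$tx, v)
  t_syn <- 150 * attr(tp$tx$mutability, "mu_syn") /
    attr(tp$tx$mutability, "mu_mis")
  ctl <- synonymous_control_scores(tp$tx, cnt, tp$cs, t_e = t_syn,
                                   N = 2000, seed = 33)
  expect_equal(attr(ctl, "score_class"), "synonymous")
  # observed synonymous counts feed m_o
  expect_equal(ctl$m_o,
               observed_contact_set_counts(cnt, tp$cs, "synonymous"),
               ignore_attr = TRUE)
  ctl2 <- synonymous_control_scores(tp$tx, cnt, tp$cs, t_e = t_syn,
                                    N = 2000, seed = 33)
  expect_identical(ctl, ctl2)
})

test_that("depleted missense variants shift COSMIS but not the control", {
  f <- rep(1, 80)
  f[30:50] <- 0.1
  tp <- toy_pipeline(L = 80, seed = 23, t_e_true = 240,
                     constraint_profile = f)
  v <- simulate_observed_variants(tp$spec, tp$matrix)
  cnt <- tally_variants(tp$tx, v)
  sc <- score_protein(tp$tx, cnt, tp$cs, t_e = 240, N = 4000, seed = 2)
  t_syn <- 240 * attr(tp$tx$mutability, "mu_syn") /
    attr(tp$tx$mutability, "mu_mis")
  ctl <- synonymous_control_scores(tp$tx, cnt, tp$cs, t_e = t_syn,
                                   N = 4000, seed = 2)
  core <- 35:45  # interior of the depleted region
  flank <- c(1:25, 55:80)
  expect_lt(median(sc$cosmis[core]), median(sc$cosmis[flank]) - 1)
  # synonymous control unaffected by missense depletion
  expect_lt(abs(median(ctl$cosmis[core]) - median(ctl$cosmis[flank])), 1)
})

test_that("score tables round-trip through the TSV writer", {
  tp <- toy_pipeline(L = 15, seed = 6, t_e_true = 30)
  cnt <- tally_variants(tp$tx, simulate_observed_variants(tp$spec,
                                                          tp$matrix))
  sc <- score_protein(tp$tx, cnt, tp$cs, t_e = 30, N = 200, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_scores_tsv(sc, path)
  header <- readLines(path, n = 1)
  expect_match(header, "seed=9")
  back <- read_scores_tsv(path)
  expect_equal(back$cosmis, sc$cosmis, tolerance = 1e-6)
  expect_equal(back$pos, sc$pos)
})
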