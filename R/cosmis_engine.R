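## The scoring core: normalized per-site mutability, multinomial
## permutation null over contact sets, COSMIS Z score, empirical p value,
## and the synonymous control score.

#' Normalized per-site mutability
#'
#' Divides each codon's mutability of the requested consequence class by
#' the transcript total, yielding the multinomial cell probabilities used
#' by the permutation null.
#'
#' @param mutability a `codon_mutability_table`.
#' @param class `"missense"` or `"synonymous"`.
#' @return numeric probability vector over sites 1..L summing to 1
#'   (within 1e-12).
#' @export
normalized_site_probabilities <- function(mutability,
                                          class = c("missense",
                                                    "synonymous")) {
  class <- match.arg(class)
  u <- switch(class, missense = mutability$u_mis,
              synonymous = mutability$u_syn)
  tot <- sum(u)
  if (tot <= 0) stop("total ", class, " mutability is zero; ",
                     "protein is unscorable")
  u / tot
}

#' Simulate null contact-set counts by multinomial permutation
#'
#' Each permutation distributes `round(t_e)` variants over the L sites
#' of the transcript according to the probability vector `p`, then sums
#' the per-site counts over each contact set's members (with
#' multiplicity for oligomeric duplicates).
#'
#' @param p probability vector over sites 1..L (sums to 1).
#' @param t_e expected total variant count (real; the number of trials
#'   is `round(t_e)` unless `trials = "poisson"`).
#' @param contact_sets a `contact_sets` object.
#' @param N number of permutations (default 10000).
#' @param seed RNG seed (required).
#' @param trials `"round"` (deterministic trial count, default) or
#'   `"poisson"` (trial count drawn as Poisson(t_e) per permutation).
#' @return integer matrix with one row per contact set (rownames = index
#'   sites) and one column per permutation.
#' @export
simulate_contact_set_counts <- function(p, t_e, contact_sets, N = 10000,
                                        seed, trials = c("round",
                                                         "poisson")) {
  trials <- match.arg(trials)
  if (missing(seed)) stop("'seed' is required")
  if (N < 1) stop("'N' must be >= 1")
  if (t_e < 0) stop("'t_e' must be >= 0")
  if (abs(sum(p) - 1) > 1e-9) stop("'p' must sum to 1")
  L <- length(p)
  bad <- contact_sets$members[
    !vapply(contact_sets$members, function(m) all(m >= 1 & m <= L),
            logical(1))]
  if (length(bad)) stop("contact set member position outside 1..L")
  set.seed(seed)
  site_counts <- if (trials == "round") {
    stats::rmultinom(N, size = round(t_e), prob = p)  # L x N
  } else {
    sizes <- stats::rpois(N, t_e)
    vapply(sizes, function(s) stats::rmultinom(1, s, p)[, 1],
           integer(L))
  }
  # indicator with multiplicity: S x L
  S <- length(contact_sets$sites)
  ind <- matrix(0, nrow = S, ncol = L)
  for (i in seq_len(S)) {
    tab <- tabulate(contact_sets$members[[i]], nbins = L)
    ind[i, ] <- tab
  }
  sims <- ind %*% site_counts
  rownames(sims) <- contact_sets$sites
  sims
}

#' Summarize a simulated null against observed counts
#'
#' @param sims matrix from [simulate_contact_set_counts()] (contact sets
#'   in rows, permutations in columns).
#' @param m_o observed unique variant count per contact set (same order
#'   as the rows of `sims`).
#' @return data.frame with columns `site`, `m_o`, `m_e` (null mean),
#'   `m_sigma` (population standard deviation), `K` (number of
#'   permutations with simulated count <= `m_o`), `N`.
#' @export
null_summary <- function(sims, m_o) {
  if (length(m_o) != nrow(sims)) stop("'m_o' length != number of sets")
  N <- ncol(sims)
  m_e <- rowMeans(sims)
  m_sigma <- sqrt(rowMeans(sims^2) - m_e^2)  # population SD
  K <- rowSums(sims <= m_o)
  data.frame(site = as.integer(rownames(sims)), m_o = m_o, m_e = m_e,
             m_sigma = m_sigma, K = K, N = N)
}

#' COSMIS Z score
#'
#' `(m_o - m_e) / m_sigma`; negative values indicate depletion of
#' missense variants in the contact set (constraint). Undefined (`NA`)
#' when the null has zero spread.
#'
#' @param m_o,m_e,m_sigma observed count, null mean, null standard
#'   deviation (vectorized).
#' @return numeric Z score(s), `NA` where `m_sigma` is 0.
#' @export
cosmis_score <- function(m_o, m_e, m_sigma) {
  ifelse(m_sigma > 0, (m_o - m_e) / m_sigma, NA_real_)
}

#' Empirical permutation p value
#'
#' `(K + 1) / (N + 1)`, where `K` of the `N` permutations produced a
#' simulated contact-set count less than or equal to the observed count.
#' One-sided for depletion; always in `(0, 1]`.
#'
#' @param K,N integers with `0 <= K <= N`, `N >= 1`.
#' @return exact rational value(s).
#' @export
empirical_p_value <- function(K, N) {
  if (any(K < 0) || any(K > N)) stop("'K' must satisfy 0 <= K <= N")
  if (any(N < 1)) stop("'N' must be >= 1")
  (K + 1) / (N + 1)
}

#' Observed contact-set counts from per-site tallies
#'
#' @param counts a `site_variant_counts` table.
#' @param contact_sets a `contact_sets` object.
#' @param class `"missense"` or `"synonymous"`.
#' @return numeric vector of m_o per contact set (members summed with
#'   multiplicity).
#' @export
observed_contact_set_counts <- function(counts, contact_sets,
                                        class = c("missense",
                                                  "synonymous")) {
  class <- match.arg(class)
  n <- switch(class, missense = counts$n_mis, synonymous = counts$n_syn)
  per_site <- stats::setNames(n, counts$site)
  vapply(contact_sets$members, function(m) {
    sum(per_site[as.character(m)])
  }, numeric(1))
}

#' Score every structure-resolved site of a protein
#'
#' Full per-protein run: normalized site probabilities from the
#' transcript's mutability, expected total count `t_e` from the
#' regression model, `N` multinomial permutations over the contact sets,
#' and per-site Z score plus empirical p value. Unresolved sites and
#' degenerate cases appear in the output with status codes rather than
#' being dropped.
#'
#' @param tx a `transcript` with attached mutability.
#' @param counts per-site unique variant tallies from [tally_variants()].
#' @param contact_sets a `contact_sets` object in the transcript's
#'   protein coordinates.
#' @param model a `regression_model` fitted on synonymous data.
#' @param N number of permutations (default 10000).
#' @param seed RNG seed (required).
#' @param class `"missense"` for the COSMIS score, `"synonymous"` for
#'   the control score.
#' @param t_e override the regression-predicted expected count (mainly
#'   for simulation studies); `NULL` to use the model.
#' @param trials trial-count policy, see [simulate_contact_set_counts()].
#' @return data.frame of class `site_scores`: one row per site 1..L with
#'   columns `protein_id`, `transcript_id`, `pos`, `aa`, `cs_size`,
#'   `m_o`, `m_e`, `m_sigma`, `cosmis`, `p_value`, `high_confidence`
#'   (p < 0.01), `status` (`"ok"`, `"unresolved"`, `"zero_sigma"`).
#'   Attributes record `seed`, `N`, `radius`, `t_e`, `class`.
#' @export
score_protein <- function(tx, counts, contact_sets, model = NULL,
                          N = 10000, seed, class = c("missense",
                                                     "synonymous"),
                          t_e = NULL, trials = "round") {
  class <- match.arg(class)
  if (missing(seed)) stop("'seed' is required")
  stopifnot(inherits(tx, "transcript"))
  if (is.null(t_e)) {
    if (is.null(model)) stop("supply either 'model' or 't_e'")
    t_e <- expected_missense_count(tx, model, class = class)
    if (!isTRUE(attr(t_e, "scorable")) || t_e == 0) {
      stop("expected count t_e is 0; protein is unscorable")
    }
  }
  if (t_e <= 0) stop("expected count t_e is 0; protein is unscorable")
  p <- normalized_site_probabilities(tx$mutability, class = class)
  m_o <- observed_contact_set_counts(counts, contact_sets, class = class)
  sims <- simulate_contact_set_counts(p, t_e, contact_sets, N = N,
                                      seed = seed, trials = trials)
  ns <- null_summary(sims, m_o)

  out <- data.frame(
    protein_id = tx$protein_id, transcript_id = tx$transcript_id,
    pos = seq_len(tx$L),
    aa = strsplit(tx$protein_seq, "")[[1]],
    cs_size = NA_integer_, m_o = NA_real_, m_e = NA_real_,
    m_sigma = NA_real_, cosmis = NA_real_, p_value = NA_real_,
    high_confidence = FALSE, status = "unresolved",
    stringsAsFactors = FALSE
  )
  i <- ns$site
  out$cs_size[i] <- contact_set_sizes(contact_sets)
  out$m_o[i] <- ns$m_o
  out$m_e[i] <- ns$m_e
  out$m_sigma[i] <- ns$m_sigma
  out$cosmis[i] <- cosmis_score(ns$m_o, ns$m_e, ns$m_sigma)
  out$p_value[i] <- empirical_p_value(ns$K, ns$N)
  out$status[i] <- ifelse(ns$m_sigma > 0, "ok", "zero_sigma")
  out$high_confidence <- !is.na(out$p_value) & out$p_value < 0.01 &
    out$status == "ok"
  structure(out, seed = seed, N = N, radius = contact_sets$radius,
            t_e = as.numeric(t_e), class = c("site_scores", "data.frame"),
            score_class = class)
}

#' Synonymous control scores
#'
#' Runs the identical scoring machinery with the consequence class
#' switched to synonymous (synonymous mutability, synonymous tallies,
#' `t_e` predicted from the same regression applied to the synonymous
#' mutability). Because synonymous variation is under minimal selection,
#' the resulting score distribution is expected to center at 0.
#'
#' @inheritParams score_protein
#' @return a `site_scores` data.frame (see [score_protein()]).
#' @export
synonymous_control_scores <- function(tx, counts, contact_sets,
                                      model = NULL, N = 10000, seed,
                                      t_e = NULL, trials = "round") {
  score_protein(tx, counts, contact_sets, model = model, N = N,
                seed = seed, class = "synonymous", t_e = t_e,
                trials = trials)
}

#' Write a per-site score table as TSV
#'
#' Header comment lines record the seed, permutation count and contact
#' radius so a run can be reproduced.
#'
#' @param scores a `site_scores` data.frame.
#' @param path output path.
#' @export
write_scores_tsv <- function(scores, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%s N=%s radius=%s t_e=%.6g",
                     attr(scores, "seed"), attr(scores, "N"),
                     attr(scores, "radius"), attr(scores, "t_e")), con)
  utils::write.table(scores, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a per-site score table written by [write_scores_tsv()]
#'
#' @param path TSV path.
#' @return data.frame of per-site scores.
#' @export
read_scores_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
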