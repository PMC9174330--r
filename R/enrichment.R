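## Odds-ratio enrichment of labeled variants across score percentile bins.

#' Odds ratio with 95% confidence interval for a 2x2 table
#'
#' `OR = (a/b) / (c/d)` with log-scale standard error
#' `sqrt(1/a + 1/b + 1/c + 1/d)` and 95% bounds
#' `exp(ln OR -/+ 1.96 * s.e.)`.
#'
#' @param a positives in the bin.
#' @param b positives not in the bin.
#' @param c negatives in the bin.
#' @param d negatives not in the bin.
#' @param haldane apply the Haldane-Anscombe +0.5 correction to every
#'   cell (default FALSE; zero cells are an error without it).
#' @return data.frame with columns `a`, `b`, `c`, `d`, `OR`,
#'   `se_log_or`, `ci_low`, `ci_high`.
#' @examples
#' odds_ratio_ci(20, 80, 10, 90)
#' @export
odds_ratio_ci <- function(a, b, c, d, haldane = FALSE) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop("contingency cells must be non-negative")
  if (haldane) {
    cells <- cells + 0.5
  } else if (any(cells == 0)) {
    stop("zero cell(s): ",
         paste(names(cells)[cells == 0], collapse = ", "),
         " (set haldane = TRUE for the +0.5 correction)")
  }
  or <- (cells["a"] / cells["b"]) / (cells["c"] / cells["d"])
  se <- sqrt(sum(1 / cells))
  data.frame(a = a, b = b, c = c, d = d,
             OR = unname(or), se_log_or = unname(se),
             ci_low = unname(exp(log(or) - 1.96 * se)),
             ci_high = unname(exp(log(or) + 1.96 * se)))
}

#' Enrichment of positive-label scores across percentile bins
#'
#' Bins the score scale at percentiles of a reference score distribution
#' (by default all scored sites would be supplied; falling back to the
#' pooled labeled scores when no reference is given), assembles a 2x2
#' table per bin (in-bin vs. out-of-bin, positive vs. negative label)
#' and applies [odds_ratio_ci()]. Bin 1 covers the lowest (most
#' constrained) scores.
#'
#' @param scores_pos scores of positive-label variants (e.g. pathogenic).
#' @param scores_neg scores of negative-label variants (e.g. benign).
#' @param reference score set defining the percentile edges; `NULL` uses
#'   the pooled labeled scores.
#' @param n_bins number of equal-percentile bins (default 10).
#' @param mode `"disjoint"` decile-style bins, or `"cumulative"` tails
#'   (bin k = scores below the k-th percentile edge).
#' @param haldane passed to [odds_ratio_ci()].
#' @return data.frame with one row per bin: `bin`, `lower`, `upper`
#'   (score-scale edges), `a`, `b`, `c`, `d`, `OR`, `se_log_or`,
#'   `ci_low`, `ci_high`.
#' @export
percentile_bin_enrichment <- function(scores_pos, scores_neg,
                                      reference = NULL, n_bins = 10,
                                      mode = c("disjoint", "cumulative"),
                                      haldane = FALSE) {
  mode <- match.arg(mode)
  if (length(scores_pos) == 0L || length(scores_neg) == 0L) {
    stop("both score vectors must be non-empty")
  }
  if (is.null(reference)) reference <- c(scores_pos, scores_neg)
  edges <- stats::quantile(reference, probs = seq(0, 1, length.out =
                                                    n_bins + 1),
                           names = FALSE)
  if (any(diff(edges) <= 0)) {
    stop("bin edges are not strictly increasing; too few distinct ",
         "reference scores for ", n_bins, " bins")
  }
  # left-closed bins, top edge closed; out-of-range scores clamp to the
  # extreme bins
  assign_bin <- function(x) {
    pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L), n_bins)
  }
  bp <- assign_bin(scores_pos)
  bn <- assign_bin(scores_neg)
  rows <- lapply(seq_len(n_bins), function(k) {
    inb_p <- if (mode == "disjoint") bp == k else bp <= k
    inb_n <- if (mode == "disjoint") bn == k else bn <= k
    tab <- tryCatch(
      odds_ratio_ci(sum(inb_p), sum(!inb_p), sum(inb_n), sum(!inb_n),
                    haldane = haldane),
      error = function(e) stop("bin ", k, ": ", conditionMessage(e),
                               call. = FALSE)
    )
    cbind(data.frame(bin = k, lower = edges[k], upper = edges[k + 1]), tab)
  })
  do.call(rbind, rows)
}
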