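#' Assign subjects to performance deciles
#'
#' Sorts subjects by deviation z-score descending (bin 1 = best performance,
#' bin 10 = poorest) and splits them into 10 contiguous equal-frequency bins.
#' When `n` is not a multiple of 10, the first `n mod 10` bins receive one
#' extra subject. Ties keep their input order (stable sort).
#'
#' @param z numeric deviation scores, length >= 10.
#' @return object of class `decile_assignment`: list with `bin` (per-subject
#'   integer 1..10), `boundaries` (the 9 z values separating consecutive
#'   bins: the smallest z in bins 1..9) and `sizes`.
#' @export
assign_deciles <- function(z) {
  n <- length(z)
  if (n < 10) stop("assign_deciles: need at least 10 subjects")
  ord <- order(-z)                       # stable; best performance first
  base <- n %/% 10L
  r <- n %% 10L
  sizes <- base + as.integer(seq_len(10) <= r)
  bin_sorted <- rep(seq_len(10), times = sizes)
  bin <- integer(n)
  bin[ord] <- bin_sorted
  edges <- cumsum(sizes)[1:9]
  boundaries <- z[ord][edges]            # smallest z in each of bins 1..9
  structure(list(bin = bin, boundaries = boundaries, sizes = sizes),
            class = "decile_assignment")
}

#' Per-decile clinical risk proportions at multiple thresholds
#'
#' A subject is "exposed" at threshold `t` when its domain score exceeds
#' `mean + t * SD`, with mean and SD taken over the whole cohort (a single
#' cutoff per threshold). Returns per-bin exposed counts and proportions at
#' every threshold.
#'
#' @param assignment a `decile_assignment`.
#' @param domain_scores numeric vector aligned with the assignment.
#' @param thresholds_sd SD multiples defining the clinical cutoffs
#'   (default `c(1, 1.5, 2, 3)`).
#' @return data.frame with columns `bin`, `threshold`, `n`, `n_above`,
#'   `proportion`.
#' @export
risk_proportions <- function(assignment, domain_scores,
                             thresholds_sd = c(1, 1.5, 2, 3)) {
  stopifnot(inherits(assignment, "decile_assignment"))
  x <- as.numeric(domain_scores)
  if (length(x) != length(assignment$bin)) {
    stop("domain_scores must align with the decile assignment")
  }
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("risk_proportions: zero-SD domain scores")
  mu <- mean(x)
  out <- expand.grid(bin = seq_len(10), threshold = thresholds_sd)
  out$n <- assignment$sizes[out$bin]
  out$n_above <- mapply(function(b, t) {
    sum(x[assignment$bin == b] > mu + t * s)
  }, out$bin, out$threshold)
  out$proportion <- out$n_above / out$n
  out
}

#' Odds ratio from a 2x2 exposure-by-case table
#'
#' `OR = (exposed cases x unexposed noncases) / (exposed noncases x unexposed
#' cases)`. In the decile analysis, "cases" are subjects in the
#' poorest-performance bin, "noncases" those in the best bin, and "exposed"
#' means a symptom score above the clinical threshold.
#'
#' @param exposed_cases,unexposed_noncases,exposed_noncases,unexposed_cases
#'   nonnegative counts.
#' @param correction apply the Haldane-Anscombe +0.5 correction to all cells
#'   (default FALSE; without it a zero denominator yields `NA` with a
#'   warning).
#' @return positive numeric odds ratio, or `NA` when undefined.
#' @export
odds_ratio <- function(exposed_cases, unexposed_noncases,
                       exposed_noncases, unexposed_cases,
                       correction = FALSE) {
  cells <- c(exposed_cases, unexposed_noncases, exposed_noncases,
             unexposed_cases)
  if (any(cells < 0)) stop("odds_ratio: counts must be nonnegative")
  if (correction) cells <- cells + 0.5
  denom <- cells[3] * cells[4]
  if (denom == 0) {
    warning("odds_ratio: zero cell in the denominator; returning NA ",
            "(use correction = TRUE for Haldane-Anscombe)")
    return(NA_real_)
  }
  (cells[1] * cells[2]) / denom
}

#' Worst-vs-best-bin odds ratios per domain threshold
#'
#' Builds the 2x2 table contrasting the poorest-performance decile (cases)
#' with the best decile (noncases) at each clinical threshold and applies
#' [odds_ratio()].
#'
#' @inheritParams risk_proportions
#' @param correction passed to [odds_ratio()].
#' @return data.frame with columns `threshold` and `odds_ratio`.
#' @export
enrichment_odds_ratios <- function(assignment, domain_scores,
                                   thresholds_sd = c(1, 1.5, 2, 3),
                                   correction = FALSE) {
  tab <- risk_proportions(assignment, domain_scores, thresholds_sd)
  out <- lapply(thresholds_sd, function(t) {
    worst <- tab[tab$bin == 10 & tab$threshold == t, ]
    best <- tab[tab$bin == 1 & tab$threshold == t, ]
    or <- odds_ratio(exposed_cases = worst$n_above,
                     unexposed_noncases = best$n - best$n_above,
                     exposed_noncases = best$n_above,
                     unexposed_cases = worst$n - worst$n_above,
                     correction = correction)
    data.frame(threshold = t, odds_ratio = or)
  })
  do.call(rbind, out)
}

#' Per-bin exposed-proportion plot
#'
#' @param enrichment data.frame from [risk_proportions()].
#' @param ... passed to [graphics::matplot()].
#' @export
plot_enrichment <- function(enrichment, ...) {
  wide <- stats::reshape(enrichment[, c("bin", "threshold", "proportion")],
                         idvar = "bin", timevar = "threshold",
                         direction = "wide")
  m <- as.matrix(wide[order(wide$bin), -1, drop = FALSE])
  graphics::matplot(seq_len(10), m, type = "b", pch = 16, lty = 1,
                    xlab = "performance decile (1 = best)",
                    ylab = "proportion above threshold", ...)
  graphics::legend("topleft",
                   legend = paste(sort(unique(enrichment$threshold)), "SD"),
                   col = seq_len(ncol(m)), lty = 1, pch = 16, bty = "n")
}
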