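#' Classify proteins by SignalP d-score
#'
#' A protein is called classically secreted when its SignalP d-score
#' strictly exceeds the threshold (default 0.5, the standard eukaryotic
#' cutoff; 0.45 applies to proteins without a transmembrane domain and is
#' available via the argument). Proteins without a score are conservatively
#' NOT_SECRETED.
#'
#' @param d_score Numeric vector of d-scores in [0, 1]; `NA` = no score.
#' @param threshold Strict threshold (default 0.5).
#' @return Character vector, `"SECRETED"` or `"NOT_SECRETED"`; an attribute
#'   `no_score` marks entries classified without a score.
#' @examples
#' classify_by_signalp(c(0.9, 0.5, 0.49, NA))
#' @export
classify_by_signalp <- function(d_score, threshold = 0.5) {
  out <- ifelse(!is.na(d_score) & d_score > threshold,
                "SECRETED", "NOT_SECRETED")
  attr(out, "no_score") <- is.na(d_score)
  out
}

#' Choose the rate-constant cutoff separating high-k from low-k proteins
#'
#' Three strategies:
#' \describe{
#'   \item{combined_fit}{(default) the class-level combined-fit `k` of the
#'     SignalP-secreted proteins — the data-driven cutoff; requires
#'     `secreted_fit`;}
#'   \item{fixed}{a user value (`value`, default 0.1/h, the empirical
#'     cutoff for classically secreted kinetics);}
#'   \item{association}{the fixed 0.02/h threshold used in the Fisher
#'     association test between secretion prediction and fast labeling.}
#' }
#' An empty/unavailable secreted class falls back to `fixed` with a
#' warning.
#'
#' @param secreted_fit The `ria_fit` of the SignalP > 0.5 class
#'   ([fit_class_k()]), or `NULL`.
#' @param strategy One of `"combined_fit"`, `"fixed"`, `"association"`.
#' @param value Cutoff for the `fixed` strategy (per hour).
#' @param association_k Threshold for the `association` strategy.
#' @return Numeric cutoff (per hour) with attribute `strategy`.
#' @export
kinetic_cutoff <- function(secreted_fit = NULL,
                           strategy = c("combined_fit", "fixed", "association"),
                           value = 0.1, association_k = 0.02) {
  strategy <- match.arg(strategy)
  if (strategy == "combined_fit" &&
      (is.null(secreted_fit) || !isTRUE(secreted_fit$converged))) {
    warning("no combined fit available for the secreted class; falling back to the fixed cutoff")
    strategy <- "fixed"
  }
  cut <- switch(strategy,
                combined_fit = secreted_fit$k,
                fixed = value,
                association = association_k)
  structure(cut, strategy = strategy)
}

#' Classify proteins by labeling rate constant
#'
#' HIGH_K when `k` strictly exceeds the cutoff, else LOW_K; ties fall to
#' LOW_K. Artifact-flagged proteins should not be classified (pass only
#' unflagged records).
#'
#' @param k Numeric vector of protein rate constants (per hour).
#' @param cutoff Cutoff from [kinetic_cutoff()] or a plain number.
#' @return Character vector `"HIGH_K"`/`"LOW_K"` (`NA` where `k` is `NA`).
#' @export
classify_by_k <- function(k, cutoff) {
  ifelse(is.na(k), NA_character_, ifelse(k > as.numeric(cutoff), "HIGH_K", "LOW_K"))
}

#' Association between predicted secretion and fast labeling
#'
#' Builds the 2x2 contingency table of SignalP > `d_threshold` against
#' `k` > `k_threshold` (default 0.02/h) and applies the two-sided Fisher
#' exact test. A strong association between a predicted signal peptide and
#' a fast labeling rate is the expected signature of authentic classical
#' secretion.
#'
#' @param d_score d-scores (one per protein record).
#' @param k Rate constants (same length).
#' @param k_threshold Rate cutoff (default 0.02/h).
#' @param d_threshold d-score cutoff (default 0.5).
#' @return List of class `sidls_association`: `table` (2x2, rows = SignalP
#'   class, cols = kinetic class), `odds_ratio` (conditional MLE; `NA` when
#'   a margin is zero), `p_value` (1 when a margin is zero), `n`.
#' @examples
#' association_test(c(.9, .8, .9, .1, .2, .1), c(.3, .2, .25, .01, .005, .004))
#' @export
association_test <- function(d_score, k, k_threshold = 0.02,
                             d_threshold = 0.5) {
  keep <- !is.na(d_score) & !is.na(k)
  d_score <- d_score[keep]; k <- k[keep]
  if (!length(k)) stop("no complete (d_score, k) records to test")
  sp <- factor(d_score > d_threshold, levels = c(TRUE, FALSE),
               labels = c("SignalP>thr", "SignalP<=thr"))
  kk <- factor(k > k_threshold, levels = c(TRUE, FALSE),
               labels = c("k>thr", "k<=thr"))
  tab <- table(sp, kk)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    res <- list(table = tab, odds_ratio = NA_real_, p_value = 1,
                n = sum(tab))
  } else {
    ft <- stats::fisher.test(tab, alternative = "two.sided")
    res <- list(table = tab, odds_ratio = unname(ft$estimate),
                p_value = ft$p.value, n = sum(tab))
  }
  structure(res, class = "sidls_association")
}

#' @export
print.sidls_association <- function(x, ...) {
  cat("Fisher exact association, SignalP class vs labeling rate\n")
  print(x$table)
  cat(sprintf("  odds ratio = %s, two-sided p = %s (n = %d)\n",
              format(x$odds_ratio, digits = 4),
              format.pval(x$p_value, digits = 3), x$n))
  invisible(x)
}
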