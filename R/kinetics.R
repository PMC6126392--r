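#' First-order rise-to-plateau labeling model
#'
#' Predicted relative isotope abundance after `t` hours of labeling at rate
#' constant `k` (per hour): `RIA(t) = 1 - exp(-k * t)`. The pool is fully
#' unlabeled at t = 0 and approaches complete labeling (RIA = 1) as t grows;
#' classically secreted proteins, having no large pre-existing intracellular
#' pool diluting new synthesis, show large `k`, while leaked intracellular
#' proteins label slowly.
#'
#' @param k Rate constant(s), per hour, non-negative.
#' @param t Time(s) since medium exchange, hours, non-negative.
#' @return `1 - exp(-k * t)`, in [0, 1).
#' @examples
#' model_ria(0.1, 24)   # ~0.909
#' @export
model_ria <- function(k, t) {
  if (any(k < 0) || any(t < 0)) stop("'k' and 't' must be non-negative")
  1 - exp(-k * t)
}

.new_ria_fit <- function(k, n_points, rss, converged, level, method, data) {
  structure(
    list(k = k, n_points = n_points, rss = rss, converged = converged,
         level = level, method = method, data = data),
    class = "ria_fit"
  )
}

#' Fit the labeling rate constant to an RIA trajectory
#'
#' Least-squares fit of `RIA(t) = 1 - exp(-k t)` with the intercept fixed at
#' 0 and the plateau fixed at 1 — the single free parameter is the rate
#' constant `k`, constrained to `[0, k_max]`. Fitting uses [stats::nls()]
#' ("port" algorithm, bounds honoured, `scaleOffset` so that noiseless data
#' converge cleanly), started from the closed-form inversion of the latest
#' point, `k0 = -log(1 - min(RIA_last, 0.99)) / t_last`. If `nls` fails to
#' converge the bounded one-dimensional minimiser [stats::optimize()] is
#' used on the residual sum of squares; only if that also fails is the fit
#' marked non-converged (it then carries no rate estimate).
#'
#' @param time Hours (> 0), length >= 3.
#' @param ria Observed RIA in [0, 1], same length.
#' @param k_max Upper bound on `k` (default 10/h).
#' @param level One of `"PEPTIDE"`, `"PROTEIN"`, `"CLASS"` — bookkeeping for
#'   what was pooled into this fit.
#' @return An object of class `ria_fit`: fields `k`, `n_points`, `rss`,
#'   `converged`, `level`, `method` and the fitted data; methods for
#'   `print`, `coef`, `predict`, `residuals`, `summary` and `plot`.
#' @examples
#' t <- c(0.5, 1, 2, 6, 24)
#' fit_k(t, model_ria(0.274, t))
#' @export
fit_k <- function(time, ria, k_max = 10, level = "PEPTIDE") {
  level <- match.arg(level, c("PEPTIDE", "PROTEIN", "CLASS"))
  if (length(time) != length(ria)) stop("'time' and 'ria' lengths differ")
  keep <- !is.na(time) & !is.na(ria)
  time <- as.numeric(time[keep]); ria <- as.numeric(ria[keep])
  if (length(time) < 3L) stop("at least 3 (time, RIA) points are required")
  if (any(time <= 0)) stop("all time points must be > 0")
  if (any(ria < 0 | ria > 1)) stop("RIA values must lie in [0, 1]")
  dat <- data.frame(time = time, ria = ria)

  if (all(ria == 0)) {
    return(.new_ria_fit(0, length(time), 0, TRUE, level, "boundary", dat))
  }

  i_last <- which.max(time)
  r_last <- min(mean(ria[time == time[i_last]]), 0.99)
  k0 <- max(-log(1 - max(r_last, 1e-6)) / time[i_last], 1e-6)

  fit <- tryCatch(
    stats::nls(ria ~ 1 - exp(-k * time), data = dat,
               start = list(k = min(max(k0, 1e-6), k_max)),
               algorithm = "port", lower = 0, upper = k_max,
               control = stats::nls.control(maxiter = 500, scaleOffset = 1,
                                            warnOnly = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    k_hat <- unname(stats::coef(fit)[["k"]])
    # polish: nls "port" stops at its own tolerance; a bracketed golden-
    # section pass tightens the single parameter to ~1e-10
    k_hat <- .polish_k(k_hat, time, ria, k_max)
    rss <- sum((ria - model_ria(k_hat, time))^2)
    return(.new_ria_fit(k_hat, length(time), rss, TRUE, level, "nls", dat))
  }
  opt <- tryCatch(
    stats::optimize(function(k) sum((ria - model_ria(k, time))^2),
                    interval = c(0, k_max), tol = 1e-10),
    error = function(e) NULL)
  if (!is.null(opt) && is.finite(opt$minimum)) {
    return(.new_ria_fit(opt$minimum, length(time), opt$objective, TRUE, level,
                        "optimize", dat))
  }
  .new_ria_fit(NA_real_, length(time), NA_real_, FALSE, level, "failed", dat)
}

.polish_k <- function(k_hat, time, ria, k_max) {
  lo <- max(0, k_hat - 1e-3); hi <- min(k_max, k_hat + 1e-3)
  opt <- stats::optimize(function(k) sum((ria - model_ria(k, time))^2),
                         interval = c(lo, hi), tol = 1e-12)
  if (opt$objective <= sum((ria - model_ria(k_hat, time))^2)) opt$minimum else k_hat
}

#' @export
print.ria_fit <- function(x, digits = 4, ...) {
  cat(sprintf("First-order labeling fit (%s level)\n", x$level))
  if (isTRUE(x$converged)) {
    cat(sprintf("  k = %s per hour  (t1/2 = %s h)\n",
                format(x$k, digits = digits),
                format(log(2) / max(x$k, .Machine$double.eps), digits = digits)))
    cat(sprintf("  n = %d points, RSS = %s\n", x$n_points,
                format(x$rss, digits = digits)))
  } else {
    cat("  did not converge (no rate estimate)\n")
  }
  invisible(x)
}

#' @export
coef.ria_fit <- function(object, ...) c(k = object$k)

#' @rdname fit_k
#' @param object,x An `ria_fit`.
#' @param newdata Optional data frame with a `time` column (hours); defaults
#'   to the fitted times.
#' @param ... Unused.
#' @export
predict.ria_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time else newdata$time
  model_ria(object$k, t)
}

#' @export
residuals.ria_fit <- function(object, ...) {
  object$data$ria - predict(object)
}

#' @export
summary.ria_fit <- function(object, ...) {
  s <- object[c("k", "n_points", "rss", "converged", "level", "method")]
  s$half_life_h <- if (isTRUE(object$converged) && object$k > 0)
    log(2) / object$k else NA_real_
  s$rmse <- if (isTRUE(object$converged)) sqrt(object$rss / object$n_points)
    else NA_real_
  structure(s, class = "summary.ria_fit")
}

#' @export
print.summary.ria_fit <- function(x, ...) {
  cat(sprintf("ria_fit (%s, %s): k = %.5g /h, half-life = %.4g h, n = %d, RMSE = %.3g, converged = %s\n",
              x$level, x$method, x$k, x$half_life_h, x$n_points, x$rmse,
              x$converged))
  invisible(x)
}

#' @export
plot.ria_fit <- function(x, ...) {
  graphics::plot(x$data$time, x$data$ria, xlab = "time (h)", ylab = "RIA",
                 ylim = c(0, 1), pch = 19, ...)
  tt <- seq(0, max(x$data$time), length.out = 200)
  if (isTRUE(x$converged))
    graphics::lines(tt, model_ria(x$k, tt), col = "red3")
  invisible(x)
}

#' Pooled protein-level labeling fit
#'
#' Pools the (time, RIA) points of every PASS trajectory of one protein into
#' a single [fit_k()] call. Shared peptides (mapping to more than one
#' protein group) are excluded so no evidence is double counted.
#'
#' @param points Trajectory points for one (sample, protein).
#' @param status Matching trajectory statuses.
#' @param k_max Upper bound for the rate constant.
#' @return An `ria_fit` with `level = "PROTEIN"`, or `NULL` when no PASS
#'   trajectory is available (the protein is excluded from kinetics).
#' @export
fit_protein_k <- function(points, status, k_max = 10) {
  pass <- status[status$filter_status == "PASS" & !status$is_shared, ,
                 drop = FALSE]
  if (!nrow(pass)) return(NULL)
  pts <- merge(points,
               pass[c("sample_id", "protein_accession", "peptide_sequence")],
               by = c("sample_id", "protein_accession", "peptide_sequence"))
  pts <- pts[!is.na(pts$ria), , drop = FALSE]
  if (nrow(pts) < 3L) return(NULL)
  fit_k(pts$time_point, pts$ria, k_max = k_max, level = "PROTEIN")
}

#' Combined (class-level) labeling fit
#'
#' Pools the PASS-trajectory RIA points of every member protein of a class
#' (e.g. all proteins with SignalP d-score > 0.5 in one cell line) into one
#' fit. The resulting "combined fit" rate constant summarises the class and
#' doubles as the default cutoff separating high-k from low-k proteins.
#'
#' @param points Trajectory points.
#' @param status Trajectory statuses.
#' @param members Character vector of member protein accessions.
#' @param k_max Upper bound for the rate constant.
#' @return An `ria_fit` with `level = "CLASS"`, or `NULL` for an empty class
#'   (with a warning).
#' @export
fit_class_k <- function(points, status, members, k_max = 10) {
  pass <- status[status$filter_status == "PASS" & !status$is_shared &
                   status$protein_accession %in% members, , drop = FALSE]
  if (!nrow(pass)) {
    warning("empty class: no PASS trajectories among member proteins")
    return(NULL)
  }
  pts <- merge(points,
               pass[c("sample_id", "protein_accession", "peptide_sequence")],
               by = c("sample_id", "protein_accession", "peptide_sequence"))
  pts <- pts[!is.na(pts$ria), , drop = FALSE]
  if (nrow(pts) < 3L) return(NULL)
  fit_k(pts$time_point, pts$ria, k_max = k_max, level = "CLASS")
}

#' Detect requant-style quantification artifacts
#'
#' Some trajectories show an instant rise to a plateau — already near-fully
#' "labeled" at 30 min with no subsequent increase — which cannot arise from
#' real first-order labeling and instead reflects mis-assignment of
#' heavy/light features (typically a single-channel feature whose missing
#' partner was imputed). A trajectory is flagged when either
#' (a) the earliest observed RIA is at least `plateau_fraction` of the
#' latest observed RIA *and* at least `floor` in absolute terms, or
#' (b) every point of the trajectory lacks one of the two channels in the
#' underlying evidence.
#'
#' @param points Trajectory points of one (sample, protein, peptide),
#'   i.e. one trajectory.
#' @param plateau_fraction Fraction of the final RIA the first RIA must
#'   reach to count as an instant plateau (default 0.9).
#' @param floor Minimum absolute first RIA for rule (a) (default 0.5).
#' @return Logical flag.
#' @export
flag_artifact_profiles <- function(points, plateau_fraction = 0.9,
                                   floor = 0.5) {
  if (!nrow(points)) return(FALSE)
  if (all(!points$both_channels)) return(TRUE)
  ok <- !is.na(points$ria)
  if (!any(ok)) return(FALSE)
  t_ok <- points$time_point[ok]; r_ok <- points$ria[ok]
  r_first <- r_ok[which.min(t_ok)]
  r_last <- r_ok[which.max(t_ok)]
  (r_first >= plateau_fraction * r_last) && (r_first >= floor)
}
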