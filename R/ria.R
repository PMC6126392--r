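#' Relative isotope abundance of a heavy/light peptide pair
#'
#' RIA = H / (H + L): the fraction of a peptide's summed ion current carried
#' by the heavy-labeled form. It is 0 for fully pre-existing (unlabeled)
#' protein and rises toward 1 as newly synthesized, labeled protein
#' accumulates. When either channel is absent the ratio is undefined and
#' `NA` is returned, unless `absent_as_zero = TRUE`, which emulates
#' requant-style behaviour by treating the missing channel as a true zero
#' (yielding RIA exactly 0 or 1).
#'
#' @param heavy,light Non-negative intensities (vectors recycle); `NA`
#'   means not quantified.
#' @param absent_as_zero Treat an absent channel as zero intensity.
#' @return Numeric vector in [0, 1], `NA` where incomputable (including
#'   H + L = 0).
#' @examples
#' compute_ria(900, 100)            # 0.9
#' compute_ria(NA, 500)             # NA
#' compute_ria(NA, 500, TRUE)       # 0
#' @export
compute_ria <- function(heavy, light, absent_as_zero = FALSE) {
  if (any(!is.na(heavy) & heavy < 0) || any(!is.na(light) & light < 0))
    stop("negative intensity (corrupt input)")
  n <- max(length(heavy), length(light))
  heavy <- rep_len(as.numeric(heavy), n)
  light <- rep_len(as.numeric(light), n)
  if (absent_as_zero) {
    heavy[is.na(heavy)] <- 0
    light[is.na(light)] <- 0
  }
  tot <- heavy + light
  out <- heavy / tot
  out[!is.na(tot) & tot == 0] <- NA_real_
  out
}

#' Assemble per-peptide RIA trajectories
#'
#' Groups kinetic-grade evidence rows into one trajectory per
#' (sample, protein, peptide). Multiple features of the same peptide at the
#' same time point (charge states, repeated elution) are merged by summing
#' the heavy and light intensities before the ratio is taken, so the RIA
#' reflects the peptide's total ion current. Points where the RIA is
#' incomputable (a missing channel in the default requant-off mode) are kept
#' in the table with `ria = NA`; downstream filters consider only computable
#' points, while the artifact detector inspects channel completeness.
#'
#' @param kinetic Kinetic-grade evidence rows (see [filter_psms()]).
#' @param requant `"off"` (default): an absent channel makes the RIA
#'   incomputable; `"on"`: absent channels count as zero intensity, so
#'   single-channel features yield RIA 0 or 1.
#' @return Data frame of trajectory points, ordered by sample, protein,
#'   peptide and time: `sample_id`, `protein_accession`, `peptide_sequence`,
#'   `is_shared`, `time_point`, `heavy_intensity`, `light_intensity`
#'   (summed; `NA` when absent in every contributing row), `both_channels`,
#'   and `ria`.
#' @export
build_trajectories <- function(kinetic, requant = c("off", "on")) {
  requant <- match.arg(requant)
  if (!nrow(kinetic)) {
    return(data.frame(sample_id = character(), protein_accession = character(),
                      peptide_sequence = character(), is_shared = logical(),
                      time_point = numeric(), heavy_intensity = numeric(),
                      light_intensity = numeric(), both_channels = logical(),
                      ria = numeric(), stringsAsFactors = FALSE))
  }
  key <- interaction(kinetic$sample_id, kinetic$protein_accession,
                     kinetic$peptide_sequence, kinetic$time_point,
                     drop = TRUE, sep = "\r")
  sum_or_na <- function(x) if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE)
  h <- tapply(kinetic$heavy_intensity, key, sum_or_na)
  l <- tapply(kinetic$light_intensity, key, sum_or_na)
  first <- !duplicated(key)
  out <- data.frame(
    sample_id = kinetic$sample_id[first],
    protein_accession = kinetic$protein_accession[first],
    peptide_sequence = kinetic$peptide_sequence[first],
    is_shared = kinetic$is_shared[first],
    time_point = kinetic$time_point[first],
    stringsAsFactors = FALSE
  )
  k2 <- as.character(key[first])
  out$heavy_intensity <- as.numeric(h[k2])
  out$light_intensity <- as.numeric(l[k2])
  out$both_channels <- !is.na(out$heavy_intensity) & !is.na(out$light_intensity)
  out$ria <- compute_ria(out$heavy_intensity, out$light_intensity,
                         absent_as_zero = (requant == "on"))
  out[order(out$sample_id, out$protein_accession, out$peptide_sequence,
            out$time_point), , drop = FALSE]
}

.traj_key <- function(points) {
  interaction(points$sample_id, points$protein_accession,
              points$peptide_sequence, drop = TRUE, sep = "\r")
}

#' Apply the trajectory-level quality filters
#'
#' Classifies every (sample, protein, peptide) trajectory by the stringent
#' criteria required before a labeling rate can be fitted, in this fixed
#' order (the first failure is recorded):
#' \describe{
#'   \item{TOO_FEW_POINTS}{fewer than 3 time points with a computable RIA;}
#'   \item{MISSING_LATE_POINTS}{no computable RIA at one of the required
#'     late times (default 6 h and 24 h), where the secretome is abundant;}
#'   \item{IMPOSSIBLE_PROFILE}{an RIA at an early time (default 0.5 h or
#'     1 h) strictly exceeds (beyond `epsilon`) an RIA at a required late
#'     time — labeling cannot decrease in this system, so such profiles are
#'     quantification artifacts;}
#'   \item{PASS}{all checks satisfied.}
#' }
#'
#' @param points Trajectory points from [build_trajectories()].
#' @param design An [experiment_design()].
#' @param epsilon Non-negative slack for the early/late comparison
#'   (default 0: any strict excess rejects).
#' @return One row per trajectory: `sample_id`, `protein_accession`,
#'   `peptide_sequence`, `is_shared`, `n_points` (computable RIA points),
#'   `filter_status` (character, one of the four states).
#' @export
apply_trajectory_filters <- function(points, design = experiment_design(),
                                     epsilon = 0) {
  stopifnot(epsilon >= 0)
  if (!nrow(points)) {
    return(data.frame(sample_id = character(), protein_accession = character(),
                      peptide_sequence = character(), is_shared = logical(),
                      n_points = integer(), filter_status = character(),
                      stringsAsFactors = FALSE))
  }
  key <- .traj_key(points)
  late <- design$required_late_points
  early <- design$early_points
  status_one <- function(df) {
    ok <- !is.na(df$ria)
    t_ok <- df$time_point[ok]
    r_ok <- df$ria[ok]
    n <- length(t_ok)
    if (n < 3L) return(list(n = n, s = "TOO_FEW_POINTS"))
    if (!all(late %in% t_ok)) return(list(n = n, s = "MISSING_LATE_POINTS"))
    r_early <- r_ok[t_ok %in% early]
    r_late <- r_ok[t_ok %in% late]
    if (length(r_early) && any(outer(r_early, r_late, `-`) > epsilon))
      return(list(n = n, s = "IMPOSSIBLE_PROFILE"))
    list(n = n, s = "PASS")
  }
  pieces <- split(points[c("time_point", "ria")], key)
  res <- lapply(pieces, status_one)
  first <- !duplicated(key)
  ord_key <- as.character(key[first])
  data.frame(
    sample_id = points$sample_id[first],
    protein_accession = points$protein_accession[first],
    peptide_sequence = points$peptide_sequence[first],
    is_shared = points$is_shared[first],
    n_points = vapply(res[ord_key], function(x) as.integer(x$n), integer(1)),
    filter_status = vapply(res[ord_key], function(x) x$s, character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Kernel density of RIA values at one time point, split by SignalP class
#'
#' Pools the RIA values of all PASS trajectories observed at `time_point`
#' and estimates, separately for proteins with d-score above and below the
#' secretion threshold, a Gaussian kernel density on [0, 1]. Bandwidth is
#' Silverman's rule on the class's RIA values; boundary bias at 0 and 1 is
#' corrected by reflection so each curve integrates to ~1 over the unit
#' interval. Classically secreted proteins show mass migrating from 0
#' toward 1 along the time course; leaked intracellular proteins stay
#' near 0.
#'
#' @param points Trajectory points ([build_trajectories()]).
#' @param status Trajectory statuses ([apply_trajectory_filters()]).
#' @param signalp SignalP table ([load_signalp()] or equivalent).
#' @param time_point The labeling time (hours) to slice at.
#' @param threshold d-score secretion threshold (default 0.5).
#' @param n_grid Grid size over [0, 1] (default 256).
#' @return Data frame `class` (`"SECRETED"`/`"NOT_SECRETED"`), `ria` (grid),
#'   `density`. A class with fewer than 2 RIA values contributes no rows
#'   (with a warning).
#' @export
ria_density_by_class <- function(points, status, signalp, time_point,
                                 threshold = 0.5, n_grid = 256L) {
  pass <- status[status$filter_status == "PASS", , drop = FALSE]
  pts <- merge(points,
               pass[c("sample_id", "protein_accession", "peptide_sequence")],
               by = c("sample_id", "protein_accession", "peptide_sequence"))
  pts <- pts[pts$time_point == time_point & !is.na(pts$ria), , drop = FALSE]
  d <- signalp$d_score[match(pts$protein_accession, signalp$protein_accession)]
  cls <- ifelse(!is.na(d) & d > threshold, "SECRETED", "NOT_SECRETED")
  out <- list()
  for (cl in c("SECRETED", "NOT_SECRETED")) {
    x <- pts$ria[cls == cl]
    if (length(x) < 2L) {
      warning(sprintf("class %s has fewer than 2 RIA values at t = %g h; empty curve",
                      cl, time_point))
      next
    }
    out[[cl]] <- data.frame(class = cl, .reflected_kde(x, n_grid = n_grid),
                            stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(class = character(), ria = numeric(), density = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Gaussian KDE on [0,1] with reflection at both boundaries:
# f(x) = f0(x) + f0(-x) + f0(2-x), f0 the unbounded Silverman KDE.
.reflected_kde <- function(x, n_grid = 256L) {
  bw <- stats::bw.nrd0(x)
  if (!is.finite(bw) || bw <= 0) bw <- 0.01  # degenerate (constant) samples
  d0 <- stats::density(x, bw = bw, from = -1, to = 2, n = 3L * n_grid)
  g <- seq(0, 1, length.out = n_grid)
  f <- stats::approx(d0$x, d0$y, xout = g)$y +
    stats::approx(d0$x, d0$y, xout = -g)$y +
    stats::approx(d0$x, d0$y, xout = 2 - g)$y
  data.frame(ria = g, density = f)
}
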