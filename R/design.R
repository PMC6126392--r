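#' Describe the labeling time course
#'
#' An experiment design records the sampling times of the dynamic-SILAC
#' labeling trajectory (hours since the switch to heavy medium), which of
#' those times must carry a computable RIA for a peptide to be analysed
#' kinetically, which count as "early" for the impossible-profile check,
#' and the residue that carries the heavy label.
#'
#' @param time_points Numeric vector of sampling times in hours, strictly
#'   increasing. Default `c(0.5, 1, 2, 6, 24)`, the standard 24 h
#'   conditioned-medium trajectory.
#' @param required_late_points Times (subset of `time_points`) at which a
#'   computable RIA is mandatory; also the pair used for the secreted
#'   amount P (later minus earlier). Default `c(6, 24)`.
#' @param early_points Times treated as early for the impossible-profile
#'   filter: an early RIA exceeding any required late RIA disqualifies the
#'   trajectory. Default `c(0.5, 1)`.
#' @param label_site_residue Single uppercase amino-acid letter carrying the
#'   heavy label; only peptides terminating in this residue, with a single
#'   instance of it, are kinetically informative. Default `"K"`
#'   (13C6-lysine labeling with tryptic digestion).
#'
#' @return An object of class `sidls_design` (a list with the four fields).
#' @examples
#' experiment_design()
#' @export
experiment_design <- function(time_points = c(0.5, 1, 2, 6, 24),
                              required_late_points = c(6, 24),
                              early_points = c(0.5, 1),
                              label_site_residue = "K") {
  time_points <- as.numeric(time_points)
  if (length(time_points) < 2 || any(diff(time_points) <= 0))
    stop("'time_points' must be strictly increasing with length >= 2")
  if (!all(required_late_points %in% time_points))
    stop("'required_late_points' must be a subset of 'time_points'")
  if (!all(early_points %in% time_points))
    stop("'early_points' must be a subset of 'time_points'")
  if (!(is.character(label_site_residue) && nchar(label_site_residue) == 1L))
    stop("'label_site_residue' must be a single character")
  structure(
    list(
      time_points = time_points,
      required_late_points = sort(as.numeric(required_late_points)),
      early_points = sort(as.numeric(early_points)),
      label_site_residue = toupper(label_site_residue)
    ),
    class = "sidls_design"
  )
}

#' @export
print.sidls_design <- function(x, ...) {
  cat("Dynamic labeling design\n")
  cat("  time points (h):  ", paste(x$time_points, collapse = ", "), "\n")
  cat("  required late (h):", paste(x$required_late_points, collapse = ", "), "\n")
  cat("  early checks (h): ", paste(x$early_points, collapse = ", "), "\n")
  cat("  label residue:    ", x$label_site_residue, "\n")
  invisible(x)
}
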