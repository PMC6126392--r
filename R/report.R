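#' Write the per-protein report
#'
#' Deterministic tab-delimited report: fixed column order, rows sorted by
#' sample then accession, all numbers serialised at fixed precision
#' (`%.10g`), so identical inputs produce byte-identical files.
#'
#' @param records The `records` element of a [sidls()] result (or any data
#'   frame with those columns).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_protein_report <- function(records, path) {
  num_cols <- grep("^abundance_", names(records), value = TRUE)
  cols <- c("sample_id", "protein_accession", "n_peptides", "n_ria_points",
            "k", "rss", "converged", num_cols, "secreted_amount_P", "flux",
            "d_score", "signalp_class", "kinetic_class", "population",
            "artifact_flag")
  cols <- cols[cols %in% names(records)]
  r <- records[cols]
  if (nrow(r)) {
    r <- r[order(r$sample_id, r$protein_accession), , drop = FALSE]
    for (cc in names(r)) {
      if (is.numeric(r[[cc]]))
        r[[cc]] <- ifelse(is.na(r[[cc]]), "NA", sprintf("%.10g", r[[cc]]))
    }
  }
  con <- file(path, open = "wb")  # binary: fixed "\n" on every platform
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con, sep = "\n")
  if (nrow(r)) {
    lines <- do.call(paste, c(lapply(r, as.character), sep = "\t"))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Write per-peptide RIA trajectories (wide)
#'
#' One row per trajectory: sample, accession, peptide, one `RIA_<t>` column
#' per design time point, and the filter status. Deterministic like
#' [write_protein_report()].
#'
#' @param points Trajectory points ([build_trajectories()]).
#' @param status Trajectory statuses ([apply_trajectory_filters()]).
#' @param design The [experiment_design()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trajectory_table <- function(points, status, design, path) {
  tp <- design$time_points
  st <- status[order(status$sample_id, status$protein_accession,
                     status$peptide_sequence), , drop = FALSE]
  key_pts <- paste(points$sample_id, points$protein_accession,
                   points$peptide_sequence, sep = "\r")
  header <- c("sample_id", "protein_accession", "peptide_sequence",
              paste0("RIA_", tp), "filter_status")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con, sep = "\n")
  if (nrow(st)) {
    lines <- vapply(seq_len(nrow(st)), function(i) {
      kk <- paste(st$sample_id[i], st$protein_accession[i],
                  st$peptide_sequence[i], sep = "\r")
      p <- points[key_pts == kk, , drop = FALSE]
      ria <- p$ria[match(tp, p$time_point)]
      paste(c(st$sample_id[i], st$protein_accession[i],
              st$peptide_sequence[i],
              ifelse(is.na(ria), "NA", sprintf("%.10g", ria)),
              st$filter_status[i]), collapse = "\t")
    }, character(1))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Write the PSM filter tally as JSON
#'
#' @param tally The `tally` element of [filter_psms()] / [sidls()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_filter_tally <- function(tally, path) {
  jsonlite::write_json(as.list(tally), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write the classification summary as JSON
#'
#' Per sample: the cutoff and its strategy, the combined-fit rate
#' constants, the 2x2 SignalP-by-kinetics table with odds ratio and Fisher
#' p, and the per-class protein counts.
#'
#' @param object A [sidls()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_classification_summary <- function(object, path) {
  out <- list()
  for (sid in names(object$cutoffs)) {
    r <- object$records[object$records$sample_id == sid &
                          !object$records$artifact_flag, , drop = FALSE]
    a <- object$association[[sid]]
    cf <- object$class_fits[[sid]]
    out[[sid]] <- list(
      cutoff_per_hour = as.numeric(object$cutoffs[[sid]]),
      cutoff_strategy = attr(object$cutoffs[[sid]], "strategy"),
      combined_k_secreted = if (!is.null(cf$secreted)) cf$secreted$k else NULL,
      combined_k_not_secreted = if (!is.null(cf$not_secreted))
        cf$not_secreted$k else NULL,
      n_classified = nrow(r),
      n_secreted_signalp = sum(r$signalp_class == "SECRETED"),
      n_high_k = sum(r$kinetic_class == "HIGH_K", na.rm = TRUE),
      contingency = if (!is.null(a)) unclass(unname(a$table)) else NULL,
      odds_ratio = if (!is.null(a) && is.finite(a$odds_ratio))
        a$odds_ratio else NULL,
      fisher_p = if (!is.null(a)) a$p_value else NULL
    )
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
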