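#' Run the full secretome labeling-kinetics pipeline
#'
#' Drives the whole analysis on a loaded evidence table: PSM filtering,
#' RIA trajectory assembly and quality filtering, protein-level pooled fits
#' of `RIA(t) = 1 - exp(-k t)`, artifact detection, medium abundance /
#' secreted amount P / flux, SignalP and kinetic classification, the
#' class-level combined fits, and the Fisher association between predicted
#' secretion and fast labeling. Samples (cell lines) are processed
#' independently for everything class- or cutoff-related.
#'
#' @param evidence Evidence data frame from [load_evidence()] or
#'   [simulate_secretome()].
#' @param signalp Optional SignalP table ([load_signalp()]); proteins
#'   without a score classify as NOT_SECRETED.
#' @param design An [experiment_design()].
#' @param requant `"off"` (absent channel makes RIA incomputable; default)
#'   or `"on"` (absent channel counts as 0).
#' @param cutoff_strategy,cutoff_value,association_k Kinetic cutoff choice,
#'   see [kinetic_cutoff()].
#' @param signalp_threshold d-score threshold for classical secretion
#'   (default 0.5, strict).
#' @param plateau_fraction,artifact_floor Artifact-profile parameters, see
#'   [flag_artifact_profiles()].
#' @param epsilon Slack for the impossible-profile filter (default 0).
#' @param k_max Upper bound for all rate fits (default 10/h).
#' @return Object of class `sidls`: a list with `records` (one row per
#'   fitted sample x protein: peptide/point counts, `k`, diagnostics,
#'   per-time abundance, `secreted_amount_P`, `flux`, `d_score`,
#'   `signalp_class`, `kinetic_class`, `population`, `artifact_flag`),
#'   `class_fits`, `cutoffs` and `association` (per sample), `tally`,
#'   `trajectories`, `status`, `abundance`, `design` and `settings`.
#'   Methods: `print`, `summary`, `coef` (protein k vector), `plot`.
#' @examples
#' toy <- make_toy_fixture()
#' res <- sidls(toy$evidence, toy$signalp, toy$design)
#' res$records[, c("protein_accession", "k", "signalp_class", "kinetic_class")]
#' @export
sidls <- function(evidence, signalp = NULL, design = experiment_design(),
                  requant = c("off", "on"),
                  cutoff_strategy = c("combined_fit", "fixed", "association"),
                  cutoff_value = 0.1, association_k = 0.02,
                  signalp_threshold = 0.5, plateau_fraction = 0.9,
                  artifact_floor = 0.5, epsilon = 0, k_max = 10) {
  requant <- match.arg(requant)
  cutoff_strategy <- match.arg(cutoff_strategy)

  filt <- filter_psms(evidence, design)
  traj <- build_trajectories(filt$kinetic, requant = requant)
  status <- apply_trajectory_filters(traj, design, epsilon = epsilon)
  abundance <- compute_abundance(rbind(filt$kinetic, filt$identification))

  # per-trajectory artifact flags (PASS trajectories only)
  pass <- status[status$filter_status == "PASS", , drop = FALSE]
  traj_key <- .traj_key(traj)
  pass_key <- paste(pass$sample_id, pass$protein_accession,
                    pass$peptide_sequence, sep = "\r")
  art_flag <- vapply(pass_key, function(kk) {
    flag_artifact_profiles(traj[as.character(traj_key) == kk, , drop = FALSE],
                           plateau_fraction = plateau_fraction,
                           floor = artifact_floor)
  }, logical(1))
  pass$artifact <- unname(art_flag)

  # protein-level fits: pool PASS, unshared trajectories per (sample, protein)
  fit_units <- unique(pass[!pass$is_shared, c("sample_id", "protein_accession")])
  records <- NULL
  fits <- list()
  if (nrow(fit_units)) {
    rec_rows <- vector("list", nrow(fit_units))
    for (i in seq_len(nrow(fit_units))) {
      sid <- fit_units$sample_id[i]; acc <- fit_units$protein_accession[i]
      st_i <- status[status$sample_id == sid &
                       status$protein_accession == acc, , drop = FALSE]
      pt_i <- traj[traj$sample_id == sid &
                     traj$protein_accession == acc, , drop = FALSE]
      fit <- fit_protein_k(pt_i, st_i, k_max = k_max)
      if (is.null(fit)) next
      pa <- pass[pass$sample_id == sid & pass$protein_accession == acc &
                   !pass$is_shared, , drop = FALSE]
      ab_i <- abundance[abundance$sample_id == sid &
                          abundance$protein_accession == acc, , drop = FALSE]
      ab_vec <- stats::setNames(rep(NA_real_, length(design$time_points)),
                                paste0("abundance_", design$time_points))
      ab_vec[paste0("abundance_", ab_i$time_point)] <- ab_i$abundance
      P <- compute_secreted_amount(ab_i, design)
      fits[[paste(sid, acc, sep = "\r")]] <- fit
      rec_rows[[i]] <- data.frame(
        sample_id = sid, protein_accession = acc,
        n_peptides = nrow(pa), n_ria_points = fit$n_points,
        k = fit$k, rss = fit$rss, converged = fit$converged,
        as.list(ab_vec),
        secreted_amount_P = P, flux = compute_flux(fit$k, P),
        artifact_flag = all(pa$artifact),
        stringsAsFactors = FALSE, check.names = FALSE)
    }
    records <- do.call(rbind, rec_rows)
  }
  if (is.null(records)) {
    records <- data.frame(sample_id = character(),
                          protein_accession = character(),
                          k = numeric(), stringsAsFactors = FALSE)
  }

  # annotation + per-sample classification
  if (!is.null(signalp) && nrow(records)) {
    records$d_score <- signalp$d_score[match(records$protein_accession,
                                             signalp$protein_accession)]
  } else if (nrow(records)) {
    records$d_score <- NA_real_
  }
  if (nrow(records)) {
    records$signalp_class <- classify_by_signalp(records$d_score,
                                                 signalp_threshold)
    records$kinetic_class <- NA_character_
  }

  class_fits <- list(); cutoffs <- list(); association <- list()
  for (sid in unique(records$sample_id)) {
    rs <- records[records$sample_id == sid, , drop = FALSE]
    usable <- rs[!rs$artifact_flag & rs$converged, , drop = FALSE]
    sec_acc <- usable$protein_accession[usable$signalp_class == "SECRETED"]
    non_acc <- usable$protein_accession[usable$signalp_class == "NOT_SECRETED"]
    st_s <- status[status$sample_id == sid, , drop = FALSE]
    pt_s <- traj[traj$sample_id == sid, , drop = FALSE]
    sec_fit <- if (length(sec_acc))
      fit_class_k(pt_s, st_s, sec_acc, k_max = k_max) else NULL
    non_fit <- if (length(non_acc))
      fit_class_k(pt_s, st_s, non_acc, k_max = k_max) else NULL
    class_fits[[sid]] <- list(secreted = sec_fit, not_secreted = non_fit)
    cut <- kinetic_cutoff(sec_fit, strategy = cutoff_strategy,
                          value = cutoff_value, association_k = association_k)
    cutoffs[[sid]] <- cut
    sel <- records$sample_id == sid & !records$artifact_flag
    records$kinetic_class[sel] <- classify_by_k(records$k[sel], cut)
    association[[sid]] <- if (nrow(usable))
      association_test(usable$d_score, usable$k,
                       k_threshold = association_k,
                       d_threshold = signalp_threshold) else NULL
  }

  if (nrow(records) && length(unique(records$sample_id)) == 2L) {
    records <- classify_populations(records)
  } else if (nrow(records)) {
    records$population <- NA_character_
  }
  if (nrow(records)) {
    records <- records[order(records$sample_id, records$protein_accession), ,
                       drop = FALSE]
    rownames(records) <- NULL
  }

  structure(
    list(records = records, class_fits = class_fits, cutoffs = cutoffs,
         association = association, tally = filt$tally, fits = fits,
         trajectories = traj, status = status, abundance = abundance,
         design = design,
         settings = list(requant = requant, cutoff_strategy = cutoff_strategy,
                         cutoff_value = cutoff_value,
                         association_k = association_k,
                         signalp_threshold = signalp_threshold,
                         plateau_fraction = plateau_fraction,
                         artifact_floor = artifact_floor, epsilon = epsilon,
                         k_max = k_max),
         call = match.call()),
    class = "sidls"
  )
}

#' @export
print.sidls <- function(x, ...) {
  cat("SIDLS secretome kinetics\n")
  cat(sprintf("  evidence rows: %d (kinetic-grade %d)\n",
              x$tally[["n_input"]], x$tally[["kinetic"]]))
  st <- table(x$status$filter_status)
  cat("  trajectories:  ",
      paste(sprintf("%s=%d", names(st), as.integer(st)), collapse = ", "), "\n")
  cat(sprintf("  fitted proteins: %d (%d artifact-flagged)\n",
              nrow(x$records), sum(x$records$artifact_flag)))
  for (sid in names(x$cutoffs)) {
    cat(sprintf("  [%s] kinetic cutoff = %.4g /h (%s)", sid,
                as.numeric(x$cutoffs[[sid]]),
                attr(x$cutoffs[[sid]], "strategy")))
    a <- x$association[[sid]]
    if (!is.null(a))
      cat(sprintf("; Fisher p = %s", format.pval(a$p_value, digits = 3)))
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.sidls <- function(object, ...) {
  r <- object$records
  per_sample <- lapply(stats::setNames(nm = names(object$cutoffs)),
                       function(sid) {
    rs <- r[r$sample_id == sid & !r$artifact_flag, , drop = FALSE]
    cf <- object$class_fits[[sid]]
    list(
      n_fitted = sum(r$sample_id == sid),
      n_artifact = sum(r$sample_id == sid & r$artifact_flag),
      n_secreted_signalp = sum(rs$signalp_class == "SECRETED"),
      n_high_k = sum(rs$kinetic_class == "HIGH_K", na.rm = TRUE),
      median_k = stats::median(rs$k, na.rm = TRUE),
      combined_k_secreted = if (!is.null(cf$secreted)) cf$secreted$k else NA_real_,
      combined_k_not_secreted = if (!is.null(cf$not_secreted)) cf$not_secreted$k else NA_real_,
      cutoff = as.numeric(object$cutoffs[[sid]]),
      fisher_p = if (!is.null(object$association[[sid]]))
        object$association[[sid]]$p_value else NA_real_
    )
  })
  structure(list(tally = object$tally,
                 status = table(object$status$filter_status),
                 per_sample = per_sample),
            class = "summary.sidls")
}

#' @export
print.summary.sidls <- function(x, ...) {
  cat("SIDLS summary\n\nPSM filter tally:\n")
  print(x$tally)
  cat("\nTrajectory statuses:\n")
  print(x$status)
  for (sid in names(x$per_sample)) {
    s <- x$per_sample[[sid]]
    cat(sprintf("\nSample %s: %d proteins fitted (%d artifacts), %d SignalP-secreted, %d high-k\n",
                sid, s$n_fitted, s$n_artifact, s$n_secreted_signalp, s$n_high_k))
    cat(sprintf("  combined fit k: secreted %.4g /h, not-secreted %.4g /h; cutoff %.4g /h; Fisher p %s\n",
                s$combined_k_secreted, s$combined_k_not_secreted, s$cutoff,
                format.pval(s$fisher_p, digits = 3)))
  }
  invisible(x)
}

#' @export
coef.sidls <- function(object, ...) {
  stats::setNames(object$records$k,
                  paste(object$records$sample_id,
                        object$records$protein_accession, sep = ":"))
}

#' Diagnostic plots for a fitted secretome
#'
#' @param x A [sidls()] result.
#' @param type `"k_dscore"` (labeling rate against SignalP d-score, log-k
#'   axis), `"density"` (RIA kernel density by SignalP class at
#'   `time_point`) or `"flux"` (flux against k).
#' @param time_point Hours, for `type = "density"` (default: last design
#'   time).
#' @param ... Passed to the underlying plot call.
#' @export
plot.sidls <- function(x, type = c("k_dscore", "density", "flux"),
                       time_point = NULL, ...) {
  type <- match.arg(type)
  r <- x$records[!x$records$artifact_flag, , drop = FALSE]
  if (type == "k_dscore") {
    graphics::plot(r$d_score, pmax(r$k, 1e-4), log = "y",
                   xlab = "SignalP d-score", ylab = "k (per hour)",
                   col = ifelse(r$signalp_class == "SECRETED", "red3", "grey40"),
                   pch = 19, ...)
    graphics::abline(v = x$settings$signalp_threshold, lty = 2)
  } else if (type == "density") {
    if (is.null(time_point)) time_point <- max(x$design$time_points)
    sp <- data.frame(protein_accession = r$protein_accession,
                     d_score = r$d_score, stringsAsFactors = FALSE)
    dd <- ria_density_by_class(x$trajectories, x$status, sp, time_point,
                               threshold = x$settings$signalp_threshold)
    graphics::plot(NA, xlim = c(0, 1), ylim = c(0, max(dd$density, 1)),
                   xlab = sprintf("RIA at %g h", time_point), ylab = "density",
                   ...)
    for (cl in unique(dd$class)) {
      di <- dd[dd$class == cl, ]
      graphics::lines(di$ria, di$density,
                      col = if (cl == "SECRETED") "red3" else "blue3")
    }
    graphics::legend("top", legend = unique(dd$class),
                     col = ifelse(unique(dd$class) == "SECRETED", "red3",
                                  "blue3"), lty = 1, bty = "n")
  } else {
    graphics::plot(r$k, r$flux, xlab = "k (per hour)", ylab = "flux",
                   col = ifelse(r$signalp_class == "SECRETED", "red3", "grey40"),
                   pch = 19, ...)
    graphics::abline(h = 0, lty = 3)
  }
  invisible(x)
}
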