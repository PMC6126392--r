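#' Protein abundance in the medium at each time point
#'
#' A peptide's abundance at a time point is its summed heavy + light ion
#' current (an absent channel contributes 0 here — abundance measures total
#' material, unlike RIA which needs both channels). Protein abundance is the
#' mean over all its quantified peptides at that time point, including
#' label-free (e.g. arginine-terminated) identification-grade peptides.
#' Shared peptides are excluded to avoid double counting across protein
#' groups.
#'
#' @param evidence Evidence rows surviving the contaminant/reverse/missed-
#'   cleavage stages — the concatenation of the `kinetic` and
#'   `identification` elements of [filter_psms()].
#' @return Data frame `sample_id`, `protein_accession`, `time_point`,
#'   `abundance` (one row per observed combination).
#' @export
compute_abundance <- function(evidence) {
  ev <- evidence[!evidence$is_shared, , drop = FALSE]
  if (!nrow(ev)) {
    return(data.frame(sample_id = character(), protein_accession = character(),
                      time_point = numeric(), abundance = numeric(),
                      stringsAsFactors = FALSE))
  }
  h <- ifelse(is.na(ev$heavy_intensity), 0, ev$heavy_intensity)
  l <- ifelse(is.na(ev$light_intensity), 0, ev$light_intensity)
  tot <- h + l
  quant <- tot > 0  # rows with neither channel carry no abundance signal
  ev <- ev[quant, , drop = FALSE]; tot <- tot[quant]
  # per-peptide total first (charge states of one peptide sum together) ...
  pep_key <- interaction(ev$sample_id, ev$protein_accession,
                         ev$peptide_sequence, ev$time_point,
                         drop = TRUE, sep = "\r")
  pep_tot <- tapply(tot, pep_key, sum)
  first <- !duplicated(pep_key)
  pep <- data.frame(sample_id = ev$sample_id[first],
                    protein_accession = ev$protein_accession[first],
                    time_point = ev$time_point[first],
                    total = as.numeric(pep_tot[as.character(pep_key[first])]),
                    stringsAsFactors = FALSE)
  # ... then the protein abundance is the mean over peptides present
  prot_key <- interaction(pep$sample_id, pep$protein_accession,
                          pep$time_point, drop = TRUE, sep = "\r")
  ab <- tapply(pep$total, prot_key, mean)
  pfirst <- !duplicated(prot_key)
  out <- data.frame(sample_id = pep$sample_id[pfirst],
                    protein_accession = pep$protein_accession[pfirst],
                    time_point = pep$time_point[pfirst],
                    abundance = as.numeric(ab[as.character(prot_key[pfirst])]),
                    stringsAsFactors = FALSE)
  out[order(out$sample_id, out$protein_accession, out$time_point), ,
      drop = FALSE]
}

#' Amount secreted over the late labeling window
#'
#' The secreted amount P is the medium abundance at the last required late
#' time minus that at the first (default 24 h - 6 h, an 18 h window). P may
#' be negative: a shrinking extracellular pool, typical of leaked
#' intracellular proteins whose release does not keep pace with degradation
#' or re-uptake.
#'
#' @param abundance_by_time Named numeric vector (names = hours) or the
#'   per-protein slice of [compute_abundance()].
#' @param design An [experiment_design()]; its `required_late_points` give
#'   the window endpoints.
#' @return P, or `NA` when either endpoint abundance is missing.
#' @examples
#' compute_secreted_amount(c(`6` = 100, `24` = 1000))  # 900
#' @export
compute_secreted_amount <- function(abundance_by_time,
                                    design = experiment_design()) {
  if (is.data.frame(abundance_by_time)) {
    v <- abundance_by_time$abundance
    names(v) <- as.character(abundance_by_time$time_point)
    abundance_by_time <- v
  }
  late <- design$required_late_points
  t0 <- as.character(late[1L]); t1 <- as.character(late[length(late)])
  if (!all(c(t0, t1) %in% names(abundance_by_time))) return(NA_real_)
  a0 <- abundance_by_time[[t0]]; a1 <- abundance_by_time[[t1]]
  if (is.na(a0) || is.na(a1)) return(NA_real_)
  a1 - a0
}

#' Secretion flux
#'
#' The rate of flow of a protein from the intracellular to the
#' extracellular pool: `flux = k * P`, the labeling rate constant times the
#' amount secreted over the late window. Sign follows P (for k > 0).
#'
#' @param k Rate constant, per hour.
#' @param P Secreted amount (see [compute_secreted_amount()]).
#' @return `k * P` (per hour, in abundance units); `NA` if either is `NA`.
#' @examples
#' compute_flux(0.274, 1000)  # 274
#' @export
compute_flux <- function(k, P) {
  ifelse(is.na(k) | is.na(P), NA_real_, k * P)
}

#' Mark proteins as common to, or exclusive to, each of two samples
#'
#' With two cell types profiled, every protein is either detected in both
#' secretomes (COMMON) or exclusive to one. Crossed with the SignalP
#' secretion class this yields the six-population partition of a two-cell
#' comparison.
#'
#' @param records Protein-level data frame with `protein_accession` and
#'   `sample_id` columns covering exactly two samples.
#' @return `records` with a `population` column added: `"COMMON"`,
#'   `"EXCLUSIVE_A"` (first sample in sort order) or `"EXCLUSIVE_B"`; an
#'   attribute `population_samples` names the A/B mapping. With a single
#'   sample the column is `NA` (with a message).
#' @export
classify_populations <- function(records) {
  samples <- sort(unique(records$sample_id))
  if (length(samples) < 2L) {
    message("only one sample present; population set to NA")
    records$population <- NA_character_
    return(records)
  }
  if (length(samples) > 2L)
    stop("population classification is defined for exactly two samples; got ",
         length(samples))
  in_a <- unique(records$protein_accession[records$sample_id == samples[1L]])
  in_b <- unique(records$protein_accession[records$sample_id == samples[2L]])
  records$population <- ifelse(
    records$protein_accession %in% intersect(in_a, in_b), "COMMON",
    ifelse(records$protein_accession %in% in_a, "EXCLUSIVE_A", "EXCLUSIVE_B"))
  attr(records, "population_samples") <- c(A = samples[1L], B = samples[2L])
  records
}
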