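#' Column-name dialect for evidence tables
#'
#' Maps the internal field names onto the column headers of the evidence
#' file. Defaults are the MaxQuant 1.5.x "evidence.txt" headers; override
#' individual entries for other MaxQuant versions or converters.
#'
#' @param sequence,proteins,heavy,light,missed_cleavages,contaminant,reverse,raw_file
#'   Header names for the corresponding fields.
#' @return Named character vector of length 8 (class `sidls_dialect`).
#' @examples
#' evidence_dialect()
#' evidence_dialect(heavy = "Intensity.H", light = "Intensity.L")
#' @export
evidence_dialect <- function(sequence = "Sequence",
                             proteins = "Proteins",
                             heavy = "Intensity H",
                             light = "Intensity L",
                             missed_cleavages = "Missed cleavages",
                             contaminant = "Potential contaminant",
                             reverse = "Reverse",
                             raw_file = "Raw file") {
  structure(
    c(sequence = sequence, proteins = proteins, heavy = heavy, light = light,
      missed_cleavages = missed_cleavages, contaminant = contaminant,
      reverse = reverse, raw_file = raw_file),
    class = "sidls_dialect"
  )
}

# "0", "", "NA", NA all mean "not quantified" in MaxQuant intensity columns;
# absence is kept as NA, never coerced to 0.
.parse_intensity <- function(x) {
  v <- suppressWarnings(as.numeric(as.character(x)))
  v[!is.na(v) & v == 0] <- NA_real_
  if (any(!is.na(v) & v < 0)) stop("negative intensity in evidence table (corrupt input)")
  v
}

.parse_flag <- function(x) {
  x <- trimws(as.character(x))
  !is.na(x) & x %in% c("+", "1", "TRUE", "True", "true", "yes")
}

#' Read a MaxQuant-style peptide evidence table
#'
#' Reads a tab-delimited evidence file (one row per quantified peptide
#' feature per run), maps each run label onto a sample and a labeling time
#' through `run_map`, and returns the internal evidence data frame used by
#' the rest of the pipeline. Heavy/light intensities reported as 0 or empty
#' are treated as absent (`NA`), never as measured zeros.
#'
#' @param path Path to the tab-delimited evidence file (header row required).
#' @param design An [experiment_design()].
#' @param run_map Data frame with columns `run_label`, `sample_id`,
#'   `time_point` mapping each raw-file label to a sample and an hour.
#' @param dialect Column-name mapping, see [evidence_dialect()].
#' @return A data frame with columns `peptide_sequence`, `protein_group`,
#'   `protein_accession` (leading protein of the group), `is_shared`
#'   (peptide maps to more than one protein group), `heavy_intensity`,
#'   `light_intensity`, `missed_cleavages`, `is_contaminant`, `is_reverse`,
#'   `time_point`, `sample_id`. Rows whose run label is absent from
#'   `run_map` are skipped with a warning giving the count.
#' @seealso [filter_psms()], [build_trajectories()]
#' @export
load_evidence <- function(path, design, run_map, dialect = evidence_dialect()) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  missing_cols <- setdiff(unname(dialect), names(tab))
  if (length(missing_cols))
    stop("evidence table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  run_map <- as.data.frame(run_map)
  need <- c("run_label", "sample_id", "time_point")
  if (!all(need %in% names(run_map)))
    stop("'run_map' needs columns run_label, sample_id, time_point")

  raw <- as.character(tab[[dialect[["raw_file"]]]])
  idx <- match(raw, run_map$run_label)
  n_skip <- sum(is.na(idx))
  if (n_skip > 0)
    warning(sprintf("%d evidence row(s) with run label(s) not in run_map skipped: %s",
                    n_skip, paste(unique(raw[is.na(idx)]), collapse = ", ")))
  keep <- !is.na(idx)
  tab <- tab[keep, , drop = FALSE]
  idx <- idx[keep]

  tp <- as.numeric(run_map$time_point[idx])
  bad_tp <- setdiff(unique(tp), design$time_points)
  if (length(bad_tp))
    stop("run_map time point(s) not in the design: ", paste(bad_tp, collapse = ", "))

  group <- as.character(tab[[dialect[["proteins"]]]])
  group[is.na(group)] <- ""
  leading <- vapply(strsplit(group, ";", fixed = TRUE),
                    function(g) if (length(g)) trimws(g[[1L]]) else "",
                    character(1))
  data.frame(
    peptide_sequence = toupper(trimws(as.character(tab[[dialect[["sequence"]]]]))),
    protein_group = group,
    protein_accession = leading,
    is_shared = grepl(";", group, fixed = TRUE),
    heavy_intensity = .parse_intensity(tab[[dialect[["heavy"]]]]),
    light_intensity = .parse_intensity(tab[[dialect[["light"]]]]),
    missed_cleavages = as.integer(tab[[dialect[["missed_cleavages"]]]]),
    is_contaminant = .parse_flag(tab[[dialect[["contaminant"]]]]),
    is_reverse = .parse_flag(tab[[dialect[["reverse"]]]]),
    time_point = tp,
    sample_id = as.character(run_map$sample_id[idx]),
    stringsAsFactors = FALSE
  )
}

#' Filter peptide-spectrum matches for kinetic analysis
#'
#' Applies, in order, the PSM-level exclusions required before any labeling
#' kinetics can be computed: (1) contaminant-flagged rows, (2) reverse-hit
#' rows, (3) mis-cleaved peptides (missed cleavages > 0, hence potentially
#' more than one labeling site), (4) peptides that do not terminate in the
#' label-site residue or contain more than one instance of it. Peptides with
#' no label-site residue at all (e.g. arginine-terminated tryptic peptides
#' under lysine labeling) carry no kinetic information but still identify
#' and quantify their protein; they are returned separately as
#' identification-grade evidence and contribute to abundance, not to RIA.
#'
#' @param evidence Evidence data frame from [load_evidence()] (or the
#'   synthetic generator).
#' @param design An [experiment_design()]; supplies the label-site residue.
#' @return A list of class `sidls_filter` with elements
#'   `kinetic` (rows usable for RIA kinetics), `identification` (label-free
#'   rows kept for identification/abundance only), and `tally`, a named
#'   integer vector with the input size and the count removed or retained at
#'   each stage. `n_input` always equals
#'   `removed_contaminant + removed_reverse + removed_missed_cleavage +
#'   removed_multi_label_site + identification_only + kinetic`.
#' @examples
#' ev <- make_toy_fixture()$evidence
#' filter_psms(ev, experiment_design())$tally
#' @export
filter_psms <- function(evidence, design = experiment_design()) {
  stopifnot(is.data.frame(evidence))
  res <- toupper(design$label_site_residue)
  n_input <- nrow(evidence)

  is_cont <- if (n_input) evidence$is_contaminant else logical(0)
  ev1 <- evidence[!is_cont, , drop = FALSE]
  n_cont <- n_input - nrow(ev1)

  ev2 <- ev1[!ev1$is_reverse, , drop = FALSE]
  n_rev <- nrow(ev1) - nrow(ev2)

  mc <- ev2$missed_cleavages
  ev3 <- ev2[is.na(mc) | mc == 0L, , drop = FALSE]  # NA = not reported, keep
  n_mc <- nrow(ev2) - nrow(ev3)

  n_sites <- nchar(ev3$peptide_sequence) -
    nchar(gsub(res, "", ev3$peptide_sequence, fixed = TRUE))
  ends_in_site <- substring(ev3$peptide_sequence,
                            nchar(ev3$peptide_sequence)) == res
  kinetic_ok <- ends_in_site & n_sites == 1L
  no_site <- n_sites == 0L

  kinetic <- ev3[kinetic_ok, , drop = FALSE]
  identification <- ev3[no_site, , drop = FALSE]
  n_multi <- nrow(ev3) - nrow(kinetic) - nrow(identification)

  tally <- c(
    n_input = n_input,
    removed_contaminant = n_cont,
    removed_reverse = n_rev,
    removed_missed_cleavage = n_mc,
    removed_multi_label_site = n_multi,
    identification_only = nrow(identification),
    kinetic = nrow(kinetic)
  )
  structure(list(kinetic = kinetic, identification = identification,
                 tally = tally),
            class = "sidls_filter")
}

#' @export
print.sidls_filter <- function(x, ...) {
  cat("PSM filter cascade\n")
  t <- x$tally
  cat(sprintf("  input rows:              %d\n", t[["n_input"]]))
  cat(sprintf("  - contaminant:           %d\n", t[["removed_contaminant"]]))
  cat(sprintf("  - reverse hit:           %d\n", t[["removed_reverse"]]))
  cat(sprintf("  - missed cleavage:       %d\n", t[["removed_missed_cleavage"]]))
  cat(sprintf("  - multi/internal K site: %d\n", t[["removed_multi_label_site"]]))
  cat(sprintf("  identification-only:     %d\n", t[["identification_only"]]))
  cat(sprintf("  kinetic-grade:           %d\n", t[["kinetic"]]))
  invisible(x)
}
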