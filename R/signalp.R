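#' Read a SignalP d-score table
#'
#' Reads a delimited table of per-protein SignalP discrimination scores
#' (accession, d-score, optional transmembrane flag). The d-score is the
#' combined signal-peptide/cleavage-site score in [0, 1]; values above the
#' classification threshold (0.5 by default downstream) mark a classically
#' secreted protein.
#'
#' @param path Path to a tab-delimited file whose first two columns are the
#'   protein accession and the d-score; an optional third column is parsed
#'   as a transmembrane-domain flag.
#' @param header Does the file carry a header row? Default `TRUE`.
#' @return Data frame with columns `protein_accession`, `d_score`,
#'   `has_tm_domain` (logical, `NA` when not provided). Duplicate accessions
#'   keep the first occurrence with a warning.
#' @export
load_signalp <- function(path, header = TRUE) {
  tab <- utils::read.delim(path, header = header, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("SignalP table needs at least two columns (accession, d-score)")
  acc <- as.character(tab[[1L]])
  d <- suppressWarnings(as.numeric(tab[[2L]]))
  bad <- which(is.na(d) | d < 0 | d > 1)
  if (length(bad))
    stop(sprintf("d-score outside [0, 1] (or unparseable) at data row %d", bad[1L]))
  tm <- if (ncol(tab) >= 3) .parse_flag(tab[[3L]]) else rep(NA, length(acc))
  dup <- duplicated(acc)
  if (any(dup)) {
    warning(sprintf("%d duplicate accession row(s) dropped (first kept): %s",
                    sum(dup), paste(unique(acc[dup]), collapse = ", ")))
    acc <- acc[!dup]; d <- d[!dup]; tm <- tm[!dup]
  }
  data.frame(protein_accession = acc, d_score = d, has_tm_domain = tm,
             stringsAsFactors = FALSE)
}
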