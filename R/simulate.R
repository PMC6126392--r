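#' Configuration of the synthetic secretome generator
#'
#' Defaults describe a 5-point dynamic-SILAC time course of a
#' conditioned-medium secretome with three generative protein classes:
#' classically secreted (fast labeling, k log-uniform on 0.05-0.5/h,
#' linearly accumulating medium abundance), leaked intracellular (slow
#' labeling, 0.001-0.01/h, declining abundance — a large pre-existing
#' unlabeled pool diluting label) and regulated-pathway (fast synthesis
#' into a stored pool, constant medium abundance). Rate ranges may be given
#' as a single number (fixed k) or a length-2 log-uniform range.
#'
#' @param n_secreted,n_leaked,n_regulated Protein counts per class
#'   (defaults 50/50/5).
#' @param peptides_per_protein Lysine-terminated peptides per protein
#'   (default 3).
#' @param time_points Sampling times in hours (default 0.5, 1, 2, 6, 24).
#' @param k_secreted,k_leaked,k_regulated Rate-constant range (per hour),
#'   scalar or `c(lo, hi)` log-uniform.
#' @param leaked_decline Fractional decline of leaked-protein abundance
#'   over 24 h (default 0.2).
#' @param base_abundance_meanlog,base_abundance_sdlog Log-normal parameters
#'   of the per-protein abundance scale (arbitrary MS intensity units;
#'   defaults log(1e6) and 0.7).
#' @param ria_noise_sd Additive Gaussian noise on the RIA scale, applied
#'   before the intensity split and clipped to [0, 1] (default 0.03).
#' @param intensity_cv Coefficient of variation of the per-peptide
#'   log-normal response factor (ionization efficiency), drawn once per
#'   peptide and persistent across the time course (default 0.2).
#' @param measurement_cv Coefficient of variation of the additional
#'   per-measurement log-normal jitter on each feature's total intensity
#'   (default 0.05, typical XIC run-to-run reproducibility). Both factors
#'   multiply the H/L pair jointly, so H/(H+L) is unaffected.
#' @param dropout_rate Independent per-channel missingness probability
#'   (default 0.1).
#' @param artifact_fraction Fraction of proteins emitted as single-channel
#'   "instant plateau" artifact profiles (default 0.02).
#' @param sample_id Run/sample label (default `"SIM"`).
#' @param seed Integer seed; the same seed reproduces the tables exactly.
#' @return List of class `sidls_simconfig`.
#' @export
simulation_config <- function(n_secreted = 50L, n_leaked = 50L,
                              n_regulated = 5L, peptides_per_protein = 3L,
                              time_points = c(0.5, 1, 2, 6, 24),
                              k_secreted = c(0.05, 0.5),
                              k_leaked = c(0.001, 0.01),
                              k_regulated = c(0.05, 0.5),
                              leaked_decline = 0.2,
                              base_abundance_meanlog = log(1e6),
                              base_abundance_sdlog = 0.7,
                              ria_noise_sd = 0.03, intensity_cv = 0.2,
                              measurement_cv = 0.05,
                              dropout_rate = 0.1, artifact_fraction = 0.02,
                              sample_id = "SIM", seed = 1L) {
  stopifnot(n_secreted >= 0, n_leaked >= 0, n_regulated >= 0,
            peptides_per_protein >= 1, ria_noise_sd >= 0, intensity_cv >= 0,
            measurement_cv >= 0,
            dropout_rate >= 0, dropout_rate < 1,
            artifact_fraction >= 0, artifact_fraction <= 1)
  if (n_secreted + n_leaked + n_regulated == 0)
    stop("at least one protein must be simulated")
  structure(
    list(n_secreted = as.integer(n_secreted), n_leaked = as.integer(n_leaked),
         n_regulated = as.integer(n_regulated),
         peptides_per_protein = as.integer(peptides_per_protein),
         time_points = as.numeric(time_points),
         k_secreted = k_secreted, k_leaked = k_leaked,
         k_regulated = k_regulated, leaked_decline = leaked_decline,
         base_abundance_meanlog = base_abundance_meanlog,
         base_abundance_sdlog = base_abundance_sdlog,
         ria_noise_sd = ria_noise_sd, intensity_cv = intensity_cv,
         measurement_cv = measurement_cv,
         dropout_rate = dropout_rate, artifact_fraction = artifact_fraction,
         sample_id = sample_id, seed = as.integer(seed)),
    class = "sidls_simconfig"
  )
}

.draw_k <- function(range, n) {
  if (length(range) == 1L) return(rep(as.numeric(range), n))
  exp(stats::runif(n, log(range[1L]), log(range[2L])))
}

# class-specific medium abundance model (see simulation_config)
.true_abundance <- function(class, A0, t, decline) {
  switch(class,
         secreted = A0 * t / 24,
         leaked = A0 * (1 - decline * t / 24),
         regulated = rep(A0, length(t)))
}

.random_peptides <- function(n) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M",
          "N", "P", "Q", "S", "T", "V", "W", "Y")  # no K/R internally
  vapply(seq_len(n), function(i)
    paste0(paste(sample(aa, 9, replace = TRUE), collapse = ""), "K"),
    character(1))
}

#' Simulate a dynamic-SILAC secretome evidence table
#'
#' Generates, from known ("truth") parameters, the peptide evidence table
#' the pipeline consumes, a matching SignalP d-score table and the truth
#' table for benchmarking. For every protein a class and true rate constant
#' are drawn; the true RIA at time t is `1 - exp(-k t)`; per peptide and
#' time point Gaussian noise (sd `ria_noise_sd`) perturbs the RIA before it
#' is split into heavy and light intensities sharing one multiplicative
#' log-normal factor — the product of a persistent per-peptide response
#' factor (CV `intensity_cv`) and per-measurement jitter (CV
#' `measurement_cv`) — so recomputing H/(H+L) returns
#' the noisy RIA exactly. Channels then drop out independently; a fraction
#' of proteins are emitted as heavy-only "instant plateau" artifact
#' profiles (the requant-style mis-assignment signature). d-scores come
#' from Beta(8, 2) for the secreted class and Beta(2, 8) otherwise.
#'
#' All draws come from R's global RNG in a fixed documented order, so a
#' given `config$seed` reproduces the tables exactly.
#'
#' @param config A [simulation_config()].
#' @return List with `evidence` (internal evidence schema, ready for
#'   [filter_psms()]), `signalp`, `truth` (accession, class, `true_k`,
#'   `is_artifact`, `d_score`, `A0` and the true abundance at each time
#'   point as `A_<t>` columns), `run_map` and `design`.
#' @examples
#' sim <- simulate_secretome(simulation_config(n_secreted = 2, n_leaked = 2,
#'                                             n_regulated = 0, seed = 7))
#' head(sim$evidence)
#' @export
simulate_secretome <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sidls_simconfig"))
  set.seed(config$seed)
  tp <- config$time_points
  classes <- rep(c("secreted", "leaked", "regulated"),
                 c(config$n_secreted, config$n_leaked, config$n_regulated))
  n_prot <- length(classes)
  acc <- sprintf("%s%03d", c(secreted = "SEC", leaked = "LEK",
                             regulated = "REG")[classes],
                 stats::ave(seq_len(n_prot), classes, FUN = seq_along))

  # draw order: k | A0 | d-score | artifact pick | peptides | per-cell noise
  k_true <- numeric(n_prot)
  k_true[classes == "secreted"] <- .draw_k(config$k_secreted, config$n_secreted)
  k_true[classes == "leaked"] <- .draw_k(config$k_leaked, config$n_leaked)
  k_true[classes == "regulated"] <- .draw_k(config$k_regulated, config$n_regulated)
  A0 <- stats::rlnorm(n_prot, config$base_abundance_meanlog,
                      config$base_abundance_sdlog)
  d_score <- ifelse(classes == "secreted",
                    stats::rbeta(n_prot, 8, 2), stats::rbeta(n_prot, 2, 8))
  n_art <- round(config$artifact_fraction * n_prot)
  is_artifact <- rep(FALSE, n_prot)
  if (n_art > 0) is_artifact[sample.int(n_prot, n_art)] <- TRUE

  sdlog_pep <- sqrt(log(1 + config$intensity_cv^2))
  sdlog_meas <- sqrt(log(1 + config$measurement_cv^2))
  rows <- vector("list", n_prot)
  truth_ab <- matrix(NA_real_, n_prot, length(tp))
  for (i in seq_len(n_prot)) {
    peps <- .random_peptides(config$peptides_per_protein)
    A_t <- .true_abundance(classes[i], A0[i], tp, config$leaked_decline)
    truth_ab[i, ] <- A_t
    npep <- config$peptides_per_protein
    nt <- length(tp)
    r_true <- rep(model_ria(k_true[i], tp), each = npep)
    resp <- stats::rlnorm(npep, -sdlog_pep^2 / 2, sdlog_pep)  # per peptide
    eps <- rep(resp, times = nt) *
      stats::rlnorm(npep * nt, -sdlog_meas^2 / 2, sdlog_meas)
    A_cell <- rep(A_t, each = npep) * eps
    if (is_artifact[i]) {
      h <- A_cell
      l <- rep(NA_real_, npep * nt)
    } else {
      r_noisy <- pmin(pmax(r_true + stats::rnorm(npep * nt, 0,
                                                 config$ria_noise_sd), 0), 1)
      h <- r_noisy * A_cell
      l <- (1 - r_noisy) * A_cell
      drop_h <- stats::runif(npep * nt) < config$dropout_rate
      drop_l <- stats::runif(npep * nt) < config$dropout_rate
      h[drop_h] <- NA_real_
      l[drop_l] <- NA_real_
      # a channel whose noisy RIA clipped to the boundary was never
      # detected: absent, not a measured zero
      h[!is.na(h) & h == 0] <- NA_real_
      l[!is.na(l) & l == 0] <- NA_real_
    }
    rows[[i]] <- data.frame(
      peptide_sequence = rep(peps, times = nt),
      protein_group = acc[i],
      protein_accession = acc[i],
      is_shared = FALSE,
      heavy_intensity = h,
      light_intensity = l,
      missed_cleavages = 0L,
      is_contaminant = FALSE,
      is_reverse = FALSE,
      time_point = rep(tp, each = npep),
      sample_id = config$sample_id,
      stringsAsFactors = FALSE
    )
  }
  evidence <- do.call(rbind, rows)
  # fully dropped-out features never appear in an evidence file
  evidence <- evidence[!(is.na(evidence$heavy_intensity) &
                           is.na(evidence$light_intensity)), , drop = FALSE]
  rownames(evidence) <- NULL

  truth <- data.frame(protein_accession = acc, class = classes,
                      true_k = k_true, is_artifact = is_artifact,
                      d_score = d_score, A0 = A0, stringsAsFactors = FALSE)
  colnames(truth_ab) <- paste0("A_", tp)
  truth <- cbind(truth, as.data.frame(truth_ab))

  signalp <- data.frame(protein_accession = acc, d_score = d_score,
                        has_tm_domain = NA, stringsAsFactors = FALSE)
  run_map <- data.frame(run_label = paste0(config$sample_id, "_t", tp),
                        sample_id = config$sample_id, time_point = tp,
                        stringsAsFactors = FALSE)
  list(evidence = evidence, signalp = signalp, truth = truth,
       run_map = run_map,
       design = experiment_design(time_points = tp))
}

#' Write evidence in the MaxQuant column dialect
#'
#' Serialises an internal evidence data frame as a tab-delimited table with
#' the configured (default MaxQuant 1.5.x) headers, the exact format
#' [load_evidence()] reads back. Absent intensities are written as 0 (the
#' MaxQuant convention), flags as `"+"`/empty, and the raw-file label as
#' `<sample>_t<time>`.
#'
#' @param evidence Internal-schema evidence data frame.
#' @param path Output path.
#' @param dialect Column dialect ([evidence_dialect()]).
#' @return Invisibly, the run map implied by the written raw-file labels.
#' @export
write_evidence_tsv <- function(evidence, path, dialect = evidence_dialect()) {
  out <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
    a = evidence$peptide_sequence,
    b = evidence$protein_group,
    c = ifelse(is.na(evidence$heavy_intensity), 0, evidence$heavy_intensity),
    d = ifelse(is.na(evidence$light_intensity), 0, evidence$light_intensity),
    e = evidence$missed_cleavages,
    f = ifelse(evidence$is_contaminant, "+", ""),
    g = ifelse(evidence$is_reverse, "+", ""),
    h = paste0(evidence$sample_id, "_t", evidence$time_point))
  names(out) <- unname(dialect[c("sequence", "proteins", "heavy", "light",
                                 "missed_cleavages", "contaminant", "reverse",
                                 "raw_file")])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  um <- unique(data.frame(run_label = paste0(evidence$sample_id, "_t",
                                             evidence$time_point),
                          sample_id = evidence$sample_id,
                          time_point = evidence$time_point,
                          stringsAsFactors = FALSE))
  invisible(um[order(um$sample_id, um$time_point), , drop = FALSE])
}

#' Miniature deterministic fixture exercising every filter branch
#'
#' Hand-constructed 11-protein evidence table (one sample, 26 rows) in
#' which each protein triggers exactly one pipeline branch: a contaminant,
#' a reverse hit, a mis-cleaved peptide, a two-lysine peptide, an
#' arginine-terminated (identification-only) peptide, a two-point
#' trajectory, a trajectory missing the late points, an impossible
#' (early > late) profile, an instant-plateau artifact, and two clean
#' proteins — one secreted-like (k = 0.2/h, rising abundance, d = 0.92)
#' and one leaked-like (k = 0.005/h, declining abundance, d = 0.08) — that
#' alone survive to unflagged kinetic fitting. The `expected` element holds
#' the hand-enumerated filter tally, per-trajectory statuses and fitted
#' rate constants the pipeline must reproduce.
#'
#' @return List with `evidence`, `signalp`, `run_map`,
#'   `design` ([experiment_design()]) and `expected`.
#' @examples
#' toy <- make_toy_fixture()
#' filter_psms(toy$evidence, toy$design)$tally
#' @export
make_toy_fixture <- function() {
  design <- experiment_design()
  s <- "TOY"
  row <- function(pep, acc, t, h, l, mc = 0L, cont = FALSE, rev = FALSE) {
    data.frame(peptide_sequence = pep, protein_group = acc,
               protein_accession = acc, is_shared = FALSE,
               heavy_intensity = h, light_intensity = l,
               missed_cleavages = mc, is_contaminant = cont,
               is_reverse = rev, time_point = t, sample_id = s,
               stringsAsFactors = FALSE)
  }
  # clean trajectories: H = RIA * A, L = (1 - RIA) * A at abundance A
  sec_t <- design$time_points
  sec_r <- model_ria(0.2, sec_t)
  sec_A <- 1e6 * sec_t / 24
  leak_r <- model_ria(0.005, sec_t)
  leak_A <- 8e5 * (1 - 0.2 * sec_t / 24)
  imp_r <- c(0.8, 0.4, 0.5); imp_t <- c(0.5, 6, 24); imp_A <- 5e5
  art_r <- c(0.95, 0.96, 0.97); art_t <- c(0.5, 6, 24); art_A <- 4e5
  ev <- rbind(
    row("AAACONTK", "P_CONT", 6, 100, 900, cont = TRUE),
    row("AAAREVK", "P_REV", 6, 100, 900, rev = TRUE),
    row("AAAMISSK", "P_MISS", 6, 100, 900, mc = 1L),
    row("AADKDDK", "P_TWOK", 6, 100, 900),
    row("AAADDR", "P_ARG", 6, 250, 750),
    row("AAAFEWK", "P_FEW", 6, 300, 700),
    row("AAAFEWK", "P_FEW", 24, 600, 400),
    row("AANOLATEK", "P_NOLATE", 0.5, 50, 950),
    row("AANOLATEK", "P_NOLATE", 1, 80, 920),
    row("AANOLATEK", "P_NOLATE", 2, 150, 850),
    row("AAAIMPK", "P_IMP", imp_t, imp_r * imp_A, (1 - imp_r) * imp_A),
    row("AAAARTK", "P_ART", art_t, art_r * art_A, (1 - art_r) * art_A),
    row("AAASECK", "P_SEC", sec_t, sec_r * sec_A, (1 - sec_r) * sec_A),
    row("AALEAQK", "P_LEAK", sec_t, leak_r * leak_A, (1 - leak_r) * leak_A)
  )
  rownames(ev) <- NULL
  signalp <- data.frame(
    protein_accession = c("P_CONT", "P_REV", "P_MISS", "P_TWOK", "P_ARG",
                          "P_FEW", "P_NOLATE", "P_IMP", "P_ART", "P_SEC",
                          "P_LEAK"),
    d_score = c(0.10, 0.10, 0.10, 0.10, 0.55, 0.60, 0.30, 0.70, 0.12,
                0.92, 0.08),
    has_tm_domain = NA, stringsAsFactors = FALSE)
  run_map <- data.frame(run_label = paste0(s, "_t", design$time_points),
                        sample_id = s, time_point = design$time_points,
                        stringsAsFactors = FALSE)
  expected <- list(
    tally = c(n_input = 26L, removed_contaminant = 1L, removed_reverse = 1L,
              removed_missed_cleavage = 1L, removed_multi_label_site = 1L,
              identification_only = 1L, kinetic = 21L),
    status = c(P_FEW = "TOO_FEW_POINTS", P_NOLATE = "MISSING_LATE_POINTS",
               P_IMP = "IMPOSSIBLE_PROFILE", P_ART = "PASS", P_SEC = "PASS",
               P_LEAK = "PASS"),
    artifact_flagged = "P_ART",
    n_unflagged_fitted = 2L,
    k = c(P_SEC = 0.2, P_LEAK = 0.005)
  )
  list(evidence = ev, signalp = signalp, run_map = run_map, design = design,
       expected = expected)
}
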