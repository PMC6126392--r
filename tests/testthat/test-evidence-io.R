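test_that("load_evidence maps runs to time points and parses flags and missing intensities", {
  design <- experiment_design()
  path <- tempfile(fileext = ".txt")
  writeLines(c(
    paste("Sequence", "Proteins", "Intensity H", "Intensity L",
          "Missed cleavages", "Potential contaminant", "Reverse", "Raw file",
          sep = "\t"),
    "SQNPVQPIGPQTPK\tMMP1_HUMAN\t100\t900\t0\t\t\tt0.5",
    "SQNPVQPIGPQTPK\tMMP1_HUMAN\t600\t400\t0\t\t\tt6",
    "AAAAAK\tCON__P123\t0\t500\t0\t+\t\tt24"
  ), path)
  rm <- data.frame(run_label = c("t0.5", "t6", "t24"), sample_id = "CAM",
                   time_point = c(0.5, 6, 24))
  ev <- load_evidence(path, design, rm)
  expect_equal(nrow(ev), 3L)
  expect_equal(ev$time_point, c(0.5, 6, 24))
  expect_equal(ev$is_contaminant, c(FALSE, FALSE, TRUE))
  # "0" intensity means not quantified, never a measured zero
  expect_true(is.na(ev$heavy_intensity[3]))
  expect_equal(ev$light_intensity[3], 500)
})

test_that("load_evidence skips unmapped runs with a warning and fails on missing columns", {
  design <- experiment_design()
  path <- tempfile(fileext = ".txt")
  writeLines(c(
    paste("Sequence", "Proteins", "Intensity H", "Intensity L",
          "Missed cleavages", "Potential contaminant", "Reverse", "Raw file",
          sep = "\t"),
    "AAAK\tP1\t10\t20\t0\t\t\tt6",
    "AAAK\tP1\t10\t20\t0\t\t\tmystery_run"
  ), path)
  rm <- data.frame(run_label = "t6", sample_id = "S", time_point = 6)
  expect_warning(ev <- load_evidence(path, design, rm), "mystery_run")
  expect_equal(nrow(ev), 1L)

  path2 <- tempfile(fileext = ".txt")
  writeLines(c("Sequence\tProteins", "AAAK\tP1"), path2)
  expect_error(load_evidence(path2, design, rm), "Intensity H")
})

test_that("filter_psms applies the cascade in order and accounts for every row", {
  toy <- make_toy_fixture()
  f <- filter_psms(toy$evidence, toy$design)
  expect_equal(f$tally, toy$expected$tally)
  # every input row lands in exactly one bucket
  expect_equal(sum(f$tally[-1]), f$tally[["n_input"]])
  # the MMP1 exemplar peptide is kinetic-grade
  ev1 <- toy$evidence[1, ]
  ev1$peptide_sequence <- "SQNPVQPIGPQTPK"
  ev1$is_contaminant <- FALSE
  f1 <- filter_psms(ev1, toy$design)
  expect_equal(unname(f1$tally[["kinetic"]]), 1L)
  # two-lysine and lysine-free peptides route correctly
  expect_false("P_TWOK" %in% f$kinetic$protein_accession)
  expect_identical(f$identification$protein_accession, "P_ARG")
})

test_that("filter_psms is idempotent and handles empty input", {
  toy <- make_toy_fixture()
  f1 <- filter_psms(toy$evidence, toy$design)
  f2 <- filter_psms(f1$kinetic, toy$design)
  expect_equal(f2$kinetic, f1$kinetic, ignore_attr = TRUE)
  expect_equal(unname(f2$tally[["kinetic"]]), unname(f1$tally[["kinetic"]]))

  f0 <- filter_psms(toy$evidence[0, ], toy$design)
  expect_equal(unname(f0$tally), rep(0L, 7L))
  expect_equal(nrow(f0$kinetic), 0L)
})

test_that("evidence written in the MaxQuant dialect round-trips through load_evidence", {
  sim <- simulate_secretome(simulation_config(n_secreted = 3, n_leaked = 3,
                                              n_regulated = 1, seed = 11))
  path <- tempfile(fileext = ".txt")
  rm <- write_evidence_tsv(sim$evidence, path)
  back <- load_evidence(path, sim$design, rm)
  ord <- function(d) {
    d <- d[order(d$protein_accession, d$peptide_sequence, d$time_point), ]
    rownames(d) <- NULL
    d
  }
  a <- ord(sim$evidence); b <- ord(back)
  for (col in names(a)) expect_equal(b[[col]], a[[col]], label = col)
})

test_that("load_signalp validates scores and deduplicates accessions", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("accession\td_score", "MMP1_HUMAN\t0.9", "TBB3_HUMAN\t0.1",
               "MMP1_HUMAN\t0.4"), p)
  expect_warning(sp <- load_signalp(p), "duplicate")
  expect_equal(nrow(sp), 2L)
  expect_equal(sp$d_score[sp$protein_accession == "MMP1_HUMAN"], 0.9)

  p2 <- tempfile(fileext = ".tsv")
  writeLines(c("accession\td_score", "A\t0.3", "B\t1.2"), p2)
  expect_error(load_signalp(p2), "row 2")
})

test_that("protein report is deterministic, byte-identical, and header-complete", {
  toy <- make_toy_fixture()
  res <- sidls(toy$evidence, toy$signalp, toy$design)
  f1 <- tempfile(); f2 <- tempfile()
  write_protein_report(res$records, f1)
  write_protein_report(res$records, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_length(readLines(f1), nrow(res$records) + 1L)

  f0 <- tempfile()
  write_protein_report(res$records[0, ], f0)
  expect_length(readLines(f0), 1L)
})

test_that("the packaged fixture files reproduce the in-code toy fixture", {
  toy <- make_toy_fixture()
  ev_path <- system.file("extdata", "toy_evidence.txt", package = "sidls")
  rm_path <- system.file("extdata", "toy_run_map.tsv", package = "sidls")
  sp_path <- system.file("extdata", "toy_signalp.tsv", package = "sidls")
  ex_path <- system.file("extdata", "toy_expected.json", package = "sidls")
  ev <- load_evidence(ev_path, toy$design, read.delim(rm_path))
  expect_equal(filter_psms(ev, toy$design)$tally, toy$expected$tally)
  sp <- load_signalp(sp_path)
  expect_equal(sp$d_score, toy$signalp$d_score)
  exp <- jsonlite::read_json(ex_path)
  expect_equal(unlist(exp$tally), toy$expected$tally)
})
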