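test_that("compute_ria is H/(H+L) with a strict missing-value contract", {
  expect_equal(compute_ria(0, 1000), 0)
  expect_equal(compute_ria(500, 500), 0.5)
  expect_equal(compute_ria(900, 100), 0.9)
  expect_true(is.na(compute_ria(NA, 500)))
  expect_true(is.na(compute_ria(0, 0)))
  # requant-style absent-as-zero mode
  expect_equal(compute_ria(NA, 500, absent_as_zero = TRUE), 0)
  expect_equal(compute_ria(500, NA, absent_as_zero = TRUE), 1)
  expect_error(compute_ria(-1, 10), "negative")
})

test_that("RIA is scale-invariant and always within [0, 1]", {
  set.seed(1)
  h <- runif(200, 0, 1e6); l <- runif(200, 0, 1e6)
  r <- compute_ria(h, l)
  expect_true(all(r >= 0 & r <= 1))
  for (s in c(1e-3, 7, 1e4)) expect_equal(compute_ria(s * h, s * l), r)
})

test_that("build_trajectories merges charge states by summing intensities first", {
  ev <- data.frame(
    peptide_sequence = "AAAK", protein_group = "P1", protein_accession = "P1",
    is_shared = FALSE,
    heavy_intensity = c(100, 300), light_intensity = c(900, 700),
    missed_cleavages = 0L, is_contaminant = FALSE, is_reverse = FALSE,
    time_point = 6, sample_id = "S", stringsAsFactors = FALSE)
  tr <- build_trajectories(ev)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$ria, 400 / 2000)  # sum-then-ratio, not mean of ratios
  expect_equal(tr$heavy_intensity, 400)
})

test_that("trajectory filters assign exactly one status, in the documented order", {
  design <- experiment_design()
  mk <- function(t, r, pep = "AAAK") data.frame(
    sample_id = "S", protein_accession = "P", peptide_sequence = pep,
    is_shared = FALSE, time_point = t, heavy_intensity = r * 1000,
    light_intensity = (1 - r) * 1000, both_channels = TRUE, ria = r,
    stringsAsFactors = FALSE)

  st <- apply_trajectory_filters(mk(c(0.5, 6, 24), c(0.05, 0.6, 0.95)), design)
  expect_equal(st$filter_status, "PASS")
  st <- apply_trajectory_filters(mk(c(6, 24), c(0.6, 0.9)), design)
  expect_equal(st$filter_status, "TOO_FEW_POINTS")
  st <- apply_trajectory_filters(mk(c(0.5, 1, 2), c(0.1, 0.2, 0.3)), design)
  expect_equal(st$filter_status, "MISSING_LATE_POINTS")
  st <- apply_trajectory_filters(mk(c(0.5, 6, 24), c(0.8, 0.4, 0.5)), design)
  expect_equal(st$filter_status, "IMPOSSIBLE_PROFILE")
  # epsilon admits small early/late inversions
  st <- apply_trajectory_filters(mk(c(0.5, 6, 24), c(0.45, 0.44, 0.9)),
                                 design, epsilon = 0.05)
  expect_equal(st$filter_status, "PASS")
})

test_that("every random trajectory receives exactly one status (filter order is total)", {
  design <- experiment_design()
  set.seed(99)
  for (i in 1:50) {
    t_obs <- sort(sample(design$time_points, sample(1:5, 1)))
    df <- data.frame(sample_id = "S", protein_accession = "P",
                     peptide_sequence = "AAAK", is_shared = FALSE,
                     time_point = t_obs, heavy_intensity = 1,
                     light_intensity = 1, both_channels = TRUE,
                     ria = runif(length(t_obs)), stringsAsFactors = FALSE)
    st <- apply_trajectory_filters(df, design)
    expect_equal(nrow(st), 1L)
    expect_true(st$filter_status %in% c("PASS", "TOO_FEW_POINTS",
                                        "MISSING_LATE_POINTS",
                                        "IMPOSSIBLE_PROFILE"))
  }
})

test_that("a PASS trajectory keeps PASS when a non-check point is removed", {
  design <- experiment_design()
  r <- 1 - exp(-0.15 * design$time_points)
  full <- data.frame(sample_id = "S", protein_accession = "P",
                     peptide_sequence = "AAAK", is_shared = FALSE,
                     time_point = design$time_points, heavy_intensity = 1,
                     light_intensity = 1, both_channels = TRUE, ria = r,
                     stringsAsFactors = FALSE)
  expect_equal(apply_trajectory_filters(full, design)$filter_status, "PASS")
  drop2h <- full[full$time_point != 2, ]  # 2 h is in neither check set
  expect_equal(apply_trajectory_filters(drop2h, design)$filter_status, "PASS")
})

test_that("RIA densities are located correctly and integrate to ~1 on [0, 1]", {
  design <- experiment_design()
  mk_prot <- function(acc, pep, r24) data.frame(
    sample_id = "S", protein_accession = acc, peptide_sequence = pep,
    is_shared = FALSE, time_point = c(0.5, 6, 24),
    heavy_intensity = 1, light_intensity = 1, both_channels = TRUE,
    ria = c(r24 * 0.05, r24 * 0.6, r24), stringsAsFactors = FALSE)
  pts <- do.call(rbind, c(
    lapply(1:6, function(i) mk_prot(paste0("SEC", i), paste0("AS", i, "K"),
                                    0.95 + 0.005 * i)),
    lapply(1:6, function(i) mk_prot(paste0("LEK", i), paste0("AL", i, "K"),
                                    0.10 + 0.005 * i))))
  st <- apply_trajectory_filters(pts, design)
  sp <- data.frame(protein_accession = c(paste0("SEC", 1:6), paste0("LEK", 1:6)),
                   d_score = rep(c(0.9, 0.1), each = 6),
                   stringsAsFactors = FALSE)
  dd <- ria_density_by_class(pts, st, sp, time_point = 24)
  for (cl in c("SECRETED", "NOT_SECRETED")) {
    di <- dd[dd$class == cl, ]
    integral <- sum(diff(di$ria) * (head(di$density, -1) + tail(di$density, -1)) / 2)
    expect_lt(abs(integral - 1), 0.01)
  }
  # secreted mass sits above 0.9, leaked mass below 0.25
  sec <- dd[dd$class == "SECRETED", ]
  expect_gt(sum(sec$density[sec$ria > 0.9]) / sum(sec$density), 0.8)
  lek <- dd[dd$class == "NOT_SECRETED", ]
  expect_gt(sum(lek$density[lek$ria < 0.25]) / sum(lek$density), 0.8)
})

test_that("a class with too few points yields an empty curve with a warning", {
  design <- experiment_design()
  pts <- data.frame(sample_id = "S", protein_accession = "SEC1",
                    peptide_sequence = rep(c("AAAK", "CCCK"), each = 3),
                    is_shared = FALSE,
                    time_point = rep(c(0.5, 6, 24), 2), heavy_intensity = 1,
                    light_intensity = 1, both_channels = TRUE,
                    ria = rep(c(0.1, 0.6, 0.95), 2), stringsAsFactors = FALSE)
  st <- apply_trajectory_filters(pts, design)
  sp <- data.frame(protein_accession = "SEC1", d_score = 0.9)
  expect_warning(dd <- ria_density_by_class(pts, st, sp, 24), "NOT_SECRETED")
  expect_false("NOT_SECRETED" %in% dd$class)
})
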