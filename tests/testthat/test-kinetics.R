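test_that("model_ria follows the closed form with correct boundaries", {
  expect_equal(model_ria(0, 17), 0)
  expect_equal(model_ria(0.3, 0), 0)
  expect_equal(model_ria(0.1, 24), 1 - exp(-2.4))
  expect_error(model_ria(-0.1, 1), "non-negative")
  expect_error(model_ria(0.1, -1), "non-negative")
  # strictly increasing in t (k>0) and in k (t>0), bounded in [0, 1)
  t <- seq(0.1, 24, length.out = 50)
  expect_true(all(diff(model_ria(0.2, t)) > 0))
  k <- seq(0.001, 2, length.out = 50)
  expect_true(all(diff(model_ria(k, 6)) > 0))
  expect_true(all(model_ria(k, 24) >= 0 & model_ria(k, 24) <= 1))
  expect_true(all(model_ria(k, 6) < 1))
})

test_that("fit_k recovers the generating rate exactly on noiseless data", {
  t <- c(0.5, 1, 2, 6, 24)
  for (k_true in c(0.005, 0.058, 0.274, 1.5)) {
    fit <- fit_k(t, model_ria(k_true, t))
    expect_true(fit$converged)
    expect_lt(abs(fit$k - k_true) / k_true, 1e-6)
    expect_equal(fit$n_points, 5L)
  }
})

test_that("fit_k enforces preconditions and handles the zero boundary", {
  expect_error(fit_k(c(6, 24), c(0.1, 0.2)), "3")
  expect_error(fit_k(c(0, 6, 24), c(0, 0.1, 0.2)), "> 0")
  expect_error(fit_k(c(1, 6, 24), c(0.1, 0.2, 1.4)), "\\[0, 1\\]")
  f0 <- fit_k(c(0.5, 6, 24), c(0, 0, 0))
  expect_equal(f0$k, 0)
  expect_true(f0$converged)
  expect_equal(f0$rss, 0)
})

test_that("fit_k matches the dense grid-search oracle on noisy data", {
  set.seed(7)
  t <- c(0.5, 1, 2, 6, 24)
  for (i in 1:10) {
    k_true <- exp(runif(1, log(0.02), log(0.5)))
    r <- pmin(pmax(model_ria(k_true, t) + rnorm(5, 0, 0.02), 0), 1)
    fit <- fit_k(t, r)
    k_grid <- grid_k_oracle(t, r)
    expect_lt(abs(fit$k - k_grid), 1e-4 + 1e-9)
  }
})

test_that("ria_fit methods are coherent", {
  t <- c(0.5, 1, 2, 6, 24)
  fit <- fit_k(t, model_ria(0.2, t))
  expect_s3_class(fit, "ria_fit")
  expect_named(coef(fit), "k")
  expect_equal(predict(fit, data.frame(time = 24)), model_ria(fit$k, 24))
  expect_equal(residuals(fit), model_ria(0.2, t) - predict(fit),
               tolerance = 1e-8)
  s <- summary(fit)
  expect_equal(s$half_life_h, log(2) / fit$k)
  expect_output(print(fit), "per hour")
})

test_that("pooled fits equal single fits under duplication and bracket mixtures", {
  t <- c(0.5, 1, 2, 6, 24)
  r <- model_ria(0.12, t) + c(0.01, -0.01, 0.02, -0.02, 0.005)
  one <- fit_k(t, r)
  five <- fit_k(rep(t, 5), rep(r, 5))
  expect_equal(five$k, one$k, tolerance = 1e-8)

  # pooled fit of two noiseless peptides lies between their rates and
  # matches the grid oracle on the pooled points
  r1 <- model_ria(0.1, t); r2 <- model_ria(0.3, t)
  pooled <- fit_k(c(t, t), c(r1, r2))
  expect_gt(pooled$k, 0.1); expect_lt(pooled$k, 0.3)
  expect_lt(abs(pooled$k - grid_k_oracle(c(t, t), c(r1, r2))), 1e-4 + 1e-9)
})

test_that("protein-level fits pool PASS trajectories and skip shared peptides", {
  design <- experiment_design()
  mk <- function(pep, r, shared = FALSE) data.frame(
    sample_id = "S", protein_accession = "P1", peptide_sequence = pep,
    is_shared = shared, time_point = design$time_points,
    heavy_intensity = r * 1000, light_intensity = (1 - r) * 1000,
    both_channels = TRUE, ria = r, stringsAsFactors = FALSE)
  r <- model_ria(0.2, design$time_points)
  pts <- rbind(mk("AAAK", r), mk("CCCK", r), mk("DDDK", model_ria(3, design$time_points), shared = TRUE))
  st <- apply_trajectory_filters(pts, design)
  fit <- fit_protein_k(pts, st)
  expect_equal(fit$level, "PROTEIN")
  # identical trajectories pool to the same k; the shared peptide is ignored
  expect_equal(fit$k, 0.2, tolerance = 1e-6)

  # a protein with no PASS trajectory is excluded
  few <- mk("AAAK", r)[1:2, ]
  st2 <- apply_trajectory_filters(few, design)
  expect_null(fit_protein_k(few, st2))
})

test_that("class-level combined fits pool member proteins and flag empty classes", {
  design <- experiment_design()
  mk <- function(acc, pep, k) data.frame(
    sample_id = "S", protein_accession = acc, peptide_sequence = pep,
    is_shared = FALSE, time_point = design$time_points,
    heavy_intensity = 1000 * model_ria(k, design$time_points),
    light_intensity = 1000 * (1 - model_ria(k, design$time_points)),
    both_channels = TRUE, ria = model_ria(k, design$time_points),
    stringsAsFactors = FALSE)
  pts <- rbind(mk("A", "AAAK", 0.2), mk("B", "CCCK", 0.2))
  st <- apply_trajectory_filters(pts, design)
  cf <- fit_class_k(pts, st, c("A", "B"))
  expect_equal(cf$level, "CLASS")
  expect_equal(cf$k, 0.2, tolerance = 1e-6)
  # class of one protein equals that protein's pooled fit
  one <- fit_class_k(pts, st, "A")
  expect_equal(one$k, fit_protein_k(pts[pts$protein_accession == "A", ],
                                    st[st$protein_accession == "A", ])$k)
  expect_warning(expect_null(fit_class_k(pts, st, "ZZZ")), "empty class")
})

test_that("random-rate property: exact recovery across k in [0.001, 2]", {
  set.seed(31)
  t <- c(0.5, 1, 2, 6, 24)
  ks <- exp(runif(25, log(0.001), log(2)))
  for (k_true in ks) {
    fit <- fit_k(t, model_ria(k_true, t))
    expect_lt(abs(fit$k - k_true) / k_true, 1e-6)
  }
})

test_that("instant-plateau and single-channel profiles are flagged as artifacts", {
  mk <- function(t, r, both = TRUE) data.frame(
    sample_id = "S", protein_accession = "P", peptide_sequence = "AAAK",
    is_shared = FALSE, time_point = t, heavy_intensity = r * 100,
    light_intensity = (1 - r) * 100, both_channels = both, ria = r,
    stringsAsFactors = FALSE)
  expect_true(flag_artifact_profiles(mk(c(0.5, 6, 24), c(0.95, 0.96, 0.97))))
  expect_false(flag_artifact_profiles(mk(c(0.5, 6, 24), c(0.05, 0.6, 0.95))))
  # a moderate plateau below the absolute floor is not flagged
  expect_false(flag_artifact_profiles(mk(c(0.5, 6, 24), c(0.30, 0.31, 0.32))))
  # all-points single-channel evidence is flagged regardless of shape
  sc <- mk(c(0.5, 6, 24), c(0.1, 0.5, 0.9), both = FALSE)
  expect_true(flag_artifact_profiles(sc))
})
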