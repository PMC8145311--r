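test_that("simulation is byte-identical for a fixed seed", {
  p <- synth_params(n_a = 3, n_b = 3, mz_lo = 400, mz_hi = 599,
                    n_discriminatory = 10, peak_density = 0.2, seed = 42)
  s1 <- simulate_cohort(p)
  s2 <- simulate_cohort(p)
  expect_identical(s1$metadata, s2$metadata)
  expect_identical(lapply(s1$spectra, `[[`, "intensities"),
                   lapply(s2$spectra, `[[`, "intensities"))
  s3 <- simulate_cohort(p, seed = 43)
  expect_false(identical(s1$spectra[[1]]$intensities,
                         s3$spectra[[1]]$intensities))
})

test_that("presets encode the study regimes and reject unknown names", {
  p <- preset("mildAD_vs_control_iontrap")
  expect_equal(p$n_a, 15L)
  expect_equal(p$n_b, 14L)
  expect_equal(p$n_discriminatory, 100L)
  expect_equal(p$effect_delta, 2)
  expect_equal(c(p$mz_lo, p$mz_hi), c(400L, 2000L))
  expect_equal(p$n_replicates, 3L)
  expect_equal(preset("moderateAD_vs_control_iontrap")$n_a, 16L)
  expect_equal(preset("null")$effect_delta, 0)
  expect_error(preset("nope"), "available")
  # all presets satisfy the parameter invariants (constructor validates)
  for (nm in c("mildAD_vs_control_iontrap", "moderateAD_vs_control_iontrap",
               "null"))
    expect_s3_class(preset(nm), "synth_params")
})

test_that("parameter invariants are enforced", {
  expect_error(synth_params(n_discriminatory = 10000), "exceeds")
  expect_error(synth_params(effect_delta = -1), ">= 0")
  expect_error(synth_params(n_a = 1), ">= 2")
  expect_error(synth_params(peak_density = 0.9), "peak_density")
})

test_that("generator moments match the log-normal model within 3 standard errors", {
  p <- synth_params(n_a = 500, n_b = 500, mz_lo = 400, mz_hi = 479,
                    n_discriminatory = 0, effect_delta = 0,
                    baseline_log_mean = log(30), baseline_log_sd = 0.8,
                    sample_cv = 0.25, replicate_cv = 0, n_replicates = 1,
                    peak_density = 0.25, seed = 314)
  sim <- simulate_cohort(p)
  bin <- sim$signal_mz[3] - p$mz_lo + 1
  logs <- log(vapply(sim$spectra, function(s) s$intensities[bin], numeric(1)))
  s_samp <- sqrt(log(1 + 0.25^2))
  n <- length(logs)                      # 1000 samples
  # per-bin log-mean mu_j is itself drawn from N(log 30, 0.8); recover it
  # as the empirical center and test the sample-level spread around it
  expect_lt(abs(sd(logs) - s_samp), 3 * s_samp / sqrt(2 * (n - 1)))
  expect_lt(abs(mean(logs) - log(30)), 3 * 0.8)  # mu_j within its own prior
})

test_that("replicate noise is mean-one so replicate averaging is unbiased", {
  p <- synth_params(n_a = 2, n_b = 2, mz_lo = 400, mz_hi = 449,
                    n_discriminatory = 0, sample_cv = 0, replicate_cv = 0.2,
                    n_replicates = 400, peak_density = 0.2, seed = 5)
  sim <- simulate_cohort(p)
  reps <- sim$spectra[vapply(sim$spectra, function(s)
    s$sample_id == sim$metadata$sample_id[1], logical(1))]
  bin <- sim$signal_mz[1] - p$mz_lo + 1
  vals <- vapply(reps, function(s) s$intensities[bin], numeric(1))
  # replicate CV matches the requested coefficient of variation, and the
  # arithmetic and log-scale means obey the log-normal mean-one relation
  expect_lt(abs(sd(vals) / mean(vals) - 0.2), 0.03)
  s_rep <- sqrt(log(1 + 0.2^2))
  expect_lt(abs(log(mean(vals)) - mean(log(vals)) - s_rep^2 / 2), 0.02)
})

test_that("planted peaks are isolated single-bin peaks after centroiding", {
  sim <- simulate_cohort(synth_params(n_a = 2, n_b = 2, mz_lo = 400,
                                      mz_hi = 599, n_discriminatory = 5,
                                      peak_density = 0.2, seed = 10))
  expect_true(all(diff(sim$signal_mz) >= 2))
  sp <- segment_normalize(sim$spectra[[1]])
  pa <- centroid_areas(sp)
  expect_setequal(as.integer(names(pa)),
                  sim$signal_mz[sim$spectra[[1]]$intensities[
                    sim$signal_mz - 400 + 1] > 0])
})

test_that("pipeline-level group separation grows with the planted effect size", {
  d_at <- function(delta) {
    mean(vapply(1:3, function(s) {
      p <- synth_params(n_a = 8, n_b = 8, mz_lo = 400, mz_hi = 799,
                        n_discriminatory = 40, effect_delta = delta,
                        peak_density = 0.2, seed = s)
      cls <- run_loocv(as_cohort(simulate_cohort(p)))
      st <- welch_t(cls$pct_a[cls$true_group == "mildAD"],
                    cls$pct_a[cls$true_group == "control"])
      a <- cls$pct_a[cls$true_group == "mildAD"]
      b <- cls$pct_a[cls$true_group == "control"]
      cohens_d(mean(a), sd(a), mean(b), sd(b))
    }, numeric(1)))
  }
  ds <- vapply(c(0, 0.5, 1, 2), d_at, numeric(1))
  expect_true(all(diff(ds) > 0))
  expect_lt(abs(ds[1]), 1.5)     # null: small effect either sign
  expect_gt(ds[4], 4)            # strong planted effect
})

test_that("simulated cohorts round-trip through the on-disk TSV dialect", {
  sim <- simulate_cohort(synth_params(n_a = 2, n_b = 2, mz_lo = 400,
                                      mz_hi = 499, n_discriminatory = 4,
                                      peak_density = 0.2, seed = 77))
  d <- tempfile()
  write_synth_cohort(sim, d)
  spectra <- read_spectra_tsv(file.path(d, "spectra.tsv"))
  md <- read.delim(file.path(d, "metadata.tsv"))
  co1 <- build_cohort(spectra, md)
  co2 <- as_cohort(sim)
  expect_equal(co1$areas[rownames(co2$areas), colnames(co2$areas)],
               co2$areas, tolerance = 1e-6)
})
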