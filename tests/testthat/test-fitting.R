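test_that("mono-exponential fit round-trips noiseless data exactly", {
  b <- c(200, 500, 800, 1000)
  fit <- fit_monoexp(b, monoexp_signal(1, 1.6e-3, b))
  expect_equal(fit$intercept, 1, tolerance = 1e-9)
  expect_equal(fit$coef, 1.6e-3, tolerance = 1e-9)
  # constant signals: zero decay, intercept at the constant
  flat <- fit_monoexp(b, rep(3.5, 4))
  expect_equal(flat$coef, 0)
  expect_equal(flat$intercept, 3.5)
  expect_error(fit_monoexp(c(100, 100), c(1, 1)), "distinct")
  expect_error(fit_monoexp(b, c(1, 1, -1, 1)), "positive")
})

test_that("high-b mono-exponential fit attains the global optimum on bi-exponential input", {
  # noiseless two-compartment curve restricted to b >= 200: the fitted
  # decay tracks D closely (CZ-like D*) and the objective matches a dense
  # brute-force grid minimisation of the same SSE
  gt <- tissue_ground_truth(d = 1.211e-3, d_star = 13.443e-3, f = 0.1)
  b_hi <- b9[b9 >= 200]
  s_hi <- ivim_signal(gt, b_hi)
  fit <- fit_monoexp(b_hi, s_hi)
  expect_lt(abs(fit$coef - gt$d) / gt$d, 0.02)
  expect_lte(fit$rss, (1 + 1e-6) * grid_min_monoexp(b_hi, s_hi))
})

test_that("segmented fit collapses correctly for a pure mono-exponential curve", {
  s <- signal_series(proto9, 60, monoexp_signal(2, 1.5e-3, b9))
  fit <- segmented_fit(s)
  expect_lte(fit$f, 1e-6)
  expect_equal(fit$d, fit$adc, tolerance = 1e-6)
  expect_equal(fit$d, 1.5e-3, tolerance = 1e-6)
  expect_equal(fit$s0, 2)
})

test_that("segmented fit is sensitive to the b-value threshold", {
  gt <- gt_cz()
  s <- signal_series(proto9, 60, ivim_signal(gt, b9))
  fit200 <- segmented_fit(s, b_threshold = 200)
  fit500 <- segmented_fit(s, b_threshold = 500)
  # both thresholds keep D near truth, but not identically
  expect_lt(abs(fit200$d - gt$d) / gt$d, 0.02)
  expect_lt(abs(fit500$d - gt$d) / gt$d, 0.02)
  expect_false(isTRUE(all.equal(fit200$d, fit500$d)))
  expect_false(isTRUE(all.equal(fit200$f, fit500$f)))
})

test_that("the D* stage attains the global optimum of its bounded objective", {
  for (gt in list(gt_pz(), gt_cz())) {
    s <- signal_series(proto9, 60, ivim_signal(gt, b9))
    fit <- segmented_fit(s)
    lo <- b9 <= 200
    oracle <- grid_min_dstar(b9[lo], ivim_signal(gt, b9[lo]), fit$s0,
                             fit$f, fit$d)
    expect_lte(fit$diagnostics$rss_dstar, (1 + 1e-6) * oracle)
  }
})

test_that("per-TE segmented f rises with TE only when tissue T2 is shorter than blood T2", {
  tes <- c(60, 70, 80, 90, 100, 120)
  f_of_te <- function(gt) vapply(series_at_tes(gt, tes),
                                 function(s) segmented_fit(s)$f, 0)
  expect_true(all(diff(f_of_te(gt_cz())) > 0))
  expect_true(all(diff(f_of_te(gt_pz())) > 0))
  f_eq <- f_of_te(gt_cz(t2t = 275, t2b = 275))
  expect_equal(max(f_eq) - min(f_eq), 0, tolerance = 1e-9)
})

test_that("negative intercept fractions are clamped and flagged", {
  # rising low-b signal forces S0' above S0
  s <- signal_series(proto9, 60,
                     c(0.8, monoexp_signal(1, 1.5e-3, b9[-1])))
  fit <- segmented_fit(s)
  expect_equal(fit$f, 0)
  expect_true(fit$diagnostics$f_clamped)
  expect_false(fit$diagnostics$dstar_converged)
})

test_that("TE-corrected joint fit recovers the generating parameters from any TE subset", {
  gt <- tissue_ground_truth(s0 = 7, d = 1.4e-3, d_star = 11e-3, f = 0.11,
                            t2_tissue = 80, t2_blood = 275)
  for (tes in list(c(60, 70, 80, 90, 100, 120), c(60, 70, 80),
                   c(90, 100, 120), c(60, 90, 120))) {
    cf <- corrected_fit(series_at_tes(gt, tes))
    expect_true(cf$converged)
    expect_equal(cf$estimate$f, gt$f, tolerance = 1e-3)
    expect_equal(cf$estimate$t2_tissue, gt$t2_tissue, tolerance = 0.01 * 80)
    expect_equal(cf$estimate$d, gt$d, tolerance = 1e-3 * gt$d)
  }
  expect_error(corrected_fit(series_at_tes(gt, c(60, 90))), "3 distinct")
})

test_that("with equal compartment T2 the corrected fit returns the true fraction", {
  gt <- tissue_ground_truth(s0 = 2, d = 1.3e-3, d_star = 12e-3, f = 0.12,
                            t2_tissue = 180, t2_blood = 180)
  cf <- corrected_fit(series_at_tes(gt, c(60, 80, 100, 120)),
                      t2_blood_fixed = 180)
  expect_equal(cf$estimate$f, gt$f, tolerance = 1e-6)
  expect_equal(cf$estimate$t2_tissue, 180, tolerance = 1e-3)
})

test_that("fits are deterministic: identical input gives identical output", {
  gt <- gt_cz()
  s <- signal_series(proto9, 60, ivim_signal(gt, b9))
  expect_identical(segmented_fit(s), segmented_fit(s))
  sl <- series_at_tes(gt, c(60, 80, 100))
  expect_identical(corrected_fit(sl)$estimate, corrected_fit(sl)$estimate)
})

test_that("under Rician noise at SNR 20 diffusion estimates are precise and error spread orders ADC = D < f < D*", {
  cfg <- cohort_config(
    n_subjects = 1,
    zone_params = list(CZ = list(d = c(1.211e-3, 0),
                                 d_star = c(13.443e-3, 0),
                                 f = c(0.111, 0), t2_tissue = c(80, 0))),
    protocol = proto60, n_exams = 200, seed = 5)
  ds <- generate_dataset(cfg)
  fits <- fit_dataset(ds)
  gt <- ds$ground_truth
  g <- tissue_ground_truth(s0 = gt$s0, d = gt$d, d_star = gt$d_star,
                           f = gt$f, t2_tissue = gt$t2_tissue,
                           t2_blood = gt$t2_blood)
  adc_true <- 1e3 * fit_monoexp(b9, extended_ivim_signal(g, b9, 60))$coef
  rel <- function(est, tru) (est - tru) / tru
  err <- list(adc = rel(fits$adc, adc_true), d = rel(fits$d, 1e3 * gt$d),
              f = rel(fits$f, gt$f), ds = rel(fits$d_star, 1e3 * gt$d_star))
  expect_lt(median(abs(err$adc)), 0.05)
  expect_lt(median(abs(err$d)), 0.05)
  iqr <- vapply(err, stats::IQR, 0)
  # ADC and D are comparably tight; perfusion quantities are much looser
  expect_lt(max(iqr[["adc"]], iqr[["d"]]), iqr[["f"]])
  expect_lt(iqr[["f"]], iqr[["ds"]])
  expect_lt(abs(iqr[["adc"]] - iqr[["d"]]),
            iqr[["f"]] - max(iqr[["adc"]], iqr[["d"]]))
})
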