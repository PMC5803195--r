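# Runs expr with the global RNG seeded to `seed`, restoring any prior
# RNG state afterwards so callers' streams are not disturbed.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Truncated-normal draws by rejection sampling; errors out if the
# untruncated distribution puts almost no mass inside the bounds.
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) {
    if (mean < lower || mean > upper)
      stop("degenerate truncated normal: mean outside bounds")
    return(rep(mean, n))
  }
  mass <- stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd)
  if (mass < 1e-3)
    stop(sprintf(
      "infeasible truncation: N(%g, %g) has mass %.2g in [%g, %g]",
      mean, sd, mass, lower, upper))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Configuration of a synthetic multi-TE test-retest cohort
#'
#' Describes a virtual repeatability study: number of subjects, per-zone
#' generating distributions, noise level, SNR target and acquisition
#' protocol. Defaults reproduce the design of the multi-TE prostate study
#' this package models: 17 subjects, peripheral (PZ) and central (CZ)
#' zones, duplicate examinations, six echo times, nine b-values, four
#' signal averages, and zone parameter distributions centred on published
#' prostate values (PZ: D 1.568, D* 9.150 in 1e-3 mm^2/s, f 0.097, tissue
#' T2 136 ms; CZ: D 1.211, D* 13.443, f 0.111, tissue T2 80 ms; blood T2
#' 275 ms).
#'
#' @param n_subjects Number of subjects.
#' @param zone_params Named list (one entry per zone) of lists with
#'   elements `d`, `d_star`, `f`, `t2_tissue`, each `c(mean, sd)`
#'   (diffusivities in mm^2/s, T2 in ms).
#' @param t2_blood Blood T2 in ms, common to all subjects.
#' @param snr_at_b1000 Length-2 target range for the realised SNR at
#'   b = 1000 s/mm^2 and the shortest TE; signal amplitude is calibrated to
#'   its midpoint.
#' @param sigma Per-channel Gaussian noise SD before averaging (arbitrary
#'   units; 0 disables noise).
#' @param protocol An [acquisition_protocol()].
#' @param n_exams Repeat examinations per subject (default 2).
#' @param n_muscle_samples Pixels in the muscle noise-reference ROI.
#' @param seed Integer RNG seed.
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(
    n_subjects = 17,
    zone_params = list(
      PZ = list(d = c(1.568e-3, 0.187e-3), d_star = c(9.150e-3, 1.634e-3),
                f = c(0.097, 0.031), t2_tissue = c(136, 15)),
      CZ = list(d = c(1.211e-3, 0.125e-3), d_star = c(13.443e-3, 3.411e-3),
                f = c(0.111, 0.032), t2_tissue = c(80, 15))),
    t2_blood = 275,
    snr_at_b1000 = c(18, 21),
    sigma = 1,
    protocol = default_protocol(),
    n_exams = 2,
    n_muscle_samples = 1000,
    seed = 1) {
  stopifnot(inherits(protocol, "ivim_protocol"))
  if (n_subjects < 1 || n_exams < 1) stop("need >= 1 subject and exam")
  if (sigma < 0) stop("sigma must be non-negative")
  for (z in names(zone_params)) {
    zp <- zone_params[[z]]
    if (!all(c("d", "d_star", "f", "t2_tissue") %in% names(zp)))
      stop("zone_params entries need d, d_star, f, t2_tissue")
    if (any(vapply(zp, function(p) p[2] < 0, TRUE)))
      stop("zone parameter SDs must be non-negative")
  }
  if (length(snr_at_b1000) != 2 || any(snr_at_b1000 <= 0) ||
      diff(snr_at_b1000) < 0)
    stop("snr_at_b1000 must be a positive, non-decreasing range")
  structure(list(n_subjects = as.integer(n_subjects),
                 zone_params = zone_params, t2_blood = t2_blood,
                 snr_at_b1000 = snr_at_b1000, sigma = sigma,
                 protocol = protocol, n_exams = as.integer(n_exams),
                 n_muscle_samples = as.integer(n_muscle_samples),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# physiological truncation bounds used when drawing ground truth
.gt_bounds <- list(d = c(1e-4, 0.02), d_star = c(2e-3, 0.1),
                   f = c(0.02, 0.4), t2_tissue = c(20, 400))

#' Draw per-subject ground-truth tissue parameters
#'
#' Samples one [tissue_ground_truth()] parameter set per subject and zone
#' from truncated normal distributions (truncated to physiologically
#' plausible bounds that respect the model invariants, with D* further
#' bounded below by 1.5 D). Uses the global RNG stream; seed it (or call
#' through [generate_dataset()]) for reproducibility.
#'
#' @param config A [cohort_config()].
#' @return A data frame with columns `subject`, `zone`, `d`, `d_star`,
#'   `f`, `t2_tissue`, `t2_blood`.
#' @export
sample_ground_truth <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  rows <- list()
  for (subject in seq_len(config$n_subjects)) {
    for (zone in names(config$zone_params)) {
      zp <- config$zone_params[[zone]]
      d <- rtrunc_norm(1, zp$d[1], zp$d[2],
                       .gt_bounds$d[1], .gt_bounds$d[2])
      d_star <- rtrunc_norm(1, zp$d_star[1], zp$d_star[2],
                            max(.gt_bounds$d_star[1], 1.5 * d),
                            .gt_bounds$d_star[2])
      f <- rtrunc_norm(1, zp$f[1], zp$f[2],
                       .gt_bounds$f[1], .gt_bounds$f[2])
      t2t <- rtrunc_norm(1, zp$t2_tissue[1], zp$t2_tissue[2],
                         .gt_bounds$t2_tissue[1], .gt_bounds$t2_tissue[2])
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subject, zone = zone, d = d, d_star = d_star, f = f,
        t2_tissue = t2t, t2_blood = config$t2_blood)
    }
  }
  do.call(rbind, rows)
}

#' Rician-noised, averaged magnitude signal
#'
#' Each acquisition draws `sqrt((clean + g1)^2 + g2^2)` with g1, g2
#' independent zero-mean Gaussians of SD `sigma` (the magnitude of a
#' complex signal with Gaussian channel noise), and the returned value is
#' the arithmetic mean of `n_averages` such acquisitions — the noise model
#' of averaged magnitude DWI. `sigma = 0` returns `clean` unchanged.
#' Vectorised over `clean`; consumes the global RNG stream.
#'
#' @param clean Non-negative noise-free signal value(s).
#' @param sigma Per-channel noise SD (>= 0).
#' @param n_averages Number of averages (>= 1).
#' @return Noisy signal value(s), same length as `clean`.
#' @export
rician_noisy_signal <- function(clean, sigma, n_averages = 1) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (n_averages < 1) stop("n_averages must be >= 1")
  if (any(clean < 0)) stop("clean signal must be non-negative")
  if (sigma == 0) return(clean)
  n <- length(clean)
  g1 <- matrix(stats::rnorm(n * n_averages, 0, sigma), nrow = n)
  g2 <- matrix(stats::rnorm(n * n_averages, 0, sigma), nrow = n)
  rowMeans(sqrt((clean + g1)^2 + g2^2))
}

#' Generate a synthetic multi-TE test-retest dataset
#'
#' Builds the complete factorial design of a virtual repeatability study:
#' for every subject x zone x exam x TE cell, the noise-free decay curve of
#' the TE-extended IVIM model is computed from that subject's ground truth,
#' scaled so the noise-free SNR at b = 1000 s/mm^2 and the shortest TE hits
#' the midpoint of `config$snr_at_b1000` (SNR defined against the noise SD
#' of the averaged image, as estimated from a muscle reference ROI), and
#' Rician noise with `config$n_averages` averages is added. The two exams
#' are independent noise realisations of the same ground truth. A muscle
#' noise-reference region (constant baseline + the same noise process) is
#' generated per exam and TE for SNR estimation.
#'
#' Everything is drawn from an RNG stream seeded with `config$seed`, so
#' regeneration with the same configuration is bit-identical.
#'
#' @param config A [cohort_config()].
#' @return An object of class `ivim_dataset`: a list with `ground_truth`
#'   (per subject x zone, including the calibrated `s0`), `signals` (long
#'   data frame: subject, zone, exam, te_ms, b, clean, signal), `muscle`
#'   (exam, te_ms, signal), `sigma_image` (noise SD on the averaged image),
#'   `protocol`, `config` and `seed`.
#' @export
#' @examples
#' ds <- generate_dataset(cohort_config(n_subjects = 2, seed = 7))
#' nrow(ds$signals)
generate_dataset <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  proto <- config$protocol
  b <- proto$b_values
  tes <- proto$te_values
  te_ref <- tes[1]
  b_max <- b[length(b)]
  # noise SD on the n-average magnitude image (high-SNR approximation)
  sigma_image <- config$sigma / sqrt(proto$n_averages)
  snr_target <- mean(config$snr_at_b1000)

  with_local_seed(config$seed, {
    gt <- sample_ground_truth(config)
    # calibrate per-ROI s0 so the noise-free SNR at (b_max, shortest TE)
    # hits the target; with sigma = 0 signals are left on a unit scale
    rel <- vapply(seq_len(nrow(gt)), function(i) {
      g <- tissue_ground_truth(
        s0 = 1, d = gt$d[i], d_star = gt$d_star[i], f = gt$f[i],
        t2_tissue = gt$t2_tissue[i], t2_blood = gt$t2_blood[i])
      extended_ivim_signal(g, b_max, te_ref)
    }, 0)
    gt$s0 <- if (config$sigma == 0) 1 / rel else
      snr_target * sigma_image / rel

    sig_rows <- vector("list",
                       nrow(gt) * config$n_exams * length(tes))
    k <- 0L
    for (i in seq_len(nrow(gt))) {
      g <- tissue_ground_truth(
        s0 = gt$s0[i], d = gt$d[i], d_star = gt$d_star[i], f = gt$f[i],
        t2_tissue = gt$t2_tissue[i], t2_blood = gt$t2_blood[i])
      for (exam in seq_len(config$n_exams)) {
        for (te in tes) {
          clean <- extended_ivim_signal(g, b, te)
          noisy <- rician_noisy_signal(clean, config$sigma,
                                       proto$n_averages)
          k <- k + 1L
          sig_rows[[k]] <- data.frame(
            subject = gt$subject[i], zone = gt$zone[i], exam = exam,
            te_ms = te, b = b, clean = clean, signal = noisy)
        }
      }
    }
    signals <- do.call(rbind, sig_rows)
    rownames(signals) <- NULL

    muscle_baseline <- max(30 * sigma_image, 1)
    mus_rows <- list()
    for (exam in seq_len(config$n_exams)) {
      for (te in tes) {
        samp <- rician_noisy_signal(
          rep(muscle_baseline, config$n_muscle_samples),
          config$sigma, proto$n_averages)
        mus_rows[[length(mus_rows) + 1L]] <- data.frame(
          exam = exam, te_ms = te, signal = samp)
      }
    }
    muscle <- do.call(rbind, mus_rows)
    rownames(muscle) <- NULL

    structure(list(ground_truth = gt, signals = signals, muscle = muscle,
                   sigma_image = sigma_image, protocol = proto,
                   config = config, seed = config$seed),
              class = "ivim_dataset")
  })
}

#' Extract one decay curve from a synthetic dataset
#'
#' @param dataset An `ivim_dataset` from [generate_dataset()].
#' @param subject,zone,exam,te Design-cell labels.
#' @return A [signal_series()].
#' @export
get_series <- function(dataset, subject, zone, exam, te) {
  stopifnot(inherits(dataset, "ivim_dataset"))
  rows <- dataset$signals[
    dataset$signals$subject == subject & dataset$signals$zone == zone &
    dataset$signals$exam == exam & dataset$signals$te_ms == te, ]
  if (nrow(rows) == 0)
    stop(sprintf("no series for subject %s, zone %s, exam %s, TE %s",
                 subject, zone, exam, te))
  rows <- rows[order(rows$b), ]
  signal_series(dataset$protocol, te = te,
                signals = pmax(rows$signal, .Machine$double.eps),
                subject_id = subject, zone = zone, exam = exam)
}

#' @export
print.ivim_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic IVIM dataset: %d subjects x %d zones x %d exams x %d TEs x %d b-values (seed %d)\n",
    x$config$n_subjects, length(x$config$zone_params), x$config$n_exams,
    length(x$protocol$te_values), length(x$protocol$b_values), x$seed))
  invisible(x)
}
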