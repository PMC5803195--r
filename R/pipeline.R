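#' Fit every decay curve of a dataset or signal table
#'
#' Applies [segmented_fit()] to each (subject, zone, exam, TE) cell.
#'
#' @param x An `ivim_dataset` from [generate_dataset()], or a long signal
#'   data frame with columns `subject, zone, exam, te_ms, b, signal`
#'   (in which case `protocol` must be given).
#' @param protocol An [acquisition_protocol()]; required for data frames.
#' @param ... Passed to [segmented_fit()] (`b_threshold`, `convention`,
#'   `dstar_subset`, ...).
#' @return Data frame with one row per fitted curve: labels, `adc`, `d`,
#'   `d_star` (reported in 1e-3 mm^2/s), `f`, `s0`, `s0_prime` and
#'   diagnostic flags `f_clamped`, `dstar_converged`.
#' @export
fit_dataset <- function(x, protocol = NULL, ...) {
  if (inherits(x, "ivim_dataset")) {
    signals <- x$signals
    protocol <- x$protocol
  } else {
    signals <- validate_signal_table(x)
    if (is.null(protocol)) stop("protocol is required for signal tables")
  }
  cells <- unique(signals[, c("subject", "zone", "exam", "te_ms")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    sub <- signals[signals$subject == cell$subject &
                   signals$zone == cell$zone &
                   signals$exam == cell$exam &
                   signals$te_ms == cell$te_ms, ]
    sub <- sub[order(sub$b), ]
    series <- signal_series(protocol, te = cell$te_ms,
                            signals = pmax(sub$signal, .Machine$double.eps),
                            subject_id = cell$subject, zone = cell$zone,
                            exam = cell$exam)
    fit <- segmented_fit(series, ...)
    data.frame(subject = cell$subject, zone = cell$zone, exam = cell$exam,
               te_ms = cell$te_ms,
               adc = 1e3 * fit$adc, d = 1e3 * fit$d,
               d_star = 1e3 * fit$d_star, f = fit$f,
               s0 = fit$s0, s0_prime = fit$s0_prime,
               f_clamped = fit$diagnostics$f_clamped,
               dstar_converged = fit$diagnostics$dstar_converged)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.parameters <- c("ADC", "D", "Dstar", "f")

param_column <- function(fits, parameter) {
  switch(parameter, ADC = fits$adc, D = fits$d, Dstar = fits$d_star,
         f = fits$f, stop("unknown parameter ", parameter))
}

#' Run a complete simulated repeatability study
#'
#' End-to-end orchestration: generate a synthetic cohort, fit every decay
#' curve with the segmented algorithm, and assemble the study's summary
#' tables — per-TE parameter means/SDs, test-retest CV and percentage
#' Bland-Altman limits, Spearman TE trends with one-way ANOVA, and the
#' muscle-referenced SNR at b = 1000 s/mm^2. All randomness derives from
#' `config$seed`, so repeated runs are identical.
#'
#' @param config A [cohort_config()].
#' @param b_threshold Segmentation threshold in s/mm^2 (default 200).
#' @param cv_method CV estimator, see [cv_test_retest()].
#' @param convention Pseudo-diffusion convention, see [ivim_signal()].
#' @param verbose Emit per-stage progress messages.
#'
#' @return An object of class `ivim_study`: `dataset`, `fits`, and the
#'   tables `parameter_table` (zone, te_ms, exam, parameter, mean, sd;
#'   diffusivities in 1e-3 mm^2/s), `repro_table` (CV and Bland-Altman per
#'   zone x TE x parameter), `trend_table` (Spearman and ANOVA per zone x
#'   exam x parameter), `snr_table`, plus `provenance` (seed, options,
#'   fit-quality counts, timestamp).
#' @export
#' @examples
#' study <- run_study(cohort_config(n_subjects = 3, seed = 11))
#' head(study$repro_table)
run_study <- function(config, b_threshold = 200,
                      cv_method = c("rms", "per_subject"),
                      convention = c("standalone", "sum"),
                      verbose = FALSE) {
  cv_method <- match.arg(cv_method)
  convention <- match.arg(convention)
  say <- function(...) if (verbose) message(sprintf(...))

  say("generating synthetic cohort (seed %d)", config$seed)
  dataset <- generate_dataset(config)
  say("fitting %d decay curves",
      nrow(unique(dataset$signals[, c("subject", "zone", "exam", "te_ms")])))
  fits <- fit_dataset(dataset, b_threshold = b_threshold,
                      convention = convention)

  zones <- sort(unique(fits$zone))
  tes <- sort(unique(fits$te_ms))
  exams <- sort(unique(fits$exam))

  # Tables 3/5 analog: mean +/- SD per zone x TE x exam x parameter
  pt <- expand.grid(zone = zones, te_ms = tes, exam = exams,
                    parameter = .parameters, stringsAsFactors = FALSE)
  pt$mean <- NA_real_; pt$sd <- NA_real_
  for (i in seq_len(nrow(pt))) {
    sel <- fits$zone == pt$zone[i] & fits$te_ms == pt$te_ms[i] &
      fits$exam == pt$exam[i]
    v <- param_column(fits[sel, ], pt$parameter[i])
    pt$mean[i] <- mean(v); pt$sd[i] <- stats::sd(v)
  }

  # Tables 1/2 analog: test-retest CV and Bland-Altman per zone x TE
  repro <- NULL
  if (length(exams) >= 2) {
    repro <- expand.grid(zone = zones, te_ms = tes,
                         parameter = .parameters, stringsAsFactors = FALSE)
    repro$cv_percent <- NA_real_; repro$cv_bin <- NA_character_
    repro$ba_bias <- NA_real_; repro$ba_lower <- NA_real_
    repro$ba_upper <- NA_real_; repro$n_pairs <- NA_integer_
    for (i in seq_len(nrow(repro))) {
      f1 <- fits[fits$zone == repro$zone[i] &
                 fits$te_ms == repro$te_ms[i] & fits$exam == exams[1], ]
      f2 <- fits[fits$zone == repro$zone[i] &
                 fits$te_ms == repro$te_ms[i] & fits$exam == exams[2], ]
      f1 <- f1[order(f1$subject), ]; f2 <- f2[order(f2$subject), ]
      x1 <- param_column(f1, repro$parameter[i])
      x2 <- param_column(f2, repro$parameter[i])
      # failed fits (clamped to zero) carry no repeatability information;
      # drop the affected pair and surface the count
      ok <- is.finite(x1) & is.finite(x2) & x1 > 0 & x2 > 0
      x1 <- x1[ok]; x2 <- x2[ok]
      repro$n_pairs[i] <- sum(ok)
      cv <- tryCatch(cv_test_retest(x1, x2, method = cv_method),
                     error = function(e) NULL)
      if (!is.null(cv)) {
        repro$cv_percent[i] <- cv$cv_percent
        repro$cv_bin[i] <- cv$bin
      }
      ba <- tryCatch(bland_altman_percent(x1, x2),
                     error = function(e) NULL)
      if (!is.null(ba)) {
        repro$ba_bias[i] <- ba$bias_percent
        repro$ba_lower[i] <- ba$lower
        repro$ba_upper[i] <- ba$upper
      }
    }
  }

  # Table 4 analog: Spearman TE trend + one-way ANOVA per zone x exam
  trend <- expand.grid(zone = zones, exam = exams,
                       parameter = .parameters, stringsAsFactors = FALSE)
  trend$rho <- NA_real_; trend$rho_p <- NA_real_
  trend$rho_bin <- NA_character_
  trend$anova_f <- NA_real_; trend$anova_p <- NA_real_
  for (i in seq_len(nrow(trend))) {
    sel <- fits[fits$zone == trend$zone[i] & fits$exam == trend$exam[i], ]
    v <- param_column(sel, trend$parameter[i])
    tr <- spearman_te_trend(v, sel$te_ms)
    trend$rho[i] <- tr$rho; trend$rho_p[i] <- tr$p_value
    trend$rho_bin[i] <- tr$bin
    groups <- split(v, sel$te_ms)
    if (length(groups) >= 2 && all(lengths(groups) >= 2)) {
      an <- anova_across_te(groups)
      trend$anova_f[i] <- an$f_statistic
      trend$anova_p[i] <- an$p_value
    }
  }

  # Table 6 analog: SNR at max b per zone x TE x exam
  b_max <- max(dataset$protocol$b_values)
  snr <- expand.grid(zone = zones, te_ms = tes, exam = exams,
                     stringsAsFactors = FALSE)
  snr$snr <- NA_real_
  for (i in seq_len(nrow(snr))) {
    roi <- dataset$signals[
      dataset$signals$zone == snr$zone[i] &
      dataset$signals$te_ms == snr$te_ms[i] &
      dataset$signals$exam == snr$exam[i] &
      dataset$signals$b == b_max, "signal"]
    mus <- dataset$muscle[
      dataset$muscle$exam == snr$exam[i] &
      dataset$muscle$te_ms == snr$te_ms[i], "signal"]
    snr$snr[i] <- tryCatch(snr_estimate(roi, mus),
                           error = function(e) NA_real_)
  }

  prov <- list(seed = config$seed, b_threshold = b_threshold,
               cv_method = cv_method, convention = convention,
               n_fits = nrow(fits),
               n_f_clamped = sum(fits$f_clamped),
               n_dstar_nonconverged = sum(!fits$dstar_converged),
               package_version = as.character(utils::packageVersion("ivimte")),
               created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  say("done: %d fits (%d f clamped, %d D* at boundary)", prov$n_fits,
      prov$n_f_clamped, prov$n_dstar_nonconverged)

  structure(list(dataset = dataset, fits = fits, parameter_table = pt,
                 repro_table = repro, trend_table = trend,
                 snr_table = snr, provenance = prov),
            class = "ivim_study")
}

#' @export
print.ivim_study <- function(x, ...) {
  cat(sprintf("IVIM repeatability study (seed %d): %d fits\n",
              x$provenance$seed, x$provenance$n_fits))
  if (!is.null(x$repro_table)) {
    agg <- stats::aggregate(cv_percent ~ parameter, x$repro_table, stats::median)
    cat("  median test-retest CV (%):",
        paste(sprintf("%s %.2f", agg$parameter, agg$cv_percent),
              collapse = ", "), "\n")
  }
  invisible(x)
}

# ---- signal-table I/O -------------------------------------------------

signal_cols <- c("subject", "zone", "exam", "te_ms", "b", "signal")

#' Validate a long signal table and its factorial design
#'
#' Checks the schema (`subject, zone, exam, te_ms, b, signal`; the b
#' column may also be named `b_s_per_mm2`) and that every
#' (subject, zone, exam, TE) cell of the factorial design spanned by the
#' observed levels is present with the full set of b-values. Missing cells
#' are reported explicitly by name.
#'
#' @param df A data frame.
#' @return The validated data frame (with the `b` column name normalised),
#'   invisibly usable downstream.
#' @export
validate_signal_table <- function(df) {
  names(df)[names(df) == "b_s_per_mm2"] <- "b"
  missing_cols <- setdiff(signal_cols, names(df))
  if (length(missing_cols))
    stop("signal table lacks columns: ", paste(missing_cols, collapse = ", "))
  design <- expand.grid(subject = unique(df$subject),
                        zone = unique(df$zone),
                        exam = unique(df$exam),
                        te_ms = unique(df$te_ms),
                        stringsAsFactors = FALSE)
  n_b <- length(unique(df$b))
  bad <- character(0)
  for (i in seq_len(nrow(design))) {
    sel <- df$subject == design$subject[i] & df$zone == design$zone[i] &
      df$exam == design$exam[i] & df$te_ms == design$te_ms[i]
    if (sum(sel) != n_b)
      bad <- c(bad, sprintf("subject %s, zone %s, exam %s, TE %s ms",
                            design$subject[i], design$zone[i],
                            design$exam[i], design$te_ms[i]))
  }
  if (length(bad))
    stop("incomplete design; missing or partial cells:\n  ",
         paste(bad, collapse = "\n  "))
  df
}

#' Write a signal table to CSV or JSON
#'
#' Writes the long-format schema `subject, zone, exam, te_ms,
#' b_s_per_mm2, signal` with full double precision (17 significant
#' digits), so a write/read round trip is bit-exact.
#'
#' @param x An `ivim_dataset` or a long signal data frame.
#' @param path Output file; format inferred from the extension unless
#'   `format` is given.
#' @param format `"csv"` or `"json"`.
#' @export
write_signals <- function(x, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  df <- if (inherits(x, "ivim_dataset")) x$signals else x
  df <- df[, intersect(c(signal_cols, "clean"), names(df))]
  df <- df[, signal_cols]
  names(df)[names(df) == "b"] <- "b_s_per_mm2"
  if (format == "csv") {
    out <- df
    for (col in c("te_ms", "b_s_per_mm2", "signal"))
      out[[col]] <- sprintf("%.17g", out[[col]])
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(df, path, digits = I(17), dataframe = "columns")
  }
  invisible(path)
}

#' Read a signal table from CSV or JSON
#'
#' Inverse of [write_signals()]; validates the schema and design
#' completeness via [validate_signal_table()].
#'
#' @param path Input file.
#' @param format `"csv"` or `"json"` (`"auto"`: by extension).
#' @return A long signal data frame with columns
#'   `subject, zone, exam, te_ms, b, signal`.
#' @export
load_signals <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  df <- if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
  for (col in intersect(c("te_ms", "b", "b_s_per_mm2", "signal"), names(df)))
    df[[col]] <- as.double(df[[col]])
  validate_signal_table(df)
}

#' ROI-mean signals from a 4D NIfTI stack
#'
#' Reduces a 4D diffusion volume (volumes ordered b-within-TE) to
#' ROI-level mean signals using an integer label mask. Requires the
#' RNifti package.
#'
#' @param image_path 4D NIfTI file with `length(b_values) *
#'   length(te_values)` volumes.
#' @param mask_path 3D integer label NIfTI (0 = background).
#' @param b_values,te_values Acquisition tables for the volume ordering.
#' @param roi_names Optional named translation of mask labels to zone
#'   labels, e.g. `c("1" = "PZ", "2" = "CZ")`.
#' @param subject,exam Labels attached to the output rows.
#' @return A long signal data frame (`subject, zone, exam, te_ms, b,
#'   signal`).
#' @export
load_signals_nifti <- function(image_path, mask_path, b_values, te_values,
                               roi_names = NULL, subject = 1, exam = 1) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("load_signals_nifti requires the RNifti package")
  img <- RNifti::readNifti(image_path)
  mask <- RNifti::readNifti(mask_path)
  dims <- dim(img)
  if (length(dims) != 4) stop("image must be 4D")
  n_expected <- length(b_values) * length(te_values)
  if (dims[4] != n_expected)
    stop(sprintf("expected %d volumes (b x TE), found %d",
                 n_expected, dims[4]))
  if (!all(dim(mask) == dims[1:3]))
    stop("mask dimensions do not match image")
  labels <- sort(setdiff(unique(as.integer(mask)), 0L))
  if (!length(labels)) stop("mask contains no non-zero labels")
  grid <- expand.grid(b = b_values, te_ms = te_values)  # b fastest
  rows <- list()
  for (v in seq_len(dims[4])) {
    vol <- img[, , , v]
    for (lab in labels) {
      zone <- if (!is.null(roi_names)) roi_names[[as.character(lab)]]
              else as.character(lab)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subject, zone = zone, exam = exam,
        te_ms = grid$te_ms[v], b = grid$b[v],
        signal = mean(vol[mask == lab]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write study tables to a directory
#'
#' Emits one tidy CSV per table, the full bundle as JSON, and the resolved
#' configuration (seed, options) beside them.
#'
#' @param study An `ivim_study` from [run_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "ivim_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- list(parameter_table = study$parameter_table,
               repro_table = study$repro_table,
               trend_table = study$trend_table,
               snr_table = study$snr_table, fits = study$fits)
  for (nm in names(tabs)) {
    if (is.null(tabs[[nm]])) next
    utils::write.csv(tabs[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(provenance = study$provenance, parameter_table = study$parameter_table,
         repro_table = study$repro_table, trend_table = study$trend_table,
         snr_table = study$snr_table),
    file.path(dir, "study_bundle.json"), digits = NA, auto_unbox = TRUE,
    dataframe = "rows", na = "null")
  cfg <- study$dataset$config
  cfg$protocol <- unclass(cfg$protocol)
  jsonlite::write_json(unclass(cfg), file.path(dir, "resolved_config.json"),
                       digits = NA, auto_unbox = TRUE, na = "null")
  invisible(dir)
}
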