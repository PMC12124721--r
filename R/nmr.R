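# Reduction of raw partition and titration measurements to logD (pH 7.4)
# and pKa.
#
# Partition: shake-flask between 1-octanol and pH 7.4 buffer with a
# fluorinated internal standard of known lipophilicity in both phases; the
# analyte logD follows from the double ratio of analyte-to-standard 19F
# integrals across phases. HPLC-UV route: mass balance on the aqueous phase
# before/after partitioning with the volume ratio.
#
# Titration: chemical shift of a reporter signal vs pH follows a
# Henderson-Hasselbalch sigmoid whose inflection is the pKa; a model-free
# second-derivative estimate is provided alongside the least-squares fit.

#' One shake-flask partition replicate
#'
#' @param analyte_integral_oct,standard_integral_oct NMR integrals in the
#'   octanol phase (dimensionless, strictly positive).
#' @param analyte_integral_aq,standard_integral_aq Integrals in the aqueous
#'   phase.
#' @param standard_logd Known logD of the internal standard.
#' @param replicate_id Replicate index.
#' @return An object of class `partition_measurement`.
#' @export
partition_measurement <- function(analyte_integral_oct, standard_integral_oct,
                                  analyte_integral_aq, standard_integral_aq,
                                  standard_logd, replicate_id = 1L) {
  vals <- c(analyte_integral_oct, standard_integral_oct,
            analyte_integral_aq, standard_integral_aq)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all NMR integrals must be strictly positive")
  structure(list(analyte_integral_oct = analyte_integral_oct,
                 standard_integral_oct = standard_integral_oct,
                 analyte_integral_aq = analyte_integral_aq,
                 standard_integral_aq = standard_integral_aq,
                 standard_logd = standard_logd,
                 replicate_id = replicate_id),
            class = "partition_measurement")
}

#' logD from a 19F NMR partition experiment
#'
#' For one replicate,
#' `logD = standard_logd + log10((analyte_oct/standard_oct) /
#' (analyte_aq/standard_aq))`. The double ratio cancels any common
#' rescaling of the integrals within a phase and references the analyte's
#' partitioning to the standard's known lipophilicity.
#'
#' @param m A `partition_measurement` or a list of them (replicates of one
#'   compound).
#' @return For a single measurement, the logD value. For replicates, a list
#'   with `logd` (per replicate), `mean` and `sd` (sample SD). Fewer than 2
#'   replicates aggregate with a warning, not an error.
#' @export
logd_from_nmr <- function(m) {
  if (inherits(m, "partition_measurement")) {
    ratio_oct <- m$analyte_integral_oct / m$standard_integral_oct
    ratio_aq <- m$analyte_integral_aq / m$standard_integral_aq
    return(m$standard_logd + log10(ratio_oct / ratio_aq))
  }
  stopifnot(is.list(m), length(m) >= 1L,
            all(vapply(m, inherits, logical(1), "partition_measurement")))
  if (length(m) < 2L)
    warning("fewer than 2 replicates: standard deviation unavailable")
  vals <- vapply(m, logd_from_nmr, numeric(1))
  list(logd = vals, mean = mean(vals),
       sd = if (length(vals) >= 2L) stats::sd(vals) else NA_real_)
}

#' logD from an HPLC-UV mass-balance partition experiment
#'
#' The aqueous phase is assayed before and after equilibration against
#' octanol; the distribution coefficient follows from the mass balance with
#' the volume ratio: `D = ((area_before - area_after)/area_after) *
#' (v_aq/v_oct)`, and logD = log10(D).
#'
#' @param area_before,area_after Signal areas of the analyte in the aqueous
#'   stock and in the aqueous phase after partitioning.
#' @param v_aq,v_oct Phase volumes (same units, strictly positive).
#' @return logD (dimensionless).
#' @export
logd_from_hplc <- function(area_before, area_after, v_aq, v_oct) {
  if (!is.finite(area_before) || !is.finite(area_after) ||
      area_before <= 0 || area_after <= 0)
    stop("areas must be strictly positive")
  if (v_aq <= 0 || v_oct <= 0) stop("volumes must be strictly positive")
  if (area_after >= area_before)
    stop("area_after >= area_before: no partitioning into octanol")
  d <- ((area_before - area_after) / area_after) * (v_aq / v_oct)
  log10(d)
}

#' A pH / chemical-shift titration series
#'
#' @param ph pH values (dimensionless).
#' @param shift Referenced chemical shifts, ppm.
#' @param nucleus `"19F"` (KF external standard at -125.00 ppm) or `"1H"`
#'   (trifluoroethanol at 3.14 ppm).
#' @param reference_shift The reference shift used, ppm (metadata).
#' @return An object of class `titration_series`, points sorted by pH.
#' @export
titration_series <- function(ph, shift, nucleus = c("19F", "1H"),
                             reference_shift = NULL) {
  nucleus <- match.arg(nucleus)
  stopifnot(length(ph) == length(shift), is.numeric(ph), is.numeric(shift))
  if (length(ph) < 8L)
    stop("a titration series needs at least 8 (pH, shift) points")
  if (anyNA(ph) || anyNA(shift)) stop("NA in titration points")
  if (is.null(reference_shift))
    reference_shift <- if (nucleus == "19F") -125.00 else 3.14
  o <- order(ph)
  structure(list(points = data.frame(ph = ph[o], shift = shift[o]),
                 nucleus = nucleus, reference_shift = reference_shift),
            class = "titration_series")
}

hh_sigmoid <- function(ph, pka, shift_acid, shift_base, slope = 1) {
  shift_acid + (shift_base - shift_acid) / (1 + 10^(slope * (pka - ph)))
}

#' Fit a Henderson-Hasselbalch sigmoid to a titration series
#'
#' Least-squares fit of
#' `shift(pH) = shift_acid + (shift_base - shift_acid)/(1 + 10^(pKa - pH))`
#' (unit Hill slope: single protonation of the pyridine nitrogen). The pKa
#' is the inflection point of the fitted curve; the numeric second
#' derivative of the fitted sigmoid changes sign exactly there. A free-slope
#' variant is available via `free_slope = TRUE`.
#'
#' @param t A `titration_series`.
#' @param free_slope Fit a free Hill slope as a fourth parameter.
#' @param noise_floor Shift amplitude (ppm) below which the series counts as
#'   degenerate (no transition within the pH window).
#' @return An object of class `sigmoid_fit`: `pka`, `shift_acid`,
#'   `shift_base`, `slope`, `residual_rms` (ppm), `fitted`.
#' @export
fit_titration <- function(t, free_slope = FALSE, noise_floor = 0.01) {
  stopifnot(inherits(t, "titration_series"))
  ph <- t$points$ph; shift <- t$points$shift
  amplitude <- diff(range(shift))
  if (amplitude < noise_floor)
    stop("degenerate titration: shift amplitude ",
         format(amplitude), " ppm is below the noise floor")

  # starting values: plateaus from the pH extremes, pKa from the midpoint
  sa0 <- shift[1L]; sb0 <- shift[length(shift)]
  mid <- (sa0 + sb0) / 2
  pka0 <- stats::approx(shift, ph, xout = mid, ties = mean)$y
  if (is.na(pka0)) pka0 <- stats::median(ph)

  obj <- function(par) {
    s <- if (free_slope) par[4L] else 1
    sum((shift - hh_sigmoid(ph, par[1L], par[2L], par[3L], s))^2)
  }
  par0 <- c(pka0, sa0, sb0, if (free_slope) 1)
  opt <- stats::optim(par0, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  # polish with Nelder-Mead in case BFGS stalled on a flat region
  opt2 <- stats::optim(opt$par, obj, control = list(maxit = 2000,
                                                    reltol = 1e-14))
  converged <- opt$convergence == 0 || opt2$convergence == 0
  if (opt2$value < opt$value) opt <- opt2
  par <- opt$par
  if (!converged || !is.finite(opt$value))
    stop("titration fit did not converge; residual SS = ",
         format(opt$value))
  rms <- sqrt(opt$value / length(ph))
  if (abs(par[3L] - par[2L]) < noise_floor)
    stop("degenerate titration fit: fitted transition amplitude below noise")
  if (par[1L] < min(ph) || par[1L] > max(ph))
    warning("fitted pKa ", format(par[1L]),
            " lies outside the observed pH range [", min(ph), ", ", max(ph), "]")
  structure(list(pka = par[1L], shift_acid = par[2L], shift_base = par[3L],
                 slope = if (free_slope) par[4L] else 1,
                 residual_rms = rms,
                 fitted = hh_sigmoid(ph, par[1L], par[2L], par[3L],
                                     if (free_slope) par[4L] else 1)),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(
    "<sigmoid_fit> pKa = %.4f  (acid %.3f ppm -> base %.3f ppm, slope %.3f, residual RMS %.4f ppm)\n",
    x$pka, x$shift_acid, x$shift_base, x$slope, x$residual_rms))
  invisible(x)
}

# Smoothed derivatives by local cubic fit over a sliding window: bare finite
# differences amplify NMR noise. Returns d2(shift)/d(pH)^2 and the slope at
# each interior point.
local_cubic_derivatives <- function(ph, shift, half_window = 2L) {
  n <- length(ph)
  d1 <- d2 <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half_window); hi <- min(n, i + half_window)
    if (hi - lo + 1L < 4L) next
    x <- ph[lo:hi] - ph[i]
    yw <- shift[lo:hi]
    fit <- stats::lm.fit(cbind(1, x, x^2, x^3), yw)
    d1[i] <- fit$coefficients[2L]
    d2[i] <- 2 * fit$coefficients[3L]
  }
  list(d1 = d1, d2 = d2)
}

#' Model-free pKa from the second derivative of shift vs pH
#'
#' Estimates the inflection point directly from the data: the shift series
#' is smoothed by a local cubic fit over a 5-point window, the numeric
#' second derivative is formed, and the pKa is read off at its zero
#' crossing. With multiple crossings the one nearest the steepest-slope pH
#' is returned with a warning. On a noiseless dense grid this agrees with
#' the sigmoid fit to within ~0.15 pH units.
#'
#' @param t A `titration_series` with at least 10 points.
#' @param half_window Half-width of the smoothing window (2 = 5-point).
#' @return The pKa estimate.
#' @export
second_derivative_pka <- function(t, half_window = 2L) {
  stopifnot(inherits(t, "titration_series"))
  ph <- t$points$ph; shift <- t$points$shift
  if (length(ph) < 10L)
    stop("second-derivative estimate needs at least 10 points")
  der <- local_cubic_derivatives(ph, shift, half_window)
  ok <- which(!is.na(der$d2))
  d2 <- der$d2[ok]; d1 <- der$d1[ok]; phs <- ph[ok]
  # curvature indistinguishable from zero (e.g. a linear shift series) must
  # not produce spurious floating-point sign changes
  amplitude <- diff(range(shift))
  floor_d2 <- 1e-6 * amplitude / diff(range(ph))^2
  if (max(abs(d2)) < floor_d2)
    stop("no inflection: second derivative does not change sign in the pH range")
  d2[abs(d2) < 1e-7 * max(abs(d2))] <- 0
  sign_change <- which(d2[-length(d2)] * d2[-1L] < 0)
  if (length(sign_change) == 0L)
    stop("no inflection: second derivative does not change sign in the pH range")
  # linear interpolation of each zero crossing
  crossings <- vapply(sign_change, function(i) {
    phs[i] + (phs[i + 1L] - phs[i]) * d2[i] / (d2[i] - d2[i + 1L])
  }, numeric(1))
  if (length(crossings) > 1L) {
    steepest <- phs[which.max(abs(d1))]
    warning(length(crossings),
            " zero crossings of the second derivative; returning the one ",
            "nearest the steepest slope at pH ", format(steepest))
    crossings <- crossings[which.min(abs(crossings - steepest))]
  }
  crossings
}

#' Read partition CSVs and reduce to logD per compound
#'
#' @param partitions_path CSV with columns
#'   `compound_id,replicate,phase,analyte_integral,standard_integral`
#'   (`phase` is `oct` or `aq`).
#' @param standards_path CSV with columns `standard_name,logd` (single row
#'   used for all measurements) or with a `compound_id` column mapping
#'   standards per compound.
#' @return data.frame `compound_id`, `n_replicates`, `logd_mean`, `logd_sd`.
#' @export
reduce_partition_table <- function(partitions_path, standards_path) {
  parts <- utils::read.csv(partitions_path, stringsAsFactors = FALSE)
  stds <- utils::read.csv(standards_path, stringsAsFactors = FALSE)
  req <- c("compound_id", "replicate", "phase", "analyte_integral",
           "standard_integral")
  if (!all(req %in% names(parts)))
    stop("partition CSV lacks column(s): ",
         paste(setdiff(req, names(parts)), collapse = ", "))
  if (!"logd" %in% names(stds)) stop("standards CSV lacks a 'logd' column")
  out <- list()
  for (cid in unique(parts$compound_id)) {
    sub <- parts[parts$compound_id == cid, ]
    sl <- if ("compound_id" %in% names(stds)) {
      stds$logd[match(cid, stds$compound_id)]
    } else stds$logd[1L]
    if (is.na(sl)) stop("no standard logd for compound ", cid)
    reps <- lapply(unique(sub$replicate), function(r) {
      oct <- sub[sub$replicate == r & sub$phase == "oct", ]
      aq <- sub[sub$replicate == r & sub$phase == "aq", ]
      if (nrow(oct) != 1L || nrow(aq) != 1L)
        stop("compound ", cid, " replicate ", r,
             ": need exactly one 'oct' and one 'aq' row")
      partition_measurement(oct$analyte_integral, oct$standard_integral,
                            aq$analyte_integral, aq$standard_integral,
                            standard_logd = sl, replicate_id = r)
    })
    agg <- if (length(reps) >= 2L) logd_from_nmr(reps) else
      suppressWarnings(logd_from_nmr(reps))
    out[[length(out) + 1L]] <- data.frame(
      compound_id = cid, n_replicates = length(reps),
      logd_mean = agg$mean, logd_sd = agg$sd, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Read a titration CSV and fit pKa per compound
#'
#' @param path CSV with columns `compound_id,pH,shift_ppm,nucleus`.
#' @param method `"sigmoid"` (least-squares fit) or `"second-derivative"`.
#' @return data.frame `compound_id`, `pka`, `method`, plus fit diagnostics
#'   for the sigmoid route.
#' @export
reduce_titration_table <- function(path,
                                   method = c("sigmoid", "second-derivative")) {
  method <- match.arg(method)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("compound_id", "pH", "shift_ppm", "nucleus")
  if (!all(req %in% names(df)))
    stop("titration CSV lacks column(s): ",
         paste(setdiff(req, names(df)), collapse = ", "))
  out <- list()
  for (cid in unique(df$compound_id)) {
    sub <- df[df$compound_id == cid, ]
    ts <- titration_series(sub$pH, sub$shift_ppm,
                           nucleus = unique(sub$nucleus)[1L])
    if (method == "sigmoid") {
      f <- fit_titration(ts)
      out[[length(out) + 1L]] <- data.frame(
        compound_id = cid, pka = f$pka, method = method,
        shift_acid = f$shift_acid, shift_base = f$shift_base,
        residual_rms = f$residual_rms, stringsAsFactors = FALSE)
    } else {
      out[[length(out) + 1L]] <- data.frame(
        compound_id = cid, pka = second_derivative_pka(ts), method = method,
        shift_acid = NA_real_, shift_base = NA_real_,
        residual_rms = NA_real_, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
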