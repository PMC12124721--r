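# Synthetic generators with known ground truth for every input the pipeline
# consumes: descriptor tables with planted linear response laws, shake-flask
# partition replicates, and pH titration series. Each generator is a pure
# function of (parameters, seed): identical inputs give identical outputs,
# and the noiseless output is exactly inverted by the corresponding pipeline
# stage.

with_local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Define a planted linear response law
#'
#' @param term_names Descriptor names the law acts on.
#' @param coefficients Per-term slope on the raw descriptor scale.
#' @param intercept Response units.
#' @param noise_sd Gaussian noise SD added to the response (>= 0).
#' @return An object of class `planted_law`.
#' @export
planted_law <- function(term_names, coefficients, intercept = 0,
                        noise_sd = 0) {
  stopifnot(length(term_names) == length(coefficients), noise_sd >= 0)
  structure(list(term_names = term_names,
                 coefficients = stats::setNames(coefficients, term_names),
                 intercept = intercept, noise_sd = noise_sd),
            class = "planted_law")
}

# Descriptor column archetypes emulating a DFT supporting-information
# table: partial charges (can straddle zero, exercising the 1/x and log
# validity paths), fluorine-like small counts, negative orbital energies,
# and positive surface/volume magnitudes.
SYNTH_DISTRIBUTIONS <- list(
  charge = list(kind = "uniform", min = -0.7, max = 0.3),
  count = list(kind = "integer", min = 0, max = 5),
  energy = list(kind = "uniform", min = -10, max = -1),
  area = list(kind = "uniform", min = 20, max = 120)
)

draw_column <- function(dist, n) {
  switch(dist$kind,
         uniform = stats::runif(n, dist$min, dist$max),
         integer = as.numeric(sample(dist$min:dist$max, n, replace = TRUE)),
         stop("unknown distribution kind"))
}

#' Generate a descriptor table with a planted linear response
#'
#' Descriptor columns cycle through four archetypes (partial charges in
#' [-0.7, 0.3], integer counts 0-5, negative energies, positive areas); the
#' response is the planted law applied to its raw columns plus Gaussian
#' noise. Everything is reproducible from the seed and the distributions
#' used are recorded in the truth record.
#'
#' @param n_compounds Number of rows (>= 8).
#' @param n_descriptors Number of descriptor columns (>= 3).
#' @param law A [planted_law()]; its `term_names` must name generated
#'   columns (`D001`, `D002`, ...).
#' @param seed Integer seed.
#' @return List with `table` (unscaled `descriptor_table`), `response`
#'   (named vector) and `truth` (law, distributions, noiseless response).
#' @export
gen_descriptor_table <- function(n_compounds, n_descriptors, law,
                                 seed = 1L) {
  stopifnot(inherits(law, "planted_law"),
            n_compounds >= 8L, n_descriptors >= 3L)
  col_names <- sprintf("D%03d", seq_len(n_descriptors))
  missing_terms <- setdiff(law$term_names, col_names)
  if (length(missing_terms) > 0L)
    stop("law references missing column(s): ",
         paste(missing_terms, collapse = ", "))
  kinds <- rep(names(SYNTH_DISTRIBUTIONS),
               length.out = n_descriptors)
  with_local_seed(seed, {
    values <- vapply(seq_len(n_descriptors), function(j) {
      draw_column(SYNTH_DISTRIBUTIONS[[kinds[j]]], n_compounds)
    }, numeric(n_compounds))
    colnames(values) <- col_names
    rownames(values) <- sprintf("C%03d", seq_len(n_compounds))
    y0 <- law$intercept +
      as.numeric(values[, law$term_names, drop = FALSE] %*%
                   law$coefficients)
    y <- y0 + stats::rnorm(n_compounds, 0, law$noise_sd)
    names(y) <- rownames(values)
    list(table = descriptor_table(values, provenance = "dft_ingested"),
         response = y,
         truth = list(law = law,
                      distributions = stats::setNames(kinds, col_names),
                      response_noiseless = stats::setNames(y0,
                                                           rownames(values)),
                      seed = seed))
  })
}

#' Paper-scale preset: 20 compounds, ~220 descriptors, 2-term planted law
#'
#' Mirrors the scale of the pyridine study: with d = 220 descriptors the
#' exhaustive 1-/2-descriptor search fits d + d(d-1)/2 = 24,310 models. The
#' planted law acts on a charge-like and a count-like column with noise
#' chosen to land near R2 ~ 0.95 in-sample.
#'
#' @param seed Integer seed.
#' @param n_compounds,n_descriptors Override the preset scale.
#' @return As [gen_descriptor_table()].
#' @export
gen_paperlike_dataset <- function(seed = 1L, n_compounds = 20L,
                                  n_descriptors = 220L) {
  law <- planted_law(c("D001", "D002"), c(2.0, 0.35), intercept = 1.2,
                     noise_sd = 0.12)
  gen_descriptor_table(n_compounds, n_descriptors, law, seed = seed)
}

#' Generate shake-flask partition replicates with known logD
#'
#' Integrals are constructed to satisfy the double-ratio identity exactly
#' (analyte octanol/aqueous ratio = 10^true_logd, standard ratio =
#' 10^standard_logd), then multiplicative log-normal noise of coefficient of
#' variation `noise_cv` is applied independently to each integral.
#'
#' @param true_logd Ground-truth analyte logD.
#' @param standard_logd Known logD of the internal standard.
#' @param noise_cv Coefficient of variation of the integral noise, in
#'   [0, 0.2].
#' @param n_replicates Number of replicates (the protocol uses 3).
#' @param seed Integer seed.
#' @return List of `partition_measurement` objects.
#' @export
gen_partition <- function(true_logd, standard_logd, noise_cv = 0.01,
                          n_replicates = 3L, seed = 1L) {
  stopifnot(noise_cv >= 0, noise_cv <= 0.2, n_replicates >= 1L)
  sdlog <- sqrt(log1p(noise_cv^2))
  with_local_seed(seed, {
    lapply(seq_len(n_replicates), function(r) {
      base <- c(analyte_oct = 10^true_logd, standard_oct = 10^standard_logd,
                analyte_aq = 1, standard_aq = 1)
      noisy <- base * stats::rlnorm(4L, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      partition_measurement(noisy[["analyte_oct"]], noisy[["standard_oct"]],
                            noisy[["analyte_aq"]], noisy[["standard_aq"]],
                            standard_logd = standard_logd, replicate_id = r)
    })
  })
}

#' Generate an NMR pH titration series with known pKa
#'
#' Shifts follow the Henderson-Hasselbalch sigmoid between the acid and base
#' plateau shifts, plus Gaussian noise.
#'
#' @param true_pka Ground-truth pKa.
#' @param shift_acid,shift_base Plateau shifts, ppm.
#' @param ph_grid pH sampling points; should span `true_pka` +/- 2 (a
#'   narrower grid triggers a warning, the fit may be unstable).
#' @param noise_sd Gaussian shift noise SD, ppm.
#' @param nucleus Reporter nucleus.
#' @param seed Integer seed.
#' @return A `titration_series`.
#' @export
gen_titration <- function(true_pka, shift_acid, shift_base,
                          ph_grid = seq(true_pka - 3, true_pka + 3,
                                        length.out = 15L),
                          noise_sd = 0, nucleus = "19F", seed = 1L) {
  stopifnot(noise_sd >= 0)
  if (min(ph_grid) > true_pka - 2 || max(ph_grid) < true_pka + 2)
    warning("pH grid does not span true_pka +/- 2; fit may be unstable")
  with_local_seed(seed, {
    shift <- hh_sigmoid(ph_grid, true_pka, shift_acid, shift_base) +
      stats::rnorm(length(ph_grid), 0, noise_sd)
    titration_series(ph_grid, shift, nucleus = nucleus)
  })
}

#' Write synthetic partition replicates in the pipeline's CSV dialect
#'
#' @param measurements List of `partition_measurement` (e.g. from
#'   [gen_partition()]), or a named list of such lists keyed by compound id.
#' @param partitions_path,standards_path Output CSV paths.
#' @param standard_name Label for the internal standard.
#' @export
write_partition_csv <- function(measurements, partitions_path,
                                standards_path,
                                standard_name = "internal_standard") {
  if (length(measurements) > 0L &&
      inherits(measurements[[1L]], "partition_measurement"))
    measurements <- list(compound = measurements)
  rows <- list()
  stds <- list()
  for (cid in names(measurements)) {
    for (m in measurements[[cid]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        compound_id = cid, replicate = m$replicate_id, phase = "oct",
        analyte_integral = m$analyte_integral_oct,
        standard_integral = m$standard_integral_oct)
      rows[[length(rows) + 1L]] <- data.frame(
        compound_id = cid, replicate = m$replicate_id, phase = "aq",
        analyte_integral = m$analyte_integral_aq,
        standard_integral = m$standard_integral_aq)
    }
    stds[[length(stds) + 1L]] <- data.frame(
      compound_id = cid, standard_name = standard_name,
      logd = measurements[[cid]][[1L]]$standard_logd)
  }
  utils::write.csv(do.call(rbind, rows), partitions_path, row.names = FALSE)
  utils::write.csv(do.call(rbind, stds), standards_path, row.names = FALSE)
  invisible(partitions_path)
}

#' Write a synthetic titration series in the pipeline's CSV dialect
#'
#' @param series A `titration_series` or named list of them keyed by
#'   compound id.
#' @param path Output CSV path.
#' @export
write_titration_csv <- function(series, path) {
  if (inherits(series, "titration_series")) series <- list(compound = series)
  rows <- lapply(names(series), function(cid) {
    s <- series[[cid]]
    data.frame(compound_id = cid, pH = s$points$ph,
               shift_ppm = s$points$shift, nucleus = s$nucleus)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
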