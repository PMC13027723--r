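#' Blank-corrected Harboe hemoglobin readout
#'
#' Hemoglobin is quantified spectrophotometrically by the Harboe approach:
#' primary absorbance at 415 nm (the Soret band of oxyhemoglobin) with
#' baseline corrections at 380 nm and 450 nm. Condition-matched blank
#' optical densities are subtracted per wavelength before the linear
#' combination H = c1 A415' - c2 A380' - c3 A450' is applied. The default
#' weights (167.2, 83.6, 83.6) are the standard Harboe coefficients; they
#' cancel in the percent-of-lysis ratio, so only relative readouts are
#' interpreted.
#'
#' @param sample Length-3 numeric (A415, A380, A450) or a one-row data.frame
#'   with those columns.
#' @param blank_mean Blank triplet in the same form, subtracted per
#'   wavelength before combining.
#' @param coefficients Length-3 positive weights (c1, c2, c3).
#' @return Scalar hemoglobin proxy (arbitrary concentration units).
#' @export
harboe_value <- function(sample, blank_mean = c(0, 0, 0),
                         coefficients = c(167.2, 83.6, 83.6)) {
  sample <- as_triplet(sample)
  blank_mean <- as_triplet(blank_mean)
  stopifnot(length(coefficients) == 3L, all(coefficients > 0))
  a <- sample - blank_mean
  coefficients[1L] * a[1L] - coefficients[2L] * a[2L] - coefficients[3L] * a[3L]
}

as_triplet <- function(x) {
  if (is.data.frame(x)) x <- unlist(x[1L, c("A415", "A380", "A450")])
  x <- as.numeric(x)
  if (length(x) != 3L || !all(is.finite(x)))
    stop("expected a finite (A415, A380, A450) triplet")
  x
}

#' Percent hemolysis relative to complete hypotonic lysis
#'
#' @param sample_H Harboe value of the sample supernatant.
#' @param lysis_reference_H Harboe value of the 100% lysis reference; must
#'   be positive.
#' @return Percent of full lysis (can be slightly negative under blank
#'   noise; values are reported as-is and gated by the LOD flag).
#' @export
percent_hemolysis <- function(sample_H, lysis_reference_H) {
  if (!is.finite(lysis_reference_H) || lysis_reference_H <= 0)
    stop("lysis reference Harboe value must be positive")
  100 * sample_H / lysis_reference_H
}

#' Limit of detection from replicate blank measurements
#'
#' Per-wavelength blank standard deviations (pooled over all replicate
#' reads) are propagated through the Harboe combination by root sum of
#' squares with the Harboe weights; the detection limit is `k_lod` times the
#' propagated sd, expressed as a percent of the lysis reference.
#'
#' @param blanks data.frame with columns replicate, read, A415, A380, A450
#'   (>= 2 reads in total per wavelength).
#' @param lysis_reference_H Harboe value of the lysis reference.
#' @param coefficients Harboe weights, as in [harboe_value()].
#' @param k_lod LOD multiplier applied to the propagated sd (default 3.3,
#'   the conventional detection-limit factor).
#' @return `lod_percent`, the smallest hemolysis percentage distinguishable
#'   from blank noise.
#' @export
lod_from_blanks <- function(blanks, lysis_reference_H,
                            coefficients = c(167.2, 83.6, 83.6),
                            k_lod = 3.3) {
  stopifnot(is.data.frame(blanks),
            all(c("A415", "A380", "A450") %in% names(blanks)))
  if (nrow(blanks) < 2L)
    stop("degenerate blanks: at least two reads are required for an LOD")
  if (!is.finite(lysis_reference_H) || lysis_reference_H <= 0)
    stop("lysis reference Harboe value must be positive")
  sds <- vapply(c("A415", "A380", "A450"),
                function(w) stats::sd(blanks[[w]]), 0)
  sd_H <- sqrt(sum((coefficients * sds)^2))
  100 * k_lod * sd_H / lysis_reference_H
}

#' Full hemolysis readout from an absorbance record table
#'
#' Convenience wrapper over [harboe_value()], [percent_hemolysis()] and
#' [lod_from_blanks()]: averages the blank reads per wavelength, corrects
#' sample and lysis-reference triplets, and reports percent hemolysis with
#' its condition-specific LOD and a below-LOD flag. Sub-LOD values
#' (including small negatives from blank noise) are reported as-is; the flag
#' marks them as uninterpretable rather than clipping to zero.
#'
#' @param records data.frame in the schema of [generate_absorbance()].
#' @param condition,timepoint Labels copied into the result.
#' @param coefficients,k_lod Passed through to the underlying functions.
#' @return One-row data.frame: condition, timepoint, percent, lod_percent,
#'   below_lod.
#' @export
hemolysis_readout <- function(records, condition = NA_character_,
                              timepoint = NA_character_,
                              coefficients = c(167.2, 83.6, 83.6),
                              k_lod = 3.3) {
  stopifnot(is.data.frame(records),
            all(c("role", "A415", "A380", "A450") %in% names(records)))
  blanks <- records[records$role == "blank", , drop = FALSE]
  samples <- records[records$role == "sample", , drop = FALSE]
  refs <- records[records$role == "lysis_reference", , drop = FALSE]
  if (!nrow(blanks) || !nrow(samples) || !nrow(refs))
    stop("records must contain blank, sample and lysis_reference roles")
  blank_mean <- colMeans(blanks[, c("A415", "A380", "A450")])
  H_ref <- harboe_value(colMeans(refs[, c("A415", "A380", "A450")]),
                        blank_mean, coefficients)
  H_sample <- harboe_value(colMeans(samples[, c("A415", "A380", "A450")]),
                           blank_mean, coefficients)
  pct <- percent_hemolysis(H_sample, H_ref)
  lod <- lod_from_blanks(blanks, H_ref, coefficients, k_lod)
  data.frame(condition = condition, timepoint = timepoint,
             percent = pct, lod_percent = lod,
             below_lod = pct < lod, stringsAsFactors = FALSE)
}
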