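#' Construct a raw IRMS measurement sequence
#'
#' Validates a time-ordered sequence of raw GC/IRMS peaks: samples, dilute
#' air standards, reference-gas pulses and blanks, each with a detector
#' amplitude (arbitrary units), a raw delta-18O (permil) and a sequence
#' position.
#'
#' @param id identifier vector.
#' @param kind one of `"sample"`, `"standard_air"`, `"blank"`, `"refgas"`
#'   per measurement.
#' @param amplitude detector signal sizes; > 0 for non-blank kinds.
#' @param raw_delta raw delta-18O values (permil).
#' @param position unique, time-ordered sequence indices.
#' @return data.frame of class `"irms_sequence"`.
#' @export
irms_sequence <- function(id, kind, amplitude, raw_delta, position) {
  kinds <- c("sample", "standard_air", "blank", "refgas")
  stopifnot(all(kind %in% kinds),
            length(unique(position)) == length(position))
  if (any(amplitude[kind != "blank"] <= 0)) {
    stop("amplitude must be > 0 for non-blank measurements")
  }
  if (any(amplitude < 0)) stop("amplitude must be >= 0")
  out <- data.frame(id = id, kind = kind, amplitude = amplitude,
                    raw_delta = raw_delta, position = position,
                    stringsAsFactors = FALSE)
  out <- out[order(out$position), ]
  rownames(out) <- NULL
  class(out) <- c("irms_sequence", "data.frame")
  out
}

#' Blank correction by isotope mass balance
#'
#' The measured peak is a mixture of analyte and blank O2; amplitudes are
#' proportional to O2 amounts, so the analyte delta follows from mass
#' balance: `delta_corr = (A_m * delta_m - A_b * delta_b) / (A_m - A_b)`.
#'
#' @param amplitude,raw_delta measured peak amplitude(s) and delta(s).
#' @param blank_amplitude,blank_delta blank peak amplitude and delta.
#' @return blank-corrected delta value(s) (permil).
#' @export
correct_blank <- function(amplitude, raw_delta, blank_amplitude, blank_delta) {
  if (any(amplitude <= blank_amplitude)) {
    stop("signal too small: measurement amplitude must exceed the blank amplitude")
  }
  (amplitude * raw_delta - blank_amplitude * blank_delta) /
    (amplitude - blank_amplitude)
}

#' Fit the instrument linearity slope from reference-gas peaks
#'
#' OLS slope of raw delta vs peak amplitude across reference-gas pulses
#' of varying size (the reference gas is isotopically constant, so any
#' dependence is instrumental). The correction subtracts
#' `slope * (A - A_ref)` with `A_ref` the median reference amplitude.
#'
#' @param amplitude,raw_delta reference-gas peak amplitudes and deltas
#'   (>= 2 distinct amplitudes).
#' @return list with `slope` (permil per amplitude unit) and `a_ref`.
#' @export
fit_linearity <- function(amplitude, raw_delta) {
  stopifnot(length(amplitude) == length(raw_delta))
  if (length(unique(amplitude)) < 2L) {
    stop("need reference-gas peaks at >= 2 distinct amplitudes")
  }
  fit <- stats::lm(raw_delta ~ amplitude)
  list(slope = unname(stats::coef(fit)["amplitude"]),
       a_ref = stats::median(amplitude))
}

#' Fit the instrument drift slope from standards
#'
#' OLS slope of (previously corrected) standard deltas vs sequence
#' position; standards are evenly spread across the sequence, so a linear
#' trend estimates instrument drift over time. The correction subtracts
#' `slope * (position - mean(position))`.
#'
#' @param position,delta standard positions (>= 2 distinct) and deltas.
#' @return list with `slope` (permil per position) and `pos_ref`.
#' @export
fit_drift <- function(position, delta) {
  stopifnot(length(position) == length(delta))
  if (length(unique(position)) < 2L) {
    stop("need standards at >= 2 distinct positions")
  }
  fit <- stats::lm(delta ~ position)
  list(slope = unname(stats::coef(fit)["position"]),
       pos_ref = mean(position))
}

#' Run the full IRMS delta-18O correction chain
#'
#' Applies, in order: blank correction (mass balance against the mean
#' blank), instrument linearity (slope fitted on reference-gas peaks),
#' instrument drift (slope fitted on linearity-corrected air standards,
#' pooled), and a one-point calibration shifting all deltas so the mean
#' corrected air standard equals the delta-18O of O2 in ambient air
#' (23.8 permil). The order matters and is fixed.
#'
#' Reference-gas pulses bypass the inlet and carry no blank; blanks and
#' refgas peaks are carried through but only samples and air standards
#' receive the blank correction.
#'
#' @param seq an [irms_sequence()].
#' @param air_true true delta-18O of the air standard (permil).
#' @return the sequence with a `corrected_delta` column appended and the
#'   fitted [`correction_model`][correct_sequence] in
#'   `attr(, "correction_model")`: `blank_amplitude`, `blank_delta`,
#'   `linearity_slope`, `drift_slope`, `calibration_offset`.
#' @export
correct_sequence <- function(seq, air_true = DELTA18O_AIR_O2) {
  stopifnot(inherits(seq, "irms_sequence"))
  is_blank <- seq$kind == "blank"
  is_ref <- seq$kind == "refgas"
  is_air <- seq$kind == "standard_air"
  is_smp <- seq$kind == "sample"
  if (!any(is_air)) stop("calibration impossible: no air standard in sequence")

  blank_a <- if (any(is_blank)) mean(seq$amplitude[is_blank]) else 0
  blank_d <- if (any(is_blank)) mean(seq$raw_delta[is_blank]) else 0

  delta <- seq$raw_delta
  inj <- is_smp | is_air
  if (blank_a > 0) {
    delta[inj] <- correct_blank(seq$amplitude[inj], delta[inj], blank_a, blank_d)
  }

  lin <- if (sum(is_ref) >= 2L) {
    fit_linearity(seq$amplitude[is_ref], delta[is_ref])
  } else {
    list(slope = 0, a_ref = stats::median(seq$amplitude[!is_blank]))
  }
  delta[!is_blank] <- delta[!is_blank] -
    lin$slope * (seq$amplitude[!is_blank] - lin$a_ref)

  drift <- if (sum(is_air) >= 2L &&
               length(unique(seq$position[is_air])) >= 2L) {
    fit_drift(seq$position[is_air], delta[is_air])
  } else {
    list(slope = 0, pos_ref = mean(seq$position))
  }
  delta[!is_blank] <- delta[!is_blank] -
    drift$slope * (seq$position[!is_blank] - drift$pos_ref)

  offset <- air_true - mean(delta[is_air])
  delta[!is_blank] <- delta[!is_blank] + offset

  out <- seq
  out$corrected_delta <- delta
  attr(out, "correction_model") <- list(
    blank_amplitude = blank_a, blank_delta = blank_d,
    linearity_slope = lin$slope, drift_slope = drift$slope,
    calibration_offset = offset
  )
  out
}

#' One-point calibration to the air-O2 anchor
#'
#' Shifts all non-blank deltas by a constant so that the mean air
#' standard equals `air_true`. Exposed separately for use on sequences
#' already blank/linearity/drift corrected.
#'
#' @param seq an [irms_sequence()] with a `delta` column to calibrate
#'   (defaults to `raw_delta`).
#' @param delta delta values aligned with `seq` rows; default
#'   `seq$raw_delta`.
#' @param air_true anchor value (permil), default 23.8.
#' @return list with `delta` (calibrated values) and `offset`.
#' @export
calibrate_one_point <- function(seq, delta = seq$raw_delta,
                                air_true = DELTA18O_AIR_O2) {
  is_air <- seq$kind == "standard_air"
  if (!any(is_air)) stop("calibration impossible: no air standard in sequence")
  offset <- air_true - mean(delta[is_air])
  list(delta = delta + offset, offset = offset)
}

#' Read / write IRMS sequence CSVs
#'
#' Sequence CSVs carry columns `id, kind, amplitude, raw_delta_permil,
#' position`; corrected output appends `corrected_delta_permil`.
#'
#' @param path CSV path.
#' @return [read_irms_csv()]: an `irms_sequence`.
#' @export
read_irms_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  irms_sequence(d$id, d$kind, d$amplitude, d$raw_delta_permil, d$position)
}

#' @rdname read_irms_csv
#' @param seq a corrected sequence from [correct_sequence()].
#' @export
write_irms_csv <- function(seq, path) {
  d <- data.frame(id = seq$id, kind = seq$kind, amplitude = seq$amplitude,
                  raw_delta_permil = seq$raw_delta,
                  position = seq$position)
  if (!is.null(seq$corrected_delta)) {
    d$corrected_delta_permil <- seq$corrected_delta
  }
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
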