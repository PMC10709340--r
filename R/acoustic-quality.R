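## Acoustic quality stage: band-limited SNR measurement over the 90%
## energy duration, and the quality gate that selects calls for sequence
## analysis.
##
## No DSP package ships with the target environment, so the Butterworth
## band-pass design (analog prototype -> LP/BP transform -> bilinear) and
## zero-phase application are implemented here in base R. The recursive
## filtering itself runs through stats::filter (C speed).

## Analog Butterworth lowpass prototype poles (cutoff 1 rad/s).
butter_prototype <- function(order) {
  k <- seq_len(order)
  exp(1i * pi * (2 * k + order - 1) / (2 * order))
}

## Polynomial coefficients (descending powers) from roots, complex-safe.
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  p
}

#' Design a digital Butterworth band-pass filter
#'
#' Classic design path: analog lowpass prototype, lowpass-to-bandpass
#' transform with pre-warped edge frequencies, bilinear transform.
#'
#' @param low,high Passband edges (Hz).
#' @param fs Sampling rate (Hz); `high` must be below Nyquist.
#' @param order Prototype order (the band-pass filter has `2 * order`
#'   poles).
#' @return List with numerator `b` and denominator `a` coefficients.
#' @export
butter_bandpass <- function(low, high, fs, order = 3) {
  if (low <= 0 || high <= low) abort("need 0 < low < high",
                                     "orcaseq_bad_parameter")
  if (high >= fs / 2) abort("high edge at or above Nyquist",
                            "orcaseq_bad_parameter")
  w1 <- 2 * fs * tan(pi * low / fs)     # pre-warped analog edges (rad/s)
  w2 <- 2 * fs * tan(pi * high / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  p_lp <- butter_prototype(order)
  ## LP -> BP: each prototype pole maps to a conjugate-symmetric pair
  half <- p_lp * bw / 2
  p_bp <- c(half + sqrt(half^2 - w0^2), half - sqrt(half^2 - w0^2))
  z_bp <- rep(0 + 0i, order)            # order zeros at s = 0
  k_analog <- bw^order                  # gain so passband peak is unity
  ## bilinear transform s -> 2 fs (z-1)/(z+1)
  fs2 <- 2 * fs
  pz <- (1 + p_bp / fs2) / (1 - p_bp / fs2)
  zz <- (1 + z_bp / fs2) / (1 - z_bp / fs2)
  ## zeros at s = infinity map to z = -1
  zz <- c(zz, rep(-1 + 0i, length(p_bp) - length(z_bp)))
  k_digital <- k_analog * Re(prod(fs2 - z_bp) / prod(fs2 - p_bp))
  b <- Re(poly_from_roots(zz)) * k_digital
  a <- Re(poly_from_roots(pz))
  list(b = b, a = a)
}

## Direct-form IIR filter via stats::filter: MA part by convolution,
## AR part recursively. Zero initial conditions.
iir_filter <- function(b, a, x) {
  nb <- length(b)
  u <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution",
                     sides = 1)
  u <- as.numeric(u)[nb:(nb - 1 + length(x))]
  if (length(a) > 1) {
    y <- stats::filter(u / a[1], -a[-1] / a[1], method = "recursive")
    as.numeric(y)
  } else u / a[1]
}

#' Zero-phase Butterworth band-pass
#'
#' Applies the designed filter forward and backward (squared magnitude
#' response, zero phase) so annotation times are not shifted. Edge
#' transients are absorbed by odd-reflection padding.
#'
#' @param x Numeric waveform.
#' @param fs Sampling rate (Hz).
#' @param low,high Passband edges (Hz); defaults 450 and 10000.
#' @param order Butterworth prototype order; default 3.
#' @return Filtered waveform, same length as `x`.
#' @export
bandpass <- function(x, fs, low = 450, high = 10000, order = 3) {
  des <- butter_bandpass(low, high, fs, order)
  n <- length(x)
  if (n == 0) return(x)
  npad <- min(n - 1L, max(3L * (length(des$a) - 1L), round(0.1 * fs)))
  if (npad > 0) {
    xp <- c(2 * x[1] - x[(npad + 1):2],          # odd reflection, left
            x,
            2 * x[n] - x[(n - 1):(n - npad)])    # odd reflection, right
  } else xp <- x
  y <- iir_filter(des$b, des$a, xp)
  y <- rev(iir_filter(des$b, des$a, rev(y)))
  if (npad > 0) y[(npad + 1):(npad + n)] else y
}

#' 90% energy window of a segment
#'
#' Finds the times at which the cumulative squared amplitude crosses 5%
#' and 95% of the segment's total energy; the 90% energy duration is the
#' distance between them.
#'
#' @param segment Numeric samples.
#' @param fs Sampling rate (Hz).
#' @param t0 Time of the first sample (s); window times are absolute.
#' @return List `t5`, `t95`, `duration_s`.
#' @export
energy_duration_90 <- function(segment, fs, t0 = 0) {
  if (!length(segment) || all(segment == 0))
    abort("segment has no energy", "orcaseq_degenerate_input")
  cs <- cumsum(as.numeric(segment)^2)
  total <- cs[length(cs)]
  i5 <- which(cs >= 0.05 * total)[1]
  i95 <- which(cs >= 0.95 * total)[1]
  t5 <- t0 + (i5 - 1) / fs
  t95 <- t0 + (i95 - 1) / fs
  list(t5 = t5, t95 = t95, duration_s = t95 - t5)
}

## Locate a 200 ms annotation-free window ending at or before
## call_start - offset, scanning backwards in 50 ms steps.
find_noise_window <- function(call_start, annotations, noise_len = 0.2,
                              step = 0.05, lookback = 5, gap0 = 0) {
  end <- call_start - gap0
  floor_t <- max(0, call_start - lookback)
  while (end - noise_len >= floor_t) {
    w0 <- end - noise_len
    clash <- any(annotations$start_s < end & annotations$end_s > w0)
    if (!clash) return(c(w0, end))
    end <- end - step
  }
  NULL
}

#' Measure call SNR against a preceding ambient-noise segment
#'
#' Band-passes the relevant slice of the recording, takes the call's
#' sound pressure level over its 90% energy duration, and compares it to
#' the level of a 200 ms annotation-free noise window found within
#' `lookback_s` before the call (scanning backwards in 50 ms steps).
#' Levels are relative (uncalibrated): only their difference is
#' meaningful.
#'
#' @param wave Numeric waveform (or a `synthetic_waveform`).
#' @param fs Sampling rate (Hz); ignored when `wave` carries its own.
#' @param call One-row data.frame (or list) with `start_s`, `end_s` and
#'   optionally `call_id`.
#' @param annotations All annotated calls on the record (used to keep the
#'   noise window call-free); defaults to `call` alone.
#' @param noise_offset_s Optional fixed gap between the noise window and
#'   the call start, bypassing the search.
#' @param lookback_s Search depth before the call (s).
#' @param band,order Band-pass parameters; defaults 450-10000 Hz, order 3.
#' @return List of class `snr_measurement`: `call_id`, `spl_call_db`,
#'   `spl_noise_db`, `snr_db`, `energy_window`, `noise_window`.
#' @export
measure_snr <- function(wave, fs = NULL, call, annotations = NULL,
                        noise_offset_s = NULL, lookback_s = 5,
                        band = c(450, 10000), order = 3) {
  if (inherits(wave, "synthetic_waveform")) {
    fs <- wave$sample_rate
    if (is.null(annotations)) annotations <- wave$annotations
    wave <- wave$wave
  }
  if (is.null(fs)) abort("fs is required", "orcaseq_bad_parameter")
  if (is.null(annotations))
    annotations <- data.frame(start_s = call$start_s, end_s = call$end_s)
  if (!is.null(noise_offset_s)) {
    nw <- c(call$start_s - noise_offset_s - 0.2, call$start_s - noise_offset_s)
    if (nw[1] < 0)
      abort("noise window before start of recording", "orcaseq_no_noise_window")
  } else {
    nw <- find_noise_window(call$start_s, annotations, lookback = lookback_s)
    if (is.null(nw))
      abort("no call-free 200 ms noise window found before call",
            "orcaseq_no_noise_window")
  }
  ## band-pass one slice covering noise window and call
  slice0 <- max(0, nw[1] - 0.05)
  slice1 <- min(length(wave) / fs, call$end_s + 0.05)
  i0 <- floor(slice0 * fs) + 1L
  i1 <- min(length(wave), ceiling(slice1 * fs))
  filt <- bandpass(wave[i0:i1], fs, band[1], band[2], order)
  grab <- function(a, b) {
    j0 <- max(1L, round((a - slice0) * fs) + 1L)
    j1 <- min(length(filt), round((b - slice0) * fs))
    filt[j0:j1]
  }
  call_seg <- grab(call$start_s, call$end_s)
  ew <- energy_duration_90(call_seg, fs, t0 = call$start_s)
  core <- grab(ew$t5, max(ew$t95, ew$t5 + 1 / fs))
  noise_seg <- grab(nw[1], nw[2])
  spl_call <- 10 * log10(mean(core^2))
  spl_noise <- 10 * log10(mean(noise_seg^2))
  structure(list(call_id = call$call_id %||% NA_character_,
                 spl_call_db = spl_call, spl_noise_db = spl_noise,
                 snr_db = spl_call - spl_noise,
                 energy_window = c(ew$t5, ew$t95),
                 noise_window = nw),
            class = "snr_measurement")
}

#' Measure SNR for every annotated call on a record
#'
#' Calls where no noise window can be found are flagged
#' (`measured = FALSE`, `snr_db = NA`), never silently dropped.
#'
#' @inheritParams measure_snr
#' @param annotations Data.frame of calls (`call_id`, `start_s`, `end_s`).
#' @return Data.frame: call_id, snr_db, spl_call_db, spl_noise_db,
#'   measured.
#' @export
measure_snr_all <- function(wave, fs = NULL, annotations = NULL,
                            lookback_s = 5, band = c(450, 10000), order = 3) {
  if (inherits(wave, "synthetic_waveform")) {
    fs <- wave$sample_rate
    if (is.null(annotations)) annotations <- wave$annotations
    wave <- wave$wave
  }
  out <- lapply(seq_len(nrow(annotations)), function(i) {
    m <- tryCatch(
      measure_snr(wave, fs, annotations[i, ], annotations,
                  lookback_s = lookback_s, band = band, order = order),
      orcaseq_no_noise_window = function(e) NULL)
    if (is.null(m)) {
      data.frame(call_id = annotations$call_id[i] %||% NA_character_,
                 snr_db = NA_real_, spl_call_db = NA_real_,
                 spl_noise_db = NA_real_, measured = FALSE)
    } else {
      data.frame(call_id = m$call_id, snr_db = m$snr_db,
                 spl_call_db = m$spl_call_db, spl_noise_db = m$spl_noise_db,
                 measured = TRUE)
    }
  })
  do.call(rbind, out)
}

#' Quality gate for sequence analysis
#'
#' Retains calls rated high quality whose SNR exceeds the threshold, or
#' which carry an explicit low-SNR override flag (used when low-frequency
#' noise contaminates the SNR measurement while the call contour is
#' clearly visible). Calls without an SNR measurement are retained but
#' flagged in the audit. VARIABLE-labeled calls pass this gate — they are
#' excluded later, at sequence construction.
#'
#' @param calls Data.frame with `quality` and optionally `snr_db` and
#'   logical `low_snr_override`.
#' @param snr_threshold_db SNR threshold (dB); strict `>` retention.
#' @param allow_low_snr_override Honour the override flag.
#' @return List of class `quality_gate_result`: `retained` (subset of
#'   `calls`) and `audit` (call_id, retained, reason).
#' @export
quality_gate <- function(calls, snr_threshold_db = 10,
                         allow_low_snr_override = TRUE) {
  if (!nrow(calls)) {
    return(structure(list(retained = calls,
                          audit = data.frame(call_id = character(0),
                                             retained = logical(0),
                                             reason = character(0))),
                     class = "quality_gate_result"))
  }
  snr <- if ("snr_db" %in% names(calls)) calls$snr_db else
    rep(NA_real_, nrow(calls))
  override <- if (allow_low_snr_override && "low_snr_override" %in% names(calls))
    isTRUE_vec(calls$low_snr_override) else rep(FALSE, nrow(calls))
  hq <- calls$quality == "high"
  snr_ok <- !is.na(snr) & snr > snr_threshold_db
  snr_missing <- is.na(snr)
  keep <- hq & (snr_ok | snr_missing | override)
  reason <- rep("retained", nrow(calls))
  reason[hq & snr_missing & !override] <- "retained_snr_unmeasured"
  reason[hq & !snr_ok & !snr_missing & override] <- "retained_low_snr_override"
  reason[!hq] <- "excluded_low_quality"
  reason[hq & !keep] <- "excluded_low_snr"
  structure(list(retained = calls[keep, , drop = FALSE],
                 audit = data.frame(call_id = calls$call_id,
                                    retained = keep, reason = reason,
                                    stringsAsFactors = FALSE)),
            class = "quality_gate_result")
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)
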