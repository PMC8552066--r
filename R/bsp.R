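# Body-surface potential processing: calibrated additive white Gaussian
# noise, zero-phase Butterworth band-pass filtering, and selection of the
# 64-electrode vest.

new_bsp_recording <- function(potentials, fs, snr_db = NULL, filter = NULL,
                              labels = NULL, channels = NULL,
                              provenance = list()) {
  structure(list(potentials = potentials, fs = fs, snr_db = snr_db,
                 filter = filter, labels = labels, channels = channels,
                 provenance = provenance), class = "bsp_recording")
}

#' @export
print.bsp_recording <- function(x, ...) {
  cat(sprintf("bsp_recording: %d electrodes x %d samples @ %g Hz (SNR: %s, filter: %s)\n",
              nrow(x$potentials), ncol(x$potentials), x$fs,
              if (is.null(x$snr_db)) "clean" else sprintf("%g dB", x$snr_db),
              if (is.null(x$filter)) "none"
              else sprintf("butterworth %d [%g, %g] Hz", x$filter$order,
                           x$filter$f_lo, x$filter$f_hi)))
  invisible(x)
}

#' Corrupt a BSP recording with calibrated white Gaussian noise
#'
#' Noise variance is set per electrode from that electrode's clean mean
#' power so that the realized SNR matches `snr_db` in expectation.
#'
#' @param bsp bsp_recording (or numeric E x S matrix)
#' @param snr_db target signal-to-noise ratio in dB; `NULL` = no noise
#' @param rng_seed integer seed
#' @return bsp_recording with noise added and `snr_db` recorded
#' @export
add_noise <- function(bsp, snr_db, rng_seed = 1L) {
  x <- if (inherits(bsp, "bsp_recording")) bsp$potentials else bsp
  if (is.null(snr_db)) return(if (inherits(bsp, "bsp_recording")) bsp
                              else new_bsp_recording(x, NA_real_))
  check_scalar(snr_db, "snr_db")
  p_sig <- rowMeans(x^2)
  if (any(p_sig == 0))
    stop_af("electrode(s) %s carry an all-zero signal; SNR undefined",
            paste(utils::head(which(p_sig == 0), 3), collapse = ","))
  sigma <- sqrt(p_sig * 10^(-snr_db / 10))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(rng_seed)
  noise <- matrix(stats::rnorm(length(x)), nrow(x)) * sigma
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  out <- x + noise
  if (inherits(bsp, "bsp_recording")) {
    bsp$potentials <- out
    bsp$snr_db <- snr_db
    bsp
  } else new_bsp_recording(out, NA_real_, snr_db = snr_db)
}

#' Digital Butterworth band-pass design
#'
#' Order-`n` Butterworth low-pass prototype, band transformation, bilinear
#' transform with edge pre-warping.  The single-pass magnitude response is
#' exactly -3 dB at both cut-offs.
#'
#' @param order prototype order (4 = the package default; the band-pass has
#'   `2 * order` poles)
#' @param f_lo,f_hi band edges in Hz
#' @param fs sampling rate in Hz
#' @return list with numerator `b` and denominator `a` coefficients
#' @export
butter_bandpass <- function(order = 4, f_lo = 3, f_hi = 30, fs = 500) {
  if (f_hi >= fs / 2)
    stop_af("upper cut-off %g Hz must be below Nyquist (%g Hz)", f_hi, fs / 2)
  if (f_lo <= 0 || f_lo >= f_hi) stop_af("need 0 < f_lo < f_hi")
  # analog prototype poles on the unit circle
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  # pre-warped analog band edges
  w1 <- 2 * fs * tan(pi * f_lo / fs)
  w2 <- 2 * fs * tan(pi * f_hi / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  # low-pass -> band-pass: each pole p maps to the two roots of
  # s^2 - (p * bw) s + w0^2 = 0
  pb <- p_lp * bw / 2
  disc <- sqrt(pb^2 - w0^2)
  poles <- c(pb + disc, pb - disc)
  zeros <- rep(0, order)                 # n zeros at s = 0 (n at infinity)
  # bilinear transform
  fs2 <- 2 * fs
  zp <- (fs2 + poles) / (fs2 - poles)
  zz <- (fs2 + zeros) / (fs2 - zeros)    # all map to z = 1
  zz <- c(zz, rep(-1, length(poles) - length(zeros)))
  a <- Re(.poly_from_roots(zp))
  b <- Re(.poly_from_roots(zz))
  # unit gain at the warped center frequency
  wc <- 2 * atan(w0 / fs2)
  resp <- .polyval_z(b, wc) / .polyval_z(a, wc)
  b <- b / Mod(resp)
  list(b = b, a = a, order = order, f_lo = f_lo, f_hi = f_hi, fs = fs)
}

.poly_from_roots <- function(r) {
  p <- 1
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  p
}

# Evaluate polynomial (coefficients of z^0 .. z^-m) at e^{i w}
.polyval_z <- function(coefs, w) {
  sum(coefs * exp(-1i * w * (seq_along(coefs) - 1)))
}

#' Magnitude response of a digital filter
#' @param filt list with `b`, `a` (and `fs` unless given)
#' @param f frequencies in Hz
#' @param fs sampling rate
#' @return |H(f)| for a single pass
#' @export
filter_response <- function(filt, f, fs = filt$fs) {
  vapply(2 * pi * f / fs, function(w)
    Mod(.polyval_z(filt$b, w) / .polyval_z(filt$a, w)), numeric(1))
}

# Steady-state initial conditions for a unit-amplitude input step
# (transposed direct form II), so filtfilt edge transients decay from the
# signal's boundary value instead of zero.
.lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b)) - 1L
  b <- c(b, rep(0, n + 1L - length(b)))
  a <- c(a, rep(0, n + 1L - length(a)))
  b <- b / a[1]; a <- a / a[1]
  A <- diag(1, n) - cbind(-a[2:(n + 1)], rbind(diag(1, n - 1L),
                                               rep(0, n - 1L)))
  B <- b[2:(n + 1)] - a[2:(n + 1)] * b[1]
  solve(A, B)
}

#' Single-pass IIR filtering
#' @param filt list with `b`, `a`
#' @param x numeric vector
#' @return filtered vector
#' @export
filter_apply <- function(filt, x) {
  as.numeric(.iir_filter(filt$b, filt$a, x, numeric(0)))
}

#' Zero-phase forward-backward filtering
#'
#' Odd-reflection padding (3 x filter length) with steady-state initial
#' conditions, filtered forward then backward; squares the magnitude
#' response and cancels the phase.
#'
#' @param filt list with `b`, `a`
#' @param x numeric vector
#' @return filtered vector, same length
#' @export
filtfilt_apply <- function(filt, x) {
  b <- filt$b; a <- filt$a
  n_ext <- 3L * (max(length(a), length(b)) - 1L)
  if (length(x) <= n_ext)
    stop_af("signal too short (%d samples) for edge padding (%d)",
            length(x), n_ext)
  zi <- .lfilter_zi(b, a)
  ext <- c(2 * x[1] - x[(n_ext + 1L):2L], x,
           2 * x[length(x)] - x[(length(x) - 1L):(length(x) - n_ext)])
  y <- as.numeric(.iir_filter(b, a, ext, zi * ext[1]))
  y <- rev(y)
  y <- as.numeric(.iir_filter(b, a, y, zi * y[1]))
  y <- rev(y)
  y[(n_ext + 1L):(n_ext + length(x))]
}

#' Band-pass filter a BSP recording
#'
#' Fourth-order Butterworth band-pass (3-30 Hz by default), applied
#' zero-phase (forward-backward) to every electrode.
#'
#' @param bsp bsp_recording (or E x S matrix with `fs` supplied)
#' @param order,f_lo,f_hi Butterworth design parameters
#' @param fs sampling rate (taken from the recording when omitted)
#' @param zero_phase logical; FALSE applies a single causal pass
#' @return filtered bsp_recording with filter provenance recorded
#' @export
bandpass_filter <- function(bsp, order = 4, f_lo = 3, f_hi = 30,
                            fs = NULL, zero_phase = TRUE) {
  x <- if (inherits(bsp, "bsp_recording")) bsp$potentials else bsp
  fs <- fs %||% (if (inherits(bsp, "bsp_recording")) bsp$fs else
                 stop_af("fs required for matrix input"))
  filt <- butter_bandpass(order, f_lo, f_hi, fs)
  app <- if (zero_phase) filtfilt_apply else filter_apply
  out <- t(apply(x, 1, function(row) app(filt, row)))
  meta <- list(order = order, f_lo = f_lo, f_hi = f_hi,
               zero_phase = zero_phase)
  if (inherits(bsp, "bsp_recording")) {
    bsp$potentials <- out
    bsp$filter <- meta
    bsp
  } else new_bsp_recording(out, fs, filter = meta)
}

#' Select the 64-electrode vest in canonical channel order
#'
#' Canonical order: front panel row-major (rows 1..6 x columns 1..4), back
#' panel row-major, then side electrodes column-major (left columns then
#' right columns, rows 3..6 within each).
#'
#' @param bsp_full bsp_recording over all torso electrodes
#' @param electrode_table data.frame as produced by [build_torso()]
#' @return 64-channel bsp_recording; `channels` records the mapping
#' @export
sample_vest <- function(bsp_full, electrode_table) {
  tab <- electrode_table[electrode_table$in_vest, , drop = FALSE]
  if (nrow(tab) != 64L)
    stop_af("vest table must map exactly 64 electrodes, got %d", nrow(tab))
  if (anyDuplicated(tab$index))
    stop_af("duplicate electrode indices in vest table")
  x <- if (inherits(bsp_full, "bsp_recording")) bsp_full$potentials
       else bsp_full
  if (any(tab$index < 1 | tab$index > nrow(x)))
    stop_af("vest table references electrodes outside the recording")
  front <- tab[tab$panel == "front", ]
  back <- tab[tab$panel == "back", ]
  left <- tab[tab$panel == "side_left", ]
  right <- tab[tab$panel == "side_right", ]
  if (nrow(front) != 24 || nrow(back) != 24 ||
      nrow(left) != 8 || nrow(right) != 8)
    stop_af("vest panels must have 24 front, 24 back, 8 left, 8 right")
  bycol_row <- function(d) d[order(d$vest_col, d$vest_row), ]
  byrow_col <- function(d) d[order(d$vest_row, d$vest_col), ]
  ord <- rbind(byrow_col(front), byrow_col(back),
               bycol_row(left), bycol_row(right))
  out <- x[ord$index, , drop = FALSE]
  rownames(out) <- ord$name
  res <- if (inherits(bsp_full, "bsp_recording")) bsp_full
         else new_bsp_recording(out, NA_real_)
  res$potentials <- out
  res$channels <- ord
  res
}

#' Empirical SNR of a noisy signal against its clean reference
#' @param clean,noisy matrices of identical shape
#' @return realized SNR in dB (global power ratio)
#' @export
measure_snr <- function(clean, noisy) {
  10 * log10(mean(clean^2) / mean((noisy - clean)^2))
}
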