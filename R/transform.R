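#' Sampled signal container
#'
#' @param samples Real numeric vector.
#' @param rate Sampling rate in samples/second.
#' @return Object of class `sampled_signal` with fields `samples`, `rate`,
#'   `duration`, `times`.
#' @export
sampled_signal <- function(samples, rate) {
  stopifnot(is.numeric(samples), rate > 0, all(is.finite(samples)))
  n <- length(samples)
  structure(list(samples = as.numeric(samples), rate = rate,
                 duration = n / rate, times = (seq_len(n) - 1) / rate),
            class = "sampled_signal")
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("Sampled signal: %d samples @ %g Hz (%.3f s), rms %.4g\n",
              length(x$samples), x$rate, x$duration,
              sqrt(mean(x$samples^2))))
  invisible(x)
}

#' Discrete Hilbert transform
#'
#' Frequency-multiplier implementation (multiplier \eqn{-i\,\mathrm{sgn}\,
#' \omega}), so that \eqn{H\cos\omega t = \sin\omega t}, \eqn{H^2 = -I} on
#' mean-free signals, and time shifts commute with \eqn{H}.  DC and Nyquist
#' bins are zeroed.
#'
#' @param f A [sampled_signal()] or numeric vector.
#' @return Same type as the input.
#' @export
hilbert_transform <- function(f) {
  x <- if (inherits(f, "sampled_signal")) f$samples else f
  n <- length(x)
  X <- stats::fft(x)
  mult <- complex(real = numeric(n), imaginary = numeric(n))
  half <- if (n %% 2 == 0) n / 2 else (n + 1) / 2
  if (half >= 2) mult[2:half] <- -1i
  if (n %% 2 == 0) mult[half + 1] <- 0          # Nyquist
  if (n %% 2 == 0 && half + 2 <= n) mult[(half + 2):n] <- 1i
  if (n %% 2 == 1 && half + 1 <= n) mult[(half + 1):n] <- 1i
  y <- Re(stats::fft(X * mult, inverse = TRUE)) / n
  if (inherits(f, "sampled_signal")) sampled_signal(y, f$rate) else y
}

# Frequency-domain wavelet at scale a: 2 * w_a(omega) on the positive bins.
# Dilation group: w_a = sqrt(a) h_c(a omega); general group model: the
# s-pullback sqrt(a s'(omega)) h_c(a s(omega)) supported inside the band.
wavelet_hat_row <- function(omega_pos, a, p, gm = NULL) {
  if (is.null(gm)) {
    sqrt(a) * extremal_h(a * omega_pos, p)
  } else {
    group_wavelet_hat(omega_pos, a, p, gm)
  }
}

#' Analytic wavelet transform (cochleogram)
#'
#' Computes \eqn{Zf(a, t) = 2\sqrt a \int_0^\infty \hat f(\omega)\,
#' h_c(a\omega)\, e^{i\omega t}\, d\omega} for every scale row, i.e. the
#' analytic signal \eqn{u + iHu} of the wavelet filterbank output, by FFT
#' filtering.  Optionally populates log-amplitude and unwrapped phase.
#'
#' @param f A [sampled_signal()].
#' @param grid A [scale_grid()] (or positive numeric vector of scales).
#' @param p A [filter_params()].
#' @param gm Optional [group_model()] replacing the dilation group.
#' @param pad Zero-pad to the next power of two (doubling if already one).
#'   Default `TRUE`.
#' @param taper Total cosine-taper fraction applied to the signal ends before
#'   the FFT (default 0.1; use 0 for periodic, on-bin test signals).
#' @param polar Populate `logr` and unwrapped `phase` fields (default
#'   `TRUE`; skip for large grids where only `Z` is needed).
#' @param floor_rel Amplitude floor relative to `max |Z|` below which phase
#'   is marked invalid. Default `1e-6`.
#' @return Object of class `cochleogram`: complex matrix `Z` (scales x
#'   times), `scales`, `times`, `rate`, `dloga`, `logr`, `phase`, `mask`,
#'   `interior_cols`, `params`, `gm`.
#' @export
analytic_transform <- function(f, grid, p, gm = NULL, pad = TRUE,
                               taper = 0.1, polar = TRUE, floor_rel = 1e-6) {
  stopifnot(inherits(f, "sampled_signal"), inherits(p, "filter_params"))
  scales <- if (inherits(grid, "scale_grid")) grid$scales else grid
  stopifnot(all(scales > 0), !is.unsorted(scales, strictly = TRUE))
  dl <- diff(log(scales))
  dloga <- if (length(dl)) dl[1] else NA_real_

  n <- length(f$samples)
  x <- f$samples * tukey_window(n, taper)
  nfft <- if (pad) { np <- nextpow2(n); if (np == n) 2L * n else np } else n
  X <- stats::fft(c(x, numeric(nfft - n)))
  kpos <- 2:(floor(nfft / 2))           # positive-frequency bins (no DC/Nyq)
  om <- 2 * pi * (kpos - 1) * f$rate / nfft

  # Nyquist guard: per-row centre frequency must sit safely below rate/2
  cf_row <- if (is.null(gm)) 1 / scales else
    vapply(scales, function(a) gm$smap_inv(1 / a), numeric(1))
  bad <- cf_row > 0.9 * pi * f$rate
  if (any(bad))
    warning(sprintf("%d scale row(s) beyond the Nyquist-safe band were masked",
                    sum(bad)))

  Z <- matrix(complex(real = NA_real_, imaginary = NA_real_),
              nrow = length(scales), ncol = n)
  filt <- complex(length.out = nfft)
  for (j in seq_along(scales)) {
    if (bad[j]) next
    filt[] <- 0
    filt[kpos] <- 2 * wavelet_hat_row(om, scales[j], p, gm)
    row <- stats::fft(X * filt, inverse = TRUE) / nfft
    Z[j, ] <- row[seq_len(n)]
  }

  m <- max(1L, ceiling(taper * n / 2))
  interior <- (m + 2L):(n - m - 1L)

  coch <- structure(list(Z = Z, scales = scales, times = f$times,
                         rate = f$rate, dloga = dloga,
                         logr = NULL, phase = NULL, mask = NULL,
                         interior_cols = interior, params = p, gm = gm,
                         row_masked = bad),
                    class = "cochleogram")
  if (polar) coch <- polar_fields(coch, floor_rel)
  coch
}

#' Real wavelet transform
#'
#' The real part \eqn{Wf(a,t)} of [analytic_transform()]; returned as a
#' cochleogram whose `Z` has zero imaginary part and no polar fields.
#' @inheritParams analytic_transform
#' @return A `cochleogram` with the real response in `Re(Z)`.
#' @export
wavelet_transform <- function(f, grid, p, gm = NULL, pad = TRUE, taper = 0.1) {
  coch <- analytic_transform(f, grid, p, gm = gm, pad = pad, taper = taper,
                             polar = FALSE)
  coch$Z <- matrix(complex(real = Re(coch$Z), imaginary = 0),
                   nrow = nrow(coch$Z))
  coch
}

# Populate logr / unwrapped phase / amplitude-floor mask.  Unwrap along time
# first, then along scale anchored at the mid-signal column.
polar_fields <- function(coch, floor_rel = 1e-6) {
  Z <- coch$Z
  mod <- Mod(Z)
  floorv <- floor_rel * max(mod, na.rm = TRUE)
  mask <- is.finite(mod) & mod > floorv
  logr <- suppressWarnings(log(mod))
  logr[!mask] <- NA_real_
  phase <- Arg(Z)
  for (j in seq_len(nrow(Z))) {
    if (all(is.na(phase[j, ]))) next
    phase[j, ] <- unwrap_phase(phase[j, ])
  }
  mid <- ceiling(ncol(Z) / 2)
  okc <- which(apply(mask, 1, any))
  if (length(okc) > 1) {
    anchor <- unwrap_phase(phase[okc, mid])
    shift <- round((anchor - phase[okc, mid]) / (2 * pi))
    phase[okc, ] <- phase[okc, ] + 2 * pi * shift
  }
  phase[!mask] <- NA_real_
  coch$logr <- logr
  coch$phase <- phase
  coch$mask <- mask
  coch
}

#' @export
print.cochleogram <- function(x, ...) {
  cat(sprintf(
    "Cochleogram: %d scales x %d samples @ %g Hz, a in [%.3g, %.3g]%s\n",
    nrow(x$Z), ncol(x$Z), x$rate, min(x$scales), max(x$scales),
    if (is.null(x$gm)) "" else sprintf(" [group: %s]", x$gm$label)))
  invisible(x)
}

#' Impulse (click) response at a place
#'
#' Inverse Fourier transform of the transfer function at place `x`, computed
#' on a time grid symmetric about 0 so that acausal leakage is measurable.
#' The response of the model to a unit click is
#' \eqn{u(x,t) = \frac1{2\pi}\int \hat g_c(x,\omega) e^{i\omega t} d\omega},
#' which for the dilation family is \eqn{(\pi a)^{-1}\,\mathrm{Re}\,
#' \Psi(t/a)} — a function of the scale-invariant time \eqn{s = t/a} alone
#' (so \eqn{t\,u(x,t)} collapses across places when plotted against
#' \eqn{s}).
#'
#' @param x Place in mm.
#' @param p A [filter_params()].
#' @param map A [tonotopic_map()].
#' @param duration Total window length in seconds (centred on 0); must cover
#'   at least 20 cycles of the characteristic frequency.
#' @param rate Sampling rate; default 64 times the CF.
#' @param gm Optional [group_model()].
#' @return List of class `impulse_response`: `times` (symmetric), `u`,
#'   `acausal_energy_fraction`, `cf`, `a`, `rate`.
#' @export
impulse_response <- function(x, p, map = tonotopic_map("exponential"),
                             duration = NULL, rate = NULL, gm = NULL) {
  xi <- position_to_frequency(x, map)
  cf_hz <- xi / (2 * pi)
  if (is.null(duration)) duration <- 40 / cf_hz
  if (duration * cf_hz < 20)
    stop("duration must cover at least 20 cycles of the CF")
  if (is.null(rate)) rate <- 64 * cf_hz
  n <- nextpow2(round(duration * rate))
  dt <- 1 / rate
  om <- 2 * pi * (0:(n - 1)) / (n * dt)
  om[om >= pi * rate] <- om[om >= pi * rate] - 2 * pi * rate  # wrap to +/-
  tf <- transfer_function(x, om, p, map, gm = gm)
  u <- Re(stats::fft(tf$values, inverse = TRUE)) / (n * dt)
  # fftshift: put t = 0 in the middle
  half <- n / 2
  u <- c(u[(half + 1):n], u[1:half])
  times <- (seq_len(n) - 1 - half) * dt
  e <- u^2
  structure(list(times = times, u = u,
                 acausal_energy_fraction = sum(e[times < 0]) / sum(e),
                 cf = xi, a = tf$a, rate = rate),
            class = "impulse_response")
}
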