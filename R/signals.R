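#' Synthetic signal specification
#'
#' Declarative description of a test signal: pure tone
#' \eqn{A\cos(\nu t + \vartheta)}, amplitude-modulated tone
#' \eqn{(1 + A\cos\mu t)\cos\nu t}, harmonic complex with a prescribed
#' dB-per-harmonic slope and seeded ripple (violin-like), unit click, or
#' band-limited Gaussian noise.
#'
#' @param kind `"tone"`, `"am"`, `"harmonic"`, `"click"` or `"noise"`.
#' @param A Amplitude (tone) or modulation depth (am). Default 1 (tone),
#'   0.5 (am).
#' @param nu_hz Tone/carrier/fundamental frequency in Hz.
#' @param theta Phase offset in radians (tone).
#' @param mu_hz Modulation rate in Hz (am); must be well below `nu_hz`.
#' @param M Number of harmonics (harmonic). Default 20.
#' @param slope_db Amplitude slope in dB per harmonic index. Default -2.
#' @param ripple_db Half-width of the seeded uniform amplitude ripple in dB.
#'   Default 3.
#' @param click_time Click instant in seconds. Default `duration/2`.
#' @param f_lo_hz,f_hi_hz Noise band edges in Hz.
#' @param rate Sampling rate. Default 44100.
#' @param duration Duration in seconds. Default 1.
#' @param seed Integer seed (harmonic ripple/phases and noise).
#' @return Object of class `generator_spec`.
#' @export
generator_spec <- function(kind = c("tone", "am", "harmonic", "click", "noise"),
                           A = NULL, nu_hz = 440, theta = 0, mu_hz = 8,
                           M = 20, slope_db = -2, ripple_db = 3,
                           click_time = NULL, f_lo_hz = 100, f_hi_hz = 1000,
                           rate = 44100, duration = 1, seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(A)) A <- if (kind == "am") 0.5 else 1
  if (is.null(click_time)) click_time <- duration / 2
  stopifnot(rate > 0, duration > 0)
  fmax <- switch(kind,
                 tone = nu_hz, am = nu_hz + mu_hz, harmonic = M * nu_hz,
                 click = rate / 2 * 0.89, noise = f_hi_hz)
  if (fmax >= 0.45 * rate)
    stop(sprintf(
      "Nyquist violation: component at %g Hz exceeds 0.45 * rate = %g Hz",
      fmax, 0.45 * rate))
  if (kind == "am" && !(mu_hz < nu_hz / 5))
    stop("amplitude modulation requires mu << nu (mu < nu/5)")
  structure(list(kind = kind, A = A, nu_hz = nu_hz, theta = theta,
                 mu_hz = mu_hz, M = M, slope_db = slope_db,
                 ripple_db = ripple_db, click_time = click_time,
                 f_lo_hz = f_lo_hz, f_hi_hz = f_hi_hz, rate = rate,
                 duration = duration, seed = as.integer(seed)),
            class = "generator_spec")
}

#' Harmonic coefficients of a generator spec
#'
#' The complex `c_m` implied by the slope/ripple/seed of a `"harmonic"`
#' spec: \eqn{|c_m|} follows `slope_db * (m - 1)` dB plus a seeded uniform
#' ripple of `ripple_db`, with seeded uniform phases.
#'
#' @param spec A `"harmonic"` [generator_spec()].
#' @return A [harmonic_spectrum()].
#' @export
spec_harmonics <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"), spec$kind == "harmonic")
  rng <- local({
    set.seed(spec$seed)
    list(rip = stats::runif(spec$M, -spec$ripple_db, spec$ripple_db),
         ph = stats::runif(spec$M, 0, 2 * pi))
  })
  m <- seq_len(spec$M)
  db <- spec$slope_db * (m - 1) + rng$rip
  db[1] <- 0                       # fundamental pinned at 0 dB
  harmonic_spectrum(2 * pi * spec$nu_hz,
                    10^(db / 20) * exp(1i * rng$ph))
}

#' Generate a synthetic signal
#'
#' Deterministic given the spec (including its seed).
#'
#' @param spec A [generator_spec()].
#' @return A [sampled_signal()] with the spec attached as attribute `"spec"`.
#' @export
generate_signal <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  n <- round(spec$rate * spec$duration)
  t <- (seq_len(n) - 1) / spec$rate
  nu <- 2 * pi * spec$nu_hz
  x <- switch(spec$kind,
    tone = spec$A * cos(nu * t + spec$theta),
    am = (1 + spec$A * cos(2 * pi * spec$mu_hz * t)) * cos(nu * t),
    harmonic = {
      hs <- spec_harmonics(spec)
      xx <- numeric(n)
      for (m in seq_len(spec$M))
        xx <- xx + Mod(hs$coefficients[m]) *
          cos(m * nu * t + Arg(hs$coefficients[m]))
      xx
    },
    click = {
      xx <- numeric(n)
      xx[1 + round(spec$click_time * spec$rate)] <- 1
      xx
    },
    noise = {
      set.seed(spec$seed)
      X <- complex(n)
      k <- 2:floor(n / 2)
      fk <- (k - 1) * spec$rate / n
      inband <- fk >= spec$f_lo_hz & fk <= spec$f_hi_hz
      kk <- k[inband]
      X[kk] <- complex(real = stats::rnorm(length(kk)),
                       imaginary = stats::rnorm(length(kk)))
      X[n + 2 - kk] <- Conj(X[kk])
      xx <- Re(stats::fft(X, inverse = TRUE)) / n
      xx / sqrt(mean(xx^2))        # unit RMS
    })
  out <- sampled_signal(x, spec$rate)
  attr(out, "spec") <- spec
  out
}
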