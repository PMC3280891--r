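#' The z-coordinate of the holomorphic representation
#'
#' In the dilation model the complex structure equation becomes a
#' dbar-equation in \eqn{z = t - a\beta + ia\gamma} (upper half-plane since
#' \eqn{a, \gamma > 0}).  For a general group model \eqn{z = t +
#' (-\beta + i\gamma)\,\eta(a)} with \eqn{\eta'(a) = s'(\omega_a)},
#' \eqn{\omega_a = s^{-1}(1/a)}; \eqn{\eta(a) = a} for the dilation group.
#'
#' @param a Scale (vector ok).
#' @param t Time (vector ok; recycled against `a`).
#' @param p A [filter_params()].
#' @param gm Optional [group_model()].
#' @return Complex `z` values.
#' @export
zmap <- function(a, t, p, gm = NULL) {
  eta <- if (is.null(gm)) a else gm$eta(a)
  t + (-p$beta + 1i * p$gamma) * eta
}

#' Time-independent particular solution
#'
#' The particular solution \eqn{P(a)} of the complex structure equation,
#' defined by \eqn{a\,\partial_a P = A + iB} and \eqn{P(1) = 0}; for the
#' dilation group \eqn{P(a) = (\gamma - i\alpha)\log a}, so that
#' \eqn{Zf = e^{P(a)}\,G(z)} with \eqn{G} holomorphic (exact at
#' \eqn{c = 1}).
#'
#' @param a Scales (positive vector).
#' @param p A [filter_params()].
#' @param gm Optional [group_model()].
#' @return Complex vector \eqn{P(a)}.
#' @export
particular_solution <- function(a, p, gm = NULL) {
  stopifnot(all(a > 0))
  if (is.null(gm)) return((p$gamma - 1i * p$alpha) * log(a))
  # integrate (A + iB) d(log a) from 1 to a, per element
  vapply(a, function(ai) {
    f <- function(la) {
      cf <- structure_coefficients(exp(la), p, gm)
      cf$A + 1i * cf$B
    }
    re <- stats::integrate(function(la) Re(f(la)), 0, log(ai),
                           rel.tol = 1e-10)$value
    im <- stats::integrate(function(la) Im(f(la)), 0, log(ai),
                           rel.tol = 1e-10)$value
    complex(real = re, imaginary = im)
  }, complex(1))
}

#' Holomorphic function of a pure tone
#'
#' For input \eqn{f(t) = A\cos(\nu t + \vartheta)} the associated
#' holomorphic function is
#' \eqn{G(z) = k e^{i\varepsilon} A e^{i\vartheta}\,
#' \nu^{\gamma - 1/2 - i\alpha}\, e^{i\nu z}}; \eqn{e^{P} G} reproduces
#' \eqn{Zf} exactly at \eqn{c = 1} and approximately (an over-estimate of
#' \eqn{\log|Zf|} off-CF) for \eqn{c > 1}.
#'
#' @param A Amplitude.
#' @param nu Circular frequency (rad/s), > 0.
#' @param theta Phase offset (radians).
#' @param p A [filter_params()].
#' @return Function `G(z)` (vectorised, complex).
#' @export
G_pure_tone <- function(A, nu, theta = 0, p) {
  stopifnot(nu > 0)
  cst <- p$k_amp * exp(1i * p$epsilon) * exp(p$gamma - p$kappa / p$c) *
    A * exp(1i * theta) * nu^(p$gamma - 0.5 - 1i * p$alpha)
  function(z) cst * exp(1i * nu * z)
}

#' Holomorphic function of an arbitrary sampled signal
#'
#' Superposition of [G_pure_tone()] over the positive-frequency FFT bins of
#' the signal (G is additive over superpositions by linearity).
#'
#' @param f A [sampled_signal()].
#' @param p A [filter_params()].
#' @return Function `G(z)`.
#' @export
G_from_signal <- function(f, p) {
  n <- length(f$samples)
  Fk <- stats::fft(f$samples) / n
  half <- floor((n - 1) / 2)
  k <- seq_len(half)
  nu_k <- 2 * pi * k * f$rate / n
  amp <- 2 * Fk[k + 1]      # f = sum_k Re(2 F_k e^{i nu_k t})
  cst <- p$k_amp * exp(1i * p$epsilon) * exp(p$gamma - p$kappa / p$c) *
    nu_k^(p$gamma - 0.5 - 1i * p$alpha)
  function(z) {
    vapply(z, function(zz) sum(amp * cst * exp(1i * nu_k * zz)), complex(1))
  }
}

#' Discrete dbar residual of the holomorphic factor
#'
#' Divides the computed cochleogram by the particular factor \eqn{e^{P(a)}}
#' and measures how far the quotient \eqn{Q = Zf\,e^{-P}} is from being
#' holomorphic in \eqn{z}: the residual \eqn{\partial_{\log a} Q - (C + iD)
#' \partial_t Q} vanishes identically iff \eqn{Q} is a function of \eqn{z}
#' alone (an anti-holomorphic component would flip the sign of the
#' \eqn{i\gamma} part and leave a nonzero residual).  Exact at \eqn{c = 1}
#' up to discretisation.
#'
#' @param coch A cochleogram (with `Z`).
#' @param p,gm Model parameters; default those stored in the cochleogram.
#' @param floor_rel Amplitude floor. Default `1e-6`.
#' @return List: `rel` (RMS over rows of the per-row relative residual),
#'   `rel_rows`, and the residual matrix (`NULL` for very large grids).
#' @export
dbar_residual <- function(coch, p = coch$params, gm = coch$gm,
                          floor_rel = 1e-6) {
  Z <- coch$Z
  nr <- nrow(Z); nc <- ncol(Z)
  if (nr < 5) stop("need at least 5 scale rows")
  dl <- coch$dloga
  dt <- 1 / coch$rate
  cols <- coch$interior_cols
  cols <- cols[cols > 1 & cols < nc]
  rows <- 2:(nr - 1)
  P <- particular_solution(coch$scales, p, gm)
  Q <- Z * exp(-P)        # column-recycling: P is per-row vector
  cf <- structure_coefficients(coch$scales[rows], p, gm)
  modZ <- Mod(Z)
  floorv <- floor_rel * max(modZ, na.rm = TRUE)
  # The particular factor e^{-P} rescales rows by ~ a^{-gamma}; rows are
  # therefore normalised individually and combined with equal weight, so the
  # diagnostic is not dominated by the smallest scales.
  relrow <- rep(NA_real_, length(rows))
  res <- matrix(NA_complex_, length(rows), length(cols))
  for (i in seq_along(rows)) {
    j <- rows[i]
    dq_a <- (Q[j + 1, cols] - Q[j - 1, cols]) / (2 * dl)
    dq_t <- (Q[j, cols + 1] - Q[j, cols - 1]) / (2 * dt)
    e <- dq_a - (cf$C[i] + 1i * cf$D[i]) * dq_t
    ok <- modZ[j, cols] > floorv
    e[!ok] <- NA_complex_
    res[i, ] <- e
    if (any(ok)) {
      sc <- Mod(dq_a[ok]) + Mod((cf$C[i] + 1i * cf$D[i]) * dq_t[ok])
      relrow[i] <- sqrt(sum(Mod(e[ok])^2) / sum(sc^2))
    }
  }
  rel <- sqrt(mean(relrow^2, na.rm = TRUE))
  if (length(res) > 2^22) res <- NULL
  list(rel = rel, rel_rows = relrow, rms = rel, residual = res)
}

#' Local holomorphic model of an amplitude-modulated tone
#'
#' For \eqn{f(t) = (1 + A\cos\mu t)\cos\nu t} with \eqn{0 < \mu \ll \nu}
#' the carrier \eqn{\nu} dominates as long as the sideband terms of the
#' holomorphic function stay small; there
#' \eqn{F(z) = \log G(z) \approx i\nu z + (\gamma - 1/2 - i\alpha)\log\nu +
#' x(z)} (using \eqn{\log(1 + x) \approx x}) with
#' \eqn{x(z) = \frac A2 [r_+ e^{i\mu z} + r_- e^{-i\mu z}]},
#' \eqn{r_\pm = ((\nu\pm\mu)/\nu)^{\gamma - 1/2 - i\alpha}}.  The derivative
#' \eqn{F'} carries the constant \eqn{i\nu} from the carrier plus a slow
#' oscillation at angular frequency \eqn{\mu}.
#'
#' @param A Modulation depth (sideband amplitude ratio), 0 < A < 1.
#' @param mu Modulation rate (rad/s).
#' @param nu Carrier (rad/s), with `mu << nu`.
#' @param p A [filter_params()].
#' @param dominance_threshold Sideband magnitude above which the expansion is
#'   declared out of range (default 0.5).
#' @return List: `F`, `Fprime` (closures in `z`), `a_range` (scales where the
#'   carrier dominates), `omega_range` (corresponding CF interval), `r_plus`,
#'   `r_minus`.
#' @export
am_local_model <- function(A, mu, nu, p, dominance_threshold = 0.5) {
  stopifnot(A > 0, mu > 0, nu > 0)
  if (mu >= nu / 5) stop("need mu << nu for the local model (mu < nu/5)")
  ex <- p$gamma - 0.5 - 1i * p$alpha
  r_plus <- ((nu + mu) / nu)^ex
  r_minus <- ((nu - mu) / nu)^ex
  g <- p$gamma
  # |(A/2) r_- e^{mu a gamma}| < thr  (growing with a)  and
  # |(A/2) r_+ e^{-mu a gamma}| < thr (shrinking with a)
  a_max <- log(dominance_threshold / (A / 2 * Mod(r_minus))) / (mu * g)
  a_min <- max(0, -log(dominance_threshold / (A / 2 * Mod(r_plus))) / (mu * g))
  if (a_max <= a_min)
    stop("dominance condition violated: no scale range where the carrier dominates")
  cst <- log(p$k_amp) + 1i * p$epsilon + (p$gamma - p$kappa / p$c) +
    ex * log(nu)
  Ffun <- function(z)
    1i * nu * z + cst +
      (A / 2) * (r_plus * exp(1i * mu * z) + r_minus * exp(-1i * mu * z))
  Fp <- function(z)
    1i * nu + (A / 2) * 1i * mu *
      (r_plus * exp(1i * mu * z) - r_minus * exp(-1i * mu * z))
  list(F = Ffun, Fprime = Fp,
       a_range = c(a_min, a_max),
       omega_range = c(1 / a_max, if (a_min > 0) 1 / a_min else Inf),
       r_plus = r_plus, r_minus = r_minus)
}

#' Harmonic spectrum (violin-type sound)
#'
#' Fundamental \eqn{\nu} plus complex harmonic coefficients \eqn{c_m},
#' \eqn{m = 1..M}; the signal is \eqn{f(t) = \sum_m \mathrm{Re}(c_m
#' e^{im\nu t})}.
#'
#' @param nu Fundamental circular frequency (rad/s).
#' @param coefficients Complex vector `c_m`.
#' @return Object of class `harmonic_spectrum`.
#' @export
harmonic_spectrum <- function(nu, coefficients) {
  stopifnot(nu > 0, length(coefficients) >= 1, all(is.finite(Mod(coefficients))))
  structure(list(nu = nu, coefficients = as.complex(coefficients),
                 M = length(coefficients)),
            class = "harmonic_spectrum")
}

#' Holomorphic function of a harmonic complex
#'
#' \eqn{G(z) = k e^{i\varepsilon} \sum_m c_m (m\nu)^{\gamma - 1/2 - i\alpha}
#' e^{im\nu z}} — a Fourier series in \eqn{t} whose per-place coefficients
#' \eqn{d_m(a)} decay like \eqn{e^{-m\nu a\gamma}}; at the place coding the
#' n-th harmonic (\eqn{a = 1/(n\nu)}) the coefficient \eqn{d_n} dominates.
#'
#' @param spec A [harmonic_spectrum()].
#' @param p A [filter_params()].
#' @return Function `G(z)`.
#' @export
G_harmonic_complex <- function(spec, p) {
  m <- seq_len(spec$M)
  w <- p$k_amp * exp(1i * p$epsilon) * exp(p$gamma - p$kappa / p$c) *
    spec$coefficients * (m * spec$nu)^(p$gamma - 0.5 - 1i * p$alpha)
  nu <- spec$nu
  function(z) vapply(z, function(zz) sum(w * exp(1i * m * nu * zz)), complex(1))
}

#' Per-place harmonic weights d_m(a)
#'
#' The coefficients of the Fourier series \eqn{G(z(a,t)) = \sum_m d_m(a)
#' e^{im\nu t}} at fixed scale `a`.
#'
#' @param spec A [harmonic_spectrum()].
#' @param p A [filter_params()].
#' @param a Scale (scalar).
#' @return Complex vector `d_m`, m = 1..M (may overflow double range for
#'   large `gamma`; use [harmonic_log_weights()] for comparisons).
#' @export
harmonic_weights <- function(spec, p, a) exp(harmonic_log_weights(spec, p, a))

#' @rdname harmonic_weights
#' @return For the log version, complex `log d_m` (overflow-safe).
#' @export
harmonic_log_weights <- function(spec, p, a) {
  m <- seq_len(spec$M)
  log(p$k_amp) + 1i * p$epsilon + (p$gamma - p$kappa / p$c) +
    log(spec$coefficients) +
    (p$gamma - 0.5 - 1i * p$alpha) * log(m * spec$nu) +
    1i * m * spec$nu * (-a * p$beta + 1i * a * p$gamma)
}

#' Dominant harmonic at a place
#' @inheritParams harmonic_weights
#' @return Index `m` maximising `|d_m(a)|`.
#' @export
dominant_harmonic <- function(spec, p, a)
  which.max(Re(harmonic_log_weights(spec, p, a)))

#' Local expansion of F near the n-th harmonic
#'
#' Splits \eqn{F(z) = \log G(z)} near the place of the n-th harmonic into
#' the carrier part \eqn{in\nu z + (\gamma - 1/2 - i\alpha)\log(n\nu) +
#' \log c_n} and a remainder that is \eqn{2\pi/\nu}-periodic in time.  The
#' two-neighbour approximation keeps only harmonics \eqn{n \pm 1} in the
#' remainder, decomposed via \eqn{s = c_+ + c_-}, \eqn{d = c_+ - c_-}.
#'
#' @param spec A [harmonic_spectrum()].
#' @param p A [filter_params()].
#' @param n Harmonic index (2 <= n <= M - 1 for the two-neighbour form).
#' @return List with closures `carrier(z)`, `remainder(z)` (full series,
#'   periodic), `remainder2(z)` (two-neighbour `log(1+x)~x` form), and the
#'   neighbour weights `c_plus`, `c_minus`, `s`, `d`.
#' @export
harmonic_local_expansion <- function(spec, p, n) {
  stopifnot(n >= 2, n <= spec$M - 1)
  ex <- p$gamma - 0.5 - 1i * p$alpha
  nu <- spec$nu
  cn <- spec$coefficients[n]
  carrier_cst <- log(p$k_amp) + 1i * p$epsilon + (p$gamma - p$kappa / p$c) +
    ex * log(n * nu) + log(cn)
  carrier <- function(z) 1i * n * nu * z + carrier_cst
  # ratio-term series: overflow-safe for large gamma
  m <- seq_len(spec$M)
  lw <- log(spec$coefficients / cn) + ex * log(m / n)
  remainder <- function(z)
    log(vapply(z, function(zz) sum(exp(lw + 1i * (m - n) * nu * zz)),
               complex(1)))
  cp <- spec$coefficients[n + 1] / cn * ((n + 1) / n)^ex
  cm <- spec$coefficients[n - 1] / cn * ((n - 1) / n)^ex
  remainder2 <- function(z) cp * exp(1i * nu * z) + cm * exp(-1i * nu * z)
  list(carrier = carrier, remainder = remainder, remainder2 = remainder2,
       c_plus = cp, c_minus = cm, s = cp + cm, d = cp - cm)
}

#' Holomorphic model of the impulse (click) response
#'
#' At \eqn{c = 1} the analytic click response factorises exactly as
#' \eqn{Z\delta = e^{P(a)} G(z)} with
#' \deqn{F(z) = \log G(z) = K_0 - (\gamma + 1/2 - i\alpha)\,\log z,}
#' principal branch (\eqn{\arg z \in (0, \pi)} on the upper half-plane);
#' \eqn{K_0 = \log[\Gamma(\gamma + 1/2 - i\alpha)\,(-i)^{-(\gamma + 1/2 -
#' i\alpha)}/\pi]} from the closed-form Fourier integral of the extremal
#' function.  In the scale-invariant time \eqn{s = t/a} the phase is
#' \eqn{f(s)} with normalised instantaneous frequency
#' \deqn{f'(s) = \frac{\gamma(\gamma + 1/2) + \alpha(s - \beta)}
#'   {(s-\beta)^2 + \gamma^2},}
#' increasing below \eqn{s = \alpha + \beta}, close to 1 around the
#' envelope peak and decreasing near \eqn{s = \beta}; the log-amplitude
#' slope \eqn{g'(s) = [\alpha\gamma - (\gamma + 1/2)(s - \beta)]/
#' [(s-\beta)^2+\gamma^2]} vanishes at the peak locus
#' \eqn{s^* = \beta + \alpha\gamma/(\gamma + 1/2)}.
#'
#' @param p A [filter_params()].
#' @return Object of class `impulse_model`: closures `F(z)`, `G(z)`,
#'   `f_prime(s)`, `g_prime(s)`, the peak locus `s_peak`, and `K0`.
#' @export
impulse_model <- function(p) {
  ex <- p$gamma + 0.5 - 1i * p$alpha
  K0 <- lgamma_complex(ex) - ex * log(complex(real = 0, imaginary = -1)) -
    log(pi) + log(p$k_amp) + 1i * p$epsilon
  g <- p$gamma; al <- p$alpha; be <- p$beta
  Ffun <- function(z) {
    if (any(Im(z) <= 0))
      stop("F(z) requires Im z > 0 (equivalently Im s > -gamma)")
    K0 - ex * log(z)
  }
  list(
    F = Ffun,
    G = function(z) exp(Ffun(z)),
    f_prime = function(s) (g * (g + 0.5) + al * (s - be)) / ((s - be)^2 + g^2),
    g_prime = function(s) (al * g - (g + 0.5) * (s - be)) / ((s - be)^2 + g^2),
    s_peak = be + al * g / (g + 0.5),
    K0 = K0)
}

#' Frequency-glide profile of the click response
#'
#' Normalised instantaneous frequency \eqn{f'(s)} (instantaneous frequency
#' over CF) as a function of scale-invariant time `s` (in radians of CF;
#' divide by \eqn{2\pi} for periods).
#'
#' @param p A [filter_params()].
#' @param s Scale-invariant times.
#' @return Data frame `s`, `s_periods`, `f_prime`.
#' @export
glide_profile <- function(p, s) {
  im <- impulse_model(p)
  data.frame(s = s, s_periods = s / (2 * pi), f_prime = im$f_prime(s))
}
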