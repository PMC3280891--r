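#' One-parameter invariance-group model
#'
#' A one-parameter transformation group of the positive frequency axis is
#' generated by a vector field \eqn{v(\omega)} (extended oddly to the whole
#' axis): the flow \eqn{\lambda_a = \tau_{\log a}} solves
#' \eqn{d\tau_t/dt = v(\tau_t)}, \eqn{\tau_0(\omega)=\omega}.  On an
#' interval between zeros of \eqn{v} (with \eqn{v < 0} there), the
#' conjugation map \eqn{s(\omega)}, determined up to a factor by
#' \eqn{s'/s = -1/v} and anchored by \eqn{s(\nu_0) = 1}, is strictly
#' increasing onto \eqn{(0, \infty)} and conjugates the flow to pure
#' dilations: \eqn{s(\lambda_a\omega) = s(\omega)/a}.  The dilation group
#' itself is \eqn{v(\omega) = -\omega}, \eqn{s(\omega) = \omega}.
#'
#' If closed forms for `smap`, `smap_inv`, `smap_prime`, `flow`, `eta` are
#' not supplied they are constructed numerically (adaptive quadrature of
#' \eqn{1/v}, root finding, and an embedded Runge-Kutta flow with relative
#' tolerance 1e-10).
#'
#' @param v Vector field, a vectorised function of \eqn{\omega > 0}
#'   (negative on the working interval).
#' @param vprime Its derivative; numeric central difference if omitted.
#' @param zeros Ordered zeros of `v` bounding the working interval
#'   (typically `c(0, R)` or `c(0, Inf)`).
#' @param band Frequency interval of action `c(lo, hi)`; defaults to the
#'   interval between the first two zeros.
#' @param anchor Reference frequency \eqn{\nu_0} with \eqn{s(\nu_0) = 1}.
#' @param smap,smap_inv,smap_prime,flow,eta Optional closed forms;
#'   `flow(a, omega)`, `eta(a)` with \eqn{\eta'(a) = s'(\omega_a)} (the
#'   z-coordinate clock, \eqn{\eta(a) = a} for dilations).
#' @param label Model name for printing.
#' @return Object of class `group_model`.
#' @export
group_model <- function(v, vprime = NULL, zeros = c(0, Inf), band = NULL,
                        anchor = 1, smap = NULL, smap_inv = NULL,
                        smap_prime = NULL, flow = NULL, eta = NULL,
                        label = "custom") {
  if (is.null(band)) band <- c(zeros[1], zeros[2])
  stopifnot(band[1] >= 0, band[2] > band[1], anchor > band[1],
            anchor < band[2])
  if (is.null(vprime)) {
    vprime <- function(w) {
      h <- pmax(1e-6 * abs(w), 1e-9)
      (v(w + h) - v(w - h)) / (2 * h)
    }
  }
  if (is.null(smap)) {
    lo <- band[1]; hi <- band[2]
    s_scalar <- function(w) {
      if (w <= lo || w >= hi) stop("smap: frequency outside the band (",
                                   lo, ", ", hi, ")")
      r <- stats::integrate(function(z) 1 / v(z), anchor, w,
                            rel.tol = 1e-11, subdivisions = 800L)
      if (r$message != "OK")
        stop("non-integrable singularity of 1/v near ", w, ": ", r$message)
      exp(-r$value)
    }
    smap <- function(w) vapply(w, s_scalar, numeric(1))
  }
  if (is.null(smap_prime)) {
    sm <- smap
    smap_prime <- function(w) -sm(w) / v(w)
  }
  if (is.null(smap_inv)) {
    sm <- smap; lo <- band[1]; hi <- band[2]
    inv_scalar <- function(y) {
      stopifnot(y > 0)
      f <- function(lw) sm(exp(lw)) - y
      llo <- log(max(lo, 1e-12) + 1e-12); lhi <- log(min(hi, 1e12))
      # expand until bracketed (s is increasing onto (0, Inf))
      while (f(llo) > 0 && llo > -60) llo <- llo - 2
      while (f(lhi) < 0 && lhi < 60) lhi <- lhi + 2
      exp(stats::uniroot(f, c(llo, lhi), tol = 1e-13)$root)
    }
    smap_inv <- function(y) vapply(y, inv_scalar, numeric(1))
  }
  if (is.null(flow)) {
    vv <- v
    flow <- function(a, omega) {
      vapply(omega, function(w) {
        if (abs(vv(w)) < 1e-300) return(w)   # fixed point
        rk45(vv, w, log(a))
      }, numeric(1))
    }
  }
  if (is.null(eta)) {
    sp <- smap_prime; si <- smap_inv
    eta <- function(a) {
      vapply(a, function(ai) {
        1 + stats::integrate(function(u) sp(si(1 / u)), 1, ai,
                             rel.tol = 1e-9)$value
      }, numeric(1))
    }
  }
  structure(list(v = v, vprime = vprime, zeros = zeros, band = band,
                 anchor = anchor, smap = smap, smap_inv = smap_inv,
                 smap_prime = smap_prime, flow = flow, eta = eta,
                 label = label),
            class = "group_model")
}

#' @export
print.group_model <- function(x, ...) {
  cat(sprintf("Group model '%s': band (%g, %g) rad/s, anchor %g\n",
              x$label, x$band[1], x$band[2], x$anchor))
  invisible(x)
}

#' Group flow
#'
#' \eqn{\lambda_a \omega}; fixed points of the vector field are returned
#' exactly.
#' @param gm A [group_model()].
#' @param a Group parameter, > 0.
#' @param omega Frequencies.
#' @return Transformed frequencies.
#' @export
group_flow <- function(gm, a, omega) {
  stopifnot(inherits(gm, "group_model"), a > 0)
  gm$flow(a, omega)
}

#' Conjugation map of a group model
#' @param gm A [group_model()].
#' @return List `s`, `s_inv`, `s_prime`.
#' @export
conjugation_map <- function(gm) {
  stopifnot(inherits(gm, "group_model"))
  list(s = gm$smap, s_inv = gm$smap_inv, s_prime = gm$smap_prime)
}

#' Dilation group (reference model)
#'
#' \eqn{v(\omega) = -\omega}: the general machinery reduces exactly to the
#' standard wavelet model. All maps are closed-form.
#' @return A [group_model()].
#' @export
model_dilation <- function() {
  group_model(v = function(w) -w,
              vprime = function(w) rep(-1, length(w)),
              zeros = c(0, Inf), band = c(0, Inf), anchor = 1,
              smap = identity,
              smap_inv = identity,
              smap_prime = function(w) rep(1, length(w)),
              flow = function(a, omega) omega / a,
              eta = function(a) a,
              label = "dilation")
}

#' Example model 1: banded affine-in-log group
#'
#' Generated by \eqn{v(\omega) = -\omega\,\log(R/\omega)/\log(R/K)},
#' the conjugate (via the rough exponential tonotopic map) of an affine
#' vector field along the place axis.  Zeros at 0 and at the absolute
#' frequency bound \eqn{R}: the model is completely indifferent to spectral
#' content beyond \eqn{R}.  Closed forms:
#' flow \eqn{\lambda_a\omega = R(\omega/R)^{a^{1/L}}} and conjugation
#' \eqn{s(\omega) = (\log(R/\omega)/L)^{-L}} with \eqn{L = \log(R/K)}.
#' As \eqn{R \to \infty} the model approaches the dilation group on
#' compacta.
#'
#' @param R_hz Absolute upper frequency bound in Hz. Default 40000.
#' @param K_hz Reference (anchor) frequency in Hz where \eqn{s = 1} and
#'   \eqn{v = -\omega}. Default 20000.
#' @return A [group_model()].
#' @export
model_example_1 <- function(R_hz = 40000, K_hz = 20000) {
  stopifnot(R_hz > K_hz, K_hz > 0)
  R <- 2 * pi * R_hz
  K <- 2 * pi * K_hz
  L <- log(R / K)
  group_model(
    v = function(w) ifelse(w <= 0 | w >= R, 0, -w * log(R / w) / L),
    vprime = function(w) ifelse(w <= 0 | w >= R, 0, (1 - log(R / w)) / L),
    zeros = c(0, R), band = c(0, R), anchor = K,
    smap = function(w) (log(R / w) / L)^(-L),
    smap_inv = function(y) R * exp(-L * y^(-1 / L)),
    smap_prime = function(w) (log(R / w) / L)^(-L - 1) / w,
    flow = function(a, omega)
      ifelse(omega <= 0 | omega >= R, omega, R * (omega / R)^(a^(1 / L))),
    label = "example1")
}

#' Example model 2: shifted (physiological) tonotopy group
#'
#' Conjugate of pure dilations under the shift map
#' \eqn{s(\omega) = (\omega + S)/(\nu_0 + S)}: the group of the
#' physiological tonotopic axis \eqn{\xi(x) = K e^{-x/l} - S}.  The raw
#' shift map does not fix the origin, so it is blended on \eqn{(0,
#' \varepsilon)} into a monotone C1 cubic Hermite arc through 0, leaving
#' \eqn{s} unchanged for \eqn{\omega \ge \varepsilon} (\eqn{\varepsilon}
#' can be made arbitrarily small).  The scaling variable of this model is
#' the shift-generalised \eqn{(\omega + S)/(\xi(x) + S)}, and the
#' group parameter relates to place by \eqn{a = (\nu_0 + S)/(\xi(x) + S)}.
#'
#' @param map A shifted [tonotopic_map()] supplying `K`, `S` (rad/s).
#' @param nu0 Anchor frequency in rad/s; default \eqn{\xi(0) = K - S}.
#' @param eps_omega Blend width near 0 in rad/s. Default 1.
#' @return A [group_model()].
#' @export
model_example_2 <- function(map = tonotopic_map("shifted"),
                            nu0 = NULL, eps_omega = 1) {
  stopifnot(inherits(map, "tonotopic_map"), map$S > 0)
  S <- map$S
  if (is.null(nu0)) nu0 <- map$K - map$S
  stopifnot(nu0 > 0, eps_omega > 0, eps_omega < nu0 / 10)
  den <- nu0 + S
  eps <- eps_omega
  p1 <- (eps + S) / den       # s at the blend edge
  m1 <- 1 / den               # slope at the blend edge
  m0 <- p1 / eps              # secant slope at 0 (monotone by Fritsch-Carlson)
  herm <- function(w) {       # C1 monotone cubic: (0,0,m0) -> (eps,p1,m1)
    u <- w / eps
    (u^3 - 2 * u^2 + u) * eps * m0 + (-2 * u^3 + 3 * u^2) * p1 +
      (u^3 - u^2) * eps * m1
  }
  herm_p <- function(w) {
    u <- w / eps
    (3 * u^2 - 4 * u + 1) * m0 + (-6 * u^2 + 6 * u) * p1 / eps +
      (3 * u^2 - 2 * u) * m1
  }
  sm <- function(w) ifelse(w >= eps, (w + S) / den, herm(pmax(w, 0)))
  smp <- function(w) ifelse(w >= eps, m1, herm_p(pmax(w, 0)))
  sm_inv_scalar <- function(y) {
    if (y >= p1) den * y - S
    else stats::uniroot(function(w) herm(w) - y, c(0, eps), tol = 1e-14)$root
  }
  sm_inv <- function(y) vapply(y, sm_inv_scalar, numeric(1))
  gm <- group_model(
    v = function(w) -sm(w) / smp(w),
    vprime = function(w) ifelse(w >= eps, -1,
                                -1 + sm(w) * vapply(w, function(x)
                                  if (x < eps && x > 0) {
                                    h <- x * 1e-6 + 1e-12
                                    (herm_p(min(x + h, eps)) - herm_p(max(x - h, 0))) /
                                      (min(x + h, eps) - max(x - h, 0))
                                  } else 0, numeric(1)) / smp(w)^2),
    zeros = c(0, Inf), band = c(0, Inf), anchor = nu0,
    smap = sm, smap_inv = sm_inv, smap_prime = smp,
    flow = function(a, omega) sm_inv(sm(omega) / a),
    eta = function(a) 1 + (a - 1) / den,
    label = "example2")
  gm$shift <- S
  gm$nu0 <- nu0
  gm
}

#' Scale grid for a group model
#'
#' Log-spaced group parameters \eqn{a_j} whose row localisations
#' \eqn{\omega_a = s^{-1}(1/a)} cover a frequency band: \eqn{a} runs from
#' \eqn{1/s(\omega_{hi})} to \eqn{1/s(\omega_{lo})}.  For the dilation group
#' this coincides with [scale_grid()]'s band construction.
#'
#' @param gm A [group_model()].
#' @param f_lo_hz,f_hi_hz Band edges in Hz (must lie inside the model band).
#' @param per_decade Scales per decade of `a`. Default 128.
#' @param a_margin Multiplicative margin `c(low, high)` applied to the `a`
#'   range so the filter support (roughly `a*s(omega)` in `[1/4, 4]`) is
#'   fully covered at the band edges; default `c(0.25, 4)`.
#' @return Numeric vector of scales (usable wherever a grid is accepted).
#' @export
group_scale_grid <- function(gm, f_lo_hz, f_hi_hz, per_decade = 128,
                             a_margin = c(0.25, 4)) {
  stopifnot(inherits(gm, "group_model"), f_hi_hz > f_lo_hz)
  wlo <- 2 * pi * f_lo_hz; whi <- 2 * pi * f_hi_hz
  if (wlo <= gm$band[1] || whi >= gm$band[2])
    stop(sprintf("band [%g, %g] Hz outside the model band (%g, %g) rad/s",
                 f_lo_hz, f_hi_hz, gm$band[1], gm$band[2]))
  a_lo <- a_margin[1] / gm$smap(whi)
  a_hi <- a_margin[2] / gm$smap(wlo)
  n <- max(5L, ceiling(log10(a_hi / a_lo) * per_decade) + 1L)
  exp(seq(log(a_lo), log(a_hi), length.out = n))
}

# Safe evaluation of the pulled-back wavelet in the frequency domain:
# sqrt(a s'(omega)) h_c(a s(omega)), zero outside the band or where the
# argument is so large that h underflows (guards 0 * Inf near a band edge
# where s' blows up).
group_wavelet_hat <- function(omega_pos, a, p, gm) {
  out <- complex(length(omega_pos))
  lo <- gm$band[1]; hi <- gm$band[2]
  inb <- omega_pos > lo & omega_pos < hi
  if (!any(inb)) return(out)
  w <- omega_pos[inb]
  sv <- gm$smap(w)
  wlim <- (600 * p$c / p$kappa)^(1 / p$c)   # |h| < 1e-260 beyond this
  okm <- a * sv < wlim & sv > 0
  vals <- complex(length(w))
  if (any(okm))
    vals[okm] <- sqrt(a * gm$smap_prime(w[okm])) *
      extremal_h(a * sv[okm], p)
  out[inb] <- vals
  out
}

#' General extremal function of a group model
#'
#' Pullback of the dilation-group extremal through the conjugation map:
#' \eqn{h^{gm}_c(\omega) = \sqrt{s'(\omega)}\, h_c(s(\omega))}
#' (the conjugation isometry maps extremals to extremals; for the dilation
#' model this is bit-identical to [extremal_h()]).
#'
#' @param gm A [group_model()].
#' @param p A [filter_params()].
#' @return List of vectorised closures `h(omega)`, `hprime(omega)`.
#' @export
general_extremal <- function(gm, p) {
  stopifnot(inherits(gm, "group_model"), inherits(p, "filter_params"))
  h <- function(w) {
    out <- complex(length(w))
    inb <- w > gm$band[1] & w < gm$band[2]
    if (any(inb)) {
      sv <- gm$smap(w[inb])
      sp <- gm$smap_prime(w[inb])
      wlim <- (600 * p$c / p$kappa)^(1 / p$c)
      ok <- sv < wlim & sv > 0
      vals <- complex(sum(inb))
      if (any(ok)) vals[ok] <- sqrt(sp[ok]) * extremal_h(sv[ok], p)
      out[inb] <- vals
    }
    out
  }
  hprime <- function(w) {
    # d/dw [ sqrt(s') h(s) ] = s''/(2 sqrt(s')) h(s) + s'^{3/2} h'(s)
    hh <- pmax(1e-7 * abs(w), 1e-10)
    (h(w + hh) - h(w - hh)) / (2 * hh)
  }
  list(h = h, hprime = hprime)
}

#' Group wavelet transform
#'
#' [analytic_transform()] with the \eqn{\lambda_a}-translated wavelet family
#' of a group model; reduces to the standard transform for the dilation
#' group.  Warns when more than 1% of the signal energy lies outside the
#' model's frequency band (a banded model is indifferent to it).
#'
#' @inheritParams analytic_transform
#' @param gm A [group_model()].
#' @return A `cochleogram`.
#' @export
group_wavelet_transform <- function(f, gm, p, grid, pad = TRUE, taper = 0.1,
                                    polar = TRUE) {
  stopifnot(inherits(gm, "group_model"))
  n <- length(f$samples)
  X <- stats::fft(f$samples)
  om <- 2 * pi * (0:(n - 1)) * f$rate / n
  om[om >= pi * f$rate] <- om[om >= pi * f$rate] - 2 * pi * f$rate
  inband <- abs(om) < gm$band[2] & abs(om) > gm$band[1]
  etot <- sum(Mod(X)^2)
  if (etot > 0 && sum(Mod(X[!inband])^2) / etot > 0.01)
    warning("more than 1% of signal energy lies outside the model band; ",
            "the transform (and any reconstruction) ignores it")
  analytic_transform(f, grid, p, gm = gm, pad = pad, taper = taper,
                     polar = polar)
}

#' Admissibility constant of the extremal wavelet
#'
#' \eqn{C_h = \int_0^\infty |h_c(u)|^2\, du/u} (the invariant-measure norm
#' entering the reconstruction formula); closed Gamma form
#' \eqn{k^2 c^{-1} (c/2\kappa)^{(2\kappa-1)/c}\,\Gamma((2\kappa-1)/c)},
#' finite for \eqn{\kappa > 1/2}.
#'
#' @param p A [filter_params()].
#' @return Positive scalar.
#' @export
admissibility_constant <- function(p) {
  stopifnot(p$kappa > 0.5)
  ex <- (2 * p$kappa - 1) / p$c
  p$k_amp^2 / p$c * (p$c / (2 * p$kappa))^ex * gamma(ex)
}

#' Weak reconstruction from a cochleogram
#'
#' Recovers the band-limited projection of the analysed signal by the
#' L2-duality formula: in the frequency domain
#' \deqn{\hat f_{rec}(\omega) = \frac{1}{2\,C_h\, s'(\omega)}
#'   \int \hat Z(a, \omega)\, \overline{w_a(\omega)}\, \frac{da}{a^2},}
#' with \eqn{C_h} the admissibility constant (computed independently in
#' closed form, not from the grid).  For a broadband input the result is
#' the projection onto the band the filterbank covers.
#'
#' @param coch A cochleogram computed with `taper = 0` (periodic analysis).
#' @param p,gm Model parameters; default those stored in the cochleogram.
#' @return A [sampled_signal()] with the reconstructed samples.
#' @export
reconstruct_signal <- function(coch, p = coch$params, gm = coch$gm) {
  Ch <- admissibility_constant(p)
  if (!is.finite(Ch) || Ch < 1e-12)
    stop("admissibility constant vanishes or diverges; not invertible")
  if (is.na(coch$dloga)) stop("reconstruction needs a uniform log-scale grid")
  n <- ncol(coch$Z)
  rate <- coch$rate
  kpos <- 2:(floor(n / 2))
  om <- 2 * pi * (kpos - 1) * rate / n
  acc <- complex(length(kpos))
  for (j in seq_len(nrow(coch$Z))) {
    if (isTRUE(coch$row_masked[j])) next
    Rj <- stats::fft(coch$Z[j, ])[kpos]
    wj <- wavelet_hat_row(om, coch$scales[j], p, gm)
    acc <- acc + Rj * Conj(wj) / coch$scales[j]
  }
  sp <- if (is.null(gm)) rep(1, length(om)) else {
    v <- gm$smap_prime(om)
    v[!(om > gm$band[1] & om < gm$band[2])] <- Inf  # no content recoverable
    v
  }
  fhat <- acc * coch$dloga / (2 * Ch * sp)
  full <- complex(n)
  full[kpos] <- fhat
  full[n + 2 - kpos] <- Conj(fhat)
  sampled_signal(Re(stats::fft(full, inverse = TRUE)) / n, rate)
}
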