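#' Extremal filter parameters
#'
#' Parameters of the extremal (coherent-state) function \eqn{h_c} of the
#' uncertainty principle for the affine-times-circle group.  On
#' \eqn{\omega > 0} the filter is
#' \deqn{h_c(\omega) = k\,e^{i\varepsilon}\,
#'   \omega^{\kappa - 1/2}\, e^{-i(\alpha\log\omega + \beta\omega)}\,
#'   e^{-(\kappa/c)\,\omega^c},}
#' extended conjugate-symmetrically to negative frequencies.  The level
#' parameter \eqn{c} indexes the linearisation level of the compressive
#' cochlea (\eqn{c \approx 1}: high sound level; \eqn{c \gg 1}: low level),
#' \eqn{\kappa > 0} sets the sharpness, \eqn{\alpha} (typically negative) the
#' logarithmic phase coefficient, \eqn{\beta} a pure time delay and
#' \eqn{\varepsilon} a constant phase offset.  With this parameterisation the
#' frequency localisation (the generalised expectation
#' \eqn{\nu_c(h)^c = \int \omega^c |h|^2 / \int |h|^2}) is exactly 1; the
#' field `nu` stores a dilation factor for members of the family with other
#' localisations, so that `extremal_h` evaluates
#' \eqn{\nu^{-1/2} h_c(\omega/\nu)}.
#'
#' @param c Level parameter, > 0. Default 1.
#' @param kappa Sharpness, > 0. Default 4.
#' @param alpha Logarithmic phase coefficient (real). Default `-pi`.
#' @param beta Pure delay in units of scaled time. Default `2*pi`.
#' @param epsilon Constant phase offset (radians). Default `2*pi`.
#' @param k_amp Positive amplitude constant. Default 1.
#' @param nu Frequency localisation (dilation of the normalised member).
#'   Default 1.
#' @return An object of class `filter_params`; `gamma = c*kappa` is stored.
#' @export
filter_params <- function(c = 1, kappa = 4, alpha = -pi, beta = 2 * pi,
                          epsilon = 2 * pi, k_amp = 1, nu = 1) {
  stopifnot(c > 0, kappa > 0, k_amp > 0, nu > 0)
  structure(list(c = c, kappa = kappa, gamma = c * kappa, alpha = alpha,
                 beta = beta, epsilon = epsilon, k_amp = k_amp, nu = nu),
            class = "filter_params")
}

#' @export
print.filter_params <- function(x, ...) {
  cat(sprintf(
    "Extremal filter: c = %g, kappa = %g (gamma = %g), alpha = %g, beta = %g, eps = %g, nu = %g\n",
    x$c, x$kappa, x$gamma, x$alpha, x$beta, x$epsilon, x$nu))
  invisible(x)
}

#' Named parameter presets
#'
#' Presets matching the worked figures of the model:
#' `"fig1"` (c = 1, kappa = 4, alpha = -pi, beta = 2*pi, eps = 2*pi),
#' `"fig2"` (phase example: eps = 16*pi, alpha = -7.8*pi, beta = 24*pi,
#' kappa = 4), `"fig5"` (impulse response at low CF: kappa = 12; alpha = -pi
#' and beta = 4*pi are this package's choice, see the methods vignette) and
#' `"fig6"` (frequency glide: alpha = -5.3*pi, beta = 16*pi, gamma = 32*pi
#' realised as c = 8, kappa = 4*pi).
#'
#' @param name One of `"fig1"`, `"fig2"`, `"fig5"`, `"fig6"`.
#' @param c Optional level-parameter override.
#' @return A [filter_params()] object.
#' @export
filter_preset <- function(name = c("fig1", "fig2", "fig5", "fig6"), c = NULL) {
  name <- match.arg(name)
  p <- switch(name,
    fig1 = filter_params(c = 1, kappa = 4, alpha = -pi, beta = 2 * pi,
                         epsilon = 2 * pi),
    fig2 = filter_params(c = 1, kappa = 4, alpha = -7.8 * pi, beta = 24 * pi,
                         epsilon = 16 * pi),
    fig5 = filter_params(c = 1, kappa = 12, alpha = -pi, beta = 4 * pi,
                         epsilon = 0),
    fig6 = filter_params(c = 8, kappa = 4 * pi, alpha = -5.3 * pi,
                         beta = 16 * pi, epsilon = 0))
  if (!is.null(c)) p <- filter_params(c = c, kappa = p$kappa, alpha = p$alpha,
                                      beta = p$beta, epsilon = p$epsilon,
                                      k_amp = p$k_amp, nu = p$nu)
  p
}

#' Evaluate the extremal function
#'
#' Closed-form evaluation of \eqn{\nu^{-1/2} h_c(\omega/\nu)} on
#' \eqn{\omega > 0}.  Use [conj_symmetric()] for the extension to the whole
#' axis.
#'
#' @param omega Circular frequencies, all > 0.
#' @param p A [filter_params()].
#' @return Complex vector.
#' @export
extremal_h <- function(omega, p) {
  stopifnot(inherits(p, "filter_params"))
  if (any(omega <= 0))
    stop("extremal_h is defined on omega > 0; use conj_symmetric() for the extension")
  w <- omega / p$nu
  p$k_amp / sqrt(p$nu) * exp(
    (p$kappa - 0.5) * log(w) - (p$kappa / p$c) * w^p$c +
      1i * (p$epsilon - p$alpha * log(w) - p$beta * w))
}

#' Derivative of the extremal function
#'
#' Analytic \eqn{d h/d\omega} of [extremal_h()] (used by the uncertainty
#' functionals and the ODE-residual checks).
#' @inheritParams extremal_h
#' @return Complex vector.
#' @export
extremal_h_prime <- function(omega, p) {
  w <- omega / p$nu
  # omega h'(omega) = [ (kappa - 1/2 - i alpha) - (i beta + kappa w^{c-1}) w ] h
  h <- extremal_h(omega, p)
  ((p$kappa - 0.5 - 1i * p$alpha) / w - 1i * p$beta - p$kappa * w^(p$c - 1)) *
    h / p$nu
}

#' Conjugate-symmetric extension of a positive-frequency filter
#'
#' Evaluates \eqn{\hat g(-\omega) = \overline{\hat g(\omega)}} so that the
#' time-domain response is real; returns 0 at \eqn{\omega = 0}.
#'
#' @param omega Circular frequencies (any sign).
#' @param fun Function of positive frequency returning complex values.
#' @return Complex vector.
#' @export
conj_symmetric <- function(omega, fun) {
  out <- complex(length(omega))
  pos <- omega > 0
  neg <- omega < 0
  if (any(pos)) out[pos] <- fun(omega[pos])
  if (any(neg)) out[neg] <- Conj(fun(-omega[neg]))
  out
}

#' Frequency localisation of a filter
#'
#' The generalised expectation value
#' \eqn{\nu_c(h) = (\int_0^\infty \omega^c |h|^2 d\omega /
#' \int_0^\infty |h|^2 d\omega)^{1/c}}, computed by adaptive quadrature.
#'
#' @param h Function of positive frequency (complex values), e.g.
#'   `function(w) extremal_h(w, p)`.
#' @param c Level parameter entering the moment, > 0.
#' @param upper Upper integration limit (default `Inf`).
#' @return Localisation (positive scalar).
#' @export
localization <- function(h, c = 1, upper = Inf) {
  dens <- function(w) Mod(h(w))^2
  quad <- function(f) {
    r <- stats::integrate(f, 0, upper, rel.tol = 1e-10,
                          subdivisions = 500L, stop.on.error = FALSE)
    if (!grepl("OK|roundoff", r$message))
      stop("localization quadrature failed: ", r$message)
    r$value
  }
  (quad(function(w) w^c * dens(w)) / quad(dens))^(1 / c)
}

#' Rescale filter parameters to unit localisation
#'
#' Measures \eqn{\nu_c} of the parameterised filter by quadrature and divides
#' the stored dilation `nu` by it, so the result has localisation 1 (within
#' quadrature tolerance).  Idempotent for already-normalised input.
#'
#' @param p A [filter_params()].
#' @return A [filter_params()] with `nu` adjusted.
#' @export
normalize_localization <- function(p) {
  nu_meas <- localization(function(w) extremal_h(w, p), c = p$c)
  filter_params(c = p$c, kappa = p$kappa, alpha = p$alpha, beta = p$beta,
                epsilon = p$epsilon, k_amp = p$k_amp, nu = p$nu / nu_meas)
}

#' Basilar-membrane transfer function at a place
#'
#' The transfer function \eqn{\hat g_c(x, \omega)} at place `x` is the
#' group translate of the normalised extremal function localised at the
#' characteristic frequency \eqn{\xi(x)}.  For the dilation group (default)
#' this is \eqn{\sqrt a\, h_c(a\omega)} with \eqn{a = 1/\xi(x)}; for a
#' general one-parameter group model it is the pullback
#' \eqn{\sqrt{a\,s'(\omega)}\, h_c(a\,s(\omega))} with \eqn{a = 1/s(\xi(x))}
#' (see [group_model()]).  Negative frequencies are filled by conjugate
#' symmetry.
#'
#' @param x Place in mm.
#' @param omega Frequency grid in rad/s (any sign; 0 maps to 0).
#' @param p A [filter_params()].
#' @param map A [tonotopic_map()].
#' @param gm Optional [group_model()]; `NULL` means the dilation group.
#' @return List of class `transfer_function`: `x`, `omega`, `values`
#'   (complex), `a` (group parameter), `cf` (\eqn{\xi(x)}, rad/s).
#' @export
transfer_function <- function(x, omega, p, map = tonotopic_map("exponential"),
                              gm = NULL) {
  stopifnot(inherits(p, "filter_params"))
  xi <- position_to_frequency(x, map)
  if (is.null(gm)) {
    a <- 1 / xi
    vals <- conj_symmetric(omega, function(w) sqrt(a) * extremal_h(a * w, p))
  } else {
    a <- 1 / gm$smap(xi)
    vals <- conj_symmetric(omega, function(w) group_wavelet_hat(w, a, p, gm))
  }
  structure(list(x = x, omega = omega, values = vals, a = a, cf = xi,
                 params = p),
            class = "transfer_function")
}

#' Closed-form modulus peak of the transfer function
#'
#' The modulus of \eqn{\hat g_c(x,\cdot)} peaks at
#' \eqn{\omega^* = \xi(x)\,(1 - 1/(2\kappa))^{1/c}}, strictly below the
#' frequency localisation \eqn{\xi(x)} and approaching it monotonically as
#' the level parameter \eqn{c} grows. Requires \eqn{\kappa > 1/2}.
#'
#' @param p A [filter_params()].
#' @param x Place in mm.
#' @param map A [tonotopic_map()].
#' @return Circular frequency of the modulus maximum (rad/s).
#' @export
modulus_peak <- function(p, x, map = tonotopic_map("exponential")) {
  stopifnot(inherits(p, "filter_params"), p$kappa > 0.5)
  xi <- position_to_frequency(x, map)
  xi * p$nu * (1 - 1 / (2 * p$kappa))^(1 / p$c)
}

#' Export a transfer function as a delimited table
#'
#' Writes tab-separated columns `omega`, `re`, `im`, `mod`, `arg` with a
#' commented header.
#' @param tf A [transfer_function()].
#' @param file Path or connection.
#' @return `file`, invisibly.
#' @export
write_transfer_table <- function(tf, file) {
  stopifnot(inherits(tf, "transfer_function"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# transfer function at x = %g mm (CF %g rad/s)",
                     tf$x, tf$cf), con)
  writeLines("# omega\tre\tim\tmod\targ", con)
  utils::write.table(
    data.frame(omega = tf$omega, re = Re(tf$values), im = Im(tf$values),
               mod = Mod(tf$values), arg = Arg(tf$values)),
    con, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(file)
}
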