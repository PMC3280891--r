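# Uncertainty functionals for the affine-times-circle group and its
# generalisations.  Everything is formulated on the positive frequency axis
# for the analytic representative of a real signal; the relevant operators
# act there as
#   L h     = -v h' - v'/2 h      (generator of the unitary group action;
#                                  dilation group v = -omega: omega h' + h/2)
#   H h     = -i h                (Hilbert transform)
#   M h     = -i s(omega) h      (multiplier with [L, M] = M)
#   M_c h   = -i s(omega)^c h
# The extremal functions make the uncertainty inequality for the pair
# (L - alpha H - beta M, H M_c + nu^c) an equality.

#' Uncertainty functionals of a filter
#'
#' Computes, by adaptive quadrature, the frequency localisation
#' \eqn{\nu_c(h)} and the minimising phase/delay coefficients
#' \eqn{\alpha(h), \beta(h)} of the modified generator
#' \eqn{L - \alpha H - \beta M}.  For a general one-parameter group model the
#' frequency variable is replaced by the conjugation map \eqn{s(\omega)} and
#' the generator uses the model's vector field.
#'
#' @param h Function of positive frequency returning complex values.
#' @param hprime Its derivative (complex values).
#' @param c Level parameter (moment order), default 1.
#' @param gm Optional [group_model()]; `NULL` means the dilation group.
#' @param upper Upper integration limit; defaults to the model band edge or
#'   `Inf`.
#' @return List with `nu` (localisation, in `s`-units), `alpha`, `beta`,
#'   `norm2` (squared norm), and the raw moments used.
#' @export
uncertainty_functionals <- function(h, hprime, c = 1, gm = NULL, upper = NULL) {
  if (is.null(upper)) upper <- if (is.null(gm)) Inf else gm$band[2]
  smap <- if (is.null(gm)) identity else gm$smap
  vfun <- if (is.null(gm)) function(w) -w else gm$v
  vpfun <- if (is.null(gm)) function(w) rep(-1, length(w)) else gm$vprime

  quad <- function(f) {
    r <- stats::integrate(f, 0, upper, rel.tol = 1e-9, abs.tol = 1e-12,
                          subdivisions = 500L, stop.on.error = FALSE)
    if (!r$message %in% c("OK", "roundoff error was detected"))
      stop("uncertainty quadrature failed: ", r$message)
    r$value
  }
  dens <- function(w) Mod(h(w))^2
  n2 <- quad(dens)
  sc_mom <- quad(function(w) smap(w)^c * dens(w))
  nu <- (sc_mom / n2)^(1 / c)

  Lh <- function(w) -vfun(w) * hprime(w) - 0.5 * vpfun(w) * h(w)
  # minimise || Lh - alpha*(-i h) - beta*(-i s h) ||^2 over real alpha, beta
  g11 <- n2
  g12 <- quad(function(w) smap(w) * dens(w))
  g22 <- quad(function(w) smap(w)^2 * dens(w))
  r1 <- quad(function(w) Re(Conj(-1i * h(w)) * Lh(w)))
  r2 <- quad(function(w) Re(Conj(-1i * smap(w) * h(w)) * Lh(w)))
  sol <- solve(matrix(c(g11, g12, g12, g22), 2), c(r1, r2))
  list(nu = nu, alpha = sol[1], beta = sol[2], norm2 = n2,
       moments = c(s = g12 / n2, s2 = g22 / n2, sc = sc_mom / n2))
}

#' Uncertainty inequality gap
#'
#' Left-minus-right of the Cauchy-Schwarz form of the uncertainty inequality:
#' \deqn{\|(L - \alpha H - \beta M) h\| \cdot \|(H M_c + \nu^c) h\| \ge
#'   |\mathrm{Re}\langle (L - \alpha H - \beta M)h, (H M_c + \nu^c)h\rangle|.}
#' The gap is non-negative for every admissible `h` and vanishes exactly for
#' the extremal functions (with their own minimising parameters).
#'
#' @inheritParams uncertainty_functionals
#' @param alpha,beta,nu Parameters of the modified operators; by default the
#'   minimisers computed by [uncertainty_functionals()].
#' @return List with `lhs` (product of norms), `rhs` (|Re inner product|),
#'   `gap = lhs - rhs`, and `gap_rel = gap / lhs`.
#' @export
uncertainty_gap <- function(h, hprime, c = 1, gm = NULL,
                            alpha = NULL, beta = NULL, nu = NULL,
                            upper = NULL) {
  if (is.null(upper)) upper <- if (is.null(gm)) Inf else gm$band[2]
  if (is.null(alpha) || is.null(beta) || is.null(nu)) {
    uf <- uncertainty_functionals(h, hprime, c = c, gm = gm, upper = upper)
    if (is.null(alpha)) alpha <- uf$alpha
    if (is.null(beta)) beta <- uf$beta
    if (is.null(nu)) nu <- uf$nu
  }
  smap <- if (is.null(gm)) identity else gm$smap
  vfun <- if (is.null(gm)) function(w) -w else gm$v
  vpfun <- if (is.null(gm)) function(w) rep(-1, length(w)) else gm$vprime

  quad <- function(f) {
    r <- stats::integrate(f, 0, upper, rel.tol = 1e-9, abs.tol = 1e-12,
                          subdivisions = 500L, stop.on.error = FALSE)
    if (!r$message %in% c("OK", "roundoff error was detected"))
      stop("uncertainty quadrature failed: ", r$message)
    r$value
  }
  Afun <- function(w)  # (L - alpha H - beta M) h : skew-hermitian part
    -vfun(w) * hprime(w) - 0.5 * vpfun(w) * h(w) +
      1i * alpha * h(w) + 1i * beta * smap(w) * h(w)
  Wfun <- function(w)  # (H M_c + nu^c) h : hermitian multiplier (nu^c - s^c)
    (nu^c - smap(w)^c) * h(w)
  na <- sqrt(quad(function(w) Mod(Afun(w))^2))
  nw <- sqrt(quad(function(w) Mod(Wfun(w))^2))
  ip <- quad(function(w) Re(Conj(Afun(w)) * Wfun(w)))
  list(lhs = na * nw, rhs = abs(ip), gap = na * nw - abs(ip),
       gap_rel = if (na * nw > 0) (na * nw - abs(ip)) / (na * nw) else 0)
}

#' Residual of the extremal differential equation
#'
#' The extremal functions satisfy, on \eqn{\omega > 0},
#' \deqn{\omega h'(\omega) = [(\kappa - 1/2 - i\alpha)
#'   - i\beta\omega - \kappa\omega^c]\, h(\omega).}
#' This helper evaluates the relative residual of that identity for an
#' arbitrary pair `(h, hprime)` on a grid — used to verify the closed form
#' against finite differences and to show perturbed functions fail it.
#'
#' @param omega Positive frequency grid.
#' @param h,hprime Complex values of the function and its derivative on
#'   `omega`.
#' @param p A [filter_params()] (must have `nu = 1`).
#' @return Relative RMS residual (scalar).
#' @export
extremal_ode_residual <- function(omega, h, hprime, p) {
  stopifnot(abs(p$nu - 1) < 1e-12)
  rhs <- ((p$kappa - 0.5 - 1i * p$alpha) - 1i * p$beta * omega -
            p$kappa * omega^p$c) * h
  lhs <- omega * hprime
  sqrt(mean(Mod(lhs - rhs)^2) / mean(Mod(rhs)^2))
}
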