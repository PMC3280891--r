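#' Structure-equation coefficients
#'
#' The analytic wavelet transform of any signal satisfies (exactly at level
#' parameter \eqn{c = 1}, approximately otherwise) the complex structure
#' equation
#' \deqn{a\,\partial_a \log Zf = (A + iB) + (C + iD)\,\partial_t \log Zf,}
#' whose real and imaginary parts couple the temporal and place derivatives
#' of log-amplitude \eqn{\log r} and phase \eqn{\varphi}:
#' \deqn{a\,\partial_a \log r = A + C\,\partial_t \log r - D\,\partial_t\varphi,}
#' \deqn{a\,\partial_a \varphi = B + D\,\partial_t \log r + C\,\partial_t\varphi.}
#' For the dilation group the coefficients are the constants-per-scale
#' \eqn{A = \gamma}, \eqn{B = -\alpha}, \eqn{C = -a\beta}, \eqn{D = a\gamma}
#' (\eqn{\gamma = c\kappa}; the \eqn{\sqrt a} normalisation shift is
#' absorbed into \eqn{A}).  For a general one-parameter group with
#' conjugation map \eqn{s(\omega)}, writing \eqn{\omega_a = s^{-1}(1/a)} for
#' the row's frequency localisation and \eqn{q_a = a\,s'(\omega_a)},
#' \deqn{A = \gamma q_a \omega_a,\quad B = -\alpha - \beta(1 - q_a\omega_a),
#'   \quad C = -\beta q_a,\quad D = \gamma q_a,}
#' which reduces exactly to the dilation constants when \eqn{v(\omega) =
#' -\omega} (then \eqn{\omega_a = 1/a}, \eqn{q_a = a}).
#'
#' @param a Scale(s), positive.
#' @param p A [filter_params()].
#' @param gm Optional [group_model()]; `NULL` means the dilation group.
#' @return Data frame with columns `a`, `A`, `B`, `C`, `D`.
#' @export
structure_coefficients <- function(a, p, gm = NULL) {
  stopifnot(inherits(p, "filter_params"), all(a > 0))
  if (is.null(gm)) {
    data.frame(a = a, A = p$gamma, B = -p$alpha, C = -a * p$beta,
               D = a * p$gamma)
  } else {
    om_a <- vapply(a, function(ai) gm$smap_inv(1 / ai), numeric(1))
    va <- gm$v(om_a)
    if (any(abs(va) < 1e-8 * pmax(om_a, 1)))
      stop("vector field vanishes at the requested localization; coefficients singular")
    q <- a * gm$smap_prime(om_a)
    data.frame(a = a, A = p$gamma * q * om_a,
               B = -p$alpha - p$beta * (1 - q * om_a),
               C = -p$beta * q, D = p$gamma * q)
  }
}

#' Structure-equation residual fields
#'
#' Evaluates the structure equations as residuals on a computed
#' cochleogram, using centred second-order differences on the interior of
#' the (log a, t) grid (one-sided edges are excluded from the norms, as are
#' points below the amplitude floor).
#'
#' Two realisations of the complex equation are available.  `"linear"`
#' (default) multiplies through by \eqn{Zf} and measures
#' \eqn{a\partial_a Zf - (A+iB)Zf - (C+iD)\partial_t Zf}; it is free of the
#' logarithmic branch singularities that occur at amplitude nulls of
#' broadband signals and converges at clean second order under grid
#' refinement.  `"log"` differences \eqn{\log r} and \eqn{\varphi}
#' themselves (the form in which the two real equations are stated); it is
#' the right tool for tones and other null-free signals.  The two real
#' residual fields are always computed in log-polar form.
#'
#' @param coch A [analytic_transform()] cochleogram (needs `Z`).
#' @param p A [filter_params()]; defaults to the one stored in `coch`.
#' @param gm Optional [group_model()]; defaults to the one stored in `coch`.
#' @param form `"linear"` or `"log"` for the complex residual (see above).
#' @param floor_rel Amplitude floor relative to max |Z|. Default `1e-6`.
#' @param keep_fields Store the residual matrices (memory ~ grid size);
#'   default `TRUE` for grids up to 2^22 points.
#' @return Object of class `structure_residuals` with RMS norms
#'   (`eq1_rms`, `eq2_rms`, `complex_rms`), the RMS of the equation terms
#'   used for normalisation (`term_rms`, `cterm_rms`), relative norms
#'   (`eq1_rel`, `eq2_rel`, `complex_rel`), a per-row table, and (if kept)
#'   matrices `residual1`, `residual2`, `residual_complex`.
#' @export
structure_residuals <- function(coch, p = coch$params, gm = coch$gm,
                                form = c("linear", "log"),
                                floor_rel = 1e-6, keep_fields = NULL) {
  stopifnot(inherits(coch, "cochleogram"))
  form <- match.arg(form)
  Z <- coch$Z
  nr <- nrow(Z); nc <- ncol(Z)
  if (nr < 5) stop("need at least 5 scale rows for interior differences")
  if (is.na(coch$dloga)) stop("structure residuals need a uniform log-scale grid")
  if (is.null(keep_fields)) keep_fields <- (nr * nc) <= 2^22
  dl <- coch$dloga
  dt <- 1 / coch$rate
  cols <- coch$interior_cols
  cols <- cols[cols > 1 & cols < nc]
  rows <- 2:(nr - 1)
  cf <- structure_coefficients(coch$scales[rows], p, gm)

  modZ <- Mod(Z)
  floorv <- floor_rel * max(modZ, na.rm = TRUE)
  if (keep_fields) {
    R1 <- matrix(NA_real_, length(rows), length(cols))
    R2 <- R1
    RC <- matrix(NA_complex_, length(rows), length(cols))
  }
  n1 <- n2 <- nl <- dle <- 0    # norm accumulators (log form)
  ncx <- dcx <- 0               # complex-form accumulators
  nkeep <- 0
  per <- matrix(NA_real_, length(rows), 3)

  for (i in seq_along(rows)) {
    j <- rows[i]
    AB <- cf$A[i] + 1i * cf$B[i]
    CD <- cf$C[i] + 1i * cf$D[i]
    Zc <- Z[j, cols]
    ok <- is.finite(Re(Zc)) & modZ[j, cols] > floorv &
      modZ[j + 1, cols] > floorv & modZ[j - 1, cols] > floorv &
      modZ[j, cols - 1] > floorv & modZ[j, cols + 1] > floorv
    # log-polar derivatives (unwrap-free Arg ratios)
    da <- (log(modZ[j + 1, cols] / modZ[j - 1, cols]) +
             1i * Arg(Z[j + 1, cols] / Z[j - 1, cols])) / (2 * dl)
    dtt <- (log(modZ[j, cols + 1] / modZ[j, cols - 1]) +
              1i * Arg(Z[j, cols + 1] / Z[j, cols - 1])) / (2 * dt)
    elog <- da - AB - CD * dtt
    elog[!ok] <- NA_complex_
    slog <- Mod(da) + Mod(CD * dtt) + Mod(AB)
    # linear (multiplied-through) complex residual
    daZ <- (Z[j + 1, cols] - Z[j - 1, cols]) / (2 * dl)
    dtZ <- (Z[j, cols + 1] - Z[j, cols - 1]) / (2 * dt)
    elin <- daZ - AB * Zc - CD * dtZ
    slin <- Mod(daZ) + Mod(AB * Zc) + Mod(CD * dtZ)

    n1 <- n1 + sum(Re(elog[ok])^2); n2 <- n2 + sum(Im(elog[ok])^2)
    nl <- nl + sum(Mod(elog[ok])^2); dle <- dle + sum(slog[ok]^2)
    if (form == "linear") {
      ncx <- ncx + sum(Mod(elin)^2); dcx <- dcx + sum(slin^2)
    }
    nkeep <- nkeep + sum(ok)
    ecplx <- if (form == "linear") elin else elog
    per[i, ] <- c(sqrt(mean(Re(elog[ok])^2)), sqrt(mean(Im(elog[ok])^2)),
                  if (form == "linear") sqrt(mean(Mod(elin)^2))
                  else sqrt(mean(Mod(elog[ok])^2)))
    if (keep_fields) {
      R1[i, ] <- Re(elog); R2[i, ] <- Im(elog); RC[i, ] <- ecplx
    }
  }
  if (nkeep == 0) stop("no grid points above the amplitude floor")
  term_rms <- sqrt(dle / nkeep)
  eq1 <- sqrt(n1 / nkeep); eq2 <- sqrt(n2 / nkeep)
  if (form == "linear") {
    npts <- length(rows) * length(cols)
    cx <- sqrt(ncx / npts)
    cterm <- sqrt(dcx / npts)
  } else {
    cx <- sqrt(nl / nkeep)
    cterm <- term_rms
  }
  out <- list(rows = rows, cols = cols, form = form,
              eq1_rms = eq1, eq2_rms = eq2, complex_rms = cx,
              term_rms = term_rms, cterm_rms = cterm,
              eq1_rel = eq1 / term_rms, eq2_rel = eq2 / term_rms,
              complex_rel = cx / cterm,
              per_row = data.frame(row = rows, a = coch$scales[rows],
                                   eq1_rms = per[, 1], eq2_rms = per[, 2],
                                   complex_rms = per[, 3]))
  if (keep_fields) {
    out$residual1 <- R1; out$residual2 <- R2; out$residual_complex <- RC
  }
  structure(out, class = "structure_residuals")
}

#' @export
print.structure_residuals <- function(x, ...) {
  cat(sprintf(
    "Structure residuals (%s complex form): eq1 %.3e, eq2 %.3e, complex %.3e (rel %.3e)\n",
    x$form, x$eq1_rms, x$eq2_rms, x$complex_rms, x$complex_rel))
  invisible(x)
}

#' Exchange phase and amplitude information
#'
#' The second structure equation can be solved for \eqn{\partial_t \log r};
#' inserting it in the first yields \eqn{a\,\partial_a\log r}.  Complete
#' knowledge of the phase derivatives therefore determines the amplitude
#' derivatives — and conversely ([exchange_amplitude_phase()]).
#'
#' @param dt_phase \eqn{\partial_t \varphi} (array).
#' @param da_phase \eqn{a\,\partial_a \varphi} (array, same shape).
#' @param coefs One row of [structure_coefficients()] (list or 1-row data
#'   frame with `A`, `B`, `C`, `D`).
#' @return List `dt_logr`, `da_logr` (amplitude derivatives).
#' @export
exchange_phase_amplitude <- function(dt_phase, da_phase, coefs) {
  if (abs(coefs$D) < 1e-12) stop("coefficient D vanishes; exchange singular")
  dt_logr <- (da_phase - coefs$B - coefs$C * dt_phase) / coefs$D
  da_logr <- coefs$A + coefs$C * dt_logr - coefs$D * dt_phase
  list(dt_logr = dt_logr, da_logr = da_logr)
}

#' @rdname exchange_phase_amplitude
#' @param dt_logr,da_logr Amplitude derivatives.
#' @return For the converse, list `dt_phase`, `da_phase`.
#' @export
exchange_amplitude_phase <- function(dt_logr, da_logr, coefs) {
  if (abs(coefs$D) < 1e-12) stop("coefficient D vanishes; exchange singular")
  dt_phase <- (coefs$A + coefs$C * dt_logr - da_logr) / coefs$D
  da_phase <- coefs$B + coefs$D * dt_logr + coefs$C * dt_phase
  list(dt_phase = dt_phase, da_phase = da_phase)
}
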