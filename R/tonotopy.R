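#' Tonotopic position-frequency maps
#'
#' Construct a tonotopic map \eqn{\xi(x)} assigning a characteristic
#' (circular) frequency to each place \eqn{x} along the cochlear duct.  Two
#' dialects are supported:
#' \describe{
#'   \item{`"exponential"`}{\eqn{\xi(x) = K e^{-x/l}} -- the classical
#'     scale-invariant law.}
#'   \item{`"shifted"`}{\eqn{\xi(x) = K e^{-x/l} - S} -- the physiological
#'     (Greenwood/Shera) form with shift \eqn{S}; the map crosses zero at the
#'     apical cutoff \eqn{x = l \log(K/S)}.}
#' }
#' Frequencies are handled internally in circular frequency (rad/s); the
#' constructor takes Hz (the unit figure captions use) and converts once.
#' Positions are physical millimetres; the normalisation by the length
#' constant \eqn{l} happens inside the map.
#'
#' @param kind `"exponential"` or `"shifted"`.
#' @param K_hz Basal frequency constant in Hz (\eqn{\xi(0) + S}). Default 20000.
#' @param l_mm Length constant in mm. Default 6.6.
#' @param S_hz Shift in Hz (0 for the exponential kind). Default 200 for the
#'   shifted kind.
#' @param length_mm Declared cochlear length (domain of `x`), default 35 mm.
#' @return An object of class `tonotopic_map`.
#' @examples
#' map <- tonotopic_map("exponential")
#' position_to_frequency(24.4, map) / (2 * pi)  # ~ 500 Hz
#' @export
tonotopic_map <- function(kind = c("exponential", "shifted"),
                          K_hz = 20000, l_mm = 6.6,
                          S_hz = if (kind == "shifted") 200 else 0,
                          length_mm = 35) {
  kind <- match.arg(kind)
  if (kind == "exponential") S_hz <- 0
  stopifnot(K_hz > 0, l_mm > 0, S_hz >= 0, length_mm > 0)
  structure(list(kind = kind,
                 K = 2 * pi * K_hz,    # rad/s
                 l = l_mm,             # mm
                 S = 2 * pi * S_hz,    # rad/s
                 length_mm = length_mm),
            class = "tonotopic_map")
}

#' @export
print.tonotopic_map <- function(x, ...) {
  cat(sprintf("Tonotopic map (%s): K = %g Hz, l = %g mm, S = %g Hz, length %g mm\n",
              x$kind, x$K / (2 * pi), x$l, x$S / (2 * pi), x$length_mm))
  invisible(x)
}

#' Apical cutoff of a shifted tonotopic map
#'
#' Place beyond which the shifted map would assign non-positive frequency.
#' `Inf` for the exponential kind.
#' @param map A [tonotopic_map()].
#' @return Cutoff position in mm.
#' @export
apical_cutoff <- function(map) {
  stopifnot(inherits(map, "tonotopic_map"))
  if (map$S <= 0) Inf else map$l * log(map$K / map$S)
}

#' Place to characteristic frequency
#'
#' Evaluates \eqn{\xi(x) = K e^{-x/l} - S} (rad/s).
#'
#' @param x Place along the cochlea in mm (0 to `map$length_mm`).
#' @param map A [tonotopic_map()].
#' @return Circular frequency in rad/s (same length as `x`).
#' @export
position_to_frequency <- function(x, map) {
  stopifnot(inherits(map, "tonotopic_map"))
  if (any(x < 0 | x > map$length_mm))
    stop("place x outside declared cochlear length [0, ", map$length_mm, "] mm")
  cut <- apical_cutoff(map)
  if (any(x >= cut))
    stop(sprintf(
      "shifted map assigns frequency <= 0 beyond the apical cutoff x = %.4f mm",
      cut))
  map$K * exp(-x / map$l) - map$S
}

#' Characteristic frequency to place (analytic inverse)
#'
#' @param omega Circular frequency in rad/s, in the open interval
#'   \eqn{(0, K - S)}.
#' @param map A [tonotopic_map()].
#' @return Place in mm.
#' @export
frequency_to_position <- function(omega, map) {
  stopifnot(inherits(map, "tonotopic_map"))
  if (any(omega <= 0 | omega > map$K - map$S))
    stop(sprintf("frequency must lie in (0, %g) rad/s for this map",
                 map$K - map$S))
  map$l * log(map$K / (omega + map$S))
}

#' Scaling variable
#'
#' The dimensionless combination in which the filter shape is
#' place-invariant: \eqn{\omega/\xi(x)} for the exponential map and the
#' generalised (shift-corrected) form
#' \eqn{(\omega + S)/(\xi(x) + S)} for the shifted map.  On the
#' characteristic-frequency point (\eqn{\omega = \xi(x)}) both equal 1.
#'
#' @param x Place in mm.
#' @param omega Circular frequency (rad/s), > 0.
#' @param map A [tonotopic_map()].
#' @return Dimensionless scalar (vectorised over `omega`).
#' @export
scaling_variable <- function(x, omega, map) {
  stopifnot(inherits(map, "tonotopic_map"), all(omega > 0))
  xi <- position_to_frequency(x, map)
  (omega + map$S) / (xi + map$S)
}

#' Log-spaced scale grid tied to cochlear place
#'
#' Scales \eqn{a_j} (dimensionless, strictly increasing) with associated
#' places \eqn{x_j = k + \log a_j} in normalised units, where
#' \eqn{k = \log K} so that \eqn{a_j\,\xi(x_j) = 1} for the exponential map.
#' Physical place in mm is \eqn{l (k + \log a_j)}.
#'
#' @param scales Strictly increasing positive scales, or `NULL` to build from
#'   a frequency band.
#' @param map A [tonotopic_map()] providing \eqn{K} and \eqn{l}.
#' @param f_lo_hz,f_hi_hz Band edges in Hz used when `scales` is `NULL`;
#'   scales then run from `1/(2*pi*f_hi_hz)` to `1/(2*pi*f_lo_hz)`.
#' @param per_decade Scales per decade for the constructed grid (default 128).
#' @return An object of class `scale_grid` with fields `scales`, `x_norm`
#'   (normalised place), `x_mm`, `k_const`, `dloga`.
#' @export
scale_grid <- function(scales = NULL, map = tonotopic_map("exponential"),
                       f_lo_hz = 100, f_hi_hz = 4000, per_decade = 128) {
  if (is.null(scales)) {
    a_lo <- 1 / (2 * pi * f_hi_hz)
    a_hi <- 1 / (2 * pi * f_lo_hz)
    n <- max(5L, ceiling(log10(a_hi / a_lo) * per_decade) + 1L)
    scales <- exp(seq(log(a_lo), log(a_hi), length.out = n))
  }
  stopifnot(all(scales > 0), !is.unsorted(scales, strictly = TRUE))
  k_const <- log(map$K)
  x_norm <- k_const + log(scales)
  dl <- diff(log(scales))
  dloga <- if (length(dl)) dl[1] else NA_real_
  if (length(dl) && max(abs(dl - dloga)) > 1e-9 * abs(dloga))
    dloga <- NA_real_   # non-uniform grid: derivative code falls back
  structure(list(scales = scales, x_norm = x_norm, x_mm = map$l * x_norm,
                 k_const = k_const, dloga = dloga),
            class = "scale_grid")
}

#' @export
print.scale_grid <- function(x, ...) {
  cat(sprintf("Scale grid: %d scales, a in [%.3g, %.3g], k = %.4f\n",
              length(x$scales), min(x$scales), max(x$scales), x$k_const))
  invisible(x)
}
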