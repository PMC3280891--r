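# Internal numerical helpers: phase unwrapping, tapers, quadrature on grids,
# a complex log-gamma and a small adaptive Runge-Kutta integrator (no ODE
# solver package is assumed at run time).

nextpow2 <- function(n) 2^ceiling(log2(n))

#' Unwrap a phase sequence
#'
#' Removes 2*pi jumps along a vector so the result is continuous.
#' @param phi Numeric vector of phases (radians).
#' @return Unwrapped phases, same length.
#' @export
unwrap_phase <- function(phi) {
  d <- diff(phi)
  jumps <- round(d / (2 * pi))
  phi - c(0, cumsum(jumps)) * 2 * pi
}

# Tukey (cosine-tapered) window; frac is the total fraction tapered (half at
# each end). frac = 0 gives all ones.
tukey_window <- function(n, frac = 0.1) {
  w <- rep(1, n)
  m <- floor(frac * n / 2)
  if (m > 0) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(m) - 1) / m))
    w[seq_len(m)] <- ramp
    w[n + 1 - seq_len(m)] <- ramp
  }
  w
}

# Trapezoidal rule on an arbitrary grid.
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

# Cumulative trapezoid, anchored at 0 for the first node.
cumtrapz <- function(x, y) c(0, cumsum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))

# Log-gamma for complex argument (Lanczos, g = 7, n = 9), principal branch.
# Accurate to ~1e-13 for Re(z) > 0, which is all this package needs.
lgamma_complex <- function(z) {
  g <- 7
  coef <- c(0.99999999999980993, 676.5203681218851, -1259.1392167224028,
            771.32342877765313, -176.61502916214059, 12.507343278686905,
            -0.13857109526572012, 9.9843695780195716e-6,
            1.5056327351493116e-7)
  zz <- z - 1
  x <- coef[1]
  for (i in 1:(length(coef) - 1)) x <- x + coef[i + 1] / (zz + i)
  t <- zz + g + 0.5
  0.5 * log(2 * pi) + (zz + 0.5) * log(t) - t + log(x)
}

# Adaptive embedded Runge-Kutta (Cash-Karp 4(5)) for a scalar autonomous ODE
# dy/dt = f(y), integrating from t = 0 to t = tend. Used for group flows.
rk45 <- function(f, y0, tend, rtol = 1e-10, atol = 1e-12) {
  if (tend == 0) return(y0)
  a <- c(0.2, 0.3, 0.6, 1, 0.875)
  b <- list(c(0.2),
            c(3 / 40, 9 / 40),
            c(0.3, -0.9, 1.2),
            c(-11 / 54, 2.5, -70 / 27, 35 / 27),
            c(1631 / 55296, 175 / 512, 575 / 13824, 44275 / 110592, 253 / 4096))
  c5 <- c(37 / 378, 0, 250 / 621, 125 / 594, 0, 512 / 1771)
  c4 <- c(2825 / 27648, 0, 18575 / 48384, 13525 / 55296, 277 / 14336, 0.25)
  t <- 0; y <- y0
  h <- tend / 16
  nmax <- 100000L
  for (it in seq_len(nmax)) {
    if ((tend > 0 && t + h > tend) || (tend < 0 && t + h < tend)) h <- tend - t
    k <- numeric(6)
    k[1] <- f(y)
    for (s in 1:5) k[s + 1] <- f(y + h * sum(b[[s]] * k[seq_len(s)]))
    y5 <- y + h * sum(c5 * k)
    y4 <- y + h * sum(c4 * k)
    err <- abs(y5 - y4)
    tol <- atol + rtol * max(abs(y), abs(y5))
    if (err <= tol || abs(h) < abs(tend) * 1e-14) {
      t <- t + h; y <- y5
      if (abs(t - tend) <= abs(tend) * 1e-15) return(y)
      if (t == tend) return(y)
    }
    fac <- if (err > 0) 0.9 * (tol / err)^0.2 else 5
    h <- h * min(5, max(0.2, fac))
  }
  stop("rk45: step limit reached (stiff flow or vanishing vector field?)")
}
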