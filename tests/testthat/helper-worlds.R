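# Shared fixtures: everything is generated in code at test time.

fig1 <- filter_preset("fig1")
exp_map <- tonotopic_map("exponential")

# A small on-bin pure-tone cochleogram around the on-CF row (taper-free,
# unpadded: the FFT analysis is exact for periodic on-bin tones).
tone_world <- function(nu_hz = 440, rate = 2^13, p = fig1,
                       half_width = 4, dloga = 5e-5) {
  n <- rate
  f <- sampled_signal(cos(2 * pi * nu_hz * (0:(n - 1)) / rate), rate)
  scales <- (1 / (2 * pi * nu_hz)) *
    exp(seq(-half_width, half_width, by = 1) * dloga)
  coch <- analytic_transform(f, scales, p, pad = FALSE, taper = 0,
                             polar = FALSE)
  list(f = f, coch = coch, nu = 2 * pi * nu_hz,
       on_cf_row = half_width + 1)
}

# Band-limited noise world used by the residual-convergence checks.
noise_world <- function(nsc, nsam, f_lo = 150, f_hi = 600, seed = 11,
                        p = fig1, gm = NULL) {
  spec <- generator_spec("noise", f_lo_hz = f_lo, f_hi_hz = f_hi,
                         rate = nsam, duration = 1, seed = seed)
  f <- generate_signal(spec)
  scales <- if (is.null(gm)) {
    exp(seq(log(1 / (2 * pi * f_hi)), log(1 / (2 * pi * f_lo)),
            length.out = nsc))
  } else {
    lo <- 1 / gm$smap(2 * pi * f_hi)
    hi <- 1 / gm$smap(2 * pi * f_lo)
    exp(seq(log(lo), log(hi), length.out = nsc))
  }
  coch <- suppressWarnings(
    analytic_transform(f, scales, p, gm = gm, pad = FALSE, taper = 0,
                       polar = FALSE))
  list(f = f, coch = coch)
}

expect_rel_equal <- function(got, want, tol) {
  expect_lt(abs(got - want) / abs(want), tol)
}
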