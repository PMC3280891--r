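test_that("flow: identity at a = 1, fixed points exact, closed dilation form, group law via the ODE path", {
  gm1 <- model_example_1(R_hz = 1000, K_hz = 500)
  om <- 2 * pi * c(50, 200, 600, 950)
  expect_equal(group_flow(gm1, 1, om), om, tolerance = 1e-10)
  expect_identical(group_flow(gm1, 2.5, c(0, gm1$band[2])),
                   c(0, gm1$band[2]))
  gmd <- model_dilation()
  expect_equal(group_flow(gmd, 3.7, om), om / 3.7)
  # group law checked on the numeric (Runge-Kutta) path
  gm_num <- group_model(v = gm1$v, zeros = gm1$zeros, anchor = gm1$anchor)
  l23 <- group_flow(gm_num, 2, group_flow(gm_num, 3, om))
  l6 <- group_flow(gm_num, 6, om)
  expect_lt(max(abs(l23 - l6) / om), 1e-8)
  # numeric flow matches the closed form
  expect_lt(max(abs(group_flow(gm_num, 3.7, om) -
                      group_flow(gm1, 3.7, om)) / om), 1e-8)
})

test_that("conjugation map: monotone onto the positive axis, s' = -s/v, and s(lambda_a w) = s(w)/a", {
  gm1 <- model_example_1(R_hz = 1000, K_hz = 500)
  R <- gm1$band[2]
  probe <- R * seq(1e-4, 0.9999, length.out = 1000)
  s <- gm1$smap(probe)
  expect_true(all(diff(s) > 0))
  expect_gt(s[length(s)], 1e2)
  # onto (0, Inf): s -> 0 at the lower end (logarithmically slowly)
  expect_lt(s[1], 0.2)
  expect_lt(gm1$smap(R * 1e-30), 0.05)
  expect_equal(gm1$smap_prime(probe), -s / gm1$v(probe), tolerance = 1e-12)
  for (a in c(0.3, 2, 11))
    expect_lt(max(abs(gm1$smap(group_flow(gm1, a, probe)) - s / a) / (s / a)),
              1e-8)
  # quadrature-built map agrees with the closed form
  gm_num <- group_model(v = gm1$v, zeros = gm1$zeros, anchor = gm1$anchor)
  sub <- probe[seq(1, 1000, by = 50)]
  expect_lt(max(abs(gm_num$smap(sub) - gm1$smap(sub)) / gm1$smap(sub)), 1e-8)
})

test_that("general extremal reduces to extremal_h for the dilation model and keeps zero uncertainty gap", {
  p <- fig1
  ge <- general_extremal(model_dilation(), p)
  w <- seq(0.05, 4, length.out = 64)
  expect_identical(ge$h(w), extremal_h(w, p))
  gm1 <- model_example_1(R_hz = 1000, K_hz = 500)
  ge1 <- general_extremal(gm1, p)
  g <- uncertainty_gap(ge1$h, ge1$hprime, c = 1, gm = gm1)
  expect_lt(abs(g$gap_rel), 1e-5)
  pert <- function(w) ge1$h(w) * (1 + 0.3 * sin(w / 100))
  pertp <- function(w) ge1$hprime(w) * (1 + 0.3 * sin(w / 100)) +
    ge1$h(w) * 0.003 * cos(w / 100)
  expect_gt(uncertainty_gap(pert, pertp, c = 1, gm = gm1)$gap_rel, 1e-4)
})

test_that("localization of the translated extremal transforms as sigma -> s^{-1}(1/a)", {
  p <- fig1
  gm1 <- model_example_1(R_hz = 1000, K_hz = 500)
  for (a in c(0.5, 2)) {
    ha <- function(w) group_wavelet_hat(w, a, p, gm1)
    sc <- integrate(function(w) gm1$smap(w) * Mod(ha(w))^2, 0,
                    gm1$band[2], rel.tol = 1e-9)$value /
      integrate(function(w) Mod(ha(w))^2, 0, gm1$band[2],
                rel.tol = 1e-9)$value
    expect_rel_equal(sc, 1 / a, 1e-6)
  }
})

test_that("group wavelet transform reduces to the standard one for v = -x", {
  p <- fig1
  nw <- noise_world(24, 2^11)
  cochg <- group_wavelet_transform(nw$f, model_dilation(), p,
                                   nw$coch$scales, pad = FALSE, taper = 0,
                                   polar = FALSE)
  expect_lt(max(Mod(cochg$Z - nw$coch$Z)), 1e-10 * max(Mod(nw$coch$Z)))
})

test_that("energy (Plancherel-type) identity with the admissibility constant holds within 1e-4", {
  # int int |Zf|^2 dt da/a^2 = 4 T C_h sum_{k>0} |fhat_k|^2 for a periodic
  # signal with Fourier coefficients fhat_k, provided the scale grid covers
  # the filter support over the whole signal band
  p <- fig1
  f <- generate_signal(generator_spec("noise", f_lo_hz = 150, f_hi_hz = 600,
                                      rate = 2^13, duration = 0.5,
                                      seed = 11))
  scales <- exp(seq(log(1 / (2 * pi * 3600)), log(1 / (2 * pi * 5)),
                    length.out = 400))
  coch <- analytic_transform(f, scales, p, pad = FALSE, taper = 0,
                             polar = FALSE)
  dl <- coch$dloga; dt <- 1 / coch$rate
  lhs <- sum(vapply(seq_len(nrow(coch$Z)), function(j)
    sum(Mod(coch$Z[j, ])^2) * dt * dl / coch$scales[j], numeric(1)))
  n <- length(f$samples)
  fhat2 <- Mod(fft(f$samples) / n)^2
  k <- 2:floor(n / 2)
  rhs <- 4 * admissibility_constant(p) * sum(fhat2[k]) * (n * dt)
  expect_rel_equal(lhs, rhs, 1e-4)
})

test_that("reconstruction: band-limited recovery, banded projection, zero in gives zero out", {
  p <- fig1
  f <- generate_signal(generator_spec("noise", f_lo_hz = 200, f_hi_hz = 800,
                                      rate = 2^13, duration = 1, seed = 7))
  grid <- scale_grid(f_lo_hz = 25, f_hi_hz = 3600, per_decade = 128)
  coch <- analytic_transform(f, grid, p, pad = FALSE, taper = 0,
                             polar = FALSE)
  rec <- reconstruct_signal(coch)
  expect_lt(sqrt(mean((rec$samples - f$samples)^2) / mean(f$samples^2)),
            1e-3)

  # broadband input through a banded model: the band-limited projection
  gm1 <- model_example_1(R_hz = 997.3, K_hz = 500)
  f2 <- generate_signal(generator_spec("noise", f_lo_hz = 50,
                                       f_hi_hz = 3000, rate = 2^13,
                                       duration = 1, seed = 8))
  grid2 <- group_scale_grid(gm1, 50, 995, per_decade = 128,
                            a_margin = c(0.02, 6))
  coch2 <- suppressWarnings(group_wavelet_transform(f2, gm1, p, grid2,
                                                    pad = FALSE, taper = 0,
                                                    polar = FALSE))
  rec2 <- reconstruct_signal(coch2)
  n <- length(f2$samples)
  X <- fft(f2$samples)
  om <- 2 * pi * (0:(n - 1)) * f2$rate / n
  om[om >= pi * f2$rate] <- om[om >= pi * f2$rate] - 2 * pi * f2$rate
  X[abs(om) >= gm1$band[2]] <- 0
  fproj <- Re(fft(X, inverse = TRUE)) / n
  expect_lt(sqrt(mean((rec2$samples - fproj)^2) / mean(fproj^2)), 1e-3)

  z <- sampled_signal(numeric(2^13), 2^13)
  cz <- analytic_transform(z, grid, p, pad = FALSE, taper = 0, polar = FALSE)
  expect_equal(max(abs(reconstruct_signal(cz)$samples)), 0)
})

test_that("a banded model is indifferent to out-of-band tones", {
  p <- fig1
  gm1 <- model_example_1(R_hz = 1000, K_hz = 500)
  grid <- group_scale_grid(gm1, 50, 995, per_decade = 64)
  mk <- function(fz) generate_signal(generator_spec("tone", nu_hz = fz,
                                                    rate = 2^13,
                                                    duration = 0.5))
  expect_warning(
    ct <- group_wavelet_transform(mk(1500), gm1, p, grid, pad = FALSE,
                                  taper = 0, polar = FALSE),
    "outside the model band")
  cr <- group_wavelet_transform(mk(300), gm1, p, grid, pad = FALSE,
                                taper = 0, polar = FALSE)
  expect_lt(sum(Mod(ct$Z)^2) / sum(Mod(cr$Z)^2), 1e-6)
})

test_that("example 1 approaches the dilation group as R grows; example 2 with vanishing shift is the exponential model", {
  om <- 2 * pi * c(200, 500, 2000)
  for (Rfac in c(10, 100)) {
    gm <- model_example_1(R_hz = 1000 * Rfac, K_hz = 1000)
    dev <- max(abs(group_flow(gm, 2, om) - om / 2) / (om / 2))
    # the deviation shrinks like 1/log(R/K)
    if (Rfac == 10) dev10 <- dev else expect_lt(dev, dev10 / 1.8)
  }
  mapt <- tonotopic_map("shifted", S_hz = 1e-4)
  gm2 <- model_example_2(mapt, eps_omega = 1e-6)
  nu0 <- mapt$K - mapt$S
  expect_equal(gm2$smap(om), om / nu0, tolerance = 1e-6)
  expect_equal(group_flow(gm2, 2, om), om / 2, tolerance = 1e-3)
})

test_that("example 2 exposes the generalized scaling variable and the fig9 panoramic family computes", {
  map2 <- tonotopic_map("shifted", K_hz = 20000, l_mm = 6.6, S_hz = 200)
  gm2 <- model_example_2(map2)
  p4 <- filter_preset("fig1", c = 4)
  # a = (nu0 + S)/(xi(x) + S) links parameter to place
  x <- 18
  xi <- position_to_frequency(x, map2)
  a <- 1 / gm2$smap(xi)
  expect_rel_equal(a, (gm2$nu0 + map2$S) / (xi + map2$S), 1e-10)
  # modulus curves as functions of place for the seven figure frequencies
  d <- seq(1, 28, length.out = 120)
  for (fz in c(250, 1000, 4000, 16000)) {
    vals <- vapply(d, function(xx) {
      tf <- transfer_function(xx, 2 * pi * fz, p4, map2, gm = gm2)
      Mod(tf$values)
    }, numeric(1))
    expect_true(all(is.finite(vals)))
    pk <- which.max(vals)
    expect_gt(pk, 1); expect_lt(pk, length(d))   # interior tuning peak
  }
})

test_that("general structure equations hold for example 2 at c = 1 (second-order) and approximately for example 1", {
  p <- fig1
  gm2 <- model_example_2(tonotopic_map("shifted"))
  r1 <- structure_residuals(noise_world(32, 2^11, gm = gm2)$coch)$complex_rel
  r2 <- structure_residuals(noise_world(64, 2^12, gm = gm2)$coch)$complex_rel
  expect_gt(r1 / r2, 2.5)
  gm1 <- model_example_1(R_hz = 8000, K_hz = 1000)
  rr <- structure_residuals(noise_world(64, 2^12, gm = gm1)$coch)$complex_rel
  expect_lt(rr, 0.05)    # approximate validity, not exactness
})
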