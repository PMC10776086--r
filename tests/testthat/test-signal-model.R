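test_that("extra-axonal radial diffusivity is linear in Delta with clipping", {
  expect_equal(extra_axonal_radial_diffusivity(0.5, 0.01, 15, 15), 0.5)
  expect_equal(extra_axonal_radial_diffusivity(0.5, 0, 60, 15), 0.5)
  expect_equal(extra_axonal_radial_diffusivity(0.5, -0.004, 60, 15), 0.32)
  expect_error(extra_axonal_radial_diffusivity(0.5, 0, 10, 15), "delta_min")
  expect_warning(d <- extra_axonal_radial_diffusivity(0.1, -0.01, 60, 15),
                 "clipped")
  expect_equal(d, 0)
})

test_that("perpendicular cylinder attenuation has the right limits and monotonicity", {
  g <- gradient_for_b(4000, 7, 17)
  expect_equal(restricted_perpendicular_attenuation(0, 1.5, g, 7, 17), 1)
  expect_equal(restricted_perpendicular_attenuation(3, 1.5, 0, 7, 17), 1)
  a <- restricted_perpendicular_attenuation(seq(0.5, 8, by = 0.5), 1.5, g, 7, 17)
  expect_true(all(a > 0 & a <= 1))
  expect_true(all(diff(a) < 0))          # monotone decreasing in diameter
  # monotone non-increasing in gradient strength
  a_g <- sapply(c(0.5, 1, 2) * g, function(gg)
    restricted_perpendicular_attenuation(4, 1.5, gg, 7, 17))
  expect_true(all(diff(a_g) < 0))
  # at fixed b the restricted attenuation relaxes monotonically toward its
  # motional-narrowing plateau as Delta grows (g shrinks with Delta)
  a_d <- sapply(c(15, 25, 40, 60), function(D)
    restricted_perpendicular_attenuation(4, 1.5, gradient_for_b(4000, 7, D),
                                         7, D))
  expect_true(all(diff(a_d) > 0))
  expect_true(all(a_d < 1))
})

test_that("GPD series matches an independent R-side evaluation", {
  # independent re-implementation of the series in plain R
  gpd_r <- function(diam, D, g, de, De, nroots = 20) {
    r <- diam / 2
    roots <- axdiam:::BESSEL_J1P_ROOTS[1:nroots]
    am2 <- (roots / r)^2
    num <- 2 * D * am2 * de - 2 + 2 * exp(-D * am2 * de) +
      2 * exp(-D * am2 * De) - exp(-D * am2 * (De - de)) -
      exp(-D * am2 * (De + de))
    den <- D^2 * am2^3 * (am2 * r^2 - 1)
    exp(-2 * axdiam:::gamma_ms()^2 * g^2 * sum(num / den))
  }
  g <- gradient_for_b(4000, 5, 60)
  for (d in c(1, 3, 5))
    expect_equal(restricted_perpendicular_attenuation(d, 1.0, g, 5, 60),
                 gpd_r(d, 1.0, g, 5, 60), tolerance = 1e-12)
})

test_that("Poisson diameter distribution has unit mass and the stated means", {
  dd <- poisson_diameter_distribution(2.0, grid_step = 0.1)
  expect_equal(sum(dd$weights), 1, tolerance = 1e-10)
  expect_true(all(dd$weights >= 0))
  expect_equal(sum(dd$weights * dd$diameters), 2.0, tolerance = 0.1)
  # a grid with a single admissible bin concentrates all weight there
  one <- suppressWarnings(
    poisson_diameter_distribution(0.05, grid_step = 5, truncation = 4))
  expect_equal(length(one$weights), 1)
  expect_equal(one$weights[1], 1)
  # volume weighting: mean strictly above lambda, equal to the brute-force sum
  dv <- poisson_diameter_distribution(2.0, grid_step = 0.1,
                                      weighting = "volume")
  k <- 0:100
  w_bf <- dpois(k, 20) * (k * 0.1)^2
  w_bf <- w_bf / sum(w_bf)
  expect_equal(sum(dv$weights * dv$diameters), sum(w_bf * k * 0.1),
               tolerance = 1e-12)
  expect_gt(sum(dv$weights * dv$diameters), 2.0)
  expect_warning(poisson_diameter_distribution(5, grid_step = 0.1,
                                               truncation = 3), "mass")
})

test_that("restricted compartment reduces to pure axial decay for vanishing diameter", {
  sch <- tiny_scheme()
  p <- tiny_params(lambda = 1e-6, u = c(0, 0, 1))
  # gradient parallel to the fibre: restricted attenuation = exp(-b Da)
  ix <- which(!sch$b0)
  att <- restricted_compartment_signal(p, 1, sch)
  par_ix <- which(abs(sch$dirs[, 3]) > 0.999 & !sch$b0)
  expect_equal(att[sch$b0], rep(1, sum(sch$b0)))
  expect_equal(att[ix], exp(-sch$bval[ix] * sch$dirs[ix, 3]^2 *
                              p$d_intra_axial), tolerance = 1e-4)
  expect_error(restricted_compartment_signal(p, 3, sch), "out of range")
})

test_that("two orthogonal equal populations are symmetric under gradient swap", {
  sch <- tiny_scheme()
  p2 <- voxel_params(rbind(c(1, 0, 0), c(0, 0, 1)), c(0.2, 0.2),
                     d_intra_axial = 1.5, d_extra_radial_min = 0.5,
                     lambda = 3, sigma = 0.05)
  a1 <- restricted_compartment_signal(p2, 1, sch)
  a2 <- restricted_compartment_signal(p2, 2, sch)
  # swapping x and z in the gradient table swaps the populations
  sch_sw <- sch
  sch_sw$dirs <- sch$dirs[, c(3, 2, 1)]
  a1_sw <- restricted_compartment_signal(p2, 1, sch_sw)
  expect_equal(a1_sw, a2, tolerance = 1e-12)
})

test_that("hindered compartment matches its closed form", {
  sch <- tiny_scheme()
  p <- tiny_params(u = c(0, 0, 1), slope = -0.003)
  h <- hindered_compartment_signal(p, sch)
  dp <- p$d_extra_radial_min + p$slope * (sch$big_delta - sch$delta_min)
  expl <- exp(-sch$bval * (dp + (p$d_extra_axial - dp) * sch$dirs[, 3]^2))
  expl[sch$b0] <- 1
  expect_equal(h, expl, tolerance = 1e-12)
  # theta = 0: exp(-b D_par), independent of slope
  i_par <- which(abs(sch$dirs[, 3]) > 0.999 & !sch$b0)
  expect_equal(h[i_par], exp(-sch$bval[i_par] * p$d_extra_axial),
               tolerance = 1e-4)
})

test_that("composed signal equals an explicitly recomputed compartment sum", {
  sch <- tiny_scheme(n_dir = 4)
  p <- tiny_params(lambda = 2, f = 0.3, d_a = 1.5, slope = -0.002,
                   u = c(0, 0, 1), weighting = "count")
  got <- compose_voxel_signal(p, sch, grid_step = 0.5, truncation = 10)
  # independent spreadsheet-style recomputation
  k <- 0:20
  w <- dpois(k, 2 / 0.5); w <- w / sum(w)
  cos2 <- sch$dirs[, 3]^2
  gperp <- sch$gmag * sqrt(pmax(0, 1 - cos2))
  aperp <- vapply(seq_len(sch$n_meas), function(j) {
    if (sch$b0[j]) return(1)
    att <- vapply(k * 0.5, function(d) restricted_perpendicular_attenuation(
      d, 1.5, gperp[j], sch$small_delta[j], sch$big_delta[j]), numeric(1))
    sum(w * att)
  }, numeric(1))
  restr <- exp(-sch$bval * cos2 * 1.5) * aperp
  restr[sch$b0] <- 1
  dperp <- tortuosity_radial(1.5, 0.3) - 0.002 * (sch$big_delta - 17)
  hind <- exp(-sch$bval * (dperp + (1.5 - dperp) * cos2)); hind[sch$b0] <- 1
  expect_equal(got, 0.3 * restr + 0.7 * hind, tolerance = 1e-8)
  # boundary fractions
  p0 <- tiny_params(f = 1e-9)
  expect_equal(compose_voxel_signal(p0, sch),
               hindered_compartment_signal(p0, sch), tolerance = 1e-6)
})

test_that("signal is invariant under antipodal flips", {
  sch <- tiny_scheme(n_dir = 5)
  p <- tiny_params()
  s1 <- compose_voxel_signal(p, sch)
  p_f <- p; p_f$orientations <- -p$orientations
  expect_equal(compose_voxel_signal(p_f, sch), s1, tolerance = 1e-12)
  sch_f <- sch; sch_f$dirs <- -sch$dirs
  expect_equal(compose_voxel_signal(p, sch_f), s1, tolerance = 1e-12)
})

test_that("Rician expected magnitude matches quadrature and its limits", {
  expect_equal(rician_expected_magnitude(0, 1), sqrt(pi / 2),
               tolerance = 1e-12)
  expect_equal(rician_expected_magnitude(0, 2.5), 2.5 * sqrt(pi / 2),
               tolerance = 1e-12)
  # frozen quadrature value of E|Rician(1, 1)| (1e-12 rel. tol. integrate)
  expect_equal(rician_expected_magnitude(1, 1), 1.548572460551,
               tolerance = 1e-9)
  expect_equal(rician_expected_magnitude(100, 1), 100, tolerance = 1e-4)
  nu <- seq(0, 5, by = 0.25)
  expect_true(all(diff(rician_expected_magnitude(nu, 0.8)) > 0))
})

test_that("Rician noise generator is seedable and has the analytic mean", {
  set.seed(11)
  a <- add_rician_noise(rep(0.5, 10), 0.1)
  set.seed(11)
  b <- add_rician_noise(rep(0.5, 10), 0.1)
  expect_identical(a, b)
  set.seed(12)
  x <- add_rician_noise(rep(0.4, 1e5), 0.2)
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - rician_expected_magnitude(0.4, 0.2)), 3 * se)
  expect_lt(max(abs(add_rician_noise(rep(1, 5), 1e-9) - 1)), 1e-6)
})
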