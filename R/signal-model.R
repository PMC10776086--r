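# Forward model: restricted cylinders (Gaussian phase distribution),
# Poisson diameter distribution, time-dependent hindered compartment,
# STEAM T1 decay and Rician noise.

# first 20 nonzero roots of J1'(x) = 0, used by the GPD series
BESSEL_J1P_ROOTS <- c(
  1.84118378134066, 5.33144277352503, 8.53631636634629, 11.7060049025921,
  14.863588633909, 18.0155278626818, 21.1643698591888, 24.3113268572108,
  27.4570505710592, 30.6019229726691, 33.7461828986674, 36.8899874092368,
  40.0334440533507, 43.1766289654488, 46.3195975611739, 49.4623911397028,
  52.6050411115567, 55.747571792251, 58.8900022991857, 62.032347870662)

#' Extra-axonal radial diffusivity as a function of diffusion time
#'
#' The hindered (extra-axonal) compartment's radial diffusivity is modelled
#' as linear in the diffusion time Delta, anchored at the shortest Delta of
#' the experiment: D_radial(Delta) = D_radial(Delta_min) + slope * (Delta -
#' Delta_min). Negative predictions are clipped at zero with a warning.
#'
#' @param d_rad_min radial diffusivity at `delta_min`, um^2/ms.
#' @param slope change per ms of Delta, um^2/ms per ms.
#' @param delta diffusion time(s) Delta, ms; must be >= `delta_min`.
#' @param delta_min shortest Delta of the scheme, ms.
#' @return radial diffusivity in um^2/ms, same length as `delta`.
#' @export
extra_axonal_radial_diffusivity <- function(d_rad_min, slope, delta,
                                            delta_min) {
  if (any(delta < delta_min))
    stop("delta must be >= delta_min (", delta_min, " ms)")
  d <- d_rad_min + slope * (delta - delta_min)
  if (any(d < 0)) {
    warning("negative extra-axonal radial diffusivity clipped at 0")
    d <- pmax(d, 0)
  }
  d
}

#' Perpendicular restricted-cylinder attenuation (GPD)
#'
#' Echo attenuation of water diffusing inside an impermeable cylinder with
#' the gradient perpendicular to the cylinder axis, under the Gaussian phase
#' distribution approximation for rectangular pulses of finite duration
#' (series over the first 20 roots of J1'). Valid for PGSE and, with the
#' stated delta/Delta, for stimulated-echo preparations.
#'
#' @param diameter cylinder diameter(s), um.
#' @param d_intra intracylinder diffusivity, um^2/ms.
#' @param g_perp perpendicular gradient amplitude, T/um.
#' @param small_delta gradient duration, ms.
#' @param big_delta gradient separation, ms.
#' @return attenuation in (0, 1]; 1 at zero diameter or zero gradient.
#' @export
restricted_perpendicular_attenuation <- function(diameter, d_intra, g_perp,
                                                 small_delta, big_delta) {
  stopifnot(all(diameter >= 0), small_delta < big_delta)
  n <- max(length(g_perp), length(small_delta), length(big_delta))
  ln <- cpp_gpd_lnatt(diameter / 2, d_intra, rep_len(g_perp, n),
                      rep_len(small_delta, n), rep_len(big_delta, n),
                      BESSEL_J1P_ROOTS)
  drop(exp(ln))
}

#' Discretized Poisson distribution of axon diameters
#'
#' A single rate parameter lambda defines both the mean and the dispersion
#' of the diameter distribution. Diameters live on the grid d_k = k *
#' `grid_step`; the Poisson pmf is evaluated at the integer index k with
#' rate lambda / `grid_step`, so the count-weighted mean diameter equals
#' lambda. With `weighting = "volume"`, weights are further multiplied by
#' d_k^2 (cross-sectional area, proportional to spin count per axon) and
#' renormalized.
#'
#' @param lambda_poisson mean diameter lambda, um; > 0.
#' @param grid_step grid resolution, um. Default 0.1.
#' @param truncation largest diameter on the grid, um. Default 10.
#' @param weighting `"count"` (default) or `"volume"`.
#' @return list of class `ax_ddist` with `diameters`, `weights`,
#'   `weighting`, `lambda`, `grid_step`.
#' @export
poisson_diameter_distribution <- function(lambda_poisson, grid_step = 0.1,
                                          truncation = 10,
                                          weighting = c("count", "volume")) {
  weighting <- match.arg(weighting)
  stopifnot(lambda_poisson > 0, grid_step > 0)
  k <- 0:floor(truncation / grid_step)
  d <- k * grid_step
  rate <- lambda_poisson / grid_step
  w <- stats::dpois(k, rate)
  mass <- sum(w)
  if (mass < 1 - 1e-6)
    warning(sprintf(
      "truncation %g um captures only %.6f of the Poisson mass; renormalizing",
      truncation, mass))
  if (weighting == "volume") w <- w * d^2
  w <- w / sum(w)
  structure(list(diameters = d, weights = w, weighting = weighting,
                 lambda = lambda_poisson, grid_step = grid_step),
            class = "ax_ddist")
}

#' Voxel parameter set
#'
#' Bundles the full per-voxel parameter set of the multicompartment model:
#' one or two restricted (intra-axonal) populations plus one hindered
#' (extra-axonal) compartment with linearly diffusion-time-dependent radial
#' diffusivity, a Poisson diameter distribution summarized by its mean
#' lambda (the MRI axonal diameter proxy), a Rician noise level and, for
#' stimulated-echo data, a T1.
#'
#' @param orientations unit 3-vector or 2 x 3 matrix (rows = populations).
#' @param fractions restricted signal fraction(s) f_i in [0, 1], sum <= 1.
#' @param d_intra_axial intra-axonal axial diffusivity, um^2/ms.
#' @param d_extra_radial_min extra-axonal radial diffusivity at Delta_min,
#'   um^2/ms.
#' @param slope linear Delta-dependence of the extra-axonal radial
#'   diffusivity, um^2/ms per ms.
#' @param d_extra_axial extra-axonal axial diffusivity, um^2/ms.
#' @param lambda mean axon diameter (Poisson parameter), um.
#' @param sigma Rician noise level, signal units.
#' @param s0 non-diffusion-weighted signal.
#' @param t1 longitudinal relaxation time, ms (used for STEAM schemes).
#' @param weighting diameter weighting passed to
#'   [poisson_diameter_distribution()].
#' @return list of class `ax_params`.
#' @export
voxel_params <- function(orientations, fractions, d_intra_axial,
                         d_extra_radial_min, slope = 0,
                         d_extra_axial = d_intra_axial, lambda = 2,
                         sigma = 0.05, s0 = 1, t1 = 1700,
                         weighting = "count") {
  o <- rbind(orientations)
  o <- o / sqrt(rowSums(o^2))
  f <- as.numeric(fractions)
  if (nrow(o) != length(f)) stop("one orientation per fraction required")
  if (any(f < 0) || sum(f) > 1 + 1e-12)
    stop("fractions must be nonnegative with sum <= 1")
  stopifnot(lambda > 0, sigma > 0, s0 > 0, d_intra_axial >= 0,
            d_extra_radial_min >= 0, d_extra_axial >= 0)
  structure(list(n_pop = nrow(o), orientations = o, fractions = f,
                 d_intra_axial = d_intra_axial,
                 d_extra_radial_min = d_extra_radial_min, slope = slope,
                 d_extra_axial = d_extra_axial, lambda = lambda,
                 sigma = sigma, s0 = s0, t1 = t1, weighting = weighting),
            class = "ax_params")
}

#' Restricted-compartment attenuation for one population
#'
#' Product of the axial Gaussian decay exp(-b cos^2(theta) D_a) along the
#' population orientation and the Poisson-averaged perpendicular GPD
#' attenuation. Equals 1 at b = 0.
#'
#' @param params an [voxel_params()] object.
#' @param pop_index which restricted population (1-based).
#' @param scheme an [ax_scheme()].
#' @param grid_step,truncation diameter grid, um.
#' @return attenuation per measurement, in (0, 1].
#' @export
restricted_compartment_signal <- function(params, pop_index = 1, scheme,
                                          grid_step = 0.1, truncation = 10) {
  if (pop_index < 1 || pop_index > params$n_pop)
    stop("pop_index out of range")
  u <- params$orientations[pop_index, ]
  ct <- drop(scheme$dirs %*% u)
  cos2 <- ct^2
  g_perp <- scheme$gmag * sqrt(pmax(0, 1 - cos2))
  dd <- poisson_diameter_distribution(params$lambda, grid_step, truncation,
                                      params$weighting)
  lnatt <- cpp_gpd_lnatt(dd$diameters / 2, params$d_intra_axial, g_perp,
                         scheme$small_delta, scheme$big_delta,
                         BESSEL_J1P_ROOTS)
  aperp <- drop(dd$weights %*% exp(lnatt))
  out <- exp(-scheme$bval * cos2 * params$d_intra_axial) * aperp
  out[scheme$b0] <- 1
  out
}

# fraction-weighted dyadic mean orientation (sign-invariant average)
dominant_orientation <- function(params) {
  if (params$n_pop == 1) return(params$orientations[1, ])
  M <- matrix(0, 3, 3)
  for (i in seq_len(params$n_pop)) {
    u <- params$orientations[i, ]
    M <- M + params$fractions[i] * tcrossprod(u)
  }
  e <- eigen(M, symmetric = TRUE)
  e$vectors[, 1]
}

#' Hindered-compartment attenuation
#'
#' Axially symmetric Gaussian attenuation
#' exp(-b (D_perp(Delta) + (D_par - D_perp(Delta)) cos^2 theta)) with the
#' radial diffusivity linear in Delta and theta the angle between the
#' gradient and the dominant orientation (fraction-weighted dyadic mean for
#' two-population voxels).
#'
#' @inheritParams restricted_compartment_signal
#' @return attenuation per measurement.
#' @export
hindered_compartment_signal <- function(params, scheme) {
  u <- dominant_orientation(params)
  cos2 <- drop(scheme$dirs %*% u)^2
  dp <- extra_axonal_radial_diffusivity(params$d_extra_radial_min,
                                        params$slope, scheme$big_delta,
                                        scheme$delta_min)
  out <- exp(-scheme$bval * (dp + (params$d_extra_axial - dp) * cos2))
  out[scheme$b0] <- 1
  out
}

#' Compose the noise-free voxel signal
#'
#' s0 * (sum_i f_i restricted_i + (1 - sum f_i) hindered) * T1 term, the T1
#' term being exp(-TM/T1) for STEAM schemes and 1 for PGSE.
#'
#' @inheritParams restricted_compartment_signal
#' @return predicted noise-free magnitude per measurement.
#' @export
compose_voxel_signal <- function(params, scheme, grid_step = 0.1,
                                 truncation = 10) {
  ftot <- sum(params$fractions)
  if (ftot > 1 + 1e-12) stop("restricted fractions sum to more than 1")
  acc <- (1 - ftot) * hindered_compartment_signal(params, scheme)
  for (i in seq_len(params$n_pop))
    acc <- acc + params$fractions[i] *
      restricted_compartment_signal(params, i, scheme, grid_step, truncation)
  sig <- params$s0 * acc
  if (scheme$sequence == "STEAM") sig <- sig * exp(-scheme$tm / params$t1)
  sig
}

#' Expected magnitude under Rician noise
#'
#' Analytic mean of a Rician(nu, sigma) variable,
#' sigma sqrt(pi/2) L_{1/2}(-nu^2 / (2 sigma^2)); reduces to the Rayleigh
#' mean sigma sqrt(pi/2) at nu = 0 and approaches nu at high SNR.
#'
#' @param nu noise-free signal(s), >= 0.
#' @param sigma Rician noise level, > 0.
#' @return expected magnitude, same length as `nu`.
#' @export
rician_expected_magnitude <- function(nu, sigma) {
  stopifnot(sigma > 0, all(nu >= 0))
  cpp_rician_mean(as.numeric(nu), sigma)
}

#' Add Rician noise to a noise-free signal
#'
#' Returns sqrt((s + n1)^2 + n2^2) with n1, n2 independent zero-mean
#' Gaussians of standard deviation sigma. Seed the R RNG (`set.seed`) for
#' reproducibility.
#'
#' @param signal noise-free magnitudes.
#' @param sigma Gaussian channel noise level, > 0.
#' @return noisy magnitudes.
#' @export
add_rician_noise <- function(signal, sigma) {
  stopifnot(sigma > 0)
  n <- length(signal)
  sqrt((signal + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
}
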