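# Synthetic data: simulation grids for the parameter-recovery experiment
# and a miniature two-hemisphere tract phantom.

#' Simulation configuration
#'
#' Bundles the conditions of a parameter-recovery experiment: how many
#' parameter draws, how many independent noise repetitions per draw, the
#' signal-to-noise ratio, which preset acquisition, and the uniform sampling
#' ranges. Defaults reproduce the wide-range condition: diameter 0.5-5 um,
#' restricted fraction 0.1-0.5, intra-axonal axial diffusivity 0.7-2.2
#' um^2/ms (i.e. 0.7-2.2e-3 mm^2/s); the narrow variant restricts the
#' diffusivity to 1.7-2.2 um^2/ms. Only these three parameters vary across
#' draws; remaining model quantities are held at fixed values (s0 = 1,
#' sigma = 1/SNR, tortuosity radial diffusivity, no diffusion-time
#' dependence, T1 = 1700 ms), with the orientation drawn uniformly on the
#' hemisphere.
#'
#' @param n_draws number of parameter combinations.
#' @param n_reps independent Rician noise realizations per draw.
#' @param snr b0 signal-to-noise ratio (17.3 human-like, 11.2 rat-like).
#' @param scheme_preset preset name, see [scheme_preset()].
#' @param diameter_range,fraction_range,d_intra_range uniform sampling
#'   ranges (um, -, um^2/ms).
#' @param slope_range range for the extra-axonal radial diffusivity slope,
#'   um^2/ms per ms; default degenerate at 0 (no time dependence in the
#'   simulated ground truth).
#' @param seed RNG seed used by [sample_parameters()] and
#'   [run_recovery_experiment()].
#' @return list of class `ax_simconfig`.
#' @export
sim_config <- function(n_draws = 2000, n_reps = 1, snr = 17.3,
                       scheme_preset = "human_connectom",
                       diameter_range = c(0.5, 5),
                       fraction_range = c(0.1, 0.5),
                       d_intra_range = c(0.7, 2.2),
                       slope_range = c(0, 0),
                       seed = 42) {
  stopifnot(n_draws >= 1, n_reps >= 1, snr > 0)
  for (r in list(diameter_range, fraction_range, d_intra_range))
    if (r[1] > r[2]) stop("range lower bound exceeds upper bound")
  structure(list(n_draws = n_draws, n_reps = n_reps, snr = snr,
                 scheme_preset = scheme_preset,
                 diameter_range = diameter_range,
                 fraction_range = fraction_range,
                 d_intra_range = d_intra_range,
                 slope_range = slope_range, seed = seed),
            class = "ax_simconfig")
}

# uniform draw allowing degenerate ranges
runif_rng <- function(n, r) if (r[1] == r[2]) rep(r[1], n) else
  stats::runif(n, r[1], r[2])

#' Draw ground-truth parameter sets
#'
#' Independent uniform draws of diameter lambda, restricted fraction and
#' intra-axonal axial diffusivity within the configured ranges, plus fixed
#' or derived values for the remaining model quantities: an orientation
#' uniform on the hemisphere, extra-axonal axial diffusivity equal to the
#' intra-axonal one, radial diffusivity at Delta_min from the tortuosity
#' approximation, s0 = 1 and sigma = 1/SNR.
#'
#' @param config an [sim_config()].
#' @return data.frame, one row per draw, with columns `lambda`, `f`,
#'   `d_intra`, `slope`, `ux`, `uy`, `uz`, `d_extra_ax`, `dperp_min`,
#'   `s0`, `sigma`.
#' @export
sample_parameters <- function(config) {
  set.seed(config$seed)
  n <- config$n_draws
  lambda <- runif_rng(n, config$diameter_range)
  f <- runif_rng(n, config$fraction_range)
  d_intra <- runif_rng(n, config$d_intra_range)
  slope <- runif_rng(n, config$slope_range)
  z <- stats::runif(n, 0, 1)            # uniform on the upper hemisphere
  phi <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  data.frame(lambda = lambda, f = f, d_intra = d_intra, slope = slope,
             ux = r * cos(phi), uy = r * sin(phi), uz = z,
             d_extra_ax = d_intra,
             dperp_min = tortuosity_radial(d_intra, f),
             s0 = 1, sigma = 1 / config$snr)
}

truth_params <- function(row, t1 = 1700) {
  voxel_params(orientations = c(row$ux, row$uy, row$uz), fractions = row$f,
               d_intra_axial = row$d_intra,
               d_extra_radial_min = row$dperp_min, slope = row$slope,
               d_extra_axial = row$d_extra_ax, lambda = row$lambda,
               sigma = row$sigma, s0 = row$s0, t1 = t1,
               weighting = "volume")
}

# fast diameter recovery for one draw with the non-diameter parameters at
# their generating values: profile the Rician-mean least-squares objective
# over a lambda grid with the noise term free, return the
# profile-likelihood-weighted mean
recover_lambda_known <- function(noisy, row, pre, scheme, lgrid,
                                 t1 = 1700) {
  p_prev <- max(row$sigma, 1e-6)
  rssg <- vapply(lgrid, function(lam) {
    pars <- list(lambda = lam, f = row$f, slope = row$slope, s0 = row$s0,
                 t1 = t1, dperp_min = row$dperp_min)
    resd <- function(p)
      noisy - cpp_rician_mean(axcaliber_predict(c(pars, sigma = p[1]), pre),
                              p[1])
    ft <- suppressWarnings(
      minpack.lm::nls.lm(p_prev, 1e-8, 1.2 * max(noisy), resd,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 15, ftol = 1e-8)))
    p_prev <<- ft$par
    ft$deviance
  }, numeric(1))
  n <- length(noisy)
  ll <- -n / 2 * log(pmax(rssg, 1e-300) / n)
  wgt <- exp(ll - max(ll))
  sum(lgrid * wgt) / sum(wgt)
}

#' Run the parameter-recovery experiment
#'
#' For every draw: compose the noise-free signal (s0 = 1, sigma = 1/SNR),
#' add independent Rician noise per repetition, estimate the diameter, and
#' record truth versus estimate. Summaries are Pearson correlations
#' between true and fitted diameter, computed on the first repetition
#' (`r_single`) and on the per-draw mean estimate over repetitions
#' (`r_mean`).
#'
#' Two recovery modes are provided. `nuisances = "known"` (default)
#' estimates the diameter and the Rician noise term from each noisy signal
#' while the remaining model parameters keep their generating values — a
#' self-consistency experiment isolating diameter precision, the reading
#' under which the published recovery correlations are reproduced.
#' `nuisances = "estimated"` runs the full blind cascade ([fit_voxel()])
#' per repetition; it is slower and its correlations are lower because
#' fraction and diffusivity uncertainty propagates into the diameter (see
#' the methods vignette).
#'
#' @param config an [sim_config()].
#' @param nuisances `"known"` or `"estimated"`.
#' @param fit_options passed to [fit_axcaliber()] in estimated mode.
#' @param progress print a progress line every 200 draws.
#' @return list of class `ax_recovery` with `table` (one row per draw x
#'   rep), `r_single`, `r_mean`, `n_failed`, `config`, `nuisances`.
#' @export
run_recovery_experiment <- function(config,
                                    nuisances = c("known", "estimated"),
                                    fit_options = list(),
                                    progress = FALSE) {
  nuisances <- match.arg(nuisances)
  scheme <- scheme_preset(config$scheme_preset)
  draws <- sample_parameters(config)
  t1_true <- 1700
  # profile support: the simulated diameter range plus headroom
  lgrid <- seq(0.5, 6, by = 0.5)
  rows <- vector("list", config$n_draws * config$n_reps)
  k <- 0
  for (i in seq_len(config$n_draws)) {
    row <- draws[i, ]
    clean <- compose_voxel_signal(truth_params(row, t1_true), scheme,
                                  grid_step = AX_GRID_STEP,
                                  truncation = AX_TRUNC)
    pre <- if (nuisances == "known")
      axcaliber_precompute(scheme, rbind(c(row$ux, row$uy, row$uz)),
                           row$d_intra, AX_GRID_STEP, AX_TRUNC)
    for (rep in seq_len(config$n_reps)) {
      noisy <- add_rician_noise(clean, row$sigma)
      lam_fit <- tryCatch({
        if (nuisances == "known") {
          recover_lambda_known(noisy, row, pre, scheme, lgrid, t1_true)
        } else {
          fit_voxel(noisy, scheme, n_pop = 1, options = fit_options)$lambda
        }
      }, error = function(e) NA_real_)
      k <- k + 1
      rows[[k]] <- data.frame(
        draw = i, rep = rep, lambda_true = row$lambda,
        lambda_fit = lam_fit, f_true = row$f,
        d_intra_true = row$d_intra)
    }
    if (progress && i %% 200 == 0)
      message(sprintf("recovery: %d / %d draws", i, config$n_draws))
  }
  tab <- do.call(rbind, rows)
  ok1 <- tab$rep == 1 & !is.na(tab$lambda_fit)
  r_single <- stats::cor(tab$lambda_true[ok1], tab$lambda_fit[ok1])
  means <- stats::aggregate(lambda_fit ~ draw + lambda_true, data = tab,
                            FUN = mean, na.action = stats::na.omit)
  r_mean <- stats::cor(means$lambda_true, means$lambda_fit)
  structure(list(table = tab, r_single = r_single, r_mean = r_mean,
                 n_failed = sum(is.na(tab$lambda_fit)), config = config,
                 nuisances = nuisances),
            class = "ax_recovery")
}

#' @export
print.ax_recovery <- function(x, ...) {
  cat(sprintf(
    "<ax_recovery> %d draws x %d reps (%s, SNR %.1f, %s nuisances)\n  r(truth, fit) single rep: %.3f | per-draw mean: %.3f | failed fits: %d\n",
    x$config$n_draws, x$config$n_reps, x$config$scheme_preset,
    x$config$snr, x$nuisances, x$r_single, x$r_mean, x$n_failed))
  invisible(x)
}

#' Generate a two-hemisphere tract phantom
#'
#' Builds a small volume containing two curved tracts, mirrored across the
#' mid-sagittal plane in position, with a position-dependent diameter
#' profile along the antero-posterior (y) axis and isotropic background.
#' Each tract arcs within its own sagittal (y-z) plane, so the two
#' hemispheres share identical voxel orientations position by position and
#' orientation-dependent estimation effects cancel in paired left-right
#' comparisons. The right ("injected") profile can be elevated posterior
#' to a marker position, emulating a unilateral axonal-damage contrast.
#' Voxel orientations follow the arc tangent.
#'
#' @param n_positions tract length in voxels along y.
#' @param lambda_left,lambda_right diameter profiles (um), length
#'   `n_positions`.
#' @param snr b0 SNR; Rician noise with sigma = 1/snr (s0 = 1).
#' @param scheme an [ax_scheme()]; default `scheme_preset("rat_stim_echo")`.
#' @param dims volume dimensions, default c(32, 32, 14).
#' @param thickness tract cross-section half-width in voxels; the bundle
#'   spans `2 * thickness + 1` voxels in x and three slices in z.
#' @param f restricted fraction inside the tract.
#' @param d_intra intra-axonal axial diffusivity inside the tract.
#' @param seed RNG seed for the noise.
#' @return list of class `ax_phantom` with `signal` (4D array), `mask`
#'   (3D logical: tract voxels), `truth` (list of 3D maps: lambda, f,
#'   side), `skeleton` (data.frame: voxel indices, side, position),
#'   `scheme`.
#' @export
generate_tract_phantom <- function(n_positions = 16,
                                   lambda_left = rep(2, n_positions),
                                   lambda_right = rep(2, n_positions),
                                   snr = 11.2, scheme = NULL,
                                   dims = c(32, 32, 14), thickness = 1,
                                   f = 0.35, d_intra = 1.7, seed = 1) {
  stopifnot(length(lambda_left) == n_positions,
            length(lambda_right) == n_positions)
  if (is.null(scheme)) scheme <- scheme_preset("rat_stim_echo")
  set.seed(seed)
  sigma <- 1 / snr
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  sig4 <- array(0, c(dims, scheme$n_meas))
  mask <- array(FALSE, dims)
  lam_map <- array(NA_real_, dims)
  f_map <- array(NA_real_, dims)
  side_map <- array(0L, dims)
  zmid <- round(nz / 2)
  y0 <- round((ny - n_positions) / 2)
  amp <- min(3, floor(nz / 3))          # sagittal arc amplitude in voxels
  skel <- list()
  bg_params <- voxel_params(c(0, 0, 1), 1e-6, d_intra_axial = 0.8,
                            d_extra_radial_min = 0.8, d_extra_axial = 0.8,
                            lambda = 1, sigma = sigma, s0 = 1)
  bg_clean <- compose_voxel_signal(bg_params, scheme,
                                   grid_step = AX_GRID_STEP,
                                   truncation = AX_TRUNC)
  for (p in seq_len(n_positions)) {
    yv <- y0 + p
    t <- (p - 1) / max(1, n_positions - 1)
    zoff <- round(amp * sin(pi * t))           # sagittal-plane arc
    dzdy <- amp * pi * cos(pi * t) / max(1, n_positions - 1)
    u <- c(0, 1, dzdy); u <- u / sqrt(sum(u^2)) # identical on both sides
    for (side in c("left", "right")) {
      sgn <- if (side == "left") -1 else 1
      xv <- round(nx / 2 + sgn * nx / 5)
      lam <- if (side == "left") lambda_left[p] else lambda_right[p]
      vx <- voxel_params(u, f, d_intra_axial = d_intra,
                         d_extra_radial_min = tortuosity_radial(d_intra, f),
                         slope = -0.002, d_extra_axial = d_intra,
                         lambda = lam, sigma = sigma, s0 = 1,
                         weighting = "volume")
      clean <- compose_voxel_signal(vx, scheme, grid_step = AX_GRID_STEP,
                                    truncation = AX_TRUNC)
      for (dx in -thickness:thickness) for (dz in -1:1) {
        xi <- xv + dx; zi <- zmid + zoff + dz
        if (xi < 1 || xi > nx || zi < 1 || zi > nz) next
        sig4[xi, yv, zi, ] <- add_rician_noise(clean, sigma)
        mask[xi, yv, zi] <- TRUE
        lam_map[xi, yv, zi] <- lam
        f_map[xi, yv, zi] <- f
        side_map[xi, yv, zi] <- if (side == "left") 1L else 2L
        skel[[length(skel) + 1]] <- data.frame(
          x = xi, y = yv, z = zi, side = side, position = p)
      }
    }
  }
  # isotropic noisy background everywhere else
  bg_idx <- which(!mask)
  nbg <- length(bg_idx)
  bg_mat <- matrix(bg_clean, nbg, scheme$n_meas, byrow = TRUE)
  bg_noisy <- sqrt((bg_mat + stats::rnorm(length(bg_mat), 0, sigma))^2 +
                     stats::rnorm(length(bg_mat), 0, sigma)^2)
  sig_flat <- matrix(sig4, prod(dims), scheme$n_meas)
  sig_flat[bg_idx, ] <- bg_noisy
  sig4 <- array(sig_flat, c(dims, scheme$n_meas))
  structure(list(signal = sig4, mask = mask,
                 truth = list(lambda = lam_map, f = f_map, side = side_map),
                 skeleton = do.call(rbind, skel), scheme = scheme,
                 snr = snr, seed = seed),
            class = "ax_phantom")
}

#' Fit a phantom's tract voxels and extract diameter profiles
#'
#' With `average_voxels = TRUE` (default) the magnitude signals of the
#' voxels sharing a tract position and side are averaged before fitting —
#' they share one orientation and one ground truth, and averaging raises
#' the effective SNR without changing the Rician-mean signal model (the
#' expectation of an average of Rician magnitudes is the single-voxel
#' Rician mean). With `average_voxels = FALSE` every voxel is fitted
#' individually and the fitted diameters are averaged per position.
#'
#' @param phantom an `ax_phantom` from [generate_tract_phantom()].
#' @param fit_options passed to [fit_axcaliber()].
#' @param refine passed to [fit_voxel()].
#' @param average_voxels average signals within (side, position) before
#'   fitting (default) rather than averaging fitted diameters.
#' @return data.frame with columns `position`, `lambda_left`,
#'   `lambda_right`.
#' @export
fit_phantom_profiles <- function(phantom, fit_options = list(),
                                 refine = TRUE, average_voxels = TRUE) {
  sk <- phantom$skeleton
  fit_one <- function(s) {
    fit <- tryCatch(fit_voxel(s, phantom$scheme, n_pop = 1,
                              options = fit_options, refine = refine),
                    error = function(e) NULL)
    if (is.null(fit)) NA_real_ else fit$lambda
  }
  if (average_voxels) {
    groups <- split(seq_len(nrow(sk)), list(sk$position, sk$side))
    agg <- do.call(rbind, lapply(groups, function(ix) {
      sig <- colMeans(do.call(rbind, lapply(ix, function(i)
        phantom$signal[sk$x[i], sk$y[i], sk$z[i], ])))
      data.frame(position = sk$position[ix[1]], side = sk$side[ix[1]],
                 lambda_fit = fit_one(sig))
    }))
  } else {
    est <- vapply(seq_len(nrow(sk)), function(i)
      fit_one(phantom$signal[sk$x[i], sk$y[i], sk$z[i], ]), numeric(1))
    sk$lambda_fit <- est
    agg <- stats::aggregate(lambda_fit ~ position + side, data = sk,
                            FUN = mean, na.rm = TRUE)
  }
  agg_l <- agg[agg$side == "left", ]
  agg_r <- agg[agg$side == "right", ]
  data.frame(position = sort(unique(sk$position)),
             lambda_left = agg_l$lambda_fit[order(agg_l$position)],
             lambda_right = agg_r$lambda_fit[order(agg_r$position)])
}
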