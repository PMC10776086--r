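# Along-tract and summary statistics: paired tests, FDR correction,
# SNR estimation, gamma histogram fit, shrinkage compounding.

#' Paired t test
#'
#' Two-sided paired t test on the element-wise differences. Degenerate
#' inputs (zero variance of the differences) are flagged: p = 1 when the
#' mean difference is 0, otherwise `degenerate = TRUE` with p = 0 and
#' infinite t.
#'
#' @param a,b equal-length paired samples, n >= 2.
#' @return list with `t`, `dof`, `p`, `mean_diff`, `degenerate`.
#' @export
paired_t_test <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  # exact or numerically constant differences short-circuit the t machinery
  if (stats::sd(d) <= 1e-10 * abs(mean(d))) {
    if (mean(d) == 0)
      return(list(t = 0, dof = length(d) - 1, p = 1, mean_diff = 0,
                  degenerate = FALSE))
    return(list(t = sign(mean(d)) * Inf, dof = length(d) - 1, p = 0,
                mean_diff = mean(d), degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), dof = unname(ht$parameter),
       p = ht$p.value, mean_diff = mean(d), degenerate = FALSE)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' @param p_values raw p values in [0, 1].
#' @param alpha FDR level. Default 0.05.
#' @return list with `adjusted` (BH-adjusted p, same order as input) and
#'   `reject` (logical mask at level `alpha`).
#' @export
bh_fdr <- function(p_values, alpha = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  adj <- stats::p.adjust(p_values, method = "BH")
  list(adjusted = adj, reject = adj <= alpha)
}

#' Build a paired tract-profile object
#'
#' @param positions strictly increasing positions along the
#'   antero-posterior axis (index from the injection point).
#' @param values_left,values_right matrices n_subjects x n_positions of
#'   per-subject diameter values (um).
#' @return list of class `ax_profiles`.
#' @export
tract_profile_pair <- function(positions, values_left, values_right) {
  values_left <- rbind(values_left); values_right <- rbind(values_right)
  stopifnot(ncol(values_left) == length(positions),
            ncol(values_right) == length(positions),
            nrow(values_left) == nrow(values_right),
            all(diff(positions) > 0))
  structure(list(positions = positions, values_left = values_left,
                 values_right = values_right,
                 n_subjects = nrow(values_left)),
            class = "ax_profiles")
}

#' Pointwise paired comparison of two tract profiles
#'
#' At each position along the tract, a paired t test across subjects
#' compares the two sides; p values are corrected with the
#' Benjamini-Hochberg procedure. A whole-tract comparison (paired test on
#' per-subject means) is also returned.
#'
#' @param pair an [tract_profile_pair()].
#' @param alpha FDR level for the pointwise rejection mask.
#' @return list with `pointwise` (data.frame: position, t, p, p_adjusted,
#'   reject), `whole_tract` (paired test on per-subject profile means),
#'   `subject_means` (data.frame).
#' @export
tract_profile_compare <- function(pair, alpha = 0.05) {
  stopifnot(inherits(pair, "ax_profiles"), pair$n_subjects >= 2)
  np <- length(pair$positions)
  tt <- lapply(seq_len(np), function(j)
    paired_t_test(pair$values_right[, j], pair$values_left[, j]))
  p <- vapply(tt, `[[`, numeric(1), "p")
  fdr <- bh_fdr(p, alpha)
  ml <- rowMeans(pair$values_left)
  mr <- rowMeans(pair$values_right)
  list(pointwise = data.frame(
         position = pair$positions,
         t = vapply(tt, `[[`, numeric(1), "t"), p = p,
         p_adjusted = fdr$adjusted, reject = fdr$reject),
       whole_tract = paired_t_test(mr, ml),
       subject_means = data.frame(subject = seq_along(ml), left = ml,
                                  right = mr))
}

#' Estimate the b0 signal-to-noise ratio
#'
#' Mean signal in a tissue mask divided by the background noise standard
#' deviation, the latter corrected for the Rayleigh distribution of
#' magnitude background noise: sigma = sd(background) / sqrt(2 - pi/2)
#' (sqrt(2 - pi/2) = 0.6551).
#'
#' @param b0_volumes 4D array (or 3D for a single b0) of non-diffusion-
#'   weighted volumes.
#' @param signal_mask logical 3D array selecting tissue.
#' @param noise_region logical 3D array selecting background; must be
#'   disjoint from `signal_mask`.
#' @return list with `snr`, `mean_signal`, `sigma`.
#' @export
estimate_snr <- function(b0_volumes, signal_mask, noise_region) {
  if (length(dim(b0_volumes)) == 3)
    b0_volumes <- array(b0_volumes, c(dim(b0_volumes), 1))
  if (!any(signal_mask) || !any(noise_region)) stop("empty mask")
  if (any(signal_mask & noise_region))
    stop("signal mask and noise region must be disjoint")
  nb0 <- dim(b0_volumes)[4]
  sig <- mean(vapply(seq_len(nb0), function(i)
    mean(b0_volumes[, , , i][signal_mask]), numeric(1)))
  bg <- unlist(lapply(seq_len(nb0), function(i)
    b0_volumes[, , , i][noise_region]))
  sdbg <- stats::sd(bg)
  if (sdbg == 0)
    return(list(snr = Inf, mean_signal = sig, sigma = 0))
  sigma <- sdbg / sqrt(2 - pi / 2)
  list(snr = sig / sigma, mean_signal = sig, sigma = sigma)
}

#' Maximum-likelihood gamma fit to a diameter histogram
#'
#' Fits shape k and scale theta by maximum likelihood (profile solution of
#' log(k) - digamma(k) = log(mean) - mean(log), then theta = mean / k). By
#' the MLE first-moment identity the fitted mean k * theta equals the
#' sample mean.
#'
#' @param diameters positive sample, n >= 10.
#' @return list with `shape`, `scale`, `rate`, `mean`, `density`
#'   (function of d).
#' @export
fit_gamma_histogram <- function(diameters) {
  if (any(diameters <= 0)) stop("diameters must be positive")
  if (length(diameters) < 10) stop("need at least 10 observations")
  m <- mean(diameters)
  s <- log(m) - mean(log(diameters))
  if (s <= 0) stop("degenerate sample (zero spread); gamma fit undefined")
  g <- function(k) log(k) - digamma(k) - s
  k <- stats::uniroot(g, c(1e-3, 1e6), tol = 1e-12)$root
  theta <- m / k
  list(shape = k, scale = theta, rate = 1 / theta, mean = k * theta,
       density = function(d) stats::dgamma(d, shape = k, scale = theta))
}

#' Compound a sequence of shrinkage fractions
#'
#' Successive shrinkage stages compose multiplicatively on the retained
#' size: total = 1 - prod(1 - s_i).
#'
#' @param fractions shrinkage fractions, each in [0, 1).
#' @return total shrinkage fraction in [0, 1).
#' @export
compound_shrinkage <- function(fractions) {
  if (any(fractions < 0 | fractions >= 1))
    stop("each shrinkage fraction must lie in [0, 1)")
  1 - prod(1 - fractions)
}

#' Format a fraction as a whole-number percentage
#'
#' @param x fraction in [0, 1].
#' @return character, e.g. "39\%".
#' @export
format_percent <- function(x) sprintf("%d%%", round(100 * x))

#' Pearson product-moment correlation
#'
#' @param x,y equal-length numeric vectors, n >= 3, nonzero variance.
#' @return correlation coefficient in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance; correlation undefined")
  stats::cor(x, y)
}
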