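# Acquisition schemes: per-measurement gradient/timing tables for
# multi-shell, multi-diffusion-time experiments.

#' Build an acquisition scheme
#'
#' An acquisition scheme describes every measurement of a multi-shell,
#' multi-diffusion-time diffusion-weighted experiment: gradient direction,
#' b-value, gradient separation (big delta), gradient duration (small delta),
#' mixing time (stimulated-echo sequences only) and sequence type. Internally
#' all times are in ms and b-values in ms/um^2 (1 s/mm^2 = 1e-3 ms/um^2).
#'
#' @param bvals numeric vector of b-values in s/mm^2 (FSL convention).
#' @param bvecs 3 x n or n x 3 matrix of gradient directions in the image
#'   frame; unit norm where b > 0, may be zero rows at b = 0.
#' @param big_delta numeric vector, gradient separation Delta in ms.
#' @param small_delta numeric vector, gradient duration delta in ms.
#' @param sequence `"PGSE"` or `"STEAM"`.
#' @param mixing_time mixing time TM in ms per measurement (STEAM only);
#'   defaults to `big_delta - small_delta`.
#' @param b0_threshold measurements with b below this value (s/mm^2) are
#'   treated as non-diffusion-weighted. Default 50.
#' @return An object of class `ax_scheme`: a list with per-measurement fields
#'   `bval` (ms/um^2), `dirs` (n x 3), `big_delta`, `small_delta`, `tm`,
#'   `sequence`, `b0` (logical), `gmag` (gradient amplitude in T/um,
#'   back-computed from b = gamma^2 g^2 delta^2 (Delta - delta/3)), and
#'   `delta_min` (the shortest big delta, the anchor of the linear
#'   diffusion-time dependence of the extra-axonal radial diffusivity).
#' @export
ax_scheme <- function(bvals, bvecs, big_delta, small_delta,
                      sequence = c("PGSE", "STEAM"), mixing_time = NULL,
                      b0_threshold = 50) {
  sequence <- match.arg(sequence)
  bvals <- as.numeric(bvals)
  n <- length(bvals)
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3 && nrow(bvecs) == 3) bvecs <- t(bvecs)
  if (nrow(bvecs) != n || ncol(bvecs) != 3)
    stop("bvecs must be 3 x n or n x 3 with n = length(bvals)")
  big_delta <- rep_len(as.numeric(big_delta), n)
  small_delta <- rep_len(as.numeric(small_delta), n)
  if (any(small_delta >= big_delta))
    stop("small_delta must be < big_delta for every measurement")
  b0 <- bvals < b0_threshold
  if (!any(b0)) stop("scheme contains no b0 measurement")
  nrm <- sqrt(rowSums(bvecs^2))
  bad <- which(!b0 & abs(nrm - 1) > 1e-6)
  if (length(bad))
    stop("non-unit gradient direction at measurement index ", bad[1])
  if (is.null(mixing_time)) mixing_time <- big_delta - small_delta
  mixing_time <- rep_len(as.numeric(mixing_time), n)

  b_int <- bvals * 1e-3                        # ms/um^2
  gmag <- sqrt(b_int / (gamma_ms()^2 * small_delta^2 *
                          (big_delta - small_delta / 3)))
  gmag[b0] <- 0
  structure(list(
    n_meas = n, bval = b_int, bval_si = bvals, dirs = bvecs,
    big_delta = big_delta, small_delta = small_delta, tm = mixing_time,
    sequence = sequence, b0 = b0, gmag = gmag,
    delta_min = min(big_delta)
  ), class = "ax_scheme")
}

#' @export
print.ax_scheme <- function(x, ...) {
  cat(sprintf(
    "<ax_scheme> %d measurements (%d b0), %s\n  shells (s/mm^2): %s\n  Delta (ms): %s | delta (ms): %s\n",
    x$n_meas, sum(x$b0), x$sequence,
    paste(sort(unique(round(x$bval_si[!x$b0]))), collapse = ", "),
    paste(sort(unique(x$big_delta)), collapse = ", "),
    paste(sort(unique(x$small_delta)), collapse = ", ")))
  invisible(x)
}

#' Subset an acquisition scheme
#'
#' @param x an `ax_scheme`.
#' @param i logical or integer index over measurements.
#' @return a new `ax_scheme` restricted to the selected measurements.
#' @export
scheme_subset <- function(x, i) {
  stopifnot(inherits(x, "ax_scheme"))
  s <- x
  for (f in c("bval", "bval_si", "big_delta", "small_delta", "tm",
              "b0", "gmag"))
    s[[f]] <- x[[f]][i]
  s$dirs <- x$dirs[i, , drop = FALSE]
  s$n_meas <- length(s$bval)
  # delta_min is a property of the full experiment, kept unchanged
  s
}

# deterministic near-uniform points on the hemisphere: Fibonacci lattice
# followed by a few rounds of electrostatic (antipodally symmetric) repulsion
repulsion_dirs <- function(n, n_iter = 60) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - i / n                      # upper hemisphere
  r <- sqrt(pmax(0, 1 - z^2))
  p <- cbind(r * cos(phi), r * sin(phi), z)
  for (it in seq_len(n_iter)) {
    f <- matrix(0, n, 3)
    for (a in seq_len(n)) {
      d <- p - matrix(p[a, ], n, 3, byrow = TRUE)
      d2 <- rowSums(d^2); d2[a] <- Inf
      da <- p + matrix(p[a, ], n, 3, byrow = TRUE)   # antipodal images
      da2 <- rowSums(da^2); da2[a] <- Inf
      f[a, ] <- -colSums(d / d2^1.5) + colSums(da / da2^1.5)
    }
    fn <- sqrt(rowSums(f^2))
    f <- f / pmax(1, fn / 0.5)          # cap step to avoid overshoot
    p <- p + 0.02 * f
    p <- p / sqrt(rowSums(p^2))
  }
  flip <- p[, 3] < 0 | (p[, 3] == 0 & p[, 1] < 0)
  p[flip, ] <- -p[flip, ]
  p
}

#' Preset acquisition schemes
#'
#' Three presets emulating the acquisitions the package is designed around:
#' \describe{
#'   \item{`rat_stim_echo`}{stimulated-echo (STEAM) preclinical protocol:
#'     per diffusion time Delta in \{15, 25, 40, 60\} ms, 3 b0 plus 15
#'     directions at b = 2000 and 15 at b = 4000 s/mm^2, delta = 5 ms
#'     (132 measurements).}
#'   \item{`rat_low_b`}{as `rat_stim_echo` with shells at 1000 and
#'     2500 s/mm^2.}
#'   \item{`human_connectom`}{PGSE protocol on a high-gradient system:
#'     per Delta in \{17, 35, 61\} ms, 1 b0, 30 directions at b = 2000 and
#'     60 at b = 4000 s/mm^2, delta = 7 ms (273 measurements).}
#' }
#' Directions are spread per shell by electrostatic repulsion and are
#' deterministic for a given preset.
#'
#' @param name preset name.
#' @return an [ax_scheme()].
#' @export
scheme_preset <- function(name = c("rat_stim_echo", "rat_low_b",
                                   "human_connectom")) {
  if (!is.character(name) || !(name[1] %in%
      c("rat_stim_echo", "rat_low_b", "human_connectom")))
    stop("unknown preset '", name[1],
         "'; available: rat_stim_echo, rat_low_b, human_connectom")
  name <- match.arg(name)
  if (name == "human_connectom") {
    deltas <- c(17, 35, 61); sdelta <- 7
    block <- function() {
      d1 <- repulsion_dirs(30); d2 <- repulsion_dirs(60)
      list(bv = c(0, rep(2000, 30), rep(4000, 60)),
           dirs = rbind(c(0, 0, 0), d1, d2))
    }
    seqt <- "PGSE"
  } else {
    deltas <- c(15, 25, 40, 60); sdelta <- 5
    shells <- if (name == "rat_low_b") c(1000, 2500) else c(2000, 4000)
    block <- function() {
      d1 <- repulsion_dirs(15); d2 <- repulsion_dirs(15, n_iter = 61)
      list(bv = c(rep(0, 3), rep(shells[1], 15), rep(shells[2], 15)),
           dirs = rbind(matrix(0, 3, 3), d1, d2))
    }
    seqt <- "STEAM"
  }
  b <- block()
  bvals <- rep(b$bv, length(deltas))
  dirs <- do.call(rbind, rep(list(b$dirs), length(deltas)))
  bd <- rep(deltas, each = length(b$bv))
  ax_scheme(bvals, dirs, big_delta = bd, small_delta = sdelta,
            sequence = seqt)
}
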