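# File I/O: NIfTI volumes with FSL-dialect bval/bvec sidecars and the
# package's own per-volume timing table ("bdelta").

#' Write scheme sidecar files
#'
#' Writes FSL-dialect `.bval` (one row, s/mm^2) and `.bvec` (three rows,
#' image frame) files plus a whitespace-delimited `.bdelta` table with one
#' row per volume and columns `Delta_ms delta_ms TM_ms SEQ`, preceded by a
#' version comment line. The three files round-trip losslessly through
#' [read_scheme()].
#'
#' @param scheme an [ax_scheme()].
#' @param prefix path prefix; writes `<prefix>.bval`, `<prefix>.bvec`,
#'   `<prefix>.bdelta`.
#' @return the prefix, invisibly.
#' @export
write_scheme <- function(scheme, prefix) {
  writeLines(paste(format(scheme$bval_si, trim = TRUE), collapse = " "),
             paste0(prefix, ".bval"))
  writeLines(apply(t(scheme$dirs), 1, function(r)
    paste(format(r, trim = TRUE, digits = 15), collapse = " ")),
    paste0(prefix, ".bvec"))
  con <- file(paste0(prefix, ".bdelta"), "w")
  writeLines("# bdelta v1: Delta_ms delta_ms TM_ms SEQ", con)
  writeLines(sprintf("%.10g %.10g %.10g %s", scheme$big_delta,
                     scheme$small_delta, scheme$tm, scheme$sequence), con)
  close(con)
  invisible(prefix)
}

#' Read scheme sidecar files
#'
#' @param prefix path prefix as used by [write_scheme()].
#' @return an [ax_scheme()].
#' @export
read_scheme <- function(prefix) {
  fb <- paste0(prefix, ".bval"); fv <- paste0(prefix, ".bvec")
  fd <- paste0(prefix, ".bdelta")
  for (f in c(fb, fv, fd)) if (!file.exists(f)) stop("missing file: ", f)
  bvals <- scan(fb, quiet = TRUE)
  bvecs <- matrix(scan(fv, quiet = TRUE), nrow = 3, byrow = TRUE)
  if (ncol(bvecs) != length(bvals))
    stop("bvec has ", ncol(bvecs), " columns but bval has ", length(bvals))
  tab <- utils::read.table(fd, comment.char = "#",
                           col.names = c("Delta", "delta", "TM", "SEQ"))
  if (nrow(tab) != length(bvals))
    stop("bdelta has ", nrow(tab), " rows but bval has ", length(bvals))
  seqs <- unique(tab$SEQ)
  if (length(seqs) != 1) stop("mixed sequence types are not supported")
  ax_scheme(bvals, bvecs, big_delta = tab$Delta, small_delta = tab$delta,
            sequence = seqs, mixing_time = tab$TM)
}

#' Read a diffusion-weighted series
#'
#' Loads a 4D NIfTI volume together with its bval/bvec/bdelta sidecars,
#' validates that lengths agree with the fourth dimension and that
#' diffusion-weighted directions are unit norm, and converts units to the
#' internal system (ms, um, um^2/ms). Volumes with b < 50 s/mm^2 are
#' flagged as b0.
#'
#' @param path_nifti 4D NIfTI file.
#' @param prefix sidecar prefix (default: `path_nifti` without extension).
#' @return list with `data` (4D array), `scheme` ([ax_scheme()]), `header`
#'   (RNifti image for geometry).
#' @export
read_dwi <- function(path_nifti, prefix = NULL) {
  if (!file.exists(path_nifti)) stop("missing file: ", path_nifti)
  img <- RNifti::readNifti(path_nifti)
  dat <- as.array(img)
  if (length(dim(dat)) != 4) stop("expected a 4D volume")
  if (is.null(prefix)) prefix <- sub("\\.nii(\\.gz)?$", "", path_nifti)
  scheme <- read_scheme(prefix)
  if (scheme$n_meas != dim(dat)[4])
    stop("scheme length ", scheme$n_meas, " does not match ",
         dim(dat)[4], " volumes")
  list(data = dat, scheme = scheme, header = img)
}

#' Write a phantom to NIfTI + sidecars
#'
#' @param phantom an `ax_phantom` from [generate_tract_phantom()].
#' @param out_dir output directory (created if needed).
#' @return out_dir, invisibly.
#' @export
write_phantom <- function(phantom, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f4 <- file.path(out_dir, "dwi.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(phantom$signal), f4)
  write_scheme(phantom$scheme, file.path(out_dir, "dwi"))
  for (nm in names(phantom$truth)) {
    v <- phantom$truth[[nm]]
    v[is.na(v)] <- NaN
    RNifti::writeNifti(RNifti::asNifti(v * 1.0),
                       file.path(out_dir, paste0("truth_", nm, ".nii.gz")))
  }
  RNifti::writeNifti(RNifti::asNifti(phantom$mask * 1.0),
                     file.path(out_dir, "mask.nii.gz"))
  utils::write.csv(phantom$skeleton,
                   file.path(out_dir, "skeleton.csv"), row.names = FALSE)
  invisible(out_dir)
}

#' Write fitted parameter maps
#'
#' One NIfTI per parameter; voxels outside the fitted mask are NaN. The
#' affine/geometry is copied from the reference image.
#'
#' @param maps named list of 3D arrays (e.g. lambda, f, dperp_min, slope,
#'   sigma).
#' @param reference an RNifti image or 3D/4D array providing geometry.
#' @param out_dir output directory.
#' @return out_dir, invisibly.
#' @export
write_maps <- function(maps, reference, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ref_dim <- dim(reference)[1:3]
  for (nm in names(maps)) {
    m <- maps[[nm]]
    if (!all(dim(m) == ref_dim))
      stop("map '", nm, "' does not match the reference geometry")
    m[is.na(m)] <- NaN
    img <- RNifti::asNifti(m * 1.0, reference = if (inherits(
      reference, "niftiImage")) reference else NULL)
    RNifti::writeNifti(img, file.path(out_dir, paste0(nm, ".nii.gz")))
  }
  invisible(out_dir)
}

#' Fit every voxel of a masked 4D volume
#'
#' @param data 4D array.
#' @param scheme matching [ax_scheme()].
#' @param mask logical 3D array of voxels to fit; default: voxels whose
#'   mean b0 intensity exceeds 3x the global b0 background level.
#' @param n_pop restricted populations per voxel.
#' @param fit_options passed to [fit_axcaliber()].
#' @param refine passed to [fit_voxel()].
#' @param jobs number of worker processes (forked; 1 = serial). Results do
#'   not depend on `jobs`.
#' @return named list of 3D maps: `lambda`, `f`, `dperp_min`, `slope`,
#'   `sigma`, `fa`.
#' @export
fit_volume <- function(data, scheme, mask = NULL, n_pop = 1,
                       fit_options = list(), refine = TRUE, jobs = 1) {
  dims <- dim(data)[1:3]
  b0mean <- apply(data[, , , scheme$b0, drop = FALSE], 1:3, mean)
  if (is.null(mask)) mask <- b0mean > 0.3 * mean(b0mean)
  idx <- which(mask)
  one <- function(v) {
    ijk <- arrayInd(v, dims)
    s <- data[ijk[1], ijk[2], ijk[3], ]
    fit <- tryCatch(fit_voxel(s, scheme, n_pop = n_pop,
                              options = fit_options, refine = refine),
                    error = function(e) NULL)
    dti <- tryCatch(fit_dti(s, scheme), error = function(e) NULL)
    c(lambda = if (is.null(fit)) NA_real_ else fit$lambda,
      f = if (is.null(fit)) NA_real_ else sum(fit$params$f),
      dperp_min = if (is.null(fit)) NA_real_ else fit$params$dperp_min,
      slope = if (is.null(fit)) NA_real_ else fit$params$slope,
      sigma = if (is.null(fit)) NA_real_ else fit$params$sigma,
      fa = if (is.null(dti)) NA_real_ else dti$fa)
  }
  res <- if (jobs > 1 && .Platform$OS.type == "unix") {
    parallel::mclapply(idx, one, mc.cores = jobs)
  } else lapply(idx, one)
  out <- list()
  for (nm in c("lambda", "f", "dperp_min", "slope", "sigma", "fa")) {
    m <- array(NA_real_, dims)
    m[idx] <- vapply(res, `[[`, numeric(1), nm)
    out[[nm]] <- m
  }
  out
}
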