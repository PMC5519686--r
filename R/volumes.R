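#' Construct a 3-D volume image
#'
#' Container for one subject's Jacobian-determinant grid together with its
#' geometry: voxel size in mm, a 4x4 voxel-to-world (RAS) affine over
#' 0-based voxel indices, and the analysis mask.
#'
#' @param data 3-D numeric array.
#' @param voxel_size numeric length-3, voxel edge lengths in mm.
#' @param affine 4x4 voxel-to-world matrix; default centers the grid at the
#'   world origin with axis-aligned voxels.
#' @param mask logical array of the same dimension as `data`; default all
#'   `TRUE`.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(data, voxel_size = c(1, 1, 1), affine = NULL,
                         mask = NULL) {
  if (length(dim(data)) != 3L) stopf("data must be a 3-D array")
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stopf("voxel_size must be 3 positive lengths")
  if (is.null(affine)) affine <- default_affine(dim(data), voxel_size)
  if (!all(dim(affine) == c(4L, 4L))) stopf("affine must be 4x4")
  if (is.null(mask)) mask <- array(TRUE, dim(data))
  if (!identical(dim(mask), dim(data))) stopf("data and mask shapes differ")
  if (!any(mask)) stopf("mask is empty")
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 affine = affine, mask = mask),
            class = "volume_image")
}

# Axis-aligned RAS affine placing the grid center at the world origin.
default_affine <- function(dim, voxel_size) {
  a <- diag(c(voxel_size, 1))
  a[1:3, 4] <- -(dim - 1) / 2 * voxel_size
  a
}

#' Map voxel indices to world coordinates
#'
#' @param ijk matrix (n x 3) of 1-based voxel indices or a length-3 vector.
#' @param affine 4x4 voxel-to-world matrix over 0-based indices.
#' @return n x 3 matrix of world mm coordinates.
#' @export
voxel_to_world <- function(ijk, affine) {
  ijk <- matrix(ijk, ncol = 3)
  xyz1 <- cbind(ijk - 1, 1) %*% t(affine)
  xyz1[, 1:3, drop = FALSE]
}

#' @rdname voxel_to_world
#' @param xyz matrix (n x 3) of world coordinates.
#' @export
world_to_voxel <- function(xyz, affine) {
  xyz <- matrix(xyz, ncol = 3)
  ijk0 <- cbind(xyz, 1) %*% t(solve(affine))
  ijk0[, 1:3, drop = FALSE] + 1
}

#' Collection of volumes on a shared grid
#'
#' Stores one column per subject of the vectorized grid, plus shared
#' geometry. Individual images are recovered with `[[`.
#'
#' @param data numeric matrix, voxels x subjects, columns named by id.
#' @param dim grid dimension (length 3).
#' @param voxel_size,affine,mask shared geometry; see [volume_image()].
#' @return An object of class `volume_set`.
#' @export
volume_set <- function(data, dim, voxel_size = c(1, 1, 1), affine = NULL,
                       mask = NULL) {
  dim <- as.integer(dim)
  if (nrow(data) != prod(dim)) stopf("data rows do not match grid size")
  if (is.null(colnames(data))) stopf("data columns must be named by subject id")
  if (is.null(affine)) affine <- default_affine(dim, voxel_size)
  if (is.null(mask)) mask <- array(TRUE, dim)
  structure(list(data = data, dim = dim, voxel_size = as.numeric(voxel_size),
                 affine = affine, mask = mask),
            class = "volume_set")
}

#' @export
`[[.volume_set` <- function(x, i) {
  col <- x$data[, i]
  volume_image(array(col, x$dim), voxel_size = x$voxel_size,
               affine = x$affine, mask = x$mask)
}

#' @export
dim.volume_set <- function(x) c(x$dim, ncol(x$data))

#' @export
print.volume_set <- function(x, ...) {
  cat(sprintf("<volume_set> %d subjects on %dx%dx%d grid (%.3g mm voxels), %d masked voxels\n",
              ncol(x$data), x$dim[1], x$dim[2], x$dim[3],
              x$voxel_size[1], sum(x$mask)))
  invisible(x)
}

subject_ids <- function(vs) colnames(vs$data)

#' Separable Gaussian smoothing of a 3-D array
#'
#' @param x 3-D array.
#' @param fwhm_mm smoothing kernel full width at half maximum, mm.
#' @param voxel_size voxel edge lengths, mm.
#' @return Smoothed array of the same dimension.
#' @export
gaussian_smooth3d <- function(x, fwhm_mm, voxel_size = c(1, 1, 1)) {
  if (fwhm_mm <= 0) return(x)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s < 1e-6) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2))
    k <- k / sum(k)
    x <- convolve_axis(x, k, ax)
  }
  x
}

# 1-D convolution along axis `ax` with zero padding at the edges,
# renormalized by the local kernel mass so constants stay constant.
convolve_axis <- function(x, k, ax) {
  d <- dim(x)
  perm <- switch(ax, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  m <- matrix(xp, nrow = dp[1])
  r <- (length(k) - 1L) %/% 2L
  n <- dp[1]
  out <- matrix(0, n, ncol(m))
  wt <- numeric(n)
  for (off in -r:r) {
    w <- k[off + r + 1L]
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    out[ok, ] <- out[ok, ] + w * m[src[ok], , drop = FALSE]
    wt[ok] <- wt[ok] + w
  }
  out <- out / wt
  aperm(array(out, dp), order(perm))
}

# ---- minimal NIfTI-1 I/O -------------------------------------------------
# Float32 single-frame volumes with an sform affine; gzipped files are
# handled via the connection. Kept intentionally small: this package only
# needs to round-trip its own synthetic Jacobian images.

#' Write a volume to a NIfTI-1 file
#'
#' @param vol a [volume_image()].
#' @param path output path; `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path) {
  d <- dim(vol$data)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(348L, 4)                                  # sizeof_hdr
  writeBin(raw(36), con)                       # unused data_type..dim_info
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2)              # dim[8]
  wf(c(0, 0, 0))                               # intent_p1..p3
  wi(c(0L, 16L, 32L, 0L), 2)                   # intent_code, datatype=float32, bitpix, slice_start
  wf(c(1, vol$voxel_size, 1, 1, 1, 1))         # pixdim[8] (qfac=1)
  wf(352)                                      # vox_offset
  wf(c(1, 0))                                  # scl_slope, scl_inter
  wi(0L, 2); writeBin(raw(1), con); writeBin(raw(1), con)  # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0))                               # cal_max, cal_min, slice_duration
  wf(0)                                        # toffset
  wi(c(0L, 0L), 4)                             # glmax, glmin
  writeBin(raw(80 + 24), con)                  # descrip, aux_file
  wi(c(0L, 2L), 2)                             # qform_code=0, sform_code=2
  wf(rep(0, 6))                                # quaternions
  wf(vol$affine[1, ]); wf(vol$affine[2, ]); wf(vol$affine[3, ])
  writeBin(raw(16), con)                       # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)  # magic
  writeBin(raw(4), con)                        # extension flag
  writeBin(as.numeric(vol$data), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 file written by [write_nifti()]
#'
#' Supports single-frame float32/float64 images with an sform affine.
#'
#' @param path input path; `.nii` or `.nii.gz`.
#' @param mask optional logical array to attach as analysis mask.
#' @return A [volume_image()].
#' @export
read_nifti <- function(path, mask = NULL) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  ri <- function(n, size) readBin(con, "integer", n = n, size = size, endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4, endian = "little")
  hdr_size <- ri(1, 4)
  if (!identical(hdr_size, 348L)) stopf("not a NIfTI-1 file: %s", path)
  readBin(con, "raw", n = 36)
  dims <- ri(8, 2)
  if (dims[1] < 3) stopf("expected a 3-D image")
  d <- dims[2:4]
  rf(3); ri(4, 2) -> codes
  datatype <- codes[2]
  rf(8) -> pixdim
  vox_offset <- rf(1)
  rf(2); ri(1, 2); readBin(con, "raw", n = 2)
  rf(3); rf(1); ri(2, 4)
  readBin(con, "raw", n = 104)
  ri(2, 2) -> formcodes
  rf(6)
  sr <- matrix(rf(12), nrow = 3, byrow = TRUE)
  readBin(con, "raw", n = 16)  # intent_name; magic consumed next
  readBin(con, "raw", n = 4)
  # header ends at 348; skip extension bytes up to vox_offset
  extra <- vox_offset - 348
  if (extra > 0) readBin(con, "raw", n = extra)
  nvox <- prod(d)
  vals <- switch(as.character(datatype),
    "16" = readBin(con, "numeric", n = nvox, size = 4, endian = "little"),
    "64" = readBin(con, "numeric", n = nvox, size = 8, endian = "little"),
    stopf("unsupported NIfTI datatype %d", datatype))
  affine <- rbind(sr, c(0, 0, 0, 1))
  if (formcodes[2] == 0) affine <- default_affine(d, pixdim[2:4])
  volume_image(array(vals, d), voxel_size = pixdim[2:4], affine = affine,
               mask = mask)
}

#' Write every volume of a set as NIfTI files
#'
#' @param vs a [volume_set()].
#' @param dir output directory (created if needed).
#' @param gz write gzipped `.nii.gz` files?
#' @return Named vector of file paths, invisibly.
#' @export
write_volume_set <- function(vs, dir, gz = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- subject_ids(vs)
  ext <- if (gz) ".nii.gz" else ".nii"
  paths <- setNames(file.path(dir, paste0(ids, ext)), ids)
  for (id in ids) write_nifti(vs[[id]], paths[[id]])
  invisible(paths)
}

#' Read a directory of NIfTI volumes into a set
#'
#' @param dir directory holding one `.nii`/`.nii.gz` per subject; file stem
#'   is taken as the subject id.
#' @param mask optional logical array used as the shared analysis mask.
#' @return A [volume_set()].
#' @export
read_volume_set <- function(dir, mask = NULL) {
  files <- sort(list.files(dir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE))
  if (!length(files)) stopf("no NIfTI files in %s", dir)
  ids <- sub("\\.nii(\\.gz)?$", "", basename(files))
  first <- read_nifti(files[1])
  mat <- matrix(NA_real_, prod(dim(first$data)), length(files),
                dimnames = list(NULL, ids))
  mat[, 1] <- as.numeric(first$data)
  for (i in seq_along(files)[-1]) {
    v <- read_nifti(files[i])
    if (!identical(dim(v$data), dim(first$data))) stopf("grid mismatch: %s", files[i])
    mat[, i] <- as.numeric(v$data)
  }
  volume_set(mat, dim(first$data), voxel_size = first$voxel_size,
             affine = first$affine, mask = mask %||% first$mask)
}
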