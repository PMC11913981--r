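#' 3D image volume with world-space geometry
#'
#' An `image_volume` is the universal carrier for MRI data in spinesynth: a
#' 3D numeric array together with a 4x4 affine mapping 0-based voxel indices
#' to world coordinates in millimetres (NIfTI RAS+ convention). Spacing and
#' the 3-letter orientation code are derived from the affine.
#'
#' @param data 3D numeric array of intensities. All values must be finite.
#' @param affine 4x4 numeric matrix, voxel-index (0-based) to world-mm
#'   transform. Must be invertible with positive column norms.
#' @return An object of class `image_volume` with fields `data` and `affine`.
#' @export
image_volume <- function(data, affine) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!all(is.finite(data)))
    stop("`data` contains non-finite values")
  affine <- matrix(as.numeric(affine), 4L, 4L)
  if (any(!is.finite(affine)) || abs(det(affine)) < 1e-12)
    stop("`affine` must be a finite, invertible 4x4 matrix")
  sp <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(sp <= 0)) stop("affine has a zero-length voxel axis")
  structure(list(data = data, affine = affine), class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(vol_spacing(x), 4), collapse = " x "),
      " mm, orientation ", orientation_code(x$affine), "\n", sep = "")
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' Voxel spacing of a volume (mm)
#' @param vol An `image_volume`.
#' @return Numeric length-3 vector of voxel sizes in mm.
#' @export
vol_spacing <- function(vol) sqrt(colSums(vol$affine[1:3, 1:3]^2))

.axis_letters_pos <- c("R", "A", "S")
.axis_letters_neg <- c("L", "P", "I")

#' Orientation code of an affine
#'
#' Per voxel axis, the anatomical direction (R/L, A/P, S/I) along which world
#' coordinates increase, following the NIfTI RAS+ world convention.
#'
#' @param affine 4x4 voxel-to-world matrix.
#' @return A 3-character string such as `"RIP"`.
#' @export
orientation_code <- function(affine) {
  letters <- character(3)
  for (j in 1:3) {
    col <- affine[1:3, j]
    i <- which.max(abs(col))
    letters[j] <- if (col[i] >= 0) .axis_letters_pos[i] else .axis_letters_neg[i]
  }
  paste(letters, collapse = "")
}

.parse_axis_code <- function(code) {
  if (!is.character(code) || length(code) != 1L || nchar(code) != 3L)
    stop("axis code must be a 3-letter string, e.g. \"RIP\"")
  letters <- toupper(strsplit(code, "")[[1]])
  world <- integer(3)
  sign <- integer(3)
  for (k in 1:3) {
    ip <- match(letters[k], .axis_letters_pos)
    im <- match(letters[k], .axis_letters_neg)
    if (!is.na(ip)) { world[k] <- ip; sign[k] <- 1L }
    else if (!is.na(im)) { world[k] <- im; sign[k] <- -1L }
    else stop("invalid axis letter '", letters[k], "' in code '", code, "'")
  }
  if (length(unique(world)) != 3L)
    stop("axis code '", code, "' does not name three distinct anatomical axes")
  list(letters = letters, world = world, sign = sign)
}

#' Reorient a volume to a target axis code
#'
#' Permutes and flips voxel axes so that the volume's orientation code equals
#' `target_code` while representing the same world-space image exactly
#' (no interpolation).
#'
#' @param vol An `image_volume`.
#' @param target_code 3-letter axis code, e.g. `"RIP"` (right, inferior,
#'   posterior) -- the working orientation used throughout this package.
#' @return The reoriented `image_volume`.
#' @export
reorient <- function(vol, target_code) {
  tgt <- .parse_axis_code(target_code)
  cur <- .parse_axis_code(orientation_code(vol$affine))
  perm <- match(tgt$world, cur$world)
  flip <- cur$sign[perm] != tgt$sign
  d <- aperm(vol$data, perm)
  A3 <- vol$affine[1:3, perm, drop = FALSE]
  origin <- vol$affine[1:3, 4]
  n <- dim(d)
  for (k in 1:3) {
    if (flip[k]) {
      idx <- list(seq_len(n[1]), seq_len(n[2]), seq_len(n[3]))
      idx[[k]] <- rev(idx[[k]])
      d <- d[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
      origin <- origin + A3[, k] * (n[k] - 1)
      A3[, k] <- -A3[, k]
    }
  }
  aff <- rbind(cbind(A3, origin), c(0, 0, 0, 1))
  image_volume(d, aff)
}

#' Map world coordinates to continuous 0-based voxel indices
#' @param vol An `image_volume`.
#' @param pts n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix of continuous voxel indices.
#' @export
world_to_voxel <- function(vol, pts) {
  pts <- rbind(t(matrix(pts, ncol = 3)), 1)
  out <- solve(vol$affine) %*% pts
  t(out[1:3, , drop = FALSE])
}

#' Voxel indices (0-based) to world coordinates
#' @param vol An `image_volume`.
#' @param idx n x 3 matrix of 0-based voxel indices.
#' @return n x 3 matrix of world coordinates (mm).
#' @export
voxel_to_world <- function(vol, idx) {
  idx <- rbind(t(matrix(idx, ncol = 3)), 1)
  out <- vol$affine %*% idx
  t(out[1:3, , drop = FALSE])
}

#' Resample a volume onto an explicit target grid
#'
#' Samples `vol` at the voxel centers of the grid described by `shape` and
#' `affine`. Voxels whose world position falls outside `vol` receive `cval`.
#'
#' @param vol An `image_volume`.
#' @param shape integer length-3 target shape.
#' @param affine 4x4 target voxel-to-world matrix.
#' @param order interpolation order: 0 (nearest), 1 (trilinear) or
#'   3 (tricubic Catmull-Rom).
#' @param cval fill value outside the source volume.
#' @return An `image_volume` on the target grid, with a logical `coverage`
#'   attribute array marking voxels that fell inside the source.
#' @export
resample_to_grid <- function(vol, shape, affine, order = 1, cval = 0) {
  stopifnot(order %in% c(0, 1, 3))
  if (any(dim(vol$data) == 1L) && order > 0) order <- 0
  affine <- matrix(as.numeric(affine), 4, 4)
  M <- solve(vol$affine) %*% affine
  res <- cpp_sample_affine(as.double(vol$data), dim(vol$data), M,
                           as.integer(shape), as.integer(order),
                           as.double(cval))
  d <- array(res$values, dim = shape)
  out <- image_volume(d, affine)
  attr(out, "coverage") <- array(res$inside, dim = shape)
  out
}

#' Resample a volume to a target voxel spacing
#'
#' World extent (span of voxel centers) is preserved to within one voxel;
#' axis directions and the origin are unchanged. Per-axis `NA` in
#' `target_spacing` keeps that axis untouched -- the usual call for sagittal
#' spine data resamples in-plane to 1.1 x 1.1 mm while keeping the
#' right-left spacing.
#'
#' @param vol An `image_volume`.
#' @param target_spacing numeric length-3, mm (NA = keep axis).
#' @param order interpolation order 0, 1 or 3 (default 1, linear).
#' @return The resampled `image_volume`.
#' @export
resample <- function(vol, target_spacing, order = 1) {
  sp <- vol_spacing(vol)
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L) stop("`target_spacing` must have length 3")
  target_spacing[is.na(target_spacing)] <- sp[is.na(target_spacing)]
  if (any(target_spacing <= 0)) stop("`target_spacing` must be positive")
  n <- dim(vol$data)
  new_n <- pmax(1L, as.integer(floor((n - 1) * sp / target_spacing + 1e-6)) + 1L)
  A3 <- sweep(vol$affine[1:3, 1:3, drop = FALSE], 2, sp, "/")
  A3 <- sweep(A3, 2, target_spacing, "*")
  aff <- vol$affine
  aff[1:3, 1:3] <- A3
  out <- resample_to_grid(vol, new_n, aff, order = order, cval = 0)
  attr(out, "coverage") <- NULL
  out
}

#' Rescale intensities from [0, max] to [-1, 1]
#'
#' Scanner units vary between runs; mapping `[0, max(data)]` linearly onto
#' `[-1, 1]` standardizes them. Negative inputs are clipped to 0 with a
#' warning; an all-zero volume maps to all `-1` (its maximum is undefined).
#'
#' @param vol An `image_volume` with non-negative intensities.
#' @return The rescaled `image_volume`; the maximum maps to exactly 1.
#' @export
rescale_intensity <- function(vol) {
  d <- vol$data
  if (any(d < 0)) {
    warning("negative intensities clipped to 0 before rescaling")
    d[d < 0] <- 0
  }
  mx <- max(d)
  if (mx == 0) {
    warning("all-zero volume: maximum undefined, returning constant -1")
    d[] <- -1
  } else {
    d <- 2 * d / mx - 1
  }
  image_volume(d, vol$affine)
}

#' Pad a volume so every dimension is a multiple of `multiple`
#'
#' The fully convolutional network halves spatial dimensions repeatedly, so
#' whole-volume inference requires dimensions divisible by 8. Padding is
#' appended after the data along each axis and filled with `value` (default
#' -1, the background level after [rescale_intensity()]).
#'
#' @param vol An `image_volume`.
#' @param multiple target divisor (default 8).
#' @param value fill value for padded voxels.
#' @return A list with `volume` (padded `image_volume`) and `record`
#'   (a `crop_record` that [crop_to_record()] uses to invert the padding
#'   exactly).
#' @export
pad_to_multiple <- function(vol, multiple = 8L, value = -1) {
  stopifnot(multiple >= 1)
  n <- dim(vol$data)
  target <- as.integer(ceiling(n / multiple) * multiple)
  pad_after <- target - n
  d <- array(value, dim = target)
  d[seq_len(n[1]), seq_len(n[2]), seq_len(n[3])] <- vol$data
  record <- structure(list(pad_before = c(0L, 0L, 0L),
                           pad_after = pad_after,
                           original_shape = n),
                      class = "crop_record")
  list(volume = image_volume(d, vol$affine), record = record)
}

#' Invert [pad_to_multiple()]
#' @param vol The padded `image_volume`.
#' @param record The `crop_record` returned by [pad_to_multiple()].
#' @return The original `image_volume`, bit-exactly.
#' @export
crop_to_record <- function(vol, record) {
  stopifnot(inherits(record, "crop_record"))
  n <- record$original_shape
  b <- record$pad_before
  d <- vol$data[b[1] + seq_len(n[1]), b[2] + seq_len(n[2]),
                b[3] + seq_len(n[3]), drop = FALSE]
  image_volume(d, vol$affine)
}

#' Photometric jitter (brightness/contrast) for training augmentation
#'
#' Operates on `[-1, 1]`-scaled data mapped internally to `[0, 1]`:
#' `v' = clamp(brightness * (mean + contrast * (v - mean)), 0, 1)`, where
#' `mean` is the volume mean on the 0-1 scale; the result is mapped back to
#' `[-1, 1]`. Factors are drawn from `[0.8, 1.2]` during training to mimic
#' scanner histogram variability.
#'
#' @param vol An `image_volume` with data in `[-1, 1]`.
#' @param brightness multiplicative brightness factor.
#' @param contrast contrast factor about the volume mean.
#' @return The jittered `image_volume`.
#' @export
color_jitter <- function(vol, brightness = 1, contrast = 1) {
  u <- (vol$data + 1) / 2
  m <- mean(u)
  u <- brightness * (m + contrast * (u - m))
  u[u < 0] <- 0
  u[u > 1] <- 1
  image_volume(2 * u - 1, vol$affine)
}

#' Read a NIfTI-1 volume
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return An `image_volume` carrying the file's data and sform/qform affine.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  image_volume(array(as.numeric(img), dim = dim(img)[1:3]),
               matrix(as.vector(aff), 4, 4))
}

#' Write a volume as NIfTI-1
#' @param vol An `image_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  aff <- structure(vol$affine, code = 2L)
  RNifti::`sform<-`(img, aff) -> img
  RNifti::`qform<-`(img, aff) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}
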