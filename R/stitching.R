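#' Ordered set of same-modality chunks sharing a world frame
#'
#' Whole-spine acquisitions are stored as several vertically limited chunks,
#' each a NIfTI volume already positioned in global (world) coordinates.
#' A `chunk_set` collects them for fusion.
#'
#' @param chunks list of `image_volume` objects, one per chunk.
#' @param modality character tag (e.g. `"t2w"`).
#' @return A `chunk_set` object.
#' @export
chunk_set <- function(chunks, modality = "unknown") {
  if (length(chunks) < 1L) stop("chunk set must contain at least one chunk")
  ok <- vapply(chunks, inherits, logical(1), what = "image_volume")
  if (!all(ok)) stop("all chunks must be image_volume objects")
  codes <- vapply(chunks, function(v) orientation_code(v$affine), character(1))
  if (length(unique(codes)) != 1L)
    stop("chunks have mixed orientations (", paste(unique(codes), collapse = ", "),
         "); reorient() them first")
  structure(list(chunks = chunks, modality = modality), class = "chunk_set")
}

#' @export
print.chunk_set <- function(x, ...) {
  cat("<chunk_set> ", length(x$chunks), " chunk(s), modality ", x$modality,
      "\n", sep = "")
  invisible(x)
}

.chunk_axes <- function(vol) {
  sp <- vol_spacing(vol)
  sweep(vol$affine[1:3, 1:3, drop = FALSE], 2, sp, "/")
}

#' Minimal world-space bounding grid of a chunk set
#'
#' Computes the smallest axis-aligned world box containing every chunk's
#' voxel centers (chunks may be laterally offset, e.g. following a scoliotic
#' spine) and grids it at `reference_spacing` using the first chunk's axis
#' directions.
#'
#' @param cs A `chunk_set`.
#' @param reference_spacing numeric length-3 spacing in mm; `NA` entries copy
#'   the first chunk's spacing.
#' @return A list with `shape` (integer length 3) and `affine` (4x4), class
#'   `volume_grid`.
#' @export
global_bounding_box <- function(cs, reference_spacing = c(NA, NA, NA)) {
  stopifnot(inherits(cs, "chunk_set"))
  ref <- cs$chunks[[1]]
  sp <- vol_spacing(ref)
  reference_spacing <- as.numeric(reference_spacing)
  reference_spacing[is.na(reference_spacing)] <- sp[is.na(reference_spacing)]
  if (any(reference_spacing <= 0)) stop("reference spacing must be positive")
  U <- .chunk_axes(ref)
  tmin <- rep(Inf, 3); tmax <- rep(-Inf, 3)
  for (ch in cs$chunks) {
    n <- dim(ch$data)
    corners <- as.matrix(expand.grid(c(0, n[1] - 1), c(0, n[2] - 1),
                                     c(0, n[3] - 1)))
    pts <- voxel_to_world(ch, corners)
    proj <- pts %*% U
    tmin <- pmin(tmin, apply(proj, 2, min))
    tmax <- pmax(tmax, apply(proj, 2, max))
  }
  shape <- as.integer(ceiling((tmax - tmin) / reference_spacing - 1e-6)) + 1L
  origin <- as.vector(U %*% tmin)
  A3 <- sweep(U, 2, reference_spacing, "*")
  affine <- rbind(cbind(A3, origin), c(0, 0, 0, 1))
  structure(list(shape = shape, affine = affine), class = "volume_grid")
}

.chunk_coverage <- function(cs, grid, order = 1) {
  vols <- lapply(cs$chunks, resample_to_grid, shape = grid$shape,
                 affine = grid$affine, order = order, cval = 0)
  cov <- lapply(vols, attr, which = "coverage")
  list(vols = vols, cov = cov)
}

#' Distance-based blending weights in chunk overlaps
#'
#' Inside a region covered by several chunks, each chunk `x` receives weight
#' `1 - d_x / sum_i d_i`, where `d_i` is the Euclidean distance (in voxels)
#' from the voxel to the nearest voxel covered *only* by chunk `i` (i.e.
#' where no interpolation is needed). Outside overlaps the sole covering
#' chunk has weight 1. With more than two overlapping chunks the raw weights
#' sum to k-1 and are renormalized to sum to 1; if all distances are zero
#' the covering chunks share equal weights.
#'
#' @param cs A `chunk_set`.
#' @param grid A `volume_grid` from [global_bounding_box()].
#' @return List with `weights` (list of arrays, one per chunk), `coverage`
#'   (integer array of covering-chunk counts), and `values` (chunk data
#'   resampled on the grid).
#' @export
overlap_weights <- function(cs, grid) {
  stopifnot(inherits(grid, "volume_grid"))
  cc <- .chunk_coverage(cs, grid)
  k <- length(cc$cov)
  count <- Reduce(`+`, lapply(cc$cov, function(m) array(as.integer(m), dim(m))))
  diag_len <- sqrt(sum(grid$shape^2))
  weights <- vector("list", k)
  dists <- vector("list", k)
  for (i in seq_len(k)) {
    excl <- cc$cov[[i]] & count == 1L
    if (any(excl)) {
      di <- array(cpp_edt(as.logical(excl), dim(excl)), dim(excl))
      di[!is.finite(di)] <- diag_len
    } else {
      di <- array(diag_len, dim(excl))
    }
    dists[[i]] <- di
    w <- array(0, dim(excl))
    w[excl] <- 1
    weights[[i]] <- w
  }
  ov <- count >= 2L
  if (any(ov)) {
    sumd <- array(0, dim(ov))
    for (i in seq_len(k)) sumd <- sumd + dists[[i]] * cc$cov[[i]]
    raw <- vector("list", k)
    rawsum <- array(0, dim(ov))
    for (i in seq_len(k)) {
      ri <- array(0, dim(ov))
      sel <- ov & cc$cov[[i]]
      safe <- sel & sumd > 0
      ri[safe] <- 1 - dists[[i]][safe] / sumd[safe]
      ri[sel & sumd == 0] <- 1  # all-zero distances: equal split below
      raw[[i]] <- ri
      rawsum <- rawsum + ri
    }
    for (i in seq_len(k)) {
      sel <- ov & cc$cov[[i]] & rawsum > 0
      weights[[i]][sel] <- raw[[i]][sel] / rawsum[sel]
    }
  }
  list(weights = weights, coverage = count, values = cc$vols)
}

#' Fuse a chunk set into one volume
#'
#' Resamples every chunk onto the global bounding grid and combines them as
#' the weighted sum of [overlap_weights()], giving a smooth transition
#' across overlaps. Voxels covered by no chunk are filled with `background`
#' and flagged in the returned coverage mask.
#'
#' @param cs A `chunk_set`.
#' @param grid A `volume_grid`; defaults to the chunk set's bounding box at
#'   the first chunk's spacing.
#' @param background fill value for uncovered voxels (default -1).
#' @return An `image_volume` on `grid`, with attribute `coverage` (logical
#'   array: TRUE where at least one chunk covered the voxel).
#' @export
blend <- function(cs, grid = NULL, background = -1) {
  if (is.null(grid)) grid <- global_bounding_box(cs)
  ow <- overlap_weights(cs, grid)
  fused <- array(0, grid$shape)
  for (i in seq_along(ow$weights))
    fused <- fused + ow$weights[[i]] * ow$values[[i]]$data
  covered <- ow$coverage > 0L
  fused[!covered] <- background
  out <- image_volume(fused, grid$affine)
  attr(out, "coverage") <- covered
  out
}

#' Translation-only registration by normalized cross-correlation
#'
#' Finds the integer-voxel translation (within `max_shift` mm per axis) that
#' maximizes the normalized cross-correlation between `moving` (resampled on
#' the fixed grid) and `fixed`, via FFT cross-correlation; optionally refines
#' the peak to sub-voxel precision with a separable quadratic fit. Used to
#' correct the few-voxel offset of axial Dixon stacks against the sagittal
#' T2w frame. Rotations and deformations are out of scope.
#'
#' @param moving,fixed `image_volume`s on comparable grids.
#' @param max_shift search bound in mm per axis.
#' @param threshold NCC below which the registration is flagged as failed
#'   (default 0.3).
#' @param refine logical: quadratic sub-voxel refinement of the peak.
#' @return A `registration_result`: list with `shift` (mm, world frame; add
#'   to the moving volume's affine origin to align it), `shift_voxels`,
#'   `score` (NCC in [-1, 1]), `failed`, and `status`.
#' @export
register_translation <- function(moving, fixed, max_shift = 20,
                                 threshold = 0.3, refine = FALSE) {
  m <- resample_to_grid(moving, dim(fixed$data), fixed$affine,
                        order = 1, cval = 0)$data
  f <- fixed$data
  if (stats::sd(f) == 0 || stats::sd(m) == 0) {
    return(structure(list(shift = c(0, 0, 0), shift_voxels = c(0, 0, 0),
                          score = NA_real_, failed = TRUE,
                          status = "constant-valued input: correlation undefined"),
                     class = "registration_result"))
  }
  f0 <- f - mean(f)
  m0 <- m - mean(m)
  n <- dim(f)
  cc <- Re(stats::fft(stats::fft(f0) * Conj(stats::fft(m0)),
                      inverse = TRUE)) / prod(n)
  sp <- vol_spacing(fixed)
  max_vox <- pmin(floor(max_shift / sp), floor((n - 1) / 2))
  lag <- function(i, nn) ifelse(i - 1 > nn / 2, i - 1 - nn, i - 1)
  lags <- lapply(1:3, function(a) lag(seq_len(n[a]), n[a]))
  allow <- lapply(1:3, function(a) abs(lags[[a]]) <= max_vox[a])
  mask <- array(FALSE, n)
  mask[allow[[1]], allow[[2]], allow[[3]]] <- TRUE
  cc_masked <- cc
  cc_masked[!mask] <- -Inf
  peak <- arrayInd(which.max(cc_masked), n)
  s <- vapply(1:3, function(a) lags[[a]][peak[a]], numeric(1))
  s_ref <- s
  if (refine) {
    for (a in 1:3) {
      idx <- peak
      val <- function(off) {
        i <- ((peak[a] - 1 + off) %% n[a]) + 1
        idx[a] <- i
        cc[idx[1], idx[2], idx[3]]
      }
      c0 <- val(0); cm <- val(-1); cp <- val(1)
      den <- cm - 2 * c0 + cp
      if (is.finite(den) && den < 0) s_ref[a] <- s[a] + 0.5 * (cm - cp) / den
    }
  }
  # true NCC on the (non-wrapped) overlap at the integer peak
  score <- .ncc_at_shift(f, m, s)
  failed <- !is.finite(score) || score < threshold
  shift_mm <- as.vector(fixed$affine[1:3, 1:3] %*% s_ref)
  structure(list(shift = shift_mm, shift_voxels = s_ref, score = score,
                 failed = failed,
                 status = if (failed) "peak correlation below threshold"
                          else "ok"),
            class = "registration_result")
}

.ncc_at_shift <- function(f, m, s) {
  n <- dim(f)
  # voxel x of the shifted moving image holds m[x - s]
  fr <- lapply(1:3, function(a) max(1, 1 + s[a]):min(n[a], n[a] + s[a]))
  if (any(vapply(fr, length, integer(1)) < 2)) return(NA_real_)
  fs <- f[fr[[1]], fr[[2]], fr[[3]]]
  mr <- lapply(1:3, function(a) fr[[a]] - s[a])
  ms <- m[mr[[1]], mr[[2]], mr[[3]]]
  if (stats::sd(fs) == 0 || stats::sd(ms) == 0) return(NA_real_)
  stats::cor(as.vector(fs), as.vector(ms))
}

#' Apply a world-space translation to a volume
#' @param vol An `image_volume`.
#' @param shift_mm length-3 translation in world mm (e.g. from
#'   [register_translation()]).
#' @return The translated `image_volume` (data untouched, affine shifted).
#' @export
apply_shift <- function(vol, shift_mm) {
  aff <- vol$affine
  aff[1:3, 4] <- aff[1:3, 4] + shift_mm
  image_volume(vol$data, aff)
}
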