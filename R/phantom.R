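#' Specification of a synthetic spine phantom
#'
#' The phantom is a schematic sagittal spine: stacked cuboid vertebral bodies
#' separated by discs, a posterior cerebrospinal-fluid canal and surrounding
#' muscle, each tissue carrying a fat fraction `f` and water fraction `w`
#' from which all five MR contrasts are rendered deterministically. It
#' stands in for restricted cohort data when exercising stitching,
#' registration, training and evaluation.
#'
#' Axis convention: axis 1 = right-left (through-plane for sagittal views),
#' axis 2 = inferior-superior (the vertical stitching axis), axis 3 =
#' anterior-posterior. The affine encodes the package's working orientation
#' RIP at the requested spacing.
#'
#' @param shape integer length-3 voxel shape (default 32 x 96 x 96).
#' @param spacing numeric length-3 voxel size in mm (default 3.0, 1.1, 1.1:
#'   coarse right-left, 1.1 mm sagittal in-plane).
#' @param n_vertebrae number of vertebral bodies.
#' @param disc_thickness disc height in voxels.
#' @param lesions list of [lesion_spec()] objects.
#' @param noise_sd standard deviation of additive Gaussian intensity noise
#'   applied when rendering contrasts.
#' @param seed integer; fully determines the phantom.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(shape = c(32L, 96L, 96L),
                         spacing = c(3.0, 1.1, 1.1),
                         n_vertebrae = 5L,
                         disc_thickness = 3L,
                         lesions = list(),
                         noise_sd = 0.02,
                         seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 8L),
            length(spacing) == 3L, all(spacing > 0),
            n_vertebrae >= 1L, disc_thickness >= 1L, noise_sd >= 0)
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 n_vertebrae = as.integer(n_vertebrae),
                 disc_thickness = as.integer(disc_thickness),
                 lesions = lesions, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Focal lesion for the spine phantom
#'
#' Supported kinds mirror common vertebral marrow findings: `modic1` and
#' `edema` are water-rich (bright on STIR, dark on T1w), `modic2` and
#' `hemangioma` are fat-rich (bright on T1w). Defaults satisfy those signal
#' conventions relative to normal vertebral marrow (f = 0.5, w = 0.2).
#'
#' @param kind one of `"modic1"`, `"modic2"`, `"hemangioma"`, `"edema"`.
#' @param center length-3 voxel coordinates (1-based) of the lesion center.
#' @param radius radius in voxels.
#' @param f,w fat and water fraction inside the lesion; defaults per kind.
#' @return A `lesion_spec` object.
#' @export
lesion_spec <- function(kind, center, radius, f = NULL, w = NULL) {
  kind <- match.arg(kind, c("modic1", "modic2", "hemangioma", "edema"))
  defaults <- list(modic1 = c(f = 0.10, w = 0.90),
                   modic2 = c(f = 0.85, w = 0.15),
                   hemangioma = c(f = 0.80, w = 0.30),
                   edema = c(f = 0.05, w = 0.95))[[kind]]
  if (is.null(f)) f <- defaults[["f"]]
  if (is.null(w)) w <- defaults[["w"]]
  stopifnot(f >= 0, f <= 1, w >= 0, w <= 1, radius >= 1)
  base <- .tissue_fw["vertebra", ]
  if (kind %in% c("modic1", "edema") && w <= base[["w"]])
    stop("water-rich lesion must have w above vertebral marrow (", base[["w"]], ")")
  if (kind %in% c("modic2", "hemangioma") && f <= base[["f"]])
    stop("fat-rich lesion must have f above vertebral marrow (", base[["f"]], ")")
  structure(list(kind = kind, center = as.numeric(center),
                 radius = as.numeric(radius), f = f, w = w),
            class = "lesion_spec")
}

.tissue_levels <- c("background", "vertebra", "disc", "canal", "muscle",
                    "lesion")

.tissue_fw <- matrix(c(0.00, 0.00,   # background
                       0.50, 0.20,   # vertebra (fatty marrow)
                       0.05, 0.80,   # disc
                       0.00, 0.90,   # canal (CSF)
                       0.10, 0.60),  # muscle
                     ncol = 2, byrow = TRUE,
                     dimnames = list(.tissue_levels[1:5], c("f", "w")))

.rip_affine <- function(shape, spacing) {
  # RIP: voxel axes increase toward Right (+x), Inferior (-z), Posterior (-y)
  A <- matrix(0, 4, 4)
  A[1, 1] <- spacing[1]
  A[3, 2] <- -spacing[2]
  A[2, 3] <- -spacing[3]
  A[4, 4] <- 1
  A[1:3, 4] <- c(0, (shape[3] - 1) * spacing[3], (shape[2] - 1) * spacing[2])
  A
}

#' Build the phantom tissue model
#'
#' Deterministically paints the label grid and the fat/water fraction maps
#' for a [phantom_spec()], including its lesions (spheres overriding f/w
#' inside vertebral bodies).
#'
#' @param spec A `phantom_spec`.
#' @return A `tissue_map`: list with `labels` (integer array indexing
#'   `levels`), `levels`, `f`, `w`, `affine`, `spacing`, and
#'   `vertebra_centers` (matrix of body centers in 1-based voxel coords).
#' @export
build_tissue_map <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$shape
  lab <- array(1L, n)  # background
  ax1 <- seq_len(n[1]); ax2 <- seq_len(n[2]); ax3 <- seq_len(n[3])
  # muscle body: inside an 8% border along the in-plane axes
  b2 <- ax2 >= ceiling(0.04 * n[2]) & ax2 <= floor(0.96 * n[2])
  b3 <- ax3 >= ceiling(0.08 * n[3]) & ax3 <= floor(0.92 * n[3])
  lab[, b2, b3] <- 5L  # muscle
  # spinal column band
  d_in <- abs(ax1 - (n[1] + 1) / 2) <= 0.3 * n[1]
  vb3 <- ax3 >= ceiling(0.30 * n[3]) & ax3 <= floor(0.50 * n[3])
  cn3 <- ax3 >= ceiling(0.52 * n[3]) & ax3 <= floor(0.58 * n[3])
  y0 <- ceiling(0.05 * n[2]); y1 <- floor(0.95 * n[2])
  span <- y1 - y0 + 1
  t <- spec$disc_thickness
  hv <- floor((span - (spec$n_vertebrae - 1) * t) / spec$n_vertebrae)
  if (hv < 3) stop("phantom too small for ", spec$n_vertebrae, " vertebrae")
  centers <- matrix(NA_real_, spec$n_vertebrae, 3)
  for (i in seq_len(spec$n_vertebrae)) {
    top <- y0 + (i - 1) * (hv + t)
    rows <- top:(top + hv - 1)
    lab[d_in, rows, vb3] <- 2L  # vertebra
    centers[i, ] <- c((n[1] + 1) / 2, mean(rows), mean(which(vb3)))
    if (i < spec$n_vertebrae) {
      drows <- (top + hv):(top + hv + t - 1)
      lab[d_in, drows, vb3] <- 3L  # disc
    }
  }
  lab[d_in, y0:y1, cn3] <- 4L  # canal
  f <- array(.tissue_fw[, "f"][lab], n)
  w <- array(.tissue_fw[, "w"][lab], n)
  # lesions override f/w and get their own label
  for (li in seq_along(spec$lesions)) {
    ls <- spec$lesions[[li]]
    c0 <- ls$center; r <- ls$radius
    if (any(c0 - r < 1) || any(c0 + r > n))
      stop("lesion ", li, " extends outside the volume")
    lo <- pmax(1, floor(c0 - r)); hi <- pmin(n, ceiling(c0 + r))
    ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
    dst <- outer(outer((ii - c0[1])^2, (jj - c0[2])^2, `+`),
                 (kk - c0[3])^2, `+`)
    inside <- dst <= r^2
    sub_lab <- lab[ii, jj, kk]; sub_f <- f[ii, jj, kk]; sub_w <- w[ii, jj, kk]
    sub_lab[inside] <- 6L
    sub_f[inside] <- ls$f
    sub_w[inside] <- ls$w
    lab[ii, jj, kk] <- sub_lab
    f[ii, jj, kk] <- sub_f
    w[ii, jj, kk] <- sub_w
  }
  structure(list(labels = lab, levels = .tissue_levels, f = f, w = w,
                 affine = .rip_affine(n, spec$spacing),
                 spacing = spec$spacing, vertebra_centers = centers),
            class = "tissue_map")
}

# base signal per tissue label and fat/water mixing coefficients per
# modality; signs encode the qualitative MR contrast behavior (fat bright on
# T1w/T2w/Dixon-fat, water dark on T1w, bright on T2w/STIR/Dixon-water).
.base_signal <- c(background = 0.05, vertebra = 0.4, disc = 0.5, canal = 0.2,
                  muscle = 0.3, lesion = 0.4)
.contrast_coef <- list(
  t1w         = c(alpha =  0.50, beta = -0.30),
  t2w         = c(alpha =  0.40, beta =  0.50),
  stir        = c(alpha = -0.35, beta =  0.60),
  dixon_fat   = c(alpha =  0.80, beta =  0.00),
  dixon_water = c(alpha = -0.10, beta =  0.80))

#' Render an MR contrast from a tissue map
#'
#' Linear mixing forward model: `signal = base(label) + alpha * f +
#' beta * w + noise`, clipped at 0. The coefficient signs fix the expected
#' qualitative behavior of each sequence (e.g. water-rich tissue is dark on
#' T1w and bright on STIR). This deterministic map (at `noise_sd = 0`) is
#' the closed-form oracle translator used throughout the tests; it makes no
#' claim of MR-physics fidelity.
#'
#' @param t A `tissue_map`.
#' @param modality one of `"t1w"`, `"t2w"`, `"stir"`, `"dixon_fat"`,
#'   `"dixon_water"`.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer RNG seed for the noise (ignored at `noise_sd = 0`).
#' @return An `image_volume` with non-negative raw intensities.
#' @export
render_contrast <- function(t, modality, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(t, "tissue_map"))
  if (!modality %in% names(.contrast_coef))
    stop("unknown modality '", modality, "'")
  cf <- .contrast_coef[[modality]]
  s <- array(.base_signal[t$labels], dim(t$labels)) +
    cf[["alpha"]] * t$f + cf[["beta"]] * t$w
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    set.seed(seed)
    s <- s + array(stats::rnorm(length(s), 0, noise_sd), dim(s))
    .Random.seed_restore(old)
  }
  s[s < 0] <- 0
  image_volume(s, t$affine)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Degrade through-plane resolution along the inferior-superior axis
#'
#' Emulates the low sagittal resolution of axially acquired Dixon stacks:
#' Gaussian blur with FWHM equal to the axial slice thickness along the
#' inferior-superior axis, decimation to that slice spacing, then linear
#' resampling back onto the original grid. Other axes are untouched.
#'
#' @param vol An `image_volume` (phantom axis convention: axis 2 is
#'   inferior-superior).
#' @param slice_thickness axial slice thickness in mm; must exceed the
#'   native inferior-superior spacing.
#' @return The degraded `image_volume` on the original grid.
#' @export
degrade_axial <- function(vol, slice_thickness) {
  sp <- vol_spacing(vol)
  if (slice_thickness <= sp[2])
    return(vol)
  sigma_vox <- slice_thickness / (2 * sqrt(2 * log(2))) / sp[2]
  r <- max(1L, ceiling(3 * sigma_vox))
  H <- dim(vol$data)[2]
  K <- matrix(0, H, H)
  for (j in seq_len(H)) {
    idx <- max(1, j - r):min(H, j + r)
    kern <- exp(-((idx - j)^2) / (2 * sigma_vox^2))
    K[j, idx] <- kern / sum(kern)
  }
  d <- vol$data
  for (k in seq_len(dim(d)[3])) d[, , k] <- d[, , k] %*% t(K)
  blurred <- image_volume(d, vol$affine)
  low <- resample(blurred, c(NA, slice_thickness, NA), order = 1)
  out <- resample_to_grid(low, dim(vol$data), vol$affine, order = 1, cval = 0)
  attr(out, "coverage") <- NULL
  out
}

#' Split a volume into overlapping vertical chunks
#'
#' Cuts the volume into `n` consecutive sub-volumes along the
#' inferior-superior axis with the stated voxel overlap, each carrying an
#' affine encoding its true world position. An optional random translation
#' jitter (uniform per axis in `[-jitter, jitter]` mm) can be added to each
#' chunk's affine to exercise registration.
#'
#' @param vol An `image_volume`.
#' @param n number of chunks (>= 1).
#' @param overlap overlap between consecutive chunks, in voxels.
#' @param jitter max absolute translation jitter in mm (0 = none).
#' @param seed RNG seed for the jitter.
#' @param modality tag passed to the returned [chunk_set()].
#' @return A `chunk_set`; each chunk has attribute `jitter_mm` recording the
#'   applied offset.
#' @export
split_into_chunks <- function(vol, n, overlap = 8L, jitter = 0, seed = 1L,
                              modality = "unknown") {
  stopifnot(n >= 1)
  H <- dim(vol$data)[2]
  h <- ceiling((H + (n - 1) * overlap) / n)
  if (n > 1 && overlap >= h)
    stop("overlap (", overlap, ") must be smaller than the chunk height (", h, ")")
  old <- .Random.seed_save()
  set.seed(seed)
  chunks <- vector("list", n)
  for (i in seq_len(n)) {
    start <- min((i - 1) * (h - overlap), H - h)
    rows <- (start + 1):(start + h)
    d <- vol$data[, rows, , drop = FALSE]
    aff <- vol$affine
    aff[1:3, 4] <- aff[1:3, 4] + aff[1:3, 2] * start
    jit <- if (jitter > 0) stats::runif(3, -jitter, jitter) else c(0, 0, 0)
    aff[1:3, 4] <- aff[1:3, 4] + jit
    ch <- image_volume(d, aff)
    attr(ch, "jitter_mm") <- jit
    chunks[[i]] <- ch
  }
  .Random.seed_restore(old)
  chunk_set(chunks, modality = modality)
}

.phantom_modalities <- c("t2w", "t1w", "stir", "dixon_fat", "dixon_water")

#' Generate one complete phantom subject
#'
#' Renders all five contrasts from one tissue model, degrades the Dixon pair
#' along the inferior-superior axis, and (by default) rescales every
#' modality to `[-1, 1]`.
#'
#' @param spec A `phantom_spec`.
#' @param slice_thickness axial Dixon slice thickness in mm (default 6).
#' @param normalize logical: map each modality to `[-1, 1]` via
#'   [rescale_intensity()].
#' @return A `subject_study`: named list of `image_volume`s (`t2w`, `t1w`,
#'   `stir`, `dixon_fat`, `dixon_water`) on a common grid, with the
#'   `tissue_map` attached as attribute `tissue`.
#' @export
phantom_subject <- function(spec, slice_thickness = 6, normalize = TRUE) {
  tm <- build_tissue_map(spec)
  vols <- list()
  for (m in .phantom_modalities) {
    v <- render_contrast(tm, m, noise_sd = spec$noise_sd,
                         seed = spec$seed + match(m, .phantom_modalities))
    if (m %in% c("dixon_fat", "dixon_water"))
      v <- degrade_axial(v, slice_thickness)
    if (normalize) v <- suppressWarnings(rescale_intensity(v))
    vols[[m]] <- v
  }
  structure(vols, class = "subject_study", tissue = tm)
}

#' Write a randomized phantom dataset to disk
#'
#' Draws `n_subjects` randomized phantoms from a template (random lesion
#' count, kind, position and size inside vertebral bodies), writes the five
#' modalities per subject as NIfTI files and a CSV manifest listing files,
#' per-subject seeds and painted lesions. The master seed fully determines
#' the dataset.
#'
#' @param spec_template A `phantom_spec` used as the base for every subject.
#' @param n_subjects number of subjects.
#' @param out_dir writable output directory (created if missing).
#' @param seed master RNG seed.
#' @param slice_thickness axial Dixon slice thickness in mm.
#' @return The manifest `data.frame`, invisibly; also written as
#'   `manifest.csv` in `out_dir`.
#' @export
make_dataset <- function(spec_template = phantom_spec(), n_subjects, out_dir,
                         seed = 1L, slice_thickness = 6) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  old <- .Random.seed_save()
  set.seed(seed)
  rows <- list()
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("s%03d", s)
    spec <- .randomize_spec(spec_template, subject_seed = seed * 1000L + s)
    study <- phantom_subject(spec, slice_thickness = slice_thickness,
                             normalize = FALSE)
    files <- character(0)
    for (m in .phantom_modalities) {
      f <- file.path(out_dir, paste0(sid, "_", m, ".nii.gz"))
      write_volume(study[[m]], f)
      files[m] <- basename(f)
    }
    lesions <- vapply(spec$lesions, function(l)
      sprintf("%s@%s r=%g", l$kind, paste(round(l$center), collapse = ","),
              l$radius), character(1))
    rows[[s]] <- data.frame(subject = sid, seed = spec$seed,
                            t(files),
                            n_lesions = length(spec$lesions),
                            lesions = paste(lesions, collapse = ";"),
                            stringsAsFactors = FALSE)
  }
  .Random.seed_restore(old)
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

.randomize_spec <- function(template, subject_seed) {
  set.seed(subject_seed)
  tm <- build_tissue_map(template)  # geometry only, to place lesions
  n_les <- sample(1:3, 1)
  n <- template$shape
  lesions <- vector("list", n_les)
  kinds <- c("modic1", "modic2", "hemangioma", "edema")
  for (i in seq_len(n_les)) {
    vi <- sample(nrow(tm$vertebra_centers), 1)
    ctr <- tm$vertebra_centers[vi, ]
    r <- stats::runif(1, 2, 4)
    ctr <- ctr + c(stats::runif(1, -1, 1), stats::runif(1, -2, 2),
                   stats::runif(1, -2, 2))
    ctr <- pmin(pmax(ctr, r + 1), n - r)
    lesions[[i]] <- lesion_spec(sample(kinds, 1), ctr, r)
  }
  phantom_spec(shape = template$shape, spacing = template$spacing,
               n_vertebrae = template$n_vertebrae,
               disc_thickness = template$disc_thickness,
               lesions = lesions, noise_sd = template$noise_sd,
               seed = subject_seed)
}

#' Read a phantom subject back from a [make_dataset()] directory
#' @param dir dataset directory.
#' @param subject subject id, e.g. `"s001"`.
#' @param normalize logical: rescale each modality to `[-1, 1]`.
#' @return A `subject_study` (without tissue attribute).
#' @export
read_subject <- function(dir, subject, normalize = TRUE) {
  vols <- list()
  for (m in .phantom_modalities) {
    v <- read_volume(file.path(dir, paste0(subject, "_", m, ".nii.gz")))
    if (normalize) v <- suppressWarnings(rescale_intensity(v))
    vols[[m]] <- v
  }
  structure(vols, class = "subject_study")
}
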