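#' Generator configuration
#'
#' Describes the fully convolutional 3D residual U-Net: residual blocks of
#' (conv3d -> group norm of 8 -> SiLU), downsampling by 2 per level,
#' addition-based skip connections, three positional-embedding input
#' channels appended to the image channels, and a single-channel tanh
#' output.
#'
#' @param in_channels total input channels (image modalities + 3 embeddings).
#' @param base_channels channels at the finest level; doubled per level.
#' @param levels number of resolution levels (input dims must be divisible
#'   by `2^(levels-1)`).
#' @param groupnorm_groups group-norm groups (default 8); must divide every
#'   level's channel count.
#' @param out_channels output channels (default 1).
#' @return A `generator_config` list.
#' @export
generator_config <- function(in_channels, base_channels = 32L, levels = 4L,
                             groupnorm_groups = 8L, out_channels = 1L) {
  stopifnot(in_channels >= 1, base_channels >= 1, levels >= 2)
  ch <- base_channels * 2^(seq_len(levels) - 1)
  if (any(ch %% groupnorm_groups != 0))
    stop("groupnorm_groups (", groupnorm_groups,
         ") must divide every level's channel count (",
         paste(ch, collapse = ", "), ")")
  structure(list(in_channels = as.integer(in_channels),
                 base_channels = as.integer(base_channels),
                 levels = as.integer(levels),
                 groupnorm_groups = as.integer(groupnorm_groups),
                 out_channels = as.integer(out_channels),
                 channels = as.integer(ch)),
            class = "generator_config")
}

#' Loss weights of the composite generator objective
#'
#' The generator objective is `l1 * L1(xhat, x) + ssim * (1 - SSIM(xhat, x))
#' + adv * L2(D(xhat), 1)`; the reconstruction terms are weighted 10:1
#' against the adversarial least-squares term by default.
#'
#' @param l1,ssim,adv term weights (defaults 10, 10, 1).
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(l1 = 10, ssim = 10, adv = 1) {
  structure(list(l1 = l1, ssim = ssim, adv = adv), class = "loss_weights")
}

#' Training configuration
#'
#' Defaults follow the full-scale training recipe (learning rate 2e-5,
#' batch size 3, patch (16, 192, 192), threefold replication of the training
#' data at random sagittal in-plane resolutions between 1.0 and 0.5 mm);
#' desk-scale runs override `patch_size`, `base_channels`, `levels`,
#' `epochs`, `learning_rate` and `replication_factor`.
#'
#' @param learning_rate Adam learning rate (default 2e-5).
#' @param batch_size patches per optimization step (default 3).
#' @param patch_size length-3 crop size; in-plane dims must be divisible
#'   by 8.
#' @param epochs training epochs.
#' @param replication_factor dataset replications at random resolutions.
#' @param resolution_range in-plane resolution range (mm) for replication.
#' @param augment logical: apply per-channel brightness/contrast jitter in
#'   `[0.8, 1.2]` to input patches.
#' @param input_modalities optional character vector overriding the task's
#'   input modalities (e.g. `"t2w"` alone for the single-input ablation).
#' @param base_channels,levels,groupnorm_groups generator size.
#' @param weights a [loss_weights()] object.
#' @param betas Adam moment decay rates (Pix2Pix convention 0.5, 0.999).
#' @param ssim_window cubic SSIM window used in the loss (default 7).
#' @param val_every validation cadence in epochs.
#' @param seed integer seed controlling initialization, patch sampling and
#'   augmentation.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 2e-5, batch_size = 3L,
                         patch_size = c(16L, 192L, 192L), epochs = 30L,
                         replication_factor = 3L,
                         resolution_range = c(0.5, 1.0),
                         augment = TRUE, input_modalities = NULL,
                         base_channels = 32L, levels = 4L,
                         groupnorm_groups = 8L,
                         weights = loss_weights(), betas = c(0.5, 0.999),
                         ssim_window = 7L, val_every = 10L, seed = 1L) {
  stopifnot(length(patch_size) == 3L,
            patch_size[2] %% 8L == 0L, patch_size[3] %% 8L == 0L,
            learning_rate > 0, batch_size >= 1, epochs >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 patch_size = as.integer(patch_size),
                 epochs = as.integer(epochs),
                 replication_factor = as.integer(replication_factor),
                 resolution_range = resolution_range,
                 augment = augment, input_modalities = input_modalities,
                 base_channels = as.integer(base_channels),
                 levels = as.integer(levels),
                 groupnorm_groups = as.integer(groupnorm_groups),
                 weights = weights, betas = betas,
                 ssim_window = as.integer(ssim_window),
                 val_every = as.integer(val_every),
                 seed = as.integer(seed)),
            class = "train_config")
}

.task_defs <- list(
  t1w_from_t2w_dixon = list(inputs = c("t2w", "dixon_fat", "dixon_water"),
                            target = "t1w"),
  stir_from_t2w_t1w = list(inputs = c("t2w", "t1w"), target = "stir"))

.task_def <- function(task, cfg = NULL) {
  if (!task %in% names(.task_defs))
    stop("unknown task '", task, "'; available: ",
         paste(names(.task_defs), collapse = ", "))
  def <- .task_defs[[task]]
  if (!is.null(cfg) && !is.null(cfg$input_modalities))
    def$inputs <- cfg$input_modalities
  def
}

# ---- positional embeddings ---------------------------------------------

.emb_channels <- function(original_shape, offset, size) {
  out <- array(0, c(size, 3))
  for (a in 1:3) {
    if (original_shape[a] <= 1) next
    g <- (offset[a] + seq_len(size[a]) - 1) / (original_shape[a] - 1)
    perm <- order(c(a, setdiff(1:3, a)))
    out[, , , a] <- aperm(array(g, size[c(a, setdiff(1:3, a))]), perm)
  }
  out
}

#' Positional embedding channels for a crop
#'
#' Each of the three channels is a linear gradient from 0 to 1 along one
#' axis, defined on the borders of the *original* volume before random
#' cropping: at index `i` (0-based) along axis `a`, the value is
#' `(crop_offset[a] + i) / (original_shape[a] - 1)`. The channels tell the
#' fully convolutional network where a patch sits inside the subject.
#'
#' @param original_shape length-3 shape of the uncropped volume.
#' @param crop_offset length-3 0-based crop offset.
#' @param crop_size length-3 crop size.
#' @return Array of shape `c(crop_size, 3)` with values in `[0, 1]`.
#' @export
position_embeddings <- function(original_shape, crop_offset, crop_size) {
  original_shape <- as.integer(original_shape)
  crop_offset <- as.integer(crop_offset)
  crop_size <- as.integer(crop_size)
  if (any(crop_offset < 0) || any(crop_offset + crop_size > original_shape))
    stop("crop must lie within the original volume")
  .emb_channels(original_shape, crop_offset, crop_size)
}

# ---- generator ----------------------------------------------------------

#' Build the 3D residual U-Net generator
#'
#' @param cfg A [generator_config()].
#' @return A `generator` list with `params` (nested weight arrays, He
#'   initialized from the current RNG state) and `cfg`.
#' @export
build_generator <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  ch <- cfg$channels
  L <- cfg$levels
  p <- list(stem = .he_init(3L, cfg$in_channels, ch[1]))
  p$enc <- lapply(seq_len(L - 1), function(l) .resblock_init(ch[l]))
  p$down <- lapply(seq_len(L - 1), function(l) .he_init(3L, ch[l], ch[l + 1]))
  p$mid <- .resblock_init(ch[L])
  p$up <- lapply(seq_len(L - 1), function(l) .he_init(3L, ch[l + 1], ch[l]))
  p$dec <- lapply(seq_len(L - 1), function(l) .resblock_init(ch[l]))
  p$head <- .he_init(3L, ch[1], cfg$out_channels)
  structure(list(params = p, cfg = cfg), class = "generator")
}

.check_gen_shape <- function(dims, levels) {
  div <- 2^(levels - 1)
  if (any(dims[1:3] %% div != 0))
    stop("input spatial dims (", paste(dims[1:3], collapse = ", "),
         ") must be divisible by ", div,
         "; pad with pad_to_multiple(vol, ", div, ")")
}

#' Generator forward pass
#' @param gen A `generator`.
#' @param x input array `(D, H, W, C)` with `C = in_channels`.
#' @param want_cache keep intermediate activations for backprop.
#' @return list with `y` (array `(D, H, W, 1)`, values in `(-1, 1)`) and,
#'   if requested, `cache`.
#' @export
gen_forward <- function(gen, x, want_cache = FALSE) {
  cfg <- gen$cfg; p <- gen$params
  stopifnot(length(dim(x)) == 4L, dim(x)[4] == cfg$in_channels)
  .check_gen_shape(dim(x), cfg$levels)
  G <- cfg$groupnorm_groups
  L <- cfg$levels
  cache <- list(enc = vector("list", L - 1), down = vector("list", L - 1),
                up = vector("list", L - 1), dec = vector("list", L - 1))
  st <- .conv_fwd(x, p$stem); cache$stem <- st
  y <- st$y
  enc_y <- vector("list", L - 1)
  for (l in seq_len(L - 1)) {
    rb <- .resblock_fwd(y, p$enc[[l]], G)
    cache$enc[[l]] <- rb$cache
    enc_y[[l]] <- rb$y
    dn <- .conv_fwd(rb$y, p$down[[l]], stride = 2L)
    cache$down[[l]] <- dn
    y <- dn$y
  }
  mid <- .resblock_fwd(y, p$mid, G)
  cache$mid <- mid$cache
  y <- mid$y
  for (l in rev(seq_len(L - 1))) {
    u <- .upsample_fwd(y)
    uc <- .conv_fwd(u, p$up[[l]])
    cache$up[[l]] <- uc
    y <- uc$y + enc_y[[l]]
    rb <- .resblock_fwd(y, p$dec[[l]], G)
    cache$dec[[l]] <- rb$cache
    y <- rb$y
  }
  hd <- .conv_fwd(y, p$head)
  cache$head <- hd
  th <- .tanh_fwd(hd$y)
  cache$tanh <- th
  if (want_cache) list(y = th$y, cache = cache) else list(y = th$y)
}

# Backward pass; returns parameter gradients (input gradient not needed).
gen_backward <- function(gen, cache, dy) {
  cfg <- gen$cfg; p <- gen$params
  G <- cfg$groupnorm_groups
  L <- cfg$levels
  g <- list(enc = vector("list", L - 1), down = vector("list", L - 1),
            up = vector("list", L - 1), dec = vector("list", L - 1))
  d <- .tanh_bwd(cache$tanh, dy)
  hb <- .conv_bwd(p$head, cache$head, d)
  g$head <- hb$grads
  d <- hb$dx
  denc <- vector("list", L - 1)  # gradient flowing into each skip
  for (l in seq_len(L - 1)) {
    rb <- .resblock_bwd(p$dec[[l]], cache$dec[[l]], d, G)
    g$dec[[l]] <- rb$grads
    denc[[l]] <- rb$dx          # via addition skip
    ub <- .conv_bwd(p$up[[l]], cache$up[[l]], rb$dx)
    g$up[[l]] <- ub$grads
    d <- .upsample_bwd(ub$dx)
  }
  mb <- .resblock_bwd(p$mid, cache$mid, d, G)
  g$mid <- mb$grads
  d <- mb$dx
  for (l in rev(seq_len(L - 1))) {
    db <- .conv_bwd(p$down[[l]], cache$down[[l]], d, stride = 2L)
    g$down[[l]] <- db$grads
    d <- db$dx + denc[[l]]
    rb <- .resblock_bwd(p$enc[[l]], cache$enc[[l]], d, G)
    g$enc[[l]] <- rb$grads
    d <- rb$dx
  }
  sb <- .conv_bwd(p$stem, cache$stem, d)
  g$stem <- sb$grads
  g
}

# ---- discriminator ------------------------------------------------------

#' Build the patch-based discriminator
#'
#' A 3-layer strided 3D convolutional critic mapping the concatenation of
#' the input stack and a candidate target to a grid of realism scores, one
#' per receptive patch (least-squares GAN targets: 1 real, 0 fake).
#'
#' @param in_channels channels of (input stack + candidate).
#' @param base_channels width of the first layer.
#' @param groupnorm_groups group-norm groups for the middle layers.
#' @return A `discriminator` list with `params` and `cfg`.
#' @export
build_discriminator <- function(in_channels, base_channels = 32L,
                                groupnorm_groups = 8L) {
  C <- as.integer(base_channels)
  p <- list(c1 = .he_init(3L, in_channels, C),
            c2 = .he_init(3L, C, 2L * C), gn2 = .gn_init(2L * C),
            c3 = .he_init(3L, 2L * C, 4L * C), gn3 = .gn_init(4L * C),
            out = .he_init(3L, 4L * C, 1L))
  cfg <- list(in_channels = as.integer(in_channels), base_channels = C,
              groupnorm_groups = as.integer(min(groupnorm_groups, C)))
  structure(list(params = p, cfg = cfg), class = "discriminator")
}

#' Discriminator forward pass
#' @param disc A `discriminator`.
#' @param x array `(D, H, W, C)`: input stack with candidate target appended.
#' @param want_cache keep activations for backprop.
#' @return list with `score` (array, one realism score per receptive patch)
#'   and optionally `cache`.
#' @export
disc_forward <- function(disc, x, want_cache = FALSE) {
  p <- disc$params; G <- disc$cfg$groupnorm_groups
  c1 <- .conv_fwd(x, p$c1, stride = 2L)
  a1 <- .silu_fwd(c1$y)
  c2 <- .conv_fwd(a1$y, p$c2, stride = 2L)
  g2 <- .gn_fwd(c2$y, p$gn2, G)
  a2 <- .silu_fwd(g2$y)
  c3 <- .conv_fwd(a2$y, p$c3, stride = 2L)
  g3 <- .gn_fwd(c3$y, p$gn3, G)
  a3 <- .silu_fwd(g3$y)
  o <- .conv_fwd(a3$y, p$out)
  if (want_cache)
    list(score = o$y, cache = list(c1 = c1, a1 = a1, c2 = c2, g2 = g2,
                                   a2 = a2, c3 = c3, g3 = g3, a3 = a3, o = o))
  else list(score = o$y)
}

disc_backward <- function(disc, cache, dscore) {
  p <- disc$params
  g <- list()
  ob <- .conv_bwd(p$out, cache$o, dscore)
  g$out <- ob$grads
  d <- .silu_bwd(cache$a3, ob$dx)
  g3 <- .gn_bwd(p$gn3, cache$g3$cache, d)
  g$gn3 <- g3$grads
  c3 <- .conv_bwd(p$c3, cache$c3, g3$dx, stride = 2L)
  g$c3 <- c3$grads
  d <- .silu_bwd(cache$a2, c3$dx)
  g2 <- .gn_bwd(p$gn2, cache$g2$cache, d)
  g$gn2 <- g2$grads
  c2 <- .conv_bwd(p$c2, cache$c2, g2$dx, stride = 2L)
  g$c2 <- c2$grads
  d <- .silu_bwd(cache$a1, c2$dx)
  c1 <- .conv_bwd(p$c1, cache$c1, d, stride = 2L)
  g$c1 <- c1$grads
  list(grads = g, dx = c1$dx)
}

# ---- SSIM ---------------------------------------------------------------

.ssim_core <- function(a, b, window, data_range, want_grad = FALSE) {
  dims <- dim(a)
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  global <- any(dims < window)
  if (global) {
    n <- length(a)
    mux <- mean(a); muy <- mean(b)
    cnorm <- if (n > 1) n / (n - 1) else 1
    vx <- cnorm * (mean(a * a) - mux^2)
    vy <- cnorm * (mean(b * b) - muy^2)
    vxy <- cnorm * (mean(a * b) - mux * muy)
    A1 <- 2 * mux * muy + C1; A2 <- 2 * vxy + C2
    B1 <- mux^2 + muy^2 + C1; B2 <- vx + vy + C2
    S <- (A1 * A2) / (B1 * B2)
    if (!want_grad) return(list(value = S))
    gmu <- 2 * muy * A2 / (B1 * B2) - S * 2 * mux / B1 +
      2 * cnorm * mux * S / B2 - 2 * cnorm * muy * A1 / (B1 * B2)
    g2 <- -cnorm * S / B2
    gxy <- 2 * cnorm * A1 / (B1 * B2)
    grad <- (gmu + 2 * a * g2 + b * gxy) / n
    return(list(value = S, grad = grad))
  }
  w3 <- window^3
  cnorm <- w3 / (w3 - 1)
  bs <- function(v) cpp_boxsum_valid(as.double(v), dims, window) / w3
  mux <- bs(a); muy <- bs(b)
  m2x <- bs(a * a); m2y <- bs(b * b); mxy <- bs(a * b)
  vx <- cnorm * (m2x - mux^2); vy <- cnorm * (m2y - muy^2)
  vxy <- cnorm * (mxy - mux * muy)
  A1 <- 2 * mux * muy + C1; A2 <- 2 * vxy + C2
  B1 <- mux^2 + muy^2 + C1; B2 <- vx + vy + C2
  S <- (A1 * A2) / (B1 * B2)
  val <- mean(S)
  if (!want_grad) return(list(value = val))
  Np <- length(S)
  gmu <- 2 * muy * A2 / (B1 * B2) - S * 2 * mux / B1 +
    2 * cnorm * mux * S / B2 - 2 * cnorm * muy * A1 / (B1 * B2)
  g2 <- -cnorm * S / B2
  gxy <- 2 * cnorm * A1 / (B1 * B2)
  gdim <- dim(S)
  sc <- function(g) cpp_boxscatter(as.double(g), gdim, window, dims)
  grad <- (sc(gmu) + 2 * a * sc(g2) + b * sc(gxy)) / (w3 * Np)
  list(value = val, grad = grad)
}

#' Volumetric structural similarity (SSIM)
#'
#' Mean local SSIM over all complete cubic windows, with the standard
#' constants `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` for data range `L` and
#' sample-covariance normalization, matching the common reference
#' implementations. If the volume is smaller than the window along any
#' axis, a single global window is used instead.
#'
#' @param a,b numeric arrays of identical shape.
#' @param window cubic window side (default 7).
#' @param data_range value range `L` of the data (default 1).
#' @return Scalar SSIM in `[-1, 1]`.
#' @export
ssim3d <- function(a, b, window = 7L, data_range = 1) {
  if (!identical(dim(a), dim(b))) stop("`a` and `b` must have the same shape")
  stopifnot(data_range > 0)
  .ssim_core(a, b, as.integer(window), data_range)$value
}

# ---- losses -------------------------------------------------------------

#' Composite generator loss
#'
#' `l1 * mean|xhat - x| + ssim * (1 - SSIM(xhat, x)) + adv *
#' mean((D_scores - 1)^2)`, with weights from [loss_weights()] (defaults
#' 10/10/1). SSIM is evaluated on the `[0, 1]` working rescale of the
#' `[-1, 1]` tensors with data range 1.
#'
#' @param xhat,x predicted and ground-truth arrays in `[-1, 1]`, same shape.
#' @param d_scores discriminator scores for `xhat` (any shape).
#' @param weights a [loss_weights()].
#' @param ssim_window SSIM window (default 7).
#' @return Scalar loss (0 iff `xhat == x` and all scores are 1).
#' @export
generator_loss <- function(xhat, x, d_scores, weights = loss_weights(),
                           ssim_window = 7L) {
  if (!identical(dim(xhat), dim(x)))
    stop("`xhat` and `x` must have the same shape")
  s <- ssim3d((.strip_ch(xhat) + 1) / 2, (.strip_ch(x) + 1) / 2,
              window = ssim_window, data_range = 1)
  weights$l1 * mean(abs(xhat - x)) + weights$ssim * (1 - s) +
    weights$adv * mean((d_scores - 1)^2)
}

#' Least-squares discriminator loss
#'
#' `0.5 * mean(D_fake^2) + 0.5 * mean((D_real - 1)^2)`: the least-squares
#' GAN objective with targets 0 for generated and 1 for real candidates.
#'
#' @param d_fake,d_real score grids of identical shape.
#' @return Scalar loss.
#' @export
discriminator_loss <- function(d_fake, d_real) {
  0.5 * mean(d_fake^2) + 0.5 * mean((d_real - 1)^2)
}

.strip_ch <- function(x) {
  d <- dim(x)
  if (length(d) == 4L && d[4] == 1L) array(x, d[1:3]) else x
}

# ---- patch sampling -----------------------------------------------------

.jitter_array <- function(arr, brightness, contrast) {
  u <- (arr + 1) / 2
  m <- mean(u)
  u <- brightness * (m + contrast * (u - m))
  u[u < 0] <- 0; u[u > 1] <- 1
  2 * u - 1
}

.pad_array <- function(arr, target, value = -1) {
  n <- dim(arr)
  if (all(n >= target)) return(arr)
  out <- array(value, pmax(n, target))
  out[seq_len(n[1]), seq_len(n[2]), seq_len(n[3])] <- arr
  out
}

#' Sample one training patch from a subject
#'
#' Crops the task's input modalities and target at a uniformly drawn valid
#' offset (volumes smaller than the patch are padded with -1 first),
#' applies independent brightness/contrast jitter in `[0.8, 1.2]` to each
#' *input* channel when `cfg$augment` is TRUE (targets are never jittered),
#' and appends the three positional-embedding channels computed in the
#' frame of the uncropped volume.
#'
#' @param study a `subject_study` with modalities scaled to `[-1, 1]`.
#' @param task `"t1w_from_t2w_dixon"` or `"stir_from_t2w_t1w"`.
#' @param cfg a [train_config()].
#' @param offset optional fixed 0-based crop offset (length 3); drawn
#'   uniformly when NULL.
#' @return list with `inputs` (array `(patch, n_inputs + 3)`), `target`
#'   (array `(patch, 1)`), `offset` and `original_shape`.
#' @export
sample_patch <- function(study, task, cfg, offset = NULL) {
  def <- .task_def(task, cfg)
  missing <- setdiff(c(def$inputs, def$target), names(study))
  if (length(missing) > 0)
    stop("study is missing modality: ", paste(missing, collapse = ", "))
  ps <- cfg$patch_size
  tgt <- study[[def$target]]$data
  orig <- dim(tgt)
  arrs <- lapply(study[def$inputs], function(v) .pad_array(v$data, ps))
  tgt <- .pad_array(tgt, ps)
  n <- dim(tgt)
  if (is.null(offset))
    offset <- vapply(1:3, function(a) sample.int(n[a] - ps[a] + 1L, 1L) - 1L,
                     integer(1))
  ii <- lapply(1:3, function(a) offset[a] + seq_len(ps[a]))
  nin <- length(arrs)
  inputs <- array(0, c(ps, nin + 3L))
  for (j in seq_len(nin)) {
    patch <- arrs[[j]][ii[[1]], ii[[2]], ii[[3]]]
    if (isTRUE(cfg$augment))
      patch <- .jitter_array(patch, stats::runif(1, 0.8, 1.2),
                             stats::runif(1, 0.8, 1.2))
    inputs[, , , j] <- patch
  }
  inputs[, , , nin + (1:3)] <- .emb_channels(orig, offset, ps)
  list(inputs = inputs,
       target = array(tgt[ii[[1]], ii[[2]], ii[[3]]], c(ps, 1L)),
       offset = offset, original_shape = orig)
}

.replicate_studies <- function(studies, cfg) {
  if (cfg$replication_factor <= 1L || is.null(cfg$resolution_range))
    return(studies)
  out <- list()
  for (s in studies) {
    out[[length(out) + 1L]] <- s
    for (r in seq_len(cfg$replication_factor - 1L)) {
      res <- stats::runif(1, min(cfg$resolution_range),
                          max(cfg$resolution_range))
      rs <- lapply(unclass(s), resample, target_spacing = c(NA, res, res))
      out[[length(out) + 1L]] <- structure(rs, class = "subject_study")
    }
  }
  out
}

# ---- training -----------------------------------------------------------

.val_l1 <- function(gen, patches) {
  mean(vapply(patches, function(p) {
    y <- gen_forward(gen, p$inputs)$y
    mean(abs(y - p$target))
  }, numeric(1)))
}

#' Train a translation network with the Pix2Pix mechanism
#'
#' Alternates least-squares discriminator updates and generator updates
#' under the composite `l1/ssim/adversarial` objective, using Adam
#' (betas 0.5/0.999) at `cfg$learning_rate`. All randomness (weight
#' initialization, patch offsets, augmentation, shuffling) derives from
#' `cfg$seed`, so runs are bit-reproducible.
#'
#' @param train_studies list of `subject_study` objects (modalities in
#'   `[-1, 1]` on a common grid).
#' @param task `"t1w_from_t2w_dixon"` or `"stir_from_t2w_t1w"`.
#' @param cfg a [train_config()].
#' @param val_studies optional held-out studies; validation L1 is measured
#'   on fixed center patches before training, every `cfg$val_every` epochs
#'   and at the end, alongside two reference baselines (constant mean
#'   predictor and copy of the first input channel).
#' @return A `spinesynth_checkpoint`: generator/discriminator parameters,
#'   configs, task, seed, per-epoch `history` (mean loss components), and
#'   validation summaries (`val_l1_initial`, `val_l1_final`,
#'   `baseline_constant`, `baseline_copy`).
#' @export
train_pix2pix <- function(train_studies, task, cfg, val_studies = NULL) {
  stopifnot(length(train_studies) >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  def <- .task_def(task, cfg)
  in_ch <- length(def$inputs) + 3L
  gcfg <- generator_config(in_channels = in_ch,
                           base_channels = cfg$base_channels,
                           levels = cfg$levels,
                           groupnorm_groups = cfg$groupnorm_groups)
  gen <- build_generator(gcfg)
  disc <- build_discriminator(in_ch + 1L, base_channels = cfg$base_channels,
                              groupnorm_groups = cfg$groupnorm_groups)
  opt_g <- adam_init(gen$params)
  opt_d <- adam_init(disc$params)
  dataset <- .replicate_studies(train_studies, cfg)
  w <- cfg$weights
  val_patches <- NULL
  if (!is.null(val_studies)) {
    vcfg <- cfg; vcfg$augment <- FALSE
    val_patches <- lapply(val_studies, function(s) {
      orig <- dim(s[[def$target]]$data)
      off <- pmax(0L, as.integer((pmax(orig, cfg$patch_size) - cfg$patch_size) %/% 2L))
      sample_patch(s, task, vcfg, offset = off)
    })
  }
  baseline_constant <- baseline_copy <- NA_real_
  if (!is.null(val_patches)) {
    baseline_constant <- mean(vapply(val_patches, function(p)
      mean(abs(p$target - mean(p$target))), numeric(1)))
    baseline_copy <- mean(vapply(val_patches, function(p)
      mean(abs(p$inputs[, , , 1] - p$target[, , , 1])), numeric(1)))
  }
  val_initial <- if (!is.null(val_patches)) .val_l1(gen, val_patches) else NA_real_
  hist <- data.frame(epoch = integer(), l1 = numeric(), ssim = numeric(),
                     adv = numeric(), d_loss = numeric(), val_l1 = numeric())
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(length(dataset))
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    comp <- c(l1 = 0, ssim = 0, adv = 0, d_loss = 0); nb <- 0L
    for (batch in batches) {
      patches <- lapply(dataset[batch], sample_patch, task = task, cfg = cfg)
      fwd <- lapply(patches, function(p) gen_forward(gen, p$inputs,
                                                     want_cache = TRUE))
      # discriminator step (generated candidates detached)
      dgrads <- NULL; dloss <- 0
      for (i in seq_along(patches)) {
        p <- patches[[i]]
        xf <- .cat_ch(p$inputs, fwd[[i]]$y)
        xr <- .cat_ch(p$inputs, p$target)
        Df <- disc_forward(disc, xf, want_cache = TRUE)
        Dr <- disc_forward(disc, xr, want_cache = TRUE)
        dloss <- dloss + discriminator_loss(Df$score, Dr$score)
        nsc <- length(Df$score)
        gf <- disc_backward(disc, Df$cache, Df$score / nsc)$grads
        gr <- disc_backward(disc, Dr$cache, (Dr$score - 1) / nsc)$grads
        dgrads <- .grads_add(dgrads, .grads_add(gf, gr))
      }
      dgrads <- .grads_scale(dgrads, 1 / length(patches))
      if (!is.finite(.grads_max_abs(dgrads)))
        stop("training diverged: non-finite discriminator gradient at epoch ",
             epoch)
      sd_ <- adam_step(disc$params, dgrads, opt_d, cfg$learning_rate,
                       cfg$betas)
      disc$params <- sd_$params; opt_d <- sd_$state
      # generator step against the updated discriminator
      ggrads <- NULL
      for (i in seq_along(patches)) {
        p <- patches[[i]]
        fake <- fwd[[i]]$y
        xf <- .cat_ch(p$inputs, fake)
        Df <- disc_forward(disc, xf, want_cache = TRUE)
        nsc <- length(Df$score)
        adv <- mean((Df$score - 1)^2)
        db <- disc_backward(disc, Df$cache, 2 * (Df$score - 1) / nsc)
        nch <- dim(xf)[4]
        dfake_adv <- db$dx[, , , nch, drop = FALSE]
        nvox <- length(fake)
        l1 <- mean(abs(fake - p$target))
        ss <- .ssim_core((.strip_ch(fake) + 1) / 2,
                         (.strip_ch(p$target) + 1) / 2,
                         cfg$ssim_window, 1, want_grad = TRUE)
        dfake <- w$l1 * sign(fake - p$target) / nvox -
          w$ssim * array(ss$grad, dim(fake)) * 0.5 +
          w$adv * dfake_adv
        ggrads <- .grads_add(ggrads, gen_backward(gen, fwd[[i]]$cache, dfake))
        comp <- comp + c(l1 = l1, ssim = ss$value, adv = adv, d_loss = 0)
      }
      comp["d_loss"] <- comp["d_loss"] + dloss
      ggrads <- .grads_scale(ggrads, 1 / length(patches))
      if (!is.finite(.grads_max_abs(ggrads)))
        stop("training diverged: non-finite generator gradient at epoch ",
             epoch)
      sg <- adam_step(gen$params, ggrads, opt_g, cfg$learning_rate, cfg$betas)
      gen$params <- sg$params; opt_g <- sg$state
      nb <- nb + length(patches)
    }
    vl <- NA_real_
    if (!is.null(val_patches) &&
        (epoch %% cfg$val_every == 0L || epoch == cfg$epochs))
      vl <- .val_l1(gen, val_patches)
    hist <- rbind(hist, data.frame(epoch = epoch, l1 = comp[["l1"]] / nb,
                                   ssim = comp[["ssim"]] / nb,
                                   adv = comp[["adv"]] / nb,
                                   d_loss = comp[["d_loss"]] / nb,
                                   val_l1 = vl))
  }
  val_final <- if (!is.null(val_patches)) .val_l1(gen, val_patches) else NA_real_
  structure(list(generator = gen, discriminator = disc, task = task,
                 cfg = cfg, seed = cfg$seed, history = hist,
                 val_l1_initial = val_initial, val_l1_final = val_final,
                 baseline_constant = baseline_constant,
                 baseline_copy = baseline_copy),
            class = "spinesynth_checkpoint")
}

.cat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

#' Save / load a training checkpoint
#' @param ckpt A `spinesynth_checkpoint`.
#' @param path file path.
#' @return `path` (save) or the checkpoint (load).
#' @export
save_checkpoint <- function(ckpt, path) {
  stopifnot(inherits(ckpt, "spinesynth_checkpoint"))
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  stopifnot(inherits(ckpt, "spinesynth_checkpoint"))
  ckpt
}

# ---- inference ----------------------------------------------------------

#' Whole-volume inference
#'
#' Pads the full input volumes to dimensions divisible by 8 (fill -1),
#' appends positional embeddings held in the original volume frame, runs
#' the generator once over the whole padded volume, and crops back, so the
#' output lands on the T2w grid with values in `[-1, 1]`.
#'
#' @param ckpt A `spinesynth_checkpoint` (or the `generator` itself plus an
#'   explicit `task`).
#' @param study a `subject_study` containing the task's input modalities.
#' @param task task name; defaults to the checkpoint's task.
#' @return An `image_volume` with the synthesized modality.
#' @export
infer <- function(ckpt, study, task = NULL) {
  gen <- if (inherits(ckpt, "spinesynth_checkpoint")) ckpt$generator else ckpt
  if (is.null(task)) task <- ckpt$task
  cfg <- if (inherits(ckpt, "spinesynth_checkpoint")) ckpt$cfg else NULL
  def <- .task_def(task, cfg)
  missing <- setdiff(def$inputs, names(study))
  if (length(missing) > 0)
    stop("study is missing modality: ", paste(missing, collapse = ", "))
  ref <- study[[def$inputs[1]]]
  orig <- dim(ref$data)
  target_dim <- as.integer(ceiling(orig / 8) * 8)
  nin <- length(def$inputs)
  x <- array(-1, c(target_dim, nin + 3L))
  for (j in seq_len(nin))
    x[, , , j] <- .pad_array(study[[def$inputs[j]]]$data, target_dim)
  x[, , , nin + (1:3)] <- .emb_channels(orig, c(0L, 0L, 0L), target_dim)
  y <- gen_forward(gen, x)$y
  out <- array(y, target_dim)[seq_len(orig[1]), seq_len(orig[2]),
                              seq_len(orig[3]), drop = FALSE]
  image_volume(out, ref$affine)
}

#' Two-stage chained inference: T2w + Dixon -> T1w -> STIR
#'
#' Stage 1 synthesizes a T1w volume from the T2w and Dixon inputs; stage 2
#' synthesizes the STIR from the T2w and the *synthetic* T1w. The native
#' T1w, even if present in the study, is never consumed by stage 2.
#'
#' @param ckpt_t1w checkpoint trained on task `t1w_from_t2w_dixon`.
#' @param ckpt_stir checkpoint trained on task `stir_from_t2w_t1w`.
#' @param study a `subject_study` with `t2w`, `dixon_fat`, `dixon_water`.
#' @return list with `t1w` and `stir` synthetic `image_volume`s, both on
#'   the T2w grid.
#' @export
two_stage_infer <- function(ckpt_t1w, ckpt_stir, study) {
  t1w_synth <- infer(ckpt_t1w, study, task = "t1w_from_t2w_dixon")
  chained <- study
  chained$t1w <- t1w_synth
  stir_synth <- infer(ckpt_stir, chained, task = "stir_from_t2w_t1w")
  list(t1w = t1w_synth, stir = stir_synth)
}
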