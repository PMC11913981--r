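test_that("positional embeddings are linear gradients in the original frame", {
  e <- position_embeddings(c(20, 30, 40), c(0, 0, 0), c(20, 30, 40))
  expect_equal(dim(e), c(20, 30, 40, 3))
  # full crop: each channel runs exactly 0 -> 1 along its own axis
  expect_equal(e[, 1, 1, 1], seq(0, 1, length.out = 20))
  expect_equal(e[1, , 1, 2], seq(0, 1, length.out = 30))
  expect_equal(e[1, 1, , 3], seq(0, 1, length.out = 40))
  # constant along the other axes
  expect_equal(diff(range(e[5, , , 1])), 0)
  expect_true(all(e >= 0 & e <= 1))

  # crop offset 10, axis length 101: first voxel embeds at 0.1
  e2 <- position_embeddings(c(101, 101, 101), c(10, 0, 0), c(16, 16, 16))
  expect_equal(e2[1, 1, 1, 1], 0.1)
  expect_equal(e2[16, 1, 1, 1], 0.25)

  # two disjoint crops agree only where they overlap
  ea <- position_embeddings(c(64, 64, 64), c(0, 0, 0), c(32, 32, 32))
  eb <- position_embeddings(c(64, 64, 64), c(16, 0, 0), c(32, 32, 32))
  expect_equal(ea[17:32, , , 1], eb[1:16, , , 1])
  expect_true(all(ea[1:16, 1, 1, 1] != eb[17:32, 1, 1, 1]))

  expect_error(position_embeddings(c(10, 10, 10), c(5, 0, 0), c(8, 8, 8)),
               "within")
  # degenerate axis of length 1: all-zero channel
  e3 <- position_embeddings(c(1, 8, 8), c(0, 0, 0), c(1, 8, 8))
  expect_true(all(e3[, , , 1] == 0))
})

test_that("layer backward passes match finite differences", {
  set.seed(101)
  x <- array(rnorm(4 * 6 * 6 * 3), c(4, 6, 6, 3))
  p <- spinesynth:::.he_init(3L, 3L, 2L)
  for (stride in c(1L, 2L)) {
    f <- spinesynth:::.conv_fwd(x, p, stride)
    bw <- spinesynth:::.conv_bwd(p, f, cos(f$y), stride)
    loss <- function(xv) sum(sin(spinesynth:::.conv_fwd(array(xv, dim(x)),
                                                        p, stride)$y))
    idx <- sample(length(x), 8)
    expect_lt(rel_err(bw$dx[idx], num_grad_at(loss, x, idx)), 2e-3)
    lossW <- function(wv) {
      p2 <- p; p2$W <- array(wv, dim(p$W))
      sum(sin(spinesynth:::.conv_fwd(x, p2, stride)$y))
    }
    idxw <- sample(length(p$W), 8)
    expect_lt(rel_err(bw$grads$W[idxw], num_grad_at(lossW, p$W, idxw)), 2e-3)
  }

  gp <- spinesynth:::.gn_init(4L)
  gp$gamma <- runif(4, 0.5, 1.5); gp$beta <- rnorm(4)
  xg <- array(rnorm(3 * 4 * 4 * 4), c(3, 4, 4, 4))
  gf <- spinesynth:::.gn_fwd(xg, gp, 2L)
  gb <- spinesynth:::.gn_bwd(gp, gf$cache, cos(gf$y))
  lossg <- function(xv) sum(sin(spinesynth:::.gn_fwd(array(xv, dim(xg)),
                                                     gp, 2L)$y))
  idx <- sample(length(xg), 8)
  expect_lt(rel_err(gb$dx[idx], num_grad_at(lossg, xg, idx, 1e-5)), 1e-4)

  xs <- array(rnorm(64), c(4, 4, 4, 1))
  sf <- spinesynth:::.silu_fwd(xs)
  sb <- spinesynth:::.silu_bwd(sf, cos(sf$y))
  losss <- function(xv) sum(sin(spinesynth:::.silu_fwd(array(xv, dim(xs)))$y))
  expect_lt(rel_err(sb, array(num_grad_at(losss, xs, seq_along(xs), 1e-5),
                              dim(xs))), 1e-4)
})

test_that("generator meets its shape contract and backprop is correct", {
  set.seed(55)
  gcfg <- generator_config(in_channels = 6, base_channels = 8, levels = 3,
                           groupnorm_groups = 8)
  gen <- build_generator(gcfg)
  x <- array(rnorm(16 * 64 * 64 * 6) * 0.3, c(16, 64, 64, 6))
  f <- gen_forward(gen, x)
  expect_equal(dim(f$y), c(16, 64, 64, 1))
  expect_true(all(abs(f$y) <= 1))
  # deterministic for fixed weights
  expect_identical(gen_forward(gen, x)$y, f$y)
  # indivisible input rejected with a padding hint
  expect_error(gen_forward(gen, array(0, c(15, 64, 64, 6))), "divisible")
  # group constraint enforced
  expect_error(generator_config(in_channels = 6, base_channels = 12,
                                groupnorm_groups = 8), "divide")

  # end-to-end parameter gradient check on a tiny generator (float conv)
  gsm <- build_generator(generator_config(in_channels = 2, base_channels = 2,
                                          levels = 2, groupnorm_groups = 2))
  xs <- array(rnorm(4 * 8 * 8 * 2) * 0.5, c(4, 8, 8, 2))
  tgt <- array(tanh(rnorm(4 * 8 * 8)), c(4, 8, 8, 1))
  fwd <- gen_forward(gsm, xs, want_cache = TRUE)
  g <- spinesynth:::gen_backward(gsm, fwd$cache, 2 * (fwd$y - tgt) / length(tgt))
  lossW <- function(wv) {
    g2 <- gsm; g2$params$enc[[1]]$conv1$W <- array(wv, dim(wv))
    mean((gen_forward(g2, xs)$y - tgt)^2)
  }
  W0 <- gsm$params$enc[[1]]$conv1$W
  idx <- sample(length(W0), 6)
  ng <- vapply(idx, function(i) {
    eps <- 1e-3
    wp <- W0; wp[i] <- wp[i] + eps; wm <- W0; wm[i] <- wm[i] - eps
    (lossW(wp) - lossW(wm)) / (2 * eps)
  }, numeric(1))
  expect_lt(rel_err(g$enc[[1]]$conv1$W[idx], ng), 5e-3)
})

test_that("patch discriminator scores patches and is shift-equivariant", {
  set.seed(66)
  disc <- build_discriminator(3, base_channels = 8, groupnorm_groups = 8)
  x <- array(rnorm(16 * 32 * 32 * 3) * 0.2, c(16, 32, 32, 3))
  s <- disc_forward(disc, x)$score
  # strictly smaller score grid (three stride-2 stages)
  expect_true(all(dim(s)[1:3] < dim(x)[1:3]))
  expect_equal(dim(s)[1:3], dim(x)[1:3] / 8)
  expect_identical(disc_forward(disc, x)$score, s)

  # shifting a blob by one full stride shifts the score grid by one cell
  z <- array(0, c(16, 64, 64, 3))
  z[5:8, 17:24, 17:24, ] <- 1
  z2 <- array(0, c(16, 64, 64, 3))
  z2[5:8, 25:32, 17:24, ] <- 1  # +8 voxels along axis 2
  s1 <- disc_forward(disc, z)$score
  s2 <- disc_forward(disc, z2)$score
  interior <- 3:6
  expect_lt(max(abs(s1[1, interior, 3, 1] - s2[1, interior + 1, 3, 1])), 1e-4)

  # input gradient (used by the adversarial term) is correct
  df <- disc_forward(disc, x, want_cache = TRUE)
  db <- spinesynth:::disc_backward(disc, df$cache,
                                   2 * (df$score - 1) / length(df$score))
  lossx <- function(xv) mean((disc_forward(disc, array(xv, dim(x)))$score - 1)^2)
  idx <- sample(length(x), 6)
  expect_lt(rel_err(db$dx[idx], num_grad_at(lossx, x, idx, eps = 5e-3)), 1e-2)
})

test_that("ssim3d matches its definition, a reference implementation, and has a correct gradient", {
  set.seed(31)
  a <- array(runif(16^3), c(16, 16, 16))
  expect_equal(ssim3d(a, a), 1.0)

  # windowed-zero-mean anti-correlated pattern: covariance term drives SSIM < 0
  i <- slice.index(array(0, c(14, 14, 14)), 1)
  pat <- array(0.5 * sin(2 * pi * i / 7), c(14, 14, 14))
  expect_lt(ssim3d(pat, -pat), 0)

  # agreement with scikit-image on random volumes (same window, data range)
  for (k in 1:5) {
    b <- array(runif(16^3), c(16, 16, 16))
    bb <- a + 0.3 * (b - 0.5)
    f <- tempfile()
    writeLines(c(paste(a, collapse = ","), paste(bb, collapse = ",")), f)
    ref <- system2("python", c("-c", shQuote(sprintf("
import numpy as np
from skimage.metrics import structural_similarity
lines = open('%s').read().splitlines()
a = np.array([float(x) for x in lines[0].split(',')]).reshape((16,16,16), order='F')
b = np.array([float(x) for x in lines[1].split(',')]).reshape((16,16,16), order='F')
print('%%.12f' %% structural_similarity(a, b, win_size=7, data_range=1.0))
", f))), stdout = TRUE)
    expect_lt(abs(ssim3d(a, bb, 7, 1) - as.numeric(ref)), 1e-6)
    unlink(f)
  }

  # analytic gradient of the SSIM loss term vs finite differences
  a5 <- array(runif(9 * 9 * 9), c(9, 9, 9))
  b5 <- array(runif(9 * 9 * 9), c(9, 9, 9))
  sg <- spinesynth:::.ssim_core(a5, b5, 7L, 1, want_grad = TRUE)
  fs <- function(av) spinesynth:::.ssim_core(array(av, dim(a5)), b5, 7L, 1)$value
  idx <- sample(length(a5), 10)
  expect_lt(rel_err(sg$grad[idx], num_grad_at(fs, a5, idx, 1e-5)), 1e-5)

  # volumes smaller than the window fall back to a single global window
  a6 <- array(runif(64), c(4, 4, 4))
  b6 <- array(runif(64), c(4, 4, 4))
  n <- 64; cn <- n / (n - 1)
  mux <- mean(a6); muy <- mean(b6)
  vx <- cn * (mean(a6^2) - mux^2); vy <- cn * (mean(b6^2) - muy^2)
  vxy <- cn * (mean(a6 * b6) - mux * muy)
  C1 <- 1e-4; C2 <- 9e-4
  Sref <- (2 * mux * muy + C1) * (2 * vxy + C2) /
    ((mux^2 + muy^2 + C1) * (vx + vy + C2))
  expect_equal(ssim3d(a6, b6), Sref)
})

test_that("loss formulas follow the weighted L1 + SSIM + LSGAN objective", {
  set.seed(12)
  x <- array(runif(8 * 16 * 16, -1, 1), c(8, 16, 16, 1))
  ones <- array(1, c(2, 2, 2))
  expect_equal(generator_loss(x, x, ones), 0)
  expect_equal(generator_loss(x, x, array(0, c(2, 2, 2))), 1.0)
  expect_error(generator_loss(x, x[, 1:8, , , drop = FALSE], ones), "shape")

  # constant-offset pair: closed-form SSIM of two constant images
  xh <- array(0.1, c(8, 16, 16, 1)); x0 <- array(0, c(8, 16, 16, 1))
  mu1 <- 0.55; mu2 <- 0.5  # on the [0, 1] working scale
  C1 <- 1e-4
  S <- (2 * mu1 * mu2 + C1) / (mu1^2 + mu2^2 + C1)
  expect_equal(generator_loss(xh, x0, ones), 10 * 0.1 + 10 * (1 - S),
               tolerance = 1e-9)

  expect_equal(discriminator_loss(array(0, c(3, 3)), array(1, c(3, 3))), 0)
  expect_equal(discriminator_loss(array(1, c(3, 3)), array(0, c(3, 3))), 1)
  expect_equal(discriminator_loss(array(0.5, c(3, 3)), array(0.5, c(3, 3))),
               0.25)
})

test_that("patch sampling is seeded, counts channels, and covers offsets uniformly", {
  study <- make_test_study(31, shape = c(16L, 48L, 48L))
  cfg <- train_config(patch_size = c(8, 24, 24), augment = TRUE,
                      base_channels = 8, levels = 2, seed = 1)
  set.seed(4)
  p1 <- sample_patch(study, "t1w_from_t2w_dixon", cfg)
  set.seed(4)
  p2 <- sample_patch(study, "t1w_from_t2w_dixon", cfg)
  expect_identical(p1$inputs, p2$inputs)
  expect_identical(p1$target, p2$target)
  # 3 modalities + 3 embeddings for the T1w task with the Dixon pair
  expect_equal(dim(p1$inputs)[4], 6)
  expect_equal(dim(p1$target), c(8, 24, 24, 1))
  # single-input ablation drops to 1 + 3 channels
  cfg1 <- cfg; cfg1$input_modalities <- "t2w"
  expect_equal(dim(sample_patch(study, "t1w_from_t2w_dixon", cfg1)$inputs)[4], 4)
  expect_error(sample_patch(study[c("t2w", "t1w")], "t1w_from_t2w_dixon", cfg),
               "missing modality")

  # offsets cover the valid range approximately uniformly
  cfg0 <- cfg; cfg0$augment <- FALSE
  set.seed(77)
  offs <- replicate(1000,
    sample_patch(study, "stir_from_t2w_t1w", cfg0)$offset[2])
  expect_setequal(sort(unique(offs)), 0:24)
  expect_gt(stats::chisq.test(table(factor(offs, levels = 0:24)))$p.value,
            0.001)
})

test_that("whole-volume and two-stage inference respect the task contracts", {
  study <- make_test_study(91, shape = c(16L, 48L, 48L))
  set.seed(3)
  gen <- build_generator(generator_config(in_channels = 6, base_channels = 8,
                                          levels = 2))
  ck <- structure(list(generator = gen, task = "t1w_from_t2w_dixon",
                       cfg = NULL), class = "spinesynth_checkpoint")
  out <- infer(ck, study)
  expect_s3_class(out, "image_volume")
  expect_equal(dim(out$data), dim(study$t2w$data))
  expect_equal(out$affine, study$t2w$affine)
  expect_true(all(out$data >= -1 & out$data <= 1))
  expect_identical(infer(ck, study)$data, out$data)
  expect_error(infer(ck, study[c("t2w", "t1w")]), "dixon")

  gen2 <- build_generator(generator_config(in_channels = 5, base_channels = 8,
                                           levels = 2))
  ck2 <- structure(list(generator = gen2, task = "stir_from_t2w_t1w",
                        cfg = NULL), class = "spinesynth_checkpoint")
  both <- two_stage_infer(ck, ck2, study)
  expect_equal(dim(both$stir$data), dim(study$t2w$data))
  expect_equal(both$t1w$affine, study$t2w$affine)

  # stage 2 depends on the stage-1 output, not the native T1w
  study_const <- study
  study_const$t1w <- image_volume(array(-1, dim(study$t1w$data)),
                                  study$t1w$affine)
  direct <- infer(ck2, study_const, task = "stir_from_t2w_t1w")
  expect_gt(max(abs(direct$data - both$stir$data)), 1e-6)

  # checkpoint save/load round trip
  f <- tempfile(fileext = ".rds")
  save_checkpoint(structure(list(generator = gen, task = "t1w_from_t2w_dixon",
                                 cfg = NULL),
                            class = "spinesynth_checkpoint"), f)
  ckr <- load_checkpoint(f)
  expect_identical(infer(ckr, study)$data, out$data)
  unlink(f)
})
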