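test_that("global bounding box is the minimal world box of all chunks", {
  aff <- diag(c(3, 1.1, 1.1, 1))
  v <- image_volume(array(runif(16 * 48 * 48), c(16, 48, 48)), aff)

  # single chunk: box equals the chunk extent
  g1 <- global_bounding_box(chunk_set(list(v)))
  expect_equal(g1$shape, c(16L, 48L, 48L))

  # two disjoint chunks stacked vertically with a 11 mm (10-voxel) gap
  a2 <- aff; a2[1:3, 4] <- a2[1:3, 4] + aff[1:3, 2] * (48 + 10)
  v2 <- image_volume(array(0, c(16, 48, 48)), a2)
  g2 <- global_bounding_box(chunk_set(list(v, v2)))
  expect_equal(g2$shape[2], 48L + 10L + 48L)

  # scoliotic offsets: lateral box width is the union across chunks
  a3 <- aff; a3[1:3, 4] <- a3[1:3, 4] + aff[1:3, 3] * 12  # shifted laterally
  v3 <- image_volume(array(0, c(16, 48, 48)), a3)
  g3 <- global_bounding_box(chunk_set(list(v, v3)))
  expect_equal(g3$shape[3], 48L + 12L)
  expect_error(chunk_set(list()), "at least one")
})

test_that("overlap weights follow 1 - d_x / sum(d_i) and sum to 1", {
  # two chunks overlapping by 4 voxels along the vertical axis
  aff <- diag(c(1, 1, 1, 1))
  top <- image_volume(array(1, c(4, 10, 4)), aff)
  a2 <- aff; a2[2, 4] <- 6
  bot <- image_volume(array(0, c(4, 10, 4)), a2)
  cs <- chunk_set(list(top, bot))
  grid <- global_bounding_box(cs)
  ow <- overlap_weights(cs, grid)

  # coverage: rows 1..6 exclusive to top, 7..10 overlap, 11..16 bottom
  expect_equal(unique(as.vector(ow$coverage[, 1:6, ])), 1L)
  expect_equal(unique(as.vector(ow$coverage[, 7:10, ])), 2L)

  # inside the overlap: d_top = o, d_bot = 5 - o for row offset o = 1..4
  for (o in 1:4) {
    w_top <- ow$weights[[1]][1, 6 + o, 1]
    expect_equal(w_top, 1 - o / 5)
    expect_equal(ow$weights[[2]][1, 6 + o, 1], 1 - (5 - o) / 5)
  }
  # symmetric-distance voxels get 0.5/0.5 (overlap of 3 -> center row)
  a3 <- aff; a3[2, 4] <- 7
  cs3 <- chunk_set(list(top, image_volume(array(0, c(4, 10, 4)), a3)))
  ow3 <- overlap_weights(cs3, global_bounding_box(cs3))
  expect_equal(ow3$weights[[1]][2, 9, 2], 0.5)
  expect_equal(ow3$weights[[2]][2, 9, 2], 0.5)

  # weights in [0,1], summing exactly to 1 wherever covered
  wsum <- ow$weights[[1]] + ow$weights[[2]]
  covered <- ow$coverage > 0
  expect_true(all(abs(wsum[covered] - 1) < 1e-12))
  expect_true(all(wsum[!covered] == 0))
  for (w in ow$weights) expect_true(all(w >= 0 & w <= 1))
  # non-overlap voxel: the sole covering chunk has weight 1
  expect_equal(ow$weights[[1]][1, 3, 1], 1)
})

test_that("blending fuses chunks smoothly and inverts chunking", {
  s <- phantom_subject(phantom_spec(seed = 5), normalize = FALSE)
  v <- s$t2w

  # constant chunks blend to the same constant in the overlap
  aff <- diag(c(1, 1, 1, 1))
  c1 <- image_volume(array(0.37, c(4, 10, 4)), aff)
  a2 <- aff; a2[2, 4] <- 6
  c2 <- image_volume(array(0.37, c(4, 10, 4)), a2)
  fused_c <- blend(chunk_set(list(c1, c2)))
  cov <- attr(fused_c, "coverage")
  expect_true(all(abs(fused_c$data[cov] - 0.37) < 1e-12))

  # split then blend reproduces the original volume
  cs <- split_into_chunks(v, 3, overlap = 8, jitter = 0)
  fused <- blend(cs)
  expect_equal(dim(fused$data), dim(v$data))
  expect_lt(max(abs(fused$data - v$data)), 1e-5)

  # permutation invariance in chunk order
  csr <- chunk_set(rev(cs$chunks), cs$modality)
  fused_r <- blend(csr, global_bounding_box(cs))
  expect_equal(fused_r$data, blend(cs, global_bounding_box(cs))$data)

  # single chunk: identity up to resampling tolerance
  one <- blend(split_into_chunks(v, 1))
  expect_lt(max(abs(one$data - v$data)), 1e-6)
})

test_that("translation registration recovers known shifts and flags failures", {
  s <- phantom_subject(phantom_spec(seed = 6), normalize = FALSE)
  fixed <- s$t2w

  r0 <- register_translation(fixed, fixed, max_shift = 10)
  expect_equal(r0$shift_voxels, c(0, 0, 0))
  expect_equal(r0$score, 1.0, tolerance = 1e-9)
  expect_false(r0$failed)

  # a moving volume whose affine is offset by a known integer-voxel shift
  sp <- vol_spacing(fixed)
  true_vox <- c(0, 3, -2)
  am <- fixed$affine
  am[1:3, 4] <- am[1:3, 4] + fixed$affine[1:3, 1:3] %*% true_vox
  moving <- image_volume(fixed$data, am)
  r <- register_translation(moving, fixed, max_shift = 15)
  expect_equal(r$shift_voxels, -true_vox)  # correction undoes the offset
  expect_false(r$failed)
  aligned <- apply_shift(moving, r$shift)
  expect_equal(aligned$affine, fixed$affine, tolerance = 1e-9)

  # independent noise: correlation near zero, flagged failed
  set.seed(11)
  noise <- image_volume(array(rnorm(prod(dim(fixed$data))), dim(fixed$data)),
                        fixed$affine)
  rn <- register_translation(noise, fixed, max_shift = 10)
  expect_lt(abs(rn$score), 0.3)
  expect_true(rn$failed)

  # constant input: explanatory failure
  flat <- image_volume(array(1, dim(fixed$data)), fixed$affine)
  rc <- register_translation(flat, fixed)
  expect_true(rc$failed)
  expect_match(rc$status, "constant")
})

test_that("jittered chunks are realigned by registration before blending", {
  s <- phantom_subject(phantom_spec(seed = 8), normalize = FALSE)
  v <- s$t1w
  cs <- split_into_chunks(v, 2, overlap = 10, jitter = 3, seed = 21)
  ref <- split_into_chunks(v, 2, overlap = 10, jitter = 0)
  fixed <- ref$chunks[[1]]
  for (i in 1:2) {
    r <- register_translation(cs$chunks[[i]], ref$chunks[[i]], max_shift = 6)
    jit <- attr(cs$chunks[[i]], "jitter_mm")
    realigned <- apply_shift(cs$chunks[[i]], r$shift)
    # integer-voxel registration cancels the jitter up to half a voxel
    expect_true(all(abs(realigned$affine[1:3, 4] -
                          ref$chunks[[i]]$affine[1:3, 4]) <=
                      vol_spacing(v) / 2 + 1e-9))
  }
})
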