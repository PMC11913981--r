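make_table <- function(n_items, n_raters, seed = 1, modality = "t1w") {
  set.seed(seed)
  items <- data.frame(item_id = seq_len(n_items), modality = modality,
                      truth = sample(c("real", "generated"), n_items, TRUE))
  ratings <- matrix(sample(c("real", "generated"), n_items * n_raters, TRUE),
                    n_items, n_raters,
                    dimnames = list(NULL, paste0("rater_", seq_len(n_raters))))
  rating_table(items, ratings)
}

test_that("misclassification rates count rating/truth disagreements", {
  items <- data.frame(item_id = 1:10, modality = "t1w",
                      truth = rep(c("real", "generated"), 5))
  ratings <- matrix(items$truth, 10, 2,
                    dimnames = list(NULL, c("r1", "r2")))
  ratings[1:4, 2] <- ifelse(ratings[1:4, 2] == "real", "generated", "real")
  tab <- rating_table(items, ratings)
  expect_equal(misclassification_rate(tab, "r1", "t1w"), 0)
  expect_equal(misclassification_rate(tab, "r2", "t1w"), 0.4)
  # flipping a rater's column complements the rate
  flipped <- ratings
  flipped[, 2] <- ifelse(ratings[, 2] == "real", "generated", "real")
  tabf <- rating_table(items, flipped)
  expect_equal(misclassification_rate(tabf, "r2", "t1w"), 0.6)
  expect_error(misclassification_rate(tab, "r1", "stir"), "no items")
  expect_error(misclassification_rate(tab, "nobody", "t1w"), "unknown rater")
})

test_that("cohort rate summaries reproduce the published reader-study means", {
  rates <- utils::read.csv(reader_rates_path())
  expect_equal(nrow(rates), 7)
  s_t1w <- summarize_rates(rates$t1w)
  s_stir <- summarize_rates(rates$stir)
  expect_equal(s_t1w$mean, 0.39)
  expect_equal(s_stir$mean, 0.42)
  # identical rates across raters: sd 0
  expect_equal(summarize_rates(rep(0.4, 5))$sd, 0)
  # rounding is half-up
  expect_equal(summarize_rates(c(0.125, 0.125))$mean, 0.13)
})

test_that("Fleiss kappa matches brute-force evaluation and its invariances", {
  # perfect agreement on a mixed-category table
  items <- data.frame(item_id = 1:6, modality = "t1w",
                      truth = rep(c("real", "generated"), 3))
  ratings <- matrix(rep(items$truth, 3), 6, 3)
  k1 <- fleiss_kappa(rating_table(items, ratings), "t1w")
  expect_equal(k1$kappa, 1)
  expect_equal(k1$band, "Very good")

  # independent fair-coin ratings: kappa near zero
  big <- make_table(500, 7, seed = 19)
  k0 <- fleiss_kappa(big, "t1w")
  expect_lt(abs(k0$kappa), 0.05)
  expect_equal(k0$band, "Poor")
  expect_equal(k0$ci99[2] - k0$kappa, 2.576 * k0$se)

  # 4-item, 3-rater hand table against a from-scratch formula evaluation
  tab <- make_table(4, 3, seed = 7)
  kh <- fleiss_kappa(tab, "t1w")
  cnt <- cbind(rowSums(tab$ratings == "real"),
               rowSums(tab$ratings == "generated"))
  n <- 3; N <- 4
  Pi <- (rowSums(cnt^2) - n) / (n * (n - 1))
  pj <- colSums(cnt) / (N * n)
  kappa_bf <- (mean(Pi) - sum(pj^2)) / (1 - sum(pj^2))
  expect_equal(kh$kappa, kappa_bf, tolerance = 1e-12)

  # invariance to item and rater permutations
  perm <- sample(500)
  tabp <- rating_table(big$items[perm, ], big$ratings[perm, sample(7)])
  expect_equal(fleiss_kappa(tabp, "t1w")$kappa, k0$kappa, tolerance = 1e-12)

  # two raters, two categories: equals Scott-style pi on pooled marginals
  two <- make_table(200, 2, seed = 23)
  k2 <- fleiss_kappa(two, "t1w")
  agree <- mean(two$ratings[, 1] == two$ratings[, 2])
  pj2 <- c(mean(two$ratings == "real"), mean(two$ratings == "generated"))
  pi_classic <- (agree - sum(pj2^2)) / (1 - sum(pj2^2))
  expect_equal(k2$kappa, pi_classic, tolerance = 1e-9)

  # degenerate: every rating one category
  items1 <- data.frame(item_id = 1:4, modality = "stir",
                       truth = rep("real", 4))
  all_real <- matrix("real", 4, 3)
  kd <- fleiss_kappa(rating_table(items1, all_real), "stir")
  expect_true(kd$degenerate)
  expect_true(is.na(kd$kappa))
  expect_match(kd$message, "one category")
})

test_that("kappa interpretation bands use the printed cut points", {
  expect_equal(interpret_kappa(0.09), "Poor")
  expect_equal(interpret_kappa(0.2), "Poor")     # boundary -> lower band
  expect_equal(interpret_kappa(0.21), "Fair")
  expect_equal(interpret_kappa(0.4), "Fair")
  expect_equal(interpret_kappa(0.41), "Moderate")
  expect_equal(interpret_kappa(0.61), "Good")
  expect_equal(interpret_kappa(1.0), "Very good")
  expect_equal(interpret_kappa(-0.3), "Poor")
  expect_error(interpret_kappa(1.5))
})

test_that("presentation images are standardized 150x150 at fixed resolution", {
  s <- phantom_subject(phantom_spec(seed = 13))
  ctr <- voxel_to_world(s$t2w, matrix(c(16, 48, 48), 1))
  img <- prepare_turing_image(s$t2w, ctr)
  expect_equal(dim(img), c(150, 150))
  expect_true(all(img >= 0 & img <= 1))
  expect_identical(prepare_turing_image(s$t2w, ctr), img)

  # a landmark at the requested center appears at the central pixel
  v <- s$t2w
  v$data[17, 49, 49] <- 100
  img2 <- prepare_turing_image(v, voxel_to_world(v, matrix(c(16, 48, 48), 1)))
  peak <- which(img2 == max(img2), arr.ind = TRUE)[1, ]
  expect_true(all(abs(peak - c(76, 76)) <= 1))

  far <- ctr + c(0, 0, 1000)
  expect_error(prepare_turing_image(s$t2w, far), "outside")
})

test_that("rating tables round trip through CSV", {
  tab <- make_table(12, 3, seed = 5, modality = "stir")
  f <- tempfile(fileext = ".csv")
  write_rating_table(tab, f)
  back <- read_rating_table(f)
  expect_equal(back$ratings, tab$ratings)
  expect_equal(back$items$truth, tab$items$truth)
  expect_equal(back$raters, tab$raters)
  unlink(f)
  expect_error(rating_table(tab$items, tab$ratings[1:5, ]), "one row per item")
  bad <- tab$ratings; bad[1, 1] <- "maybe"
  expect_error(rating_table(tab$items, bad), "'real' or 'generated'")
})
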