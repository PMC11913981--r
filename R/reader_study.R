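#' Reader-study rating table
#'
#' Holds the judgments of a Turing-style reader study: for each presented
#' item (one 2D image of a given modality, either natively acquired or
#' generated), every rater labels it `"real"` or `"generated"`.
#'
#' @param items `data.frame` with columns `item_id`, `modality` (`"t1w"` or
#'   `"stir"`) and `truth` (`"real"` / `"generated"`).
#' @param ratings character matrix (items x raters) with values `"real"` /
#'   `"generated"`; column names are the rater labels.
#' @return A `rating_table` object.
#' @export
rating_table <- function(items, ratings) {
  stopifnot(is.data.frame(items),
            all(c("item_id", "modality", "truth") %in% names(items)))
  ratings <- as.matrix(ratings)
  if (nrow(ratings) != nrow(items))
    stop("ratings must have one row per item")
  if (any(is.na(ratings)))
    stop("rating table has missing cells")
  bad <- !(ratings %in% c("real", "generated"))
  if (any(bad))
    stop("ratings must be 'real' or 'generated'")
  if (!all(items$truth %in% c("real", "generated")))
    stop("truth must be 'real' or 'generated'")
  if (is.null(colnames(ratings)))
    colnames(ratings) <- paste0("rater_", seq_len(ncol(ratings)))
  structure(list(items = items, ratings = ratings,
                 raters = colnames(ratings)),
            class = "rating_table")
}

#' @export
print.rating_table <- function(x, ...) {
  cat("<rating_table> ", nrow(x$items), " items x ", length(x$raters),
      " raters (", paste(unique(x$items$modality), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Read / write a rating table as CSV
#'
#' CSV layout: columns `item_id`, `modality`, `truth`, then one column per
#' rater (named `rater_*` or anything else).
#'
#' @param path CSV file path.
#' @return A `rating_table` (read) or `path` (write).
#' @export
read_rating_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fixed <- c("item_id", "modality", "truth")
  if (!all(fixed %in% names(df)))
    stop("CSV must contain columns: ", paste(fixed, collapse = ", "))
  rater_cols <- setdiff(names(df), fixed)
  if (length(rater_cols) < 1) stop("no rater columns found")
  rating_table(df[fixed], as.matrix(df[rater_cols]))
}

#' @rdname read_rating_table
#' @param table A `rating_table`.
#' @export
write_rating_table <- function(table, path) {
  df <- cbind(table$items[c("item_id", "modality", "truth")],
              as.data.frame(table$ratings))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

.modality_rows <- function(table, modality) {
  rows <- which(table$items$modality == modality)
  if (length(rows) == 0)
    stop("no items with modality '", modality, "'")
  rows
}

#' Misclassification rate of one rater on one modality
#'
#' The fraction false / (false + correct) of the rater's judgments on that
#' modality's items that disagree with the ground truth. A rate near 0.5
#' means real and generated images were indistinguishable to that rater.
#'
#' @param table A `rating_table`.
#' @param rater rater label (column of the table).
#' @param modality `"t1w"` or `"stir"`.
#' @return Misclassification rate in `[0, 1]`.
#' @export
misclassification_rate <- function(table, rater, modality) {
  stopifnot(inherits(table, "rating_table"))
  if (!rater %in% table$raters) stop("unknown rater '", rater, "'")
  rows <- .modality_rows(table, modality)
  mean(table$ratings[rows, rater] != table$items$truth[rows])
}

.round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Cohort summary of misclassification rates
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of the
#' per-rater misclassification rates for one modality, rounded half-up to
#' `digits` decimals.
#'
#' @param table A `rating_table` (>= 2 raters), or directly a numeric
#'   vector of per-rater misclassification rates (as reported in published
#'   reader studies).
#' @param modality `"t1w"` or `"stir"`; ignored when `table` is numeric.
#' @param digits decimals for the rounded summary (default 2).
#' @return List with `rates` (named per-rater vector), `mean`, `sd`
#'   (rounded), and `mean_raw`, `sd_raw`.
#' @export
summarize_rates <- function(table, modality = NULL, digits = 2) {
  if (is.numeric(table)) {
    stopifnot(length(table) >= 2)
    rates <- table
  } else {
    stopifnot(length(table$raters) >= 2)
    rates <- vapply(table$raters, misclassification_rate, numeric(1),
                    table = table, modality = modality)
  }
  list(rates = rates,
       mean = .round_half_up(mean(rates), digits),
       sd = .round_half_up(stats::sd(rates), digits),
       mean_raw = mean(rates), sd_raw = stats::sd(rates))
}

#' Fleiss kappa over the rated labels
#'
#' Standard multi-rater Fleiss kappa on the items x raters label matrix
#' (categories `real` / `generated`): with per-item agreement
#' `P_i = (sum_j n_ij^2 - n) / (n (n - 1))`, mean agreement `Pbar`, and
#' chance agreement `Pe = sum_j p_j^2` from the category marginals,
#' `kappa = (Pbar - Pe) / (1 - Pe)`. The large-sample standard error
#' follows the classical Fleiss variance, and the 99% confidence interval
#' uses z = 2.576. Note kappa is computed over the *rated labels*, not
#' over correctness against the truth.
#'
#' @param table A `rating_table` (>= 2 raters, >= 2 items of the modality).
#' @param modality `"t1w"` or `"stir"`.
#' @return A `kappa_result`: list with `kappa`, `se`, `ci99`, `band`
#'   (interpretation per [interpret_kappa()]), and bookkeeping fields. If
#'   every rating is a single category, chance agreement is 1 and the
#'   result is flagged `degenerate` with `kappa = NA`.
#' @export
fleiss_kappa <- function(table, modality) {
  stopifnot(inherits(table, "rating_table"), length(table$raters) >= 2)
  rows <- .modality_rows(table, modality)
  if (length(rows) < 2) stop("need at least 2 items")
  R <- table$ratings[rows, , drop = FALSE]
  N <- nrow(R); n <- ncol(R)
  cats <- c("real", "generated")
  counts <- cbind(rowSums(R == "real"), rowSums(R == "generated"))
  pj <- colSums(counts) / (N * n)
  Pe <- sum(pj^2)
  if (Pe >= 1 - 1e-12) {
    return(structure(list(kappa = NA_real_, se = NA_real_,
                          ci99 = c(NA_real_, NA_real_), band = NA_character_,
                          degenerate = TRUE, n_items = N, n_raters = n,
                          message = "all ratings fall in one category; chance agreement is 1 and kappa is undefined"),
                     class = "kappa_result"))
  }
  Pi <- (rowSums(counts^2) - n) / (n * (n - 1))
  Pbar <- mean(Pi)
  kappa <- (Pbar - Pe) / (1 - Pe)
  qj <- 1 - pj
  se <- sqrt(2 / (N * n * (n - 1))) *
    sqrt(sum(pj * qj)^2 - sum(pj * qj * (qj - pj))) / sum(pj * qj)
  z <- 2.576
  structure(list(kappa = kappa, se = se, ci99 = c(kappa - z * se,
                                                  kappa + z * se),
                 band = interpret_kappa(kappa), degenerate = FALSE,
                 n_items = N, n_raters = n, message = "ok"),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("<kappa_result> degenerate: ", x$message, "\n", sep = "")
  } else {
    cat(sprintf("<kappa_result> kappa = %.3f (SE %.3f, 99%% CI %.3f to %.3f): %s\n",
                x$kappa, x$se, x$ci99[1], x$ci99[2], x$band))
  }
  invisible(x)
}

#' Interpretation band for a kappa value
#'
#' Bands: 0-0.2 Poor, 0.21-0.4 Fair, 0.41-0.6 Moderate, 0.61-0.8 Good,
#' 0.81-1.0 Very good; boundary values belong to the lower band and
#' negative kappa maps to Poor.
#'
#' @param k kappa value (<= 1).
#' @return One of `"Poor"`, `"Fair"`, `"Moderate"`, `"Good"`,
#'   `"Very good"`.
#' @export
interpret_kappa <- function(k) {
  stopifnot(is.finite(k), k <= 1 + 1e-12)
  if (k <= 0.2) "Poor"
  else if (k <= 0.4) "Fair"
  else if (k <= 0.6) "Moderate"
  else if (k <= 0.8) "Good"
  else "Very good"
}

#' Prepare a standardized 2D presentation image
#'
#' Extracts the sagittal slice through `center`, resamples it to a uniform
#' in-plane resolution (default 1.1 mm/px), crops/pads to `size x size`
#' pixels with the requested center at the central pixel, and windows
#' intensities to `[0, 1]` for display -- the standardization used when
#' presenting images to readers.
#'
#' @param vol An `image_volume`.
#' @param center length-3 world coordinate (mm); must lie inside the
#'   volume.
#' @param size output side length in pixels (default 150).
#' @param resolution output in-plane resolution in mm/px (default 1.1).
#' @return A `size x size` numeric matrix in `[0, 1]` with attributes
#'   `resolution` and `center`.
#' @export
prepare_turing_image <- function(vol, center, size = 150L, resolution = 1.1) {
  stopifnot(inherits(vol, "image_volume"), length(center) == 3)
  n <- dim(vol$data)
  v <- as.vector(world_to_voxel(vol, matrix(center, 1)))
  if (any(v < -0.5) || any(v > n - 0.5))
    stop("center lies outside the volume")
  sp <- vol_spacing(vol)
  U <- sweep(vol$affine[1:3, 1:3], 2, sp, "/")
  half <- size %/% 2  # requested center lands on this (0-based) pixel
  Ainv <- solve(vol$affine)
  # output (1, size, size) grid: index (0, i, j) -> world
  # center + (i - half) * res * U[,2] + (j - half) * res * U[,3]
  M <- matrix(0, 4, 4)
  M[, 2] <- Ainv %*% c(resolution * U[, 2], 0)
  M[, 3] <- Ainv %*% c(resolution * U[, 3], 0)
  M[, 4] <- Ainv %*% c(center, 1) - half * M[, 2] - half * M[, 3]
  res <- cpp_sample_affine(as.double(vol$data), n, M,
                           c(1L, as.integer(size), as.integer(size)),
                           1L, 0)
  img <- matrix(res$values, size, size)
  rng <- range(img)
  img <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  attr(img, "resolution") <- resolution
  attr(img, "center") <- center
  img
}

#' Full reader-study report for one modality
#'
#' Convenience wrapper combining [summarize_rates()] and [fleiss_kappa()].
#'
#' @param table A `rating_table`.
#' @param modality `"t1w"` or `"stir"`.
#' @return List with `rates` (summary) and `kappa` (`kappa_result`).
#' @export
reader_study_report <- function(table, modality) {
  list(rates = summarize_rates(table, modality),
       kappa = fleiss_kappa(table, modality))
}
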