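#' Image-quality metrics between a native and a generated volume
#'
#' Computes, on the `[0, 1]` evaluation scale with data range 1:
#' `L1 = mean|a - b|`, `MSE = mean((a - b)^2)`,
#' `PSNR = 10 * log10(1 / MSE)` dB, and volumetric SSIM ([ssim3d()]).
#' Identical volumes give `MSE = 0`, reported as `PSNR = Inf`.
#'
#' @param real,gen `image_volume`s (or bare arrays) on the same grid with
#'   values in `[0, 1]`; data in `[-1, 1]` is detected and mapped to
#'   `[0, 1]` automatically.
#' @param case optional case label.
#' @param ssim_window SSIM window (default 7).
#' @return One-row `data.frame` with columns `case`, `L1`, `MSE`, `PSNR`,
#'   `SSIM`.
#' @export
pairwise_metrics <- function(real, gen, case = "case", ssim_window = 7L) {
  a <- if (inherits(real, "image_volume")) real$data else real
  b <- if (inherits(gen, "image_volume")) gen$data else gen
  if (!identical(dim(a), dim(b)))
    stop("volumes must share the same grid")
  if (min(a) < 0 || min(b) < 0) {  # [-1, 1] convention -> [0, 1]
    a <- (a + 1) / 2
    b <- (b + 1) / 2
  }
  l1 <- mean(abs(a - b))
  mse <- mean((a - b)^2)
  psnr <- if (mse == 0) Inf else 10 * log10(1 / mse)
  s <- ssim3d(a, b, window = ssim_window, data_range = 1)
  data.frame(case = case, L1 = l1, MSE = mse, PSNR = psnr, SSIM = s,
             stringsAsFactors = FALSE)
}

#' Aggregate per-case metrics into a cohort report
#'
#' Arithmetic means per metric, shaped like the usual ablation tables
#' (L1 and MSE: lower better; PSNR and SSIM: higher better).
#'
#' @param reports `data.frame` of per-case rows from [pairwise_metrics()]
#'   (or a list of such rows, which is rbind-ed).
#' @param method_label label for the method column.
#' @return A `metrics_report`: list with `per_case` and one-row `aggregate`.
#' @export
aggregate_metrics <- function(reports, method_label = "method") {
  if (is.list(reports) && !is.data.frame(reports))
    reports <- do.call(rbind, reports)
  stopifnot(nrow(reports) >= 1)
  agg <- data.frame(method = method_label,
                    L1 = mean(reports$L1), MSE = mean(reports$MSE),
                    PSNR = mean(reports$PSNR), SSIM = mean(reports$SSIM),
                    stringsAsFactors = FALSE)
  structure(list(per_case = reports, aggregate = agg),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> ", nrow(x$per_case), " case(s)\n", sep = "")
  print(x$aggregate, row.names = FALSE)
  invisible(x)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank p-value for paired per-case metric values, exact
#' for n <= 25 (no ties), normal approximation with continuity correction
#' otherwise. Zero differences are discarded (the classical convention);
#' if all differences are zero the test is degenerate and p = 1 is
#' returned with a warning.
#'
#' @param a,b equal-length (>= 5) numeric vectors paired by case.
#' @return The two-sided p-value.
#' @export
paired_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 5)
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0) {
    warning("all paired differences are zero; test degenerate, p = 1")
    return(1)
  }
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  stats::wilcox.test(d, mu = 0, exact = exact, correct = TRUE)$p.value
}
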