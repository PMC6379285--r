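#' Lin's concordance correlation coefficient
#'
#' Quantifies agreement between a reference and a test measurement as
#' `rho_c = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)`, which
#' decomposes into precision (Pearson `rho`) times accuracy (the bias
#' correction factor `C_b = rho_c / rho`, penalising location and scale
#' shifts). Moments are population moments (1/n), the original estimator;
#' a sample-moment (1/(n-1)) variant is available via `moments`.
#'
#' @param x Numeric vector, reference measurements.
#' @param y Numeric vector, test measurements (same length, n >= 3).
#' @param moments `"population"` (default) or `"sample"`.
#' @return Object of class `concordance_result`: list with `rho`, `c_b`,
#'   `rho_c`, `n`.
#' @export
#' @examples
#' lin_ccc(c(50, 100, 200, 400), c(55, 95, 210, 380))
lin_ccc <- function(x, y, moments = c("population", "sample")) {
  moments <- match.arg(moments)
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("`x` and `y` must have equal length")
  if (n < 3L) stop("need at least 3 pairs")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("inputs must be finite")
  mx <- mean(x); my <- mean(y)
  dx <- x - mx; dy <- y - my
  denom_n <- if (moments == "population") n else n - 1L
  sx2 <- sum(dx^2) / denom_n
  sy2 <- sum(dy^2) / denom_n
  sxy <- sum(dx * dy) / denom_n
  if (sx2 == 0 || sy2 == 0) {
    stop("correlation undefined: a measurement vector is constant")
  }
  rho <- sxy / sqrt(sx2 * sy2)
  rho_c <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  structure(
    list(rho = rho, c_b = rho_c / rho, rho_c = rho_c, n = n,
         moments = moments),
    class = "concordance_result"
  )
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    "<concordance> rho = %.4f, C_b = %.4f, rho_c = %.4f (n = %d, %s moments)\n",
    x$rho, x$c_b, x$rho_c, x$n, x$moments
  ))
  invisible(x)
}

#' Reduced major axis regression
#'
#' Symmetric line fit appropriate when both variables carry measurement
#' error: `slope = sign(rho) * s_y / s_x`, `intercept = mean(y) - slope *
#' mean(x)`.
#'
#' @inheritParams lin_ccc
#' @return Object of class `rma_fit`: list with `slope`, `intercept`, `n`.
#' @export
#' @examples
#' rma_fit(1:10, 2 * (1:10)) # slope 2, intercept 0
rma_fit <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("`x` and `y` must have equal length")
  if (n < 3L) stop("need at least 3 pairs")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  if (sx2 == 0) stop("`x` is constant: slope undefined")
  sxy <- mean((x - mx) * (y - my))
  slope <- sign(sxy) * sqrt(sy2 / sx2)
  structure(
    list(slope = slope, intercept = my - slope * mx, n = n),
    class = "rma_fit"
  )
}

#' @export
print.rma_fit <- function(x, ...) {
  cat(sprintf("<rma_fit> y = %.4f x + %.4f (n = %d)\n",
              x$slope, x$intercept, x$n))
  invisible(x)
}

#' Percent-based Bland-Altman analysis
#'
#' Expresses each pair as a percent difference and summarises bias and
#' limits of agreement: `d_i = 100 (y_i - x_i) / x_i` with the reference
#' value as denominator (differences "with respect to" the reference
#' method; the textbook pair-mean denominator is available via
#' `denominator = "mean"`), `bias = mean(d)`, `sd` the sample (n-1)
#' standard deviation, and `LoA = bias +/- 1.96 sd`.
#'
#' @param x Reference measurements (strictly positive).
#' @param y Test measurements (same length, n >= 3).
#' @param denominator `"reference"` (default) or `"mean"`.
#' @return Object of class `bland_altman_result`: list with `bias`, `sd`,
#'   `loa_low`, `loa_high`, `differences`, `n`, `denominator`.
#' @export
#' @examples
#' bland_altman_percent(c(100, 200, 300), c(102, 196, 312))
bland_altman_percent <- function(x, y, denominator = c("reference", "mean")) {
  denominator <- match.arg(denominator)
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("`x` and `y` must have equal length")
  if (n < 3L) stop("need at least 3 pairs")
  if (denominator == "reference") {
    if (any(x <= 0)) stop("reference values must be strictly positive")
    d <- 100 * (y - x) / x
  } else {
    m <- (x + y) / 2
    if (any(m <= 0)) stop("pair means must be strictly positive")
    d <- 100 * (y - x) / m
  }
  bias <- mean(d)
  s <- sd(d)
  structure(
    list(bias = bias, sd = s,
         loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
         differences = d, n = n, denominator = denominator),
    class = "bland_altman_result"
  )
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> bias %.2f%%, LoA [%.2f%%, %.2f%%] (sd %.2f, n = %d, %s denominator)\n",
    x$bias, x$loa_low, x$loa_high, x$sd, x$n, x$denominator
  ))
  invisible(x)
}

# concordance-vs-truth table over a grid of thresholds, from a volume matrix
# (rows = cases, columns = thresholds); shared by calibrate_threshold and
# the study pipeline so the report table is reproducible from its own
# volume columns
concordance_by_c <- function(truth, volumes, c_grid) {
  stopifnot(is.matrix(volumes), nrow(volumes) == length(truth),
            ncol(volumes) == length(c_grid))
  rows <- lapply(seq_along(c_grid), function(j) {
    ok <- is.finite(volumes[, j])
    cc <- lin_ccc(truth[ok], volumes[ok, j])
    tibble::tibble(c = c_grid[j], rho = cc$rho, c_b = cc$c_b,
                   rho_c = cc$rho_c, n = sum(ok))
  })
  do.call(rbind, rows)
}

#' Calibrate the SIT threshold against known volumes
#'
#' Segments every case at every threshold in `c_grid`, measures mask
#' volumes, and computes Lin's concordance against the true volumes per
#' threshold. The selected threshold is the one maximising `rho_c`; ties
#' break towards the smaller (more inclusive) threshold. Segmentation
#' failures are recorded per case (as `NA` volume, with a warning) rather
#' than aborting the sweep.
#'
#' @param cases List of cases, each a list with elements `image`
#'   (a [volumetric_image]), `roi` (a [spherical_roi]) and `volume_true`
#'   (mm^3). At least 3 cases.
#' @param c_grid Thresholds to compare (default `c(0.20, 0.30, 0.40,
#'   0.50)`).
#' @param keep_largest Passed to [segment_sit()].
#' @return List with `table` (tibble: c, rho, c_b, rho_c, n), `selected_c`,
#'   and `volumes` (case-by-threshold matrix, mm^3).
#' @export
calibrate_threshold <- function(cases, c_grid = c(0.20, 0.30, 0.40, 0.50),
                                keep_largest = FALSE) {
  if (length(cases) < 3L) stop("need at least 3 cases")
  c_grid <- sort(as.numeric(c_grid))
  truth <- vapply(cases, `[[`, 0, "volume_true")
  volumes <- matrix(NA_real_, nrow = length(cases), ncol = length(c_grid),
                    dimnames = list(NULL, paste0("c_", c_grid)))
  for (i in seq_along(cases)) {
    for (j in seq_along(c_grid)) {
      volumes[i, j] <- tryCatch({
        m <- segment_sit(cases[[i]]$image, cases[[i]]$roi, c_grid[j],
                         keep_largest = keep_largest)
        mask_volume(m)
      }, error = function(e) {
        warning("case ", i, " failed at c = ", c_grid[j], ": ",
                conditionMessage(e))
        NA_real_
      })
    }
  }
  tab <- concordance_by_c(truth, volumes, c_grid)
  selected <- tab$c[which.max(tab$rho_c)]
  list(table = tab, selected_c = selected, volumes = volumes)
}
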