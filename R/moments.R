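#' Distributional moments of a single band's radiance DNs
#'
#' Summarizes the shape of the at-sensor radiance digital-number (DN)
#' distribution across raster pixels: mean, sample standard deviation
#' (denominator n-1), coefficient of variation sd/mean, skewness
#' \eqn{m_3/m_2^{3/2}} and raw (non-excess) kurtosis \eqn{m_4/m_2^2}, with
#' \eqn{m_k} the central moments (denominator n). Because CV, skewness and
#' kurtosis are scale-free they are unchanged by a multiplicative
#' illumination gain, which is what makes uncalibrated radiance usable.
#'
#' Non-finite and negative pixels are masked before computation. For an
#' all-constant band sd and cv are 0 while skewness and kurtosis are
#' undefined (`NA`); a zero-mean band has undefined cv. Undefined moments
#' propagate as `NA` and are excluded from cross-band averaging.
#'
#' @param pixels Numeric vector, matrix or array of DN values for one band.
#' @return Named list: `mean_dn`, `sd`, `cv`, `skewness`, `kurtosis`,
#'   `n_pixels` (used), `n_masked` (dropped).
#' @export
band_moments <- function(pixels) {
  x <- as.numeric(pixels)
  keep <- is.finite(x) & x >= 0
  n_masked <- length(x) - sum(keep)
  x <- x[keep]
  n <- length(x)
  if (n < 2L) stop("need at least 2 finite nonnegative pixels, got ", n)
  mu <- mean(x)
  s <- stats::sd(x)
  cv <- if (s == 0) {
    if (mu == 0) NA_real_ else 0
  } else if (mu == 0) NA_real_ else s / mu
  d <- x - mu
  m2 <- mean(d^2)
  if (m2 == 0) {
    skew <- NA_real_
    kurt <- NA_real_
  } else {
    skew <- mean(d^3) / m2^1.5
    kurt <- mean(d^4) / m2^2
  }
  list(mean_dn = mu, sd = s, cv = cv, skewness = skew, kurtosis = kurt,
       n_pixels = n, n_masked = n_masked)
}

#' Crop all bands of a multispectral image to a rectangular ROI
#'
#' ROIs follow a 0-based, half-open convention
#' `[row0, row1) x [col0, col1)` in pixel coordinates, so `row1 - row0` is
#' the cropped height. Metadata are preserved.
#'
#' @param image A `multispectral_image` (see [multispectral_image()]).
#' @param roi Numeric vector `c(row0, row1, col0, col1)`.
#' @return Cropped `multispectral_image`.
#' @export
crop_to_roi <- function(image, roi) {
  stopifnot(inherits(image, "multispectral_image"))
  if (length(roi) != 4L || anyNA(roi)) stop("roi must be c(row0, row1, col0, col1)")
  roi <- as.integer(roi)
  nr <- nrow(image$bands[[1]]); nc <- ncol(image$bands[[1]])
  if (roi[1] < 0 || roi[3] < 0 || roi[2] > nr || roi[4] > nc) {
    stop("roi outside image bounds (", nr, " x ", nc, ")")
  }
  if (roi[2] <= roi[1] || roi[4] <= roi[3]) stop("zero-area roi")
  image$bands <- lapply(image$bands, function(b) {
    b[(roi[1] + 1L):roi[2], (roi[3] + 1L):roi[4], drop = FALSE]
  })
  image$roi <- roi
  image
}

#' Construct a five-band multispectral image
#'
#' @param bands Named list of 5 numeric matrices (names [SPECTRAL_BANDS]),
#'   identical dimensions, nonnegative DN values.
#' @param quadrat_id,sampling_day,height_m Acquisition metadata; recording
#'   height in meters must be positive.
#' @return Object of class `multispectral_image`.
#' @export
multispectral_image <- function(bands, quadrat_id, sampling_day, height_m) {
  if (!identical(sort(names(bands)), sort(SPECTRAL_BANDS))) {
    stop("bands must be named exactly: ", paste(SPECTRAL_BANDS, collapse = ", "))
  }
  bands <- bands[SPECTRAL_BANDS]
  dims <- vapply(bands, dim, integer(2))
  if (any(dims != dims[, 1])) stop("all bands must have identical dimensions")
  if (!is.finite(height_m) || height_m <= 0) stop("height_m must be positive")
  structure(
    list(bands = bands, quadrat_id = quadrat_id,
         sampling_day = sampling_day, height_m = height_m, roi = NULL),
    class = "multispectral_image"
  )
}

#' @export
print.multispectral_image <- function(x, ...) {
  d <- dim(x$bands[[1]])
  cat(sprintf("multispectral_image: quadrat %s, day %s, height %.1f m, %d x %d px, 5 bands\n",
              x$quadrat_id, x$sampling_day, x$height_m, d[1], d[2]))
  invisible(x)
}

#' Per-band and band-averaged moments for one observation
#'
#' Computes [band_moments()] for each of the 5 bands, then averages each
#' moment arithmetically across bands. A band whose moment is undefined
#' (constant band) is excluded from that moment's average rather than
#' zero-filled, and the result is flagged.
#'
#' @param image A `multispectral_image`.
#' @return Object of class `spectral_moments`: list with `quadrat_id`,
#'   `sampling_day`, `height_m`, `per_band` (data frame, one row per band)
#'   and `averaged` (named list `cv`, `sd`, `skewness`, `kurtosis`,
#'   plus `n_undefined` flags).
#' @export
observation_moments <- function(image) {
  stopifnot(inherits(image, "multispectral_image"))
  pb <- lapply(image$bands, band_moments)
  per_band <- data.frame(
    band = SPECTRAL_BANDS,
    mean_dn = vapply(pb, `[[`, 0, "mean_dn"),
    sd = vapply(pb, `[[`, 0, "sd"),
    cv = vapply(pb, `[[`, 0, "cv"),
    skewness = vapply(pb, `[[`, 0, "skewness"),
    kurtosis = vapply(pb, `[[`, 0, "kurtosis"),
    n_pixels = vapply(pb, `[[`, 0, "n_pixels"),
    n_masked = vapply(pb, `[[`, 0, "n_masked"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  avg_of <- function(m) mean(per_band[[m]], na.rm = TRUE)
  averaged <- list(
    cv = avg_of("cv"), sd = avg_of("sd"),
    skewness = avg_of("skewness"), kurtosis = avg_of("kurtosis"),
    n_undefined = sum(is.na(per_band$cv)) + sum(is.na(per_band$skewness)) +
      sum(is.na(per_band$kurtosis))
  )
  structure(
    list(quadrat_id = image$quadrat_id, sampling_day = image$sampling_day,
         height_m = image$height_m, per_band = per_band, averaged = averaged),
    class = "spectral_moments"
  )
}

#' @export
print.spectral_moments <- function(x, ...) {
  cat(sprintf("spectral_moments: quadrat %s, day %s, height %.1f m\n",
              x$quadrat_id, x$sampling_day, x$height_m))
  cat(sprintf("  averaged cv %.4f, sd %.2f, skewness %.3f, kurtosis %.3f\n",
              x$averaged$cv, x$averaged$sd, x$averaged$skewness, x$averaged$kurtosis))
  invisible(x)
}

#' Drop observations recorded above a height cutoff
#'
#' Images recorded above `max_height_m` (default 8 m) are discarded;
#' retention counts are reported via `message()` and attached as the
#' `"filter_counts"` attribute. Records with missing height are rejected
#' with a warning.
#'
#' @param records Data frame with a `height_m` column.
#' @param max_height_m Inclusive height cutoff in meters.
#' @return Filtered data frame.
#' @export
filter_observations <- function(records, max_height_m = 8) {
  if (!"height_m" %in% names(records)) stop("records must carry height_m")
  n_in <- nrow(records)
  missing_h <- is.na(records$height_m)
  if (any(missing_h)) {
    warning(sum(missing_h), " record(s) with missing height_m rejected")
  }
  keep <- !missing_h & records$height_m <= max_height_m
  out <- records[keep, , drop = FALSE]
  counts <- c(rows_in = n_in, rows_kept = nrow(out),
              rows_filtered = sum(!keep & !missing_h),
              rows_missing_height = sum(missing_h))
  message(sprintf("height filter (<= %g m): kept %d of %d observations",
                  max_height_m, counts["rows_kept"], n_in))
  attr(out, "filter_counts") <- counts
  out
}

#' Block-average a matrix into k x k blocks
#'
#' Aggregates pixels into non-overlapping k x k blocks by their mean,
#' emulating the coarser ground footprint of higher recording heights.
#' Trailing rows/columns that do not fill a block are trimmed. By the
#' within/between variance decomposition the variance of block means never
#' exceeds the pixel variance, so block-averaging cannot increase the
#' coefficient of variation (the smoothing effect of flying height).
#'
#' @param m Numeric matrix.
#' @param k Integer block factor >= 1.
#' @return Matrix of block means, dimensions `floor(dim(m)/k)`.
#' @export
block_average <- function(m, k) {
  k <- as.integer(k)
  stopifnot(is.matrix(m), k >= 1L)
  if (k == 1L) return(m)
  nr <- (nrow(m) %/% k) * k
  nc <- (ncol(m) %/% k) * k
  if (nr < k || nc < k) stop("matrix smaller than one ", k, "x", k, " block")
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  rowsq <- matrix(colMeans(matrix(m, nrow = k)), nrow = nr %/% k)
  t(matrix(colMeans(matrix(t(rowsq), nrow = k)), nrow = nc %/% k))
}
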