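# TIFF I/O. DNs are integers in the 16-bit sensor range [0, 65535]; the tiff
# package stores samples in [0,1], so files hold DN/65535 and readers rescale.

DN_MAX <- 65535

#' Write one band as a 16-bit grayscale TIFF
#'
#' @param m Numeric matrix of DN values in `[0, 65535]`; rounded to integers.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_band_tiff <- function(m, path) {
  stopifnot(is.matrix(m))
  if (any(!is.finite(m)) || any(m < 0) || any(m > DN_MAX)) {
    stop("DN values must be finite and within [0, ", DN_MAX, "]")
  }
  tiff::writeTIFF(round(m) / DN_MAX, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read one band from a grayscale TIFF as integer DNs
#'
#' @param path TIFF file path (single-band grayscale).
#' @return Numeric matrix of DN values.
#' @export
read_band_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) {
    if (dim(m)[3] != 1L) stop(path, " is not single-band (", dim(m)[3], " samples)")
    m <- m[, , 1]
  }
  round(m * DN_MAX)
}

.manifest_band_cols <- paste0("path_", tolower(SPECTRAL_BANDS))
.roi_cols <- c("roi_row0", "roi_row1", "roi_col0", "roi_col1")

#' Read an image manifest CSV
#'
#' One row per observation. Required columns: `quadrat_id`, `sampling_day`,
#' `height_m`, plus either the five per-band path columns
#' (`path_b450`, `path_g560`, `path_r650`, `path_re730`, `path_nir840`) or a
#' single multiband `path` column. Optional ROI columns
#' `roi_row0, roi_row1, roi_col0, roi_col1` (0-based half-open).
#'
#' @param path Manifest CSV path.
#' @return Data frame with a `"manifest_dir"` attribute (relative image
#'   paths resolve against the manifest's directory).
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("quadrat_id", "sampling_day", "height_m")
  if (!all(need %in% names(df))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(.manifest_band_cols %in% names(df)) && !"path" %in% names(df)) {
    stop("manifest needs per-band path columns (",
         paste(.manifest_band_cols, collapse = ", "), ") or a 'path' column")
  }
  attr(df, "manifest_dir") <- dirname(normalizePath(path))
  df
}

.resolve_path <- function(p, dir) {
  ifelse(file.exists(p), p, file.path(dir, p))
}

#' Load one manifest row as a multispectral image
#'
#' @param row One-row data frame from [read_manifest()].
#' @param manifest_dir Directory against which relative paths resolve.
#' @return A `multispectral_image`, cropped to the row's ROI if present.
#' @export
load_observation <- function(row, manifest_dir = ".") {
  if (all(.manifest_band_cols %in% names(row)) &&
      !anyNA(unlist(row[.manifest_band_cols]))) {
    paths <- .resolve_path(unlist(row[.manifest_band_cols]), manifest_dir)
    bands <- lapply(paths, read_band_tiff)
    names(bands) <- SPECTRAL_BANDS
  } else if ("path" %in% names(row) && !is.na(row$path)) {
    a <- tiff::readTIFF(.resolve_path(row$path, manifest_dir))
    if (length(dim(a)) != 3L || dim(a)[3] != 5L) {
      stop("multiband file must have 5 samples per pixel; band order B,G,R,RE,NIR")
    }
    bands <- lapply(seq_len(5), function(j) round(a[, , j] * DN_MAX))
    names(bands) <- SPECTRAL_BANDS
  } else {
    stop("manifest row has neither complete per-band paths nor a 'path'")
  }
  img <- multispectral_image(bands, quadrat_id = row$quadrat_id,
                             sampling_day = row$sampling_day,
                             height_m = row$height_m)
  if (all(.roi_cols %in% names(row)) && !anyNA(unlist(row[.roi_cols]))) {
    img <- crop_to_roi(img, unlist(row[.roi_cols]))
  }
  img
}

#' Compute per-observation spectral moments for a whole manifest
#'
#' Applies the recording-height filter, loads each observation, computes
#' per-band and band-averaged moments, and returns a tidy table (one row per
#' quadrat x day x height). Per-band columns are suffixed with the band name.
#'
#' @param manifest Data frame from [read_manifest()] or path to manifest CSV.
#' @param max_height_m Height filter cutoff in meters (inclusive).
#' @return Data frame of moments; `"filter_counts"` attribute carries the
#'   height-filter bookkeeping.
#' @export
compute_spectral_moments <- function(manifest, max_height_m = 8) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  dir <- attr(manifest, "manifest_dir")
  if (is.null(dir)) dir <- "."
  kept <- filter_observations(manifest, max_height_m)
  counts <- attr(kept, "filter_counts")
  if (nrow(kept) == 0L) {
    out <- data.frame()
    attr(out, "filter_counts") <- counts
    return(out)
  }
  rows <- lapply(seq_len(nrow(kept)), function(i) {
    sm <- observation_moments(load_observation(kept[i, , drop = FALSE], dir))
    base <- data.frame(
      quadrat_id = sm$quadrat_id, sampling_day = sm$sampling_day,
      height_m = sm$height_m,
      cv_avg = sm$averaged$cv, sd_avg = sm$averaged$sd,
      skewness_avg = sm$averaged$skewness, kurtosis_avg = sm$averaged$kurtosis,
      n_undefined = sm$averaged$n_undefined,
      stringsAsFactors = FALSE
    )
    for (m in c("mean_dn", "sd", "cv", "skewness", "kurtosis")) {
      vals <- sm$per_band[[m]]
      names(vals) <- paste0(m, "_", sm$per_band$band)
      base[names(vals)] <- as.list(vals)
    }
    base
  })
  out <- do.call(rbind, rows)
  attr(out, "filter_counts") <- counts
  out
}

#' Reshape a moments table to band-level long format
#'
#' One row per observation x band, with columns `band`, `mean_dn`, `sd`,
#' `cv`, `skewness`, `kurtosis`, for band-level models where moments are not
#' averaged across bands.
#'
#' @param moments_df Output of [compute_spectral_moments()].
#' @return Long data frame with a `band` factor (reference level blue).
#' @export
moments_to_band_long <- function(moments_df) {
  meta <- c("quadrat_id", "sampling_day", "height_m")
  stopifnot(all(meta %in% names(moments_df)))
  rows <- lapply(SPECTRAL_BANDS, function(b) {
    df <- moments_df[meta]
    df$band <- b
    for (m in c("mean_dn", "sd", "cv", "skewness", "kurtosis")) {
      df[[m]] <- moments_df[[paste0(m, "_", b)]]
    }
    df
  })
  out <- do.call(rbind, rows)
  out$band <- factor(out$band, levels = SPECTRAL_BANDS)
  rownames(out) <- NULL
  out
}
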