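# Synthetic multispectral quadrat scenes. The generator emulates the
# statistical structure the analysis assumes: species with distinct mean
# radiance signatures per band, within-species texture, a per-image
# multiplicative solar gain (residual after the UAV's sunlight-sensor
# exposure compensation), additive sensor noise, and height-dependent pixel
# footprint via exact block averaging.

# Typical mid-exposure vegetation DN profile for a 16-bit sensor: chlorophyll
# absorption lowers blue/red, green peak in between, strong red-edge/NIR.
.BASE_SIGNATURE <- c(B450 = 9000, G560 = 16000, R650 = 11000,
                     RE730 = 22000, NIR840 = 30000)

#' Build a pool of species spectral signatures
#'
#' Each species gets a 5-band mean-DN signature obtained by perturbing a
#' common vegetation profile with independent log-normal factors
#' `exp(band_separation * z)`, `z ~ N(0,1)`, per species and band: larger
#' `band_separation` spreads signatures further apart (the premise that
#' species differ in reflectance across the spectrum), zero makes all
#' species spectrally identical.
#'
#' @param n_species Number of species in the pool (>= 1).
#' @param band_separation Nonnegative log-scale spread of signatures.
#' @param texture_sd Within-species pixel DN standard deviation (>= 0).
#' @param seed Optional integer; `NULL` uses the current RNG stream.
#' @return Object of class `species_pool`: list with `n_species`,
#'   `signatures` (n_species x 5 matrix, rows `sp01`...), `texture_sd`,
#'   `band_separation`.
#' @export
build_species_pool <- function(n_species, band_separation = 0.25,
                               texture_sd = 1200, seed = NULL) {
  if (n_species < 1) stop("n_species must be >= 1")
  if (band_separation < 0 || texture_sd < 0) {
    stop("band_separation and texture_sd must be nonnegative")
  }
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(stats::rnorm(n_species * 5), nrow = n_species)
  sig <- sweep(exp(band_separation * z), 2, .BASE_SIGNATURE, `*`)
  colnames(sig) <- SPECTRAL_BANDS
  rownames(sig) <- sprintf("sp%02d", seq_len(n_species))
  structure(list(n_species = as.integer(n_species), signatures = sig,
                 texture_sd = texture_sd, band_separation = band_separation),
            class = "species_pool")
}

#' Generate a synthetic quadrat community scene
#'
#' Draws species abundances from a symmetric Dirichlet whose concentration
#' grows with `evenness` (`alpha = 10 * evenness / (1 - evenness + 1e-6)`,
#' so `evenness -> 1` approaches a uniform community), then places species
#' spatially by abundance-weighted seed points and nearest-seed tessellation
#' at a characteristic patch scale. True covers are recomputed from the
#' realized label map.
#'
#' @param pool A `species_pool`.
#' @param richness Number of species to draw from the pool.
#' @param evenness Community evenness in (0, 1].
#' @param patch_scale_cm Characteristic patch diameter in cm (quadrat is
#'   1 x 1 m).
#' @param base_px Scene side length in pixels at base resolution.
#' @param seed Optional integer; `NULL` uses the current RNG stream.
#' @return Object of class `synthetic_scene`: `label_map` (base_px^2 integer
#'   matrix of pool species indices), `true_covers` (named proportions over
#'   realized species), `species` (pool indices used), `base_px`.
#' @export
generate_community <- function(pool, richness, evenness = 0.45,
                               patch_scale_cm = 5, base_px = 1000,
                               seed = NULL) {
  stopifnot(inherits(pool, "species_pool"))
  if (richness < 1 || richness > pool$n_species) {
    stop("richness must be in [1, pool$n_species]")
  }
  if (evenness <= 0 || evenness > 1) stop("evenness must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  species <- sort(sample.int(pool$n_species, richness))
  alpha <- 10 * evenness / (1 - evenness + 1e-6)
  g <- stats::rgamma(richness, shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, richness)
  abund <- g / sum(g)

  n_seeds <- max(richness, round((100 / patch_scale_cm)^2))
  # every drawn species anchors at least one patch; the rest follow abundance
  seed_sp <- c(seq_len(richness),
               sample.int(richness, n_seeds - richness, replace = TRUE,
                          prob = abund))
  pts <- cbind(stats::runif(n_seeds), stats::runif(n_seeds))
  gx <- (seq_len(base_px) - 0.5) / base_px
  px <- cbind(rep(gx, times = base_px), rep(gx, each = base_px))
  lab <- class::knn1(pts, px, factor(seed_sp, levels = seq_len(richness)))
  label_map <- matrix(species[as.integer(lab)], nrow = base_px)

  tab <- tabulate(match(label_map, species), nbins = richness)
  keep <- tab > 0
  true_covers <- stats::setNames(tab[keep] / sum(tab),
                                 rownames(pool$signatures)[species[keep]])
  structure(list(label_map = label_map, true_covers = true_covers,
                 species = species, base_px = as.integer(base_px)),
            class = "synthetic_scene")
}

#' Acquisition model for synthetic imaging
#'
#' @param gain_sdlog Log-sd of the per-image multiplicative solar gain
#'   (log-normal with median 1; one draw per image, shared across bands).
#' @param sensor_noise_sd Additive DN sensor noise sd.
#' @param base_pixel_cm Ground footprint of a base-resolution pixel in cm.
#' @param height_to_pixel Function mapping recording height (m) to pixel
#'   size (cm); default `0.05 * height` (2 m -> 0.1 cm, 8 m -> 0.4 cm).
#' @return Object of class `acquisition_model`.
#' @export
acquisition_model <- function(gain_sdlog = 0.15, sensor_noise_sd = 150,
                              base_pixel_cm = 0.1,
                              height_to_pixel = function(h) 0.05 * h) {
  stopifnot(gain_sdlog >= 0, sensor_noise_sd >= 0, base_pixel_cm > 0)
  structure(list(gain_sdlog = gain_sdlog, sensor_noise_sd = sensor_noise_sd,
                 base_pixel_cm = base_pixel_cm,
                 height_to_pixel = height_to_pixel),
            class = "acquisition_model")
}

#' Render a 5-band radiance image of a scene at a recording height
#'
#' Per-pixel DN in band b is
#' `gain * (signature[species, b] + texture noise) + sensor noise`,
#' truncated to the sensor range, then block-averaged so the pixel footprint
#' matches `height_to_pixel(height_m)`. The gain is drawn once per image and
#' shared across bands, mimicking residual solar-illumination differences
#' between images.
#'
#' @param scene A `synthetic_scene`.
#' @param pool The `species_pool` the scene was generated from.
#' @param acquisition An `acquisition_model`.
#' @param height_m Recording height in meters; `height_to_pixel(height_m)`
#'   must be an integer multiple of `base_pixel_cm`.
#' @param quadrat_id,sampling_day Metadata stamped on the image.
#' @param gain Optional fixed gain (skips the random draw).
#' @return A `multispectral_image`; the drawn gain is attached as
#'   attribute `"gain"`.
#' @export
render_image <- function(scene, pool, acquisition, height_m,
                         quadrat_id = "Q01", sampling_day = 1, gain = NULL) {
  stopifnot(inherits(scene, "synthetic_scene"),
            inherits(pool, "species_pool"),
            inherits(acquisition, "acquisition_model"))
  px_cm <- acquisition$height_to_pixel(height_m)
  k <- px_cm / acquisition$base_pixel_cm
  if (!is.finite(k) || k < 1 - 1e-9 || abs(k - round(k)) > 1e-6) {
    stop("height ", height_m, " m maps to pixel size ", px_cm,
         " cm, not an integer multiple of the base pixel")
  }
  k <- as.integer(round(k))
  if (is.null(gain)) gain <- stats::rlnorm(1, 0, acquisition$gain_sdlog)
  lab <- as.vector(scene$label_map)
  npix <- length(lab)
  bands <- lapply(SPECTRAL_BANDS, function(b) {
    dn <- gain * (pool$signatures[lab, b] +
                    stats::rnorm(npix, 0, pool$texture_sd)) +
      stats::rnorm(npix, 0, acquisition$sensor_noise_sd)
    m <- matrix(pmin(pmax(dn, 0), DN_MAX), nrow = scene$base_px)
    block_average(m, k)
  })
  names(bands) <- SPECTRAL_BANDS
  img <- multispectral_image(bands, quadrat_id = quadrat_id,
                             sampling_day = sampling_day, height_m = height_m)
  attr(img, "gain") <- gain
  img
}

.allocate_treatments <- function(n) {
  # study allocation: 25 ambient, 5 drought, 5 irrigated, 2 procedural controls
  props <- c(ambient = 25, drought = 5, irrigated = 5, procedural_control = 2) / 37
  counts <- floor(props * n)
  counts["ambient"] <- counts["ambient"] + (n - sum(counts))
  rep(names(counts), counts)
}

#' Simulate a complete imaging + survey study and write its files
#'
#' Generates `n_quadrats` synthetic communities, images each on every
#' sampling day at every recording height, and writes exactly the file
#' layout the analysis pipeline consumes: per-band TIFFs with a manifest
#' CSV, long-format cover and biomass survey CSVs, a quadrat treatment
#' table, and ground-truth tables (true per-quadrat indices; per-image
#' gains). A single RNG stream is seeded once per call, so equal seeds give
#' byte-identical outputs.
#'
#' Defaults mirror the field design: 37 quadrats, recording heights 2/4/6/8
#' m, 7 sampling days, 16-33 species per quadrat, treatment allocation
#' 25/5/5/2 (ambient/drought/irrigated/procedural control).
#'
#' @param out_dir Output directory (created if needed).
#' @param n_quadrats Number of quadrats.
#' @param heights Recording heights in meters.
#' @param n_days Number of sampling days.
#' @param richness_range Inclusive range of per-quadrat species richness.
#' @param n_species_pool Species pool size (>= max richness).
#' @param evenness,patch_scale_cm,base_px Passed to [generate_community()].
#' @param band_separation,texture_sd Passed to [build_species_pool()].
#' @param acquisition An [acquisition_model()].
#' @param shelter_attenuation Multiplier (< 1 dampens) on within-quadrat
#'   texture for drought and procedural-control quadrats, emulating rain
#'   shelter structural interference; default 1 (no artifact).
#' @param seed Integer seed for the single global RNG stream.
#' @return Invisibly, a list of written file paths plus the truth tables.
#' @export
simulate_study <- function(out_dir,
                           n_quadrats = 37,
                           heights = c(2, 4, 6, 8),
                           n_days = 7,
                           richness_range = c(16, 33),
                           n_species_pool = 40,
                           evenness = 0.45,
                           patch_scale_cm = 5,
                           base_px = 1000,
                           band_separation = 0.25,
                           texture_sd = 1200,
                           acquisition = acquisition_model(),
                           shelter_attenuation = 1,
                           seed = 1) {
  if (n_quadrats < 1 || n_days < 1 || length(heights) < 1) {
    stop("inconsistent design: need >= 1 quadrat, day, and height")
  }
  if (max(richness_range) > n_species_pool) {
    stop("richness_range exceeds the species pool size")
  }
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  pool <- build_species_pool(n_species_pool, band_separation, texture_sd)
  treatments <- .allocate_treatments(n_quadrats)
  qids <- sprintf("Q%02d", seq_len(n_quadrats))

  covers <- list(); biomass <- list(); truth <- list()
  manifest <- list(); gains <- list()
  fg_weights <- c(graminoid = 0.591, forb = 0.25, legume = 0.10,
                  woody = 0.03, bryophyte = 0.029)

  for (qi in seq_len(n_quadrats)) {
    richness <- if (richness_range[1] == richness_range[2]) richness_range[1] else
      sample(seq(richness_range[1], richness_range[2]), 1)
    scene <- generate_community(pool, richness, evenness = evenness,
                                patch_scale_cm = patch_scale_cm,
                                base_px = base_px)
    p <- scene$true_covers
    # overlapping canopies: totals exceed 100% by a random margin
    total_pct <- stats::runif(1, 95, 135)
    covers[[qi]] <- data.frame(
      quadrat_id = qids[qi], species = names(p),
      percent_cover = pmax(round(p * total_pct, 1), 0.1),
      stringsAsFactors = FALSE
    )
    area <- if (treatments[qi] == "ambient" && qi <= ceiling(n_quadrats * 0.54))
      0.2 else 0.25
    total_gm2 <- min(max(stats::rlnorm(1, log(360), 0.45), 150), 950)
    shares_g <- stats::rgamma(5, shape = 30 * fg_weights, rate = 1)
    shares <- shares_g / sum(shares_g)
    biomass[[qi]] <- data.frame(
      quadrat_id = qids[qi], functional_group = names(fg_weights),
      mass_g = round(total_gm2 * shares * area, 1), strip_area_m2 = area,
      stringsAsFactors = FALSE
    )
    truth[[qi]] <- data.frame(
      quadrat_id = qids[qi], treatment = treatments[qi],
      richness_true = length(p),
      shannon_true = shannon_index(p),
      simpson_true = simpson_index(p),
      biomass_true_g_m2 = total_gm2,
      stringsAsFactors = FALSE
    )
    qpool <- pool
    if (treatments[qi] %in% c("drought", "procedural_control")) {
      qpool$texture_sd <- pool$texture_sd * shelter_attenuation
    }
    for (day in seq_len(n_days)) {
      for (h in heights) {
        img <- render_image(scene, qpool, acquisition, h,
                            quadrat_id = qids[qi], sampling_day = day)
        stem <- sprintf("%s_d%02d_h%03.0f", qids[qi], day, h * 10)
        paths <- stats::setNames(
          file.path("images", paste0(stem, "_", tolower(SPECTRAL_BANDS), ".tif")),
          .manifest_band_cols
        )
        for (b in seq_along(SPECTRAL_BANDS)) {
          write_band_tiff(img$bands[[b]], file.path(out_dir, paths[b]))
        }
        manifest[[length(manifest) + 1L]] <- cbind(
          data.frame(quadrat_id = qids[qi], sampling_day = day, height_m = h,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(paths), stringsAsFactors = FALSE)
        )
        gains[[length(gains) + 1L]] <- data.frame(
          quadrat_id = qids[qi], sampling_day = day, height_m = h,
          gain = attr(img, "gain"), stringsAsFactors = FALSE
        )
      }
    }
  }

  files <- list(
    covers = file.path(out_dir, "covers.csv"),
    biomass = file.path(out_dir, "biomass.csv"),
    quadrats = file.path(out_dir, "quadrats.csv"),
    manifest = file.path(out_dir, "manifest.csv"),
    truth = file.path(out_dir, "truth_quadrats.csv"),
    gains = file.path(out_dir, "image_gains.csv")
  )
  wr <- function(x, f) utils::write.csv(x, f, row.names = FALSE, quote = FALSE)
  truth_df <- do.call(rbind, truth)
  wr(do.call(rbind, covers), files$covers)
  wr(do.call(rbind, biomass), files$biomass)
  wr(data.frame(quadrat_id = qids, treatment = treatments), files$quadrats)
  wr(do.call(rbind, manifest), files$manifest)
  wr(truth_df, files$truth)
  wr(do.call(rbind, gains), files$gains)
  invisible(c(files, list(truth_table = truth_df, pool = pool)))
}
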