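#' Convert percent covers to relative proportions
#'
#' Botanical percent-cover estimates of overlapping canopies routinely sum to
#' more than 100% per quadrat; diversity indices are therefore computed from
#' relative proportions \eqn{p_i = c_i / \sum_j c_j} of the quadrat's own
#' total cover, never from covers capped at 100.
#'
#' @param covers Named numeric vector of percent covers (one entry per
#'   species), all `>= 0`, at least one `> 0`.
#' @return Named numeric vector of proportions summing to 1. Species with
#'   zero cover are dropped (the \eqn{0 \log 0 = 0} limit convention).
#' @examples
#' cover_to_proportions(c(A = 80, B = 40, C = 40))
#' @export
cover_to_proportions <- function(covers) {
  if (length(covers) == 0L) stop("empty cover table: invalid survey")
  covers <- unlist(covers)
  if (anyNA(covers)) stop("NA percent cover: invalid survey")
  if (any(covers < 0)) stop("negative percent cover: invalid survey")
  total <- sum(covers)
  if (total <= 0) stop("all-zero cover table: invalid survey")
  p <- covers[covers > 0] / total
  p
}

.check_proportions <- function(p, tol = 1e-8) {
  if (length(p) == 0L || anyNA(p)) stop("proportions must be non-missing and nonempty")
  if (any(p <= 0) || any(p > 1)) stop("proportions must lie in (0, 1]")
  if (abs(sum(p) - 1) > tol) {
    stop("proportions do not sum to 1; normalize covers with cover_to_proportions() first")
  }
  invisible(p)
}

#' Shannon-Weiner diversity index
#'
#' \eqn{H = -\sum_i p_i \ln p_i} in nats over species proportions. Zero for a
#' monoculture and at most \eqn{\ln(\mathrm{richness})}, attained at the
#' uniform community.
#'
#' @param p Numeric vector of species proportions in (0, 1] summing to 1.
#' @return Shannon index in nats.
#' @examples
#' shannon_index(rep(0.25, 4)) # log(4)
#' @export
shannon_index <- function(p) {
  .check_proportions(p)
  -sum(p * log(p))
}

#' Simpson's index
#'
#' The printed dominance form \eqn{D = \sum_i p_i^2} (probability two random
#' draws are conspecific; larger means *less* diverse). The Gini-Simpson
#' complement \eqn{1 - D} is available behind an explicit `variant` switch,
#' never silently.
#'
#' @inheritParams shannon_index
#' @param variant `"dominance"` (default, \eqn{\sum p^2}) or `"gini"`
#'   (\eqn{1 - \sum p^2}).
#' @return Simpson index; the dominance form lies in `[1/richness, 1]`.
#' @examples
#' simpson_index(c(0.5, 0.3, 0.2)) # 0.38
#' @export
simpson_index <- function(p, variant = c("dominance", "gini")) {
  variant <- match.arg(variant)
  .check_proportions(p)
  d <- sum(p^2)
  if (variant == "gini") 1 - d else d
}

#' Species richness of a survey
#'
#' @param covers Named numeric vector of percent covers.
#' @return Count of species with cover strictly greater than zero.
#' @export
species_richness <- function(covers) {
  if (length(covers) == 0L) stop("empty cover table: invalid survey")
  covers <- unlist(covers)
  if (anyNA(covers) || any(covers < 0)) stop("invalid survey: covers must be >= 0")
  n <- sum(covers > 0)
  if (n < 1L) stop("all-zero cover table: invalid survey")
  as.integer(n)
}

#' Scale clip-strip biomass to areal density
#'
#' Clip strips (1 x 0.2 m or 1 x 0.25 m depending on the research network)
#' are scaled to g/m^2 for analysis.
#'
#' @param clip_mass_g Dry mass in grams (scalar or vector), `>= 0`.
#' @param clip_area_m2 Strip area in m^2, `> 0`.
#' @return Biomass density in g/m^2.
#' @export
biomass_density <- function(clip_mass_g, clip_area_m2) {
  if (any(!is.finite(clip_area_m2)) || any(clip_area_m2 <= 0)) {
    stop("clip_area_m2 must be positive")
  }
  if (any(!is.finite(clip_mass_g)) || any(clip_mass_g < 0)) {
    stop("clip_mass_g must be nonnegative")
  }
  clip_mass_g / clip_area_m2
}

#' Per-quadrat biodiversity indices from survey tables
#'
#' Takes a long-format cover table and (optionally) a clip-strip biomass
#' table, and returns one row per quadrat with richness, Shannon H, Simpson D
#' and biomass in g/m^2. Bryophytes appear only in the biomass table (they
#' are not scored in species-level percent cover) and so never enter the
#' cover-based indices.
#'
#' @param covers_df Data frame with columns `quadrat_id`, `species`,
#'   `percent_cover`.
#' @param biomass_df Optional data frame with columns `quadrat_id`,
#'   `functional_group`, `mass_g`, `strip_area_m2` (one strip per quadrat;
#'   masses are summed over functional groups).
#' @param simpson_variant Passed to [simpson_index()].
#' @return Data frame: `quadrat_id`, `richness`, `shannon`, `simpson`,
#'   and `biomass_g_m2` when `biomass_df` is given.
#' @export
biodiversity_indices <- function(covers_df, biomass_df = NULL,
                                 simpson_variant = "dominance") {
  need <- c("quadrat_id", "species", "percent_cover")
  if (!all(need %in% names(covers_df))) {
    stop("covers_df must have columns: ", paste(need, collapse = ", "))
  }
  if (anyNA(covers_df$percent_cover)) stop("missing percent_cover values")
  ids <- unique(covers_df$quadrat_id)
  out <- do.call(rbind, lapply(ids, function(q) {
    sub <- covers_df[covers_df$quadrat_id == q, ]
    if (anyDuplicated(sub$species)) {
      stop("duplicate species rows for quadrat ", q)
    }
    cov <- stats::setNames(sub$percent_cover, sub$species)
    p <- cover_to_proportions(cov)
    data.frame(
      quadrat_id = q,
      richness = species_richness(cov),
      shannon = shannon_index(p),
      simpson = simpson_index(p, variant = simpson_variant),
      stringsAsFactors = FALSE
    )
  }))
  if (!is.null(biomass_df)) {
    needb <- c("quadrat_id", "functional_group", "mass_g", "strip_area_m2")
    if (!all(needb %in% names(biomass_df))) {
      stop("biomass_df must have columns: ", paste(needb, collapse = ", "))
    }
    bm <- do.call(rbind, lapply(split(biomass_df, biomass_df$quadrat_id), function(sub) {
      area <- unique(sub$strip_area_m2)
      if (length(area) != 1L) stop("inconsistent strip_area_m2 within quadrat")
      data.frame(
        quadrat_id = sub$quadrat_id[1],
        biomass_g_m2 = biomass_density(sum(sub$mass_g), area),
        stringsAsFactors = FALSE
      )
    }))
    out <- merge(out, bm, by = "quadrat_id", all.x = TRUE)
  }
  rownames(out) <- NULL
  out[order(out$quadrat_id), , drop = FALSE]
}

#' Read a long-format percent-cover survey CSV
#'
#' @param path CSV with header `quadrat_id,species,percent_cover` (UTF-8).
#' @return Data frame suitable for [biodiversity_indices()].
#' @export
read_cover_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("quadrat_id", "species", "percent_cover")
  if (!all(need %in% names(df))) {
    stop(path, " must have header columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Read a clip-strip biomass CSV
#'
#' @param path CSV with header
#'   `quadrat_id,functional_group,mass_g,strip_area_m2`.
#' @return Data frame suitable for [biodiversity_indices()].
#' @export
read_biomass_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("quadrat_id", "functional_group", "mass_g", "strip_area_m2")
  if (!all(need %in% names(df))) {
    stop(path, " must have header columns: ", paste(need, collapse = ", "))
  }
  df
}
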