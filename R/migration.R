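# Lifetime migration metrics: planar distances to the nearest km,
# population-density lookups on a raster, and the risk-taking follow-up
# associations under tiered covariate adjustment.

#' Population density raster
#'
#' A regular planar raster of persons-per-square-km values on a
#' national-grid-like easting/northing system (km units). Cells are
#' half-open (`[x, x + cell)`), so a point on a cell edge belongs to the
#' cell for which the edge is the lower/left boundary.
#'
#' @param values Numeric matrix of densities, indexed `[ix, iy]` with x
#'   (easting) along rows.
#' @param cell_km Cell edge length in km.
#' @param origin Length-2 numeric, the (x, y) of the lower-left corner.
#' @return A `density_map` object.
#' @export
density_map <- function(values, cell_km, origin = c(0, 0)) {
  values <- as.matrix(values)
  if (any(values < 0)) abort("densities must be non-negative")
  if (cell_km <= 0) abort("cell size must be positive")
  structure(list(values = values, cell_km = cell_km,
                 origin = as.numeric(origin)),
            class = "density_map")
}

#' Generate a synthetic density map with urban peaks
#'
#' Base rural density plus a few Gaussian urban bumps at random centres;
#' emulates the coordinate-to-density lookup against census district
#' data without any boundary machinery.
#'
#' @param extent_km Map edge length (square map, origin at 0).
#' @param cell_km Cell size.
#' @param base Rural base density (persons/km^2).
#' @param n_peaks Number of urban centres.
#' @param peak_density Peak amplitude above base.
#' @param peak_sd_km Spatial SD of each urban bump.
#' @return A [density_map()].
#' @export
make_density_map <- function(extent_km = 500, cell_km = 10, base = 50,
                             n_peaks = 5, peak_density = 3000,
                             peak_sd_km = 30) {
  ncell <- ceiling(extent_km / cell_km)
  cx <- (seq_len(ncell) - 0.5) * cell_km
  vals <- matrix(base, ncell, ncell)
  if (n_peaks > 0) {
    px <- runif(n_peaks, 0, extent_km)
    py <- runif(n_peaks, 0, extent_km)
    amp <- peak_density * runif(n_peaks, 0.5, 1)
    for (p in seq_len(n_peaks)) {
      dx2 <- outer((cx - px[p])^2, (cx - py[p])^2, "+")
      vals <- vals + amp[p] * exp(-dx2 / (2 * peak_sd_km^2))
    }
  }
  density_map(vals, cell_km = cell_km, origin = c(0, 0))
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %d x %d cells of %g km | density %.1f-%.1f /km^2\n",
              nrow(x$values), ncol(x$values), x$cell_km,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Euclidean migration distance to the nearest km
#'
#' `round(sqrt((e2 - e1)^2 + (n2 - n1)^2))` with round-half-to-even at
#' the km scale (coarsening to whole km mirrors the
#' disclosure-protection convention for residence coordinates).
#'
#' @param birth_e,birth_n,current_e,current_n Easting/northing in km
#'   (vectorised).
#' @return Integer km.
#' @export
distance_km <- function(birth_e, birth_n, current_e, current_n) {
  d <- sqrt((current_e - birth_e)^2 + (current_n - birth_n)^2)
  as.integer(round(d))
}

#' Look up population density at a location
#'
#' Value of the raster cell containing the point, with half-open cells:
#' a point exactly on an edge belongs to the cell whose lower/left
#' boundary it is. Out-of-bounds locations error.
#'
#' @param map A [density_map()].
#' @param e,n Easting/northing in km (vectorised).
#' @return Persons per square km.
#' @export
density_at <- function(map, e, n) {
  stopifnot(inherits(map, "density_map"))
  ix <- floor((e - map$origin[1]) / map$cell_km) + 1
  iy <- floor((n - map$origin[2]) / map$cell_km) + 1
  bad <- ix < 1 | iy < 1 | ix > nrow(map$values) | iy > ncol(map$values) |
    !is.finite(e) | !is.finite(n)
  if (any(bad)) abort("location outside the density map bounds")
  map$values[cbind(ix, iy)]
}

#' Per-sample migration table
#'
#' Derives, for each individual, the Euclidean distance between birth and
#' current residence (nearest km), the population density at each, and
#' their difference (`density_current - density_birth`, so a move to a
#' less dense area is negative).
#'
#' @param locations Tibble with `sample_id`, `birth_e`, `birth_n`,
#'   `current_e`, `current_n` and optionally `years_at_residence`.
#' @param map A [density_map()].
#' @return Tibble: `sample_id`, `distance_km`, `density_birth`,
#'   `density_current`, `density_change`, `years_at_residence`.
#' @export
migration_table <- function(locations, map) {
  db <- density_at(map, locations$birth_e, locations$birth_n)
  dc <- density_at(map, locations$current_e, locations$current_n)
  tibble(sample_id = locations$sample_id,
         distance_km = distance_km(locations$birth_e, locations$birth_n,
                                   locations$current_e, locations$current_n),
         density_birth = db, density_current = dc,
         density_change = dc - db,
         years_at_residence = locations$years_at_residence %||% NA_real_)
}

#' Risk-taking follow-up associations with tiered covariate adjustment
#'
#' For each outcome (migration or substance-use variable, or a control
#' trait), regresses the outcome on the exposure (the risk-taking trait
#' or the PRS) under each covariate tier — by default a base tier (age,
#' sex) and an extended tier adding deprivation and education — and
#' reports the per-tier effect together with the attenuation ratio
#' `beta_extended / beta_base`. Ratios below 1 indicate the association
#' is partly carried by the socio-economic covariates.
#'
#' @param data Per-individual tibble containing outcomes, exposure and
#'   covariates.
#' @param outcomes Character vector of outcome column names.
#' @param exposure Exposure column name (e.g. `"trait"` or `"prs"`).
#' @param tiers Named list of covariate-name vectors; the first tier is
#'   the attenuation baseline.
#' @param families Optional named vector of regression families per
#'   outcome (`"linear"`/`"logistic"`); auto-detected otherwise.
#' @return Tibble with one row per outcome and tier (`outcome`, `tier`,
#'   `beta`, `se`, `p_value`, `r2_incremental`, `n_used`,
#'   `attenuation_ratio`).
#' @export
follow_up_associations <- function(data, outcomes, exposure = "trait",
                                   tiers = list(
                                     base = c("age", "sex"),
                                     extended = c("age", "sex",
                                                  "deprivation_index", "education")),
                                   families = NULL) {
  for (tier in tiers) {
    const <- vapply(tier, function(cv) length(unique(stats::na.omit(data[[cv]]))) < 2,
                    logical(1))
    if (any(const)) abort(paste0("constant covariate: ", paste(tier[const], collapse = ", ")))
  }
  res <- purrr::map_dfr(outcomes, function(out) {
    fam <- if (!is.null(families) && out %in% names(families)) families[[out]] else "auto"
    per_tier <- purrr::imap_dfr(tiers, function(cvs, tname) {
      r <- prs_associate(data, trait = out, prs = exposure,
                         covariates = cvs, family = fam)
      tibble(outcome = out, tier = tname, beta = r$beta, se = r$se,
             p_value = r$p_value, r2_incremental = r$r2_incremental,
             n_used = r$n_used)
    })
    per_tier$attenuation_ratio <- per_tier$beta / per_tier$beta[1]
    per_tier
  })
  res
}
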