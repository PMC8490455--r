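#' Partition a grid's bounding box into rectangular regions
#'
#' Builds a regular `nrow_regions x ncol_regions` tiling of the area spanned
#' by the supplied cell centres (half a cell of margin on each side) and
#' assigns regions to countries in contiguous column blocks.
#'
#' @param lat,lon cell-centre coordinates (vectors over cells).
#' @param nrow_regions,ncol_regions tiling dimensions.
#' @param n_countries number of countries; regions are split into
#'   `n_countries` contiguous groups.
#' @return an object of class `region_set`: list with `regions` (data frame
#'   of region, country) and `polygons` (named list of two-column
#'   lon/lat vertex matrices).
#' @export
makeGridRegions <- function(lat, lon, nrow_regions = 1L, ncol_regions = 2L,
                            n_countries = 1L) {
  n_reg <- nrow_regions * ncol_regions
  if (n_countries > n_reg)
    stop("more countries than regions", call. = FALSE)
  dy <- if (length(unique(lat)) > 1L) min(diff(sort(unique(lat)))) else 1
  dx <- if (length(unique(lon)) > 1L) min(diff(sort(unique(lon)))) else 1
  y0 <- min(lat) - dy / 2; y1 <- max(lat) + dy / 2
  x0 <- min(lon) - dx / 2; x1 <- max(lon) + dx / 2
  ybreaks <- seq(y0, y1, length.out = nrow_regions + 1L)
  xbreaks <- seq(x0, x1, length.out = ncol_regions + 1L)
  ids <- character(0); polys <- list()
  k <- 0L
  for (i in seq_len(nrow_regions)) {
    for (j in seq_len(ncol_regions)) {
      k <- k + 1L
      id <- sprintf("R%02d", k)
      ids <- c(ids, id)
      polys[[id]] <- cbind(
        lon = c(xbreaks[j], xbreaks[j + 1L], xbreaks[j + 1L], xbreaks[j]),
        lat = c(ybreaks[i], ybreaks[i], ybreaks[i + 1L], ybreaks[i + 1L]))
    }
  }
  country <- sprintf("C%02d", ceiling(seq_len(n_reg) / (n_reg / n_countries)))
  structure(list(regions = data.frame(region = ids, country = country),
                 polygons = polys),
            class = "region_set")
}

#' Assign grid cells to regions by point-in-polygon membership
#'
#' @param lat,lon cell-centre coordinates.
#' @param regions a `region_set`.
#' @return character vector of region ids (NA for cells outside every
#'   region).
#' @export
assignCells <- function(lat, lon, regions) {
  stopifnot(inherits(regions, "region_set"))
  out <- rep(NA_character_, length(lat))
  for (id in names(regions$polygons)) {
    hit <- point_in_polygon(lon, lat, regions$polygons[[id]])
    out[is.na(out) & hit] <- id
  }
  out
}

#' Write a region set as GeoJSON
#'
#' @param regions a `region_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeRegionsGeoJSON <- function(regions, path) {
  stopifnot(inherits(regions, "region_set"))
  feats <- lapply(seq_len(nrow(regions$regions)), function(i) {
    id <- regions$regions$region[i]
    ring <- regions$polygons[[id]]
    ring <- rbind(ring, ring[1L, ])
    list(type = "Feature",
         properties = list(region = id,
                           country = regions$regions$country[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                           function(k) c(ring[k, 1L], ring[k, 2L])))))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Generate a synthetic population grid with spatial concentration
#'
#' Draws lognormal cell counts (heavy right tail, so population clusters in
#' a few cells) for a set of snapshot years with a constant annual growth
#' rate between snapshots.
#'
#' @param lat,lon cell-centre coordinates.
#' @param years snapshot years (sorted).
#' @param base_pop expected count per cell in the first snapshot.
#' @param concentration lognormal sdlog; larger values concentrate
#'   population more strongly.
#' @param growth annual multiplicative growth rate.
#' @param seed integer seed.
#' @return an object of class `population_grid`: list with `lat`, `lon`,
#'   `years`, and a `counts` matrix (`n_cells x n_years`).
#' @export
generatePopulation <- function(lat, lon, years = c(2000L, 2005L, 2010L),
                               base_pop = 1000, concentration = 1,
                               growth = 0.01, seed = 1L) {
  years <- sort(as.integer(years))
  ncell <- length(lat)
  base <- with_seed(seed,
    rlnorm(ncell, meanlog = log(base_pop) - concentration^2 / 2,
           sdlog = concentration))
  counts <- outer(base, (1 + growth)^(years - years[1L]))
  structure(list(lat = lat, lon = lon, years = years, counts = counts),
            class = "population_grid")
}

#' Population counts interpolated to a target year
#'
#' Linear interpolation between snapshot years; constant extrapolation
#' outside the covered range (the earliest snapshot is used for earlier
#' years, mirroring fixed-mask historical runs).
#'
#' @param pop a `population_grid`.
#' @param year target year.
#' @return numeric vector of per-cell counts.
#' @export
populationAtYear <- function(pop, year) {
  stopifnot(inherits(pop, "population_grid"))
  if (length(pop$years) == 1L) return(pop$counts[, 1L])
  sapply(seq_along(pop$lat), function(i) {
    approx(pop$years, pop$counts[i, ], xout = year, rule = 2)$y
  })
}
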