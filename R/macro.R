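# Corridor geometry around the covered street network. With no polygon
# clipping library, the corridor union (fixed-radius buffer around covered
# edge intervals) is evaluated on a regular grid: a cell belongs to the
# corridor when its centre lies within the radius of any covered polyline.
# Deterministic, with discretisation error O(resolution * perimeter).

corridor_polylines <- function(network, buffer) {
  if (!nrow(buffer$covered)) return(list())
  out <- list()
  for (i in seq_len(nrow(buffer$covered))) {
    cv <- buffer$covered[i, ]
    g <- network$geoms[[cv$edge_id]]
    sp <- sub_polyline(g, cv$start, cv$end)
    if (nrow(sp) >= 2) out[[length(out) + 1L]] <- sp
  }
  out
}

corridor_grid <- function(polylines, radius_m, resolution_m) {
  stopifnot(length(polylines) > 0)
  allc <- do.call(rbind, polylines)
  xr <- range(allc[, 1]) + c(-1, 1) * (radius_m + resolution_m)
  yr <- range(allc[, 2]) + c(-1, 1) * (radius_m + resolution_m)
  xs <- seq(xr[1] + resolution_m / 2, xr[2], by = resolution_m)
  ys <- seq(yr[1] + resolution_m / 2, yr[2], by = resolution_m)
  px <- rep(xs, times = length(ys))
  py <- rep(ys, each = length(xs))
  d <- rep(Inf, length(px))
  for (pl in polylines) {
    # cheap bounding-box pre-filter per polyline
    bb <- c(range(pl[, 1]), range(pl[, 2])) + c(-1, 1, -1, 1) * radius_m
    cand <- which(px >= bb[1] & px <= bb[2] & py >= bb[3] & py <= bb[4] & d > radius_m)
    if (!length(cand)) next
    d[cand] <- pmin(d[cand], points_polyline_dist(px[cand], py[cand], pl))
  }
  inside <- d <= radius_m
  list(x = px[inside], y = py[inside], cell_area_m2 = resolution_m^2)
}

#' Corridor (line-buffer) area of a buffer zone
#'
#' Area of the union of fixed-radius corridors around the covered edge
#' intervals of a street-network buffer, in square kilometres. The default
#' radius of 95 m matches the 0.095 km road-centreline buffer conventional
#' for school-neighbourhood land-use analysis. Computed by rasterising the
#' corridor union at `resolution_m`.
#'
#' @param network A `street_network`.
#' @param buffer A `buffer_zone`.
#' @param corridor_radius_m Corridor radius in metres (> 0, default 95).
#' @param resolution_m Grid resolution in metres (default 2).
#' @return Area in square kilometres (0 for an empty buffer).
#' @export
buffer_area <- function(network, buffer, corridor_radius_m = 95,
                        resolution_m = 2) {
  stopifnot(corridor_radius_m > 0, resolution_m > 0)
  pls <- corridor_polylines(network, buffer)
  if (!length(pls)) return(0)
  gr <- corridor_grid(pls, corridor_radius_m, resolution_m)
  length(gr$x) * gr$cell_area_m2 / 1e6
}

#' Intersection and residential density
#'
#' Counts per square kilometre of corridor area. A single residence is
#' assumed occupied at a single address point.
#'
#' @param n Count of junctions (respectively residences) in the buffer.
#' @param area_km2 Neighbourhood area in square kilometres (> 0).
#' @return Density per square kilometre.
#' @export
intersection_density <- function(n, area_km2) {
  if (!is.finite(area_km2) || area_km2 <= 0)
    stop("undefined density: area must be positive")
  n / area_km2
}

#' @rdname intersection_density
#' @export
residential_density <- intersection_density

#' Land-use-mix entropy
#'
#' Normalised Shannon entropy of land-use proportions over the five
#' configured categories: 0 for a single land use (homogeneity), 1 for a
#' uniform spread (heterogeneity). The number of categories is fixed at the
#' configured five regardless of how many are locally present; set
#' `k = "present"` to normalise by the number of non-zero categories
#' instead.
#'
#' @param proportions Numeric vector of category proportions (>= 0, summing
#'   to 1 within 1e-9).
#' @param k Number of categories for normalisation: `"configured"` (default,
#'   `length(proportions)`) or `"present"`.
#' @return Value in `[0, 1]`.
#' @examples
#' land_use_mix(c(1, 0, 0, 0, 0))              # 0
#' land_use_mix(rep(0.2, 5))                   # 1
#' land_use_mix(c(0.5, 0.5, 0, 0, 0))          # 0.4307 (ln 2 / ln 5)
#' @export
land_use_mix <- function(proportions, k = c("configured", "present")) {
  k <- match.arg(k)
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-9)
    stop("normalization error: proportions must be non-negative and sum to 1")
  kk <- if (k == "configured") length(proportions) else sum(proportions > 0)
  if (kk < 2) return(0)
  p <- proportions[proportions > 0]
  -sum(p * log(p)) / log(kk)
}

#' Land-use proportions within the corridor
#'
#' Shares of corridor area falling in each of the five land-use categories,
#' measured by parcel area intersected with the corridor polygon
#' (rasterised: corridor grid cells classified by point-in-polygon test
#' against the parcels). Cells outside every parcel are excluded from the
#' denominator.
#'
#' @inheritParams buffer_area
#' @return Named numeric vector over [LAND_USE_CATEGORIES] summing to 1, or
#'   all-`NA` when no corridor cell falls inside a parcel.
#' @export
land_use_proportions <- function(network, buffer, corridor_radius_m = 95,
                                 resolution_m = 2) {
  pls <- corridor_polylines(network, buffer)
  empty <- stats::setNames(rep(NA_real_, length(LAND_USE_CATEGORIES)),
                           LAND_USE_CATEGORIES)
  if (!length(pls) || !length(network$parcels)) return(empty)
  gr <- corridor_grid(pls, corridor_radius_m, resolution_m)
  cat_of <- rep(NA_character_, length(gr$x))
  for (p in network$parcels) {
    un <- which(is.na(cat_of))
    if (!length(un)) break
    bb <- c(range(p$coords[, 1]), range(p$coords[, 2]))
    cand <- un[gr$x[un] >= bb[1] & gr$x[un] <= bb[2] &
               gr$y[un] >= bb[3] & gr$y[un] <= bb[4]]
    if (!length(cand)) next
    inp <- pracma::inpolygon(gr$x[cand], gr$y[cand],
                             p$coords[, 1], p$coords[, 2], boundary = TRUE)
    cat_of[cand[inp]] <- p$category
  }
  n <- sum(!is.na(cat_of))
  if (n == 0) return(empty)
  counts <- table(factor(cat_of, levels = LAND_USE_CATEGORIES))
  as.numeric(counts) / n -> pr
  stats::setNames(pr, LAND_USE_CATEGORIES)
}

#' Macro-scale profile of one school neighbourhood
#'
#' @inheritParams buffer_area
#' @return One-row data frame: `school_id`, `area_km2`, `n_intersections`,
#'   `n_residences`, `intersection_density`, `residential_density`,
#'   `land_use_mix`.
#' @export
macro_profile <- function(network, buffer, corridor_radius_m = 95,
                          resolution_m = 2) {
  area <- buffer_area(network, buffer, corridor_radius_m, resolution_m)
  ints <- identify_intersections(network, buffer)
  segs <- extract_segments(network, buffer)
  n_res <- sum(segs$residences_odd + segs$residences_even)
  pr <- land_use_proportions(network, buffer, corridor_radius_m, resolution_m)
  mix <- if (anyNA(pr)) NA_real_ else land_use_mix(pr)
  data.frame(school_id = buffer$school_id, area_km2 = area,
             n_intersections = nrow(ints), n_residences = n_res,
             intersection_density = intersection_density(nrow(ints), area),
             residential_density = residential_density(n_res, area),
             land_use_mix = mix, stringsAsFactors = FALSE)
}

#' Composite walkability index
#'
#' Per-school sum of within-sample z-scores of intersection density,
#' residential density and land-use mix. z-scores use the sample standard
#' deviation (n - 1); a component with zero variance contributes 0 to every
#' school (with a warning). The index has sample mean 0 by construction.
#'
#' @param profiles Data frame with columns `intersection_density`,
#'   `residential_density`, `land_use_mix`; one row per school (>= 2 rows).
#' @return Numeric vector of walkability indices (one per row).
#' @export
walkability <- function(profiles) {
  comps <- c("intersection_density", "residential_density", "land_use_mix")
  stopifnot(all(comps %in% names(profiles)))
  if (nrow(profiles) < 2)
    stop("walkability requires at least two schools (z-scores undefined)")
  z <- sapply(comps, function(nm) {
    v <- profiles[[nm]]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      warning("component '", nm, "' has zero variance; z-scores set to 0")
      return(rep(0, length(v)))
    }
    (v - mean(v)) / s
  })
  unname(rowSums(z))
}
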