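#' Configuration for the synthetic city generator
#'
#' The generator emulates the study conditions of a small-city school
#' neighbourhood audit: a jittered street grid (default spacing 115 m,
#' matching a mean audited segment length of ~114 m), 12 secondary schools,
#' residence placement by street side with odd/even house numbering, a
#' residential-dominant five-category land-use mixture (low land-use
#' heterogeneity), ordinal two-sided audit item values drawn from latent
#' Gaussian pairs with controllable between-side correlation `rho`, and a
#' second rater as the first plus discretised Gaussian noise.
#'
#' @param n_schools Number of schools (default 12).
#' @param grid_nx,grid_ny Grid dimensions in nodes.
#' @param spacing_m Mean grid spacing in metres.
#' @param jitter_sd_m SD of node-position jitter in metres.
#' @param drop_edge_frac Fraction of grid edges removed (keeping the network
#'   connected) to create irregularity and dead ends.
#' @param residences_per_100m Expected residences per 100 m per street side.
#' @param landuse_mixture Named probabilities over the five land-use
#'   categories.
#' @param parcel_size_m Side length of square land-use parcels.
#' @param item_latent_mean Latent mean shift of audit items (negative values
#'   give sparse streetscapes, the realistic regime).
#' @param rho Between-side latent correlation, in `[-1, 1]`.
#' @param rater_noise_sd Latent SD of the second rater's noise.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A validated list of class `city_config`.
#' @export
city_config <- function(n_schools = 12, grid_nx = 16, grid_ny = 16,
                        spacing_m = 115, jitter_sd_m = 18,
                        drop_edge_frac = 0.06,
                        residences_per_100m = 4,
                        landuse_mixture = c(residential = 0.85,
                                            commercial = 0.06,
                                            industrial = 0.03,
                                            tertiary_campus = 0.02,
                                            open_space = 0.04),
                        parcel_size_m = 150,
                        item_latent_mean = -0.8,
                        rho = 0.9, rater_noise_sd = 0.4, seed = 1) {
  stopifnot(rho >= -1, rho <= 1, rater_noise_sd >= 0,
            residences_per_100m >= 0, n_schools >= 1,
            grid_nx >= 2, grid_ny >= 2, spacing_m > 0)
  if (!setequal(names(landuse_mixture), LAND_USE_CATEGORIES))
    stop("landuse_mixture must name the five land-use categories")
  if (abs(sum(landuse_mixture) - 1) > 1e-9)
    stop("landuse_mixture must sum to 1")
  structure(as.list(environment()), class = "city_config")
}

#' Generate a synthetic city
#'
#' Builds a connected planar street network (jittered grid with a fraction
#' of edges removed), numbers addresses odd/even by street side, tiles the
#' extent with land-use parcels and places schools at well-separated
#' junctions.
#'
#' @param config A `city_config`.
#' @return List with `network` (a `street_network`) and `schools` (data
#'   frame `school_id`, `node_id`, `x`, `y`).
#' @export
generate_city <- function(config) {
  stopifnot(inherits(config, "city_config"))
  set.seed(config$seed)
  nx <- config$grid_nx; ny <- config$grid_ny; sp <- config$spacing_m

  idx <- function(i, j) (j - 1L) * nx + i
  nodes <- data.frame(
    node_id = sprintf("N%04d", seq_len(nx * ny)),
    x = rep(seq_len(nx), times = ny) * sp +
      stats::rnorm(nx * ny, 0, config$jitter_sd_m),
    y = rep(seq_len(ny), each = nx) * sp +
      stats::rnorm(nx * ny, 0, config$jitter_sd_m),
    stringsAsFactors = FALSE)

  eh <- do.call(rbind, lapply(seq_len(ny), function(j)
    data.frame(from = idx(seq_len(nx - 1L), j), to = idx(seq_len(nx - 1L) + 1L, j),
               street_id = sprintf("H%02d", j))))
  ev <- do.call(rbind, lapply(seq_len(nx), function(i)
    data.frame(from = idx(i, seq_len(ny - 1L)), to = idx(i, seq_len(ny - 1L) + 1L),
               street_id = sprintf("V%02d", i))))
  edges <- rbind(eh, ev)
  edges$from <- nodes$node_id[edges$from]
  edges$to <- nodes$node_id[edges$to]
  if (nrow(edges) == 0L) stop("config error: network has no edges")

  # remove a fraction of edges, keeping the graph connected
  n_drop <- round(config$drop_edge_frac * nrow(edges))
  if (n_drop > 0) {
    cand <- sample(nrow(edges))
    dropped <- 0L
    for (i in cand) {
      if (dropped >= n_drop) break
      g <- igraph::graph_from_data_frame(edges[-i, c("from", "to")],
                                         directed = FALSE,
                                         vertices = nodes$node_id)
      if (igraph::is_connected(g)) {
        edges <- edges[-i, , drop = FALSE]
        dropped <- dropped + 1L
        cand <- cand[cand != i]
        cand[cand > i] <- cand[cand > i] - 1L
      }
    }
  }
  edges$edge_id <- sprintf("E%04d", seq_len(nrow(edges)))
  edges <- edges[, c("edge_id", "from", "to", "street_id")]

  net0 <- street_network(nodes, edges)

  # addresses: per edge and side, Poisson by length, numbered odd/even,
  # offset 6 m perpendicular from the centreline
  addr <- list()
  for (i in seq_len(nrow(net0$edges))) {
    e <- net0$edges[i, ]
    g <- net0$geoms[[e$edge_id]]
    dx <- g[2, 1] - g[1, 1]; dy <- g[2, 2] - g[1, 2]
    nrm <- sqrt(dx^2 + dy^2)
    perp <- c(-dy, dx) / nrm
    lam <- config$residences_per_100m * e$length_m / 100
    for (side in c("O", "E")) {
      n_res <- stats::rpois(1, lam)
      if (n_res == 0) next
      t <- sort(stats::runif(n_res, 0.05, 0.95)) * e$length_m
      sgn <- if (side == "O") 1 else -1
      num <- if (side == "O") 2 * seq_len(n_res) - 1 else 2 * seq_len(n_res)
      addr[[length(addr) + 1L]] <- data.frame(
        x = g[1, 1] + t / nrm * dx + sgn * 6 * perp[1],
        y = g[1, 2] + t / nrm * dy + sgn * 6 * perp[2],
        number = num, edge_id = e$edge_id, t = t, stringsAsFactors = FALSE)
    }
  }
  addresses <- do.call(rbind, addr)

  # land-use parcels tiling the extent
  ps <- config$parcel_size_m
  xr <- range(nodes$x) + c(-ps, ps); yr <- range(nodes$y) + c(-ps, ps)
  xs <- seq(xr[1], xr[2], by = ps); ys <- seq(yr[1], yr[2], by = ps)
  parcels <- list()
  for (xi in xs[-length(xs)]) {
    for (yi in ys[-length(ys)]) {
      cat_i <- sample(names(config$landuse_mixture), 1,
                      prob = config$landuse_mixture)
      parcels[[length(parcels) + 1L]] <- list(
        category = cat_i,
        coords = rbind(c(xi, yi), c(xi + ps, yi), c(xi + ps, yi + ps),
                       c(xi, yi + ps)))
    }
  }

  network <- street_network(nodes, edges, net0$geoms, addresses, parcels)

  # schools at well-separated junctions
  sep <- 3 * sp
  chosen <- integer(0)
  ord <- sample(nrow(nodes))
  for (i in ord) {
    if (length(chosen) >= config$n_schools) break
    if (!length(chosen) ||
        all(sqrt((nodes$x[chosen] - nodes$x[i])^2 +
                 (nodes$y[chosen] - nodes$y[i])^2) >= sep))
      chosen <- c(chosen, i)
  }
  if (length(chosen) < config$n_schools)
    stop("config error: could not place ", config$n_schools,
         " schools with ", sep, " m separation")
  schools <- data.frame(school_id = sprintf("SCH%02d", seq_along(chosen)),
                        node_id = nodes$node_id[chosen],
                        x = nodes$x[chosen] + 5, y = nodes$y[chosen] + 5,
                        stringsAsFactors = FALSE)
  list(network = network, schools = schools)
}

# discretise a latent Gaussian value to an item's ordinal range by quantile
# thresholds; bounded count items use cap + 3 effective levels
discretise_item <- function(item, z) {
  K <- item$max - item$min + 1L
  if (K > 12L) K <- if (is.finite(item$cap)) as.integer(item$cap) + 3L else 8L
  u <- stats::pnorm(z)
  item$min + pmin(K - 1L, floor(u * K))
}

#' Generate synthetic audit records for an audit frame
#'
#' For every street segment, odd- and even-side item values are drawn from a
#' latent Gaussian pair with correlation `rho` and discretised to the item's
#' ordinal range by quantile thresholds (so the latent correlation is
#' controlled exactly; the ordinal-scale correlation is attenuated by
#' discretisation). A second rater observes the same latent values plus
#' independent Gaussian noise (`rater_noise_sd`), re-discretised. Crossing
#' audits are generated per connecting road and carry no side; cul-de-sac
#' amenities are recorded for dead-end junctions.
#'
#' @param frame List with `segments` (a `segment_set`), `intersections`
#'   (from [identify_intersections()]) and optionally `culdesacs`
#'   (data frame with `culdesac_id`).
#' @param scheme A `scoring_scheme`.
#' @param config A `city_config` (uses `rho`, `rater_noise_sd`,
#'   `item_latent_mean`).
#' @param raters 1 or 2.
#' @param school_id School identifier stamped on the records.
#' @return For `raters = 1`, a named list of `audit_set`s (`route_side`,
#'   `segment_side`, `crossing`, `cul_de_sac`); for `raters = 2`, a list
#'   `list(rater1 = ..., rater2 = ...)`.
#' @export
generate_audits <- function(frame, scheme, config, raters = 1,
                            school_id = "SCH01") {
  stopifnot(inherits(scheme, "scoring_scheme"), raters %in% 1:2)
  rho <- config$rho; mu <- config$item_latent_mean; nsd <- config$rater_noise_sd
  segs <- frame$segments
  n_seg <- nrow(segs)

  side_table <- function(kind) {
    items <- scheme_item_names(scheme, kind)
    z1 <- matrix(stats::rnorm(n_seg * length(items)), n_seg)
    z2 <- rho * z1 + sqrt(max(0, 1 - rho^2)) *
      matrix(stats::rnorm(n_seg * length(items)), n_seg)
    noise_o <- matrix(stats::rnorm(n_seg * length(items), 0, nsd), n_seg)
    noise_e <- matrix(stats::rnorm(n_seg * length(items), 0, nsd), n_seg)
    build <- function(zo, ze) {
      df <- data.frame(unit_id = rep(segs$segment_id, 2),
                       side = rep(c("O", "E"), each = n_seg),
                       school_id = school_id, stringsAsFactors = FALSE)
      for (ii in seq_along(items)) {
        it <- scheme$items[[items[ii]]]
        df[[items[ii]]] <- c(discretise_item(it, zo[, ii] + mu),
                             discretise_item(it, ze[, ii] + mu))
      }
      df
    }
    list(r1 = build(z1, z2), r2 = build(z1 + noise_o, z2 + noise_e))
  }

  crossing_table <- function() {
    ints <- frame$intersections
    if (is.null(ints) || nrow(ints) == 0L) return(NULL)
    rows <- data.frame(
      unit_id = rep(ints$node_id, lengths(ints$connecting_roads)),
      subunit = unlist(ints$connecting_roads),
      school_id = school_id, stringsAsFactors = FALSE)
    items <- scheme_item_names(scheme, "crossing")
    z <- matrix(stats::rnorm(nrow(rows) * length(items)), nrow(rows))
    noise <- matrix(stats::rnorm(nrow(rows) * length(items), 0, nsd), nrow(rows))
    build <- function(zz) {
      df <- rows
      for (ii in seq_along(items))
        df[[items[ii]]] <- discretise_item(scheme$items[[items[ii]]], zz[, ii] + mu)
      df
    }
    list(r1 = build(z), r2 = build(z + noise))
  }

  culdesac_table <- function() {
    cds <- frame$culdesacs
    if (is.null(cds) || nrow(cds) == 0L) return(NULL)
    items <- scheme_item_names(scheme, "cul_de_sac")
    z <- matrix(stats::rnorm(nrow(cds) * length(items)), nrow(cds))
    df <- data.frame(unit_id = cds$culdesac_id, school_id = school_id,
                     stringsAsFactors = FALSE)
    for (ii in seq_along(items))
      df[[items[ii]]] <- discretise_item(scheme$items[[items[ii]]], z[, ii] + mu)
    list(r1 = df, r2 = df)
  }

  rt <- side_table("route_side")
  sg <- side_table("segment_side")
  cr <- crossing_table()
  cd <- culdesac_table()
  pack <- function(which) {
    out <- list(route_side = as_audit_set(stamp(rt[[which]], which), scheme),
                segment_side = as_audit_set(stamp(sg[[which]], which), scheme))
    if (!is.null(cr)) out$crossing <- as_audit_set(stamp(cr[[which]], which), scheme)
    if (!is.null(cd)) out$cul_de_sac <- as_audit_set(stamp(cd[[which]], which), scheme)
    out
  }
  stamp <- function(df, which = "r1") {
    df$auditor_id <- toupper(which)
    df$audit_date <- "2017-10-02"
    df
  }
  if (raters == 1) pack("r1") else list(rater1 = pack("r1"), rater2 = pack("r2"))
}

#' Run the full synthetic study pipeline
#'
#' Generates a city, then for every school: the 500 m network buffer, the
#' segment and intersection audit frames, the boundary protocol rules,
#' synthetic audits (two raters for the first two schools, emulating a
#' co-audit reliability sample), odd/even/combined school summaries, and
#' macro-scale profiles with the composite walkability index. Per-school
#' audit generation uses a derived sub-seed so schools are reproducible
#' independently.
#'
#' @param config A `city_config`.
#' @param buffer_m Buffer threshold in metres (default 500).
#' @param corridor_radius_m Corridor radius for macro metrics (default 95).
#' @param resolution_m Raster resolution for macro metrics (default 5).
#' @param macro Compute macro profiles (default TRUE; the raster step
#'   dominates run time).
#' @return List with `city`, `frames` (per school), `summaries` (per school,
#'   odd/even/combined), `paired` (concordance input table), `concordance`,
#'   `macro` (profile table with `walkability`), `reliability` (two-rater
#'   audit sets for the first two schools) and `logs`
#'   (exclusions/extensions per school).
#' @export
simulate_study <- function(config = city_config(), buffer_m = 500,
                           corridor_radius_m = 95, resolution_m = 5,
                           macro = TRUE) {
  scheme <- default_scheme()
  city <- generate_city(config)
  net <- city$network
  deg <- node_degrees(net)

  frames <- list(); summaries <- list(); profiles <- list()
  reliability <- list(); logs <- list()
  for (si in seq_len(nrow(city$schools))) {
    sid <- city$schools$school_id[si]
    buf <- compute_service_area(net, c(city$schools$x[si], city$schools$y[si]),
                                threshold_m = buffer_m, school_id = sid)
    segs <- extract_segments(net, buf)
    rules <- apply_protocol_rules(segs)
    ints <- identify_intersections(net, buf)
    dead <- names(deg)[deg == 1L]
    dead <- dead[dead %in% names(buf$node_dist)[buf$node_dist <= buffer_m]]
    culdesacs <- if (length(dead))
      data.frame(culdesac_id = paste0(sid, ".CDS.", dead),
                 stringsAsFactors = FALSE) else NULL
    frame <- list(segments = rules$kept, intersections = ints,
                  culdesacs = culdesacs, buffer = buf)
    frames[[sid]] <- frame
    logs[[sid]] <- rules[c("exclusions", "extensions")]

    set.seed((config$seed * 1000L + si) %% .Machine$integer.max)
    two <- si <= 2L
    aud <- generate_audits(frame, scheme, config, raters = if (two) 2 else 1,
                           school_id = sid)
    if (two) {
      reliability[[sid]] <- aud
      aud <- aud$rater1
    }
    for (scope in c("odd", "even", "combined"))
      summaries[[paste(sid, scope, sep = ".")]] <-
        aggregate_school(aud, scheme, side_scope = scope, school_id = sid)

    if (macro)
      profiles[[sid]] <- macro_profile(net, buf, corridor_radius_m, resolution_m)
  }

  paired <- concordance_inputs(unname(summaries))
  conc <- concordance(paired)
  macro_tab <- NULL
  if (macro) {
    macro_tab <- do.call(rbind, profiles)
    macro_tab$walkability <- walkability(macro_tab)
    rownames(macro_tab) <- NULL
  }
  list(city = city, frames = frames, summaries = summaries, paired = paired,
       concordance = conc, macro = macro_tab, reliability = reliability,
       logs = logs, scheme = scheme)
}
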