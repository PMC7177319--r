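#' Construct a street network
#'
#' A street network is the geometric substrate for neighbourhood audits:
#' junction nodes, road-centreline edges with metric lengths, address points
#' (with house numbers) snapped to their nearest edge, and land-use parcels
#' in one of five configured categories. Coordinates are planar metric
#' (metres); geographic coordinates must be projected upstream.
#'
#' @param nodes Data frame with `node_id`, `x`, `y`.
#' @param edges Data frame with `edge_id`, `from`, `to` (node ids) and
#'   optionally `street_id` and `length_m`; `geoms` supplies the polylines.
#' @param geoms Named list (by `edge_id`) of two-column coordinate matrices.
#'   When omitted, straight lines between endpoint nodes are used.
#' @param addresses Optional data frame with `x`, `y`, `number` (house
#'   number; parity defines the street side). `edge_id` and `t` (curve
#'   position along the edge, metres) are computed by snapping when absent.
#' @param parcels Optional list of land-use parcels, each
#'   `list(category =, coords = <matrix>)` with `category` one of
#'   `r paste(LAND_USE_CATEGORIES, collapse = ", ")`.
#' @return An object of class `street_network`.
#' @export
street_network <- function(nodes, edges, geoms = NULL, addresses = NULL,
                           parcels = NULL) {
  stopifnot(all(c("node_id", "x", "y") %in% names(nodes)),
            all(c("edge_id", "from", "to") %in% names(edges)))
  nodes$node_id <- as.character(nodes$node_id)
  edges$edge_id <- as.character(edges$edge_id)
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (is.null(edges$street_id)) edges$street_id <- edges$edge_id
  if (anyDuplicated(edges$edge_id)) stop("duplicate edge_id in edges")
  if (anyDuplicated(nodes$node_id)) stop("duplicate node_id in nodes")
  bad <- setdiff(c(edges$from, edges$to), nodes$node_id)
  if (length(bad)) stop("edge endpoint(s) not in nodes: ", paste(bad, collapse = ", "))

  if (is.null(geoms)) {
    geoms <- lapply(seq_len(nrow(edges)), function(i) {
      a <- nodes[match(edges$from[i], nodes$node_id), c("x", "y")]
      b <- nodes[match(edges$to[i], nodes$node_id), c("x", "y")]
      rbind(as.numeric(a), as.numeric(b))
    })
    names(geoms) <- edges$edge_id
  }
  glen <- vapply(edges$edge_id, function(e) polyline_length(geoms[[e]]), 0)
  if (is.null(edges$length_m)) {
    edges$length_m <- unname(glen)
  } else {
    rel <- abs(edges$length_m - glen) / pmax(glen, 1e-12)
    if (any(rel > 1e-6))
      stop("edge length_m inconsistent with polyline geometry for edge(s): ",
           paste(edges$edge_id[rel > 1e-6], collapse = ", "))
  }
  if (any(edges$length_m <= 0)) stop("edges must have positive length")

  net <- structure(list(nodes = nodes, edges = edges, geoms = geoms,
                        addresses = NULL, parcels = parcels %||% list()),
                   class = "street_network")
  if (!is.null(addresses) && nrow(addresses)) {
    stopifnot(all(c("x", "y", "number") %in% names(addresses)))
    if (is.null(addresses$edge_id) || is.null(addresses$t)) {
      sn <- snap_points_to_edges(net, addresses$x, addresses$y)
      addresses$edge_id <- sn$edge_id
      addresses$t <- sn$t
    }
    addresses$address_id <- addresses$address_id %||% seq_len(nrow(addresses))
    net$addresses <- addresses
  }
  for (p in net$parcels) {
    if (!p$category %in% LAND_USE_CATEGORIES)
      stop("unknown land-use category: ", p$category)
  }
  net
}

#' Five land-use categories used throughout the package
#' @export
LAND_USE_CATEGORIES <- c("residential", "commercial", "industrial",
                         "tertiary_campus", "open_space")

# snap arbitrary points to their nearest edge; returns edge_id, t, dist
snap_points_to_edges <- function(network, px, py) {
  n <- length(px)
  edge_id <- character(n); tt <- numeric(n); dd <- rep(Inf, n)
  for (e in network$edges$edge_id) {
    g <- network$geoms[[e]]
    cl <- polyline_cumlen(g)
    for (i in seq_len(nrow(g) - 1L)) {
      r <- point_segment_dist(px, py, g[i, 1], g[i, 2], g[i + 1L, 1], g[i + 1L, 2])
      better <- r$dist < dd
      if (any(better)) {
        dd[better] <- r$dist[better]
        tt[better] <- cl[i] + r$t[better]
        edge_id[better] <- e
      }
    }
  }
  list(edge_id = edge_id, t = tt, dist = dd)
}

as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    d = data.frame(from = network$edges$from, to = network$edges$to,
                   weight = network$edges$length_m,
                   edge_id = network$edges$edge_id),
    directed = FALSE,  # one-way restrictions ignored: pedestrian traversal
    vertices = network$nodes$node_id)
}

node_degrees <- function(network) {
  tab <- table(c(network$edges$from, network$edges$to))
  out <- stats::setNames(rep(0L, nrow(network$nodes)), network$nodes$node_id)
  out[names(tab)] <- as.integer(tab)
  out
}

#' @export
print.street_network <- function(x, ...) {
  cat("Street network:", nrow(x$nodes), "junctions,", nrow(x$edges), "edges (",
      round(sum(x$edges$length_m) / 1000, 2), "km ),",
      if (is.null(x$addresses)) 0L else nrow(x$addresses), "address points,",
      length(x$parcels), "land-use parcels\n")
  invisible(x)
}

#' Read a street network from GeoJSON files
#'
#' Road centrelines are LineString features (optional properties `street_id`,
#' `length_m`). Each LineString is split at junction points: interior
#' vertices that coincide with an endpoint or vertex of another feature
#' become junction nodes, so a single road crossing several junctions yields
#' one edge per inter-junction piece. Addresses are Point features with a
#' `number` property; land-use parcels are Polygon features with a
#' `category` property (exterior ring used).
#'
#' @param network_path GeoJSON FeatureCollection of LineStrings.
#' @param addresses_path,landuse_path Optional GeoJSON FeatureCollections.
#' @param snap_tol Coordinate tolerance (m) for identifying shared junction
#'   points.
#' @return A `street_network`.
#' @export
read_street_network <- function(network_path, addresses_path = NULL,
                                landuse_path = NULL, snap_tol = 0.01) {
  gj <- jsonlite::read_json(network_path)
  feats <- gj$features
  lines <- lapply(feats, function(f) {
    stopifnot(identical(f$geometry$type, "LineString"))
    do.call(rbind, lapply(f$geometry$coordinates, function(c2) as.numeric(unlist(c2))))
  })
  props <- lapply(feats, function(f) f$properties %||% list())

  key <- function(x, y) paste(round(x / snap_tol), round(y / snap_tol))
  # junction keys: feature endpoints plus any vertex used by >= 2 features
  all_keys <- unlist(lapply(lines, function(m) key(m[, 1], m[, 2])))
  vertex_count <- table(all_keys)
  end_keys <- unlist(lapply(lines, function(m)
    key(m[c(1, nrow(m)), 1], m[c(1, nrow(m)), 2])))
  junction_keys <- union(end_keys, names(vertex_count)[vertex_count >= 2])

  nodes_x <- c(); nodes_y <- c(); node_key <- character(0)
  get_node <- function(x, y) {
    k <- key(x, y)
    i <- match(k, node_key)
    if (is.na(i)) {
      node_key[length(node_key) + 1L] <<- k
      nodes_x[length(nodes_x) + 1L] <<- x
      nodes_y[length(nodes_y) + 1L] <<- y
      i <- length(node_key)
    }
    sprintf("N%04d", i)
  }

  edges <- list(); geoms <- list(); eid <- 0L
  for (fi in seq_along(lines)) {
    m <- lines[[fi]]
    ks <- key(m[, 1], m[, 2])
    is_junc <- ks %in% junction_keys
    is_junc[c(1, nrow(m))] <- TRUE
    cuts <- which(is_junc)
    street <- props[[fi]]$street_id %||% sprintf("F%03d", fi)
    for (ci in seq_len(length(cuts) - 1L)) {
      piece <- m[cuts[ci]:cuts[ci + 1L], , drop = FALSE]
      eid <- eid + 1L
      id <- sprintf("E%04d", eid)
      edges[[eid]] <- data.frame(
        edge_id = id,
        from = get_node(piece[1, 1], piece[1, 2]),
        to = get_node(piece[nrow(piece), 1], piece[nrow(piece), 2]),
        street_id = street, stringsAsFactors = FALSE)
      geoms[[id]] <- unname(piece)
    }
  }
  edges <- do.call(rbind, edges)
  nodes <- data.frame(node_id = sprintf("N%04d", seq_along(node_key)),
                      x = nodes_x, y = nodes_y, stringsAsFactors = FALSE)

  addresses <- NULL
  if (!is.null(addresses_path)) {
    aj <- jsonlite::read_json(addresses_path)
    addresses <- do.call(rbind, lapply(aj$features, function(f) {
      data.frame(x = as.numeric(f$geometry$coordinates[[1]]),
                 y = as.numeric(f$geometry$coordinates[[2]]),
                 number = as.integer(f$properties$number))
    }))
  }
  parcels <- NULL
  if (!is.null(landuse_path)) {
    lj <- jsonlite::read_json(landuse_path)
    parcels <- lapply(lj$features, function(f) {
      ring <- f$geometry$coordinates[[1]]
      list(category = f$properties$category,
           coords = do.call(rbind, lapply(ring, function(c2) as.numeric(unlist(c2)))))
    })
  }
  street_network(nodes, edges, geoms, addresses, parcels)
}

fmt_coord <- function(x) format(round(x, 3), nsmall = 0, trim = TRUE, scientific = FALSE)

geojson_feature <- function(type, coords_txt, props_txt) {
  sprintf('{"type":"Feature","geometry":{"type":"%s","coordinates":%s},"properties":{%s}}',
          type, coords_txt, props_txt)
}

#' Write a street network (and optional school points) to GeoJSON
#'
#' Writes `streets.geojson` (LineStrings), `addresses.geojson` (Points),
#' `landuse.geojson` (Polygons) and, when schools are given,
#' `schools.geojson` into `dir`. Output is byte-deterministic for identical
#' inputs (fixed number formatting, fixed feature order).
#'
#' @param network A `street_network`.
#' @param dir Output directory (created if needed).
#' @param schools Optional data frame with `school_id`, `x`, `y`.
#' @return Invisibly, the paths written.
#' @export
write_street_network <- function(network, dir, schools = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  fc <- function(features) paste0('{"type":"FeatureCollection","features":[',
                                  paste(features, collapse = ","), "]}")
  line_feats <- vapply(seq_len(nrow(network$edges)), function(i) {
    e <- network$edges[i, ]
    g <- network$geoms[[e$edge_id]]
    coords <- paste0("[", paste(sprintf("[%s,%s]", fmt_coord(g[, 1]), fmt_coord(g[, 2])),
                                collapse = ","), "]")
    geojson_feature("LineString", coords,
                    sprintf('"edge_id":"%s","street_id":"%s","length_m":%s',
                            e$edge_id, e$street_id, fmt_coord(e$length_m)))
  }, "")
  p <- file.path(dir, "streets.geojson")
  writeLines(fc(line_feats), p); paths <- c(paths, p)

  if (!is.null(network$addresses)) {
    a <- network$addresses
    ft <- vapply(seq_len(nrow(a)), function(i)
      geojson_feature("Point", sprintf("[%s,%s]", fmt_coord(a$x[i]), fmt_coord(a$y[i])),
                      sprintf('"number":%d', as.integer(a$number[i]))), "")
    p <- file.path(dir, "addresses.geojson")
    writeLines(fc(ft), p); paths <- c(paths, p)
  }
  if (length(network$parcels)) {
    ft <- vapply(network$parcels, function(pc) {
      ring <- rbind(pc$coords, pc$coords[1, ])
      coords <- paste0("[[", paste(sprintf("[%s,%s]", fmt_coord(ring[, 1]),
                                           fmt_coord(ring[, 2])), collapse = ","), "]]")
      geojson_feature("Polygon", coords, sprintf('"category":"%s"', pc$category))
    }, "")
    p <- file.path(dir, "landuse.geojson")
    writeLines(fc(ft), p); paths <- c(paths, p)
  }
  if (!is.null(schools)) {
    ft <- vapply(seq_len(nrow(schools)), function(i)
      geojson_feature("Point", sprintf("[%s,%s]", fmt_coord(schools$x[i]),
                                       fmt_coord(schools$y[i])),
                      sprintf('"school_id":"%s"', schools$school_id[i])), "")
    p <- file.path(dir, "schools.geojson")
    writeLines(fc(ft), p); paths <- c(paths, p)
  }
  invisible(paths)
}
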