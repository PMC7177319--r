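#' Compute a street-network service area (buffer zone) around a school
#'
#' The buffer zone is the set of network locations whose shortest-path
#' distance along the road network from the school's snapped address point is
#' at most `threshold_m` (default 500 m, the conventional school-catchment
#' audit distance). The school point is snapped to the nearest edge within
#' `snap_radius_m`; edges wholly inside the threshold are covered in full,
#' frontier edges carry partial covered intervals measured in metres from the
#' edge's `from` endpoint. Coverage is half-open: an edge touched only at a
#' boundary point is not covered. A disconnected origin component smaller
#' than the threshold simply yields that component.
#'
#' @param network A `street_network`.
#' @param school Numeric `c(x, y)` school address point, or a one-row data
#'   frame with `x`, `y` (and optionally `school_id`).
#' @param threshold_m Network distance threshold in metres (default 500).
#' @param snap_radius_m Maximum snapping distance in metres (default 50).
#' @param school_id Identifier attached to the result.
#' @return An object of class `buffer_zone`: list with `school_id`, `origin`
#'   (edge, curve position, coordinates), `threshold_m`, `covered` (data
#'   frame `edge_id`, `start`, `end`) and `node_dist` (named vector of
#'   shortest network distances to every junction).
#' @export
compute_service_area <- function(network, school, threshold_m = 500,
                                 snap_radius_m = 50, school_id = NULL) {
  if (is.data.frame(school)) {
    school_id <- school_id %||% school$school_id[1]
    school <- c(school$x[1], school$y[1])
  }
  school_id <- school_id %||% "school"
  stopifnot(threshold_m >= 0)
  sn <- snap_points_to_edges(network, school[1], school[2])
  if (sn$dist > snap_radius_m)
    stop("geocoding error: school point is ", round(sn$dist, 1),
         " m from the nearest road (snap radius ", snap_radius_m, " m)")
  oe <- sn$edge_id
  ot <- sn$t
  g <- as_igraph(network)
  erow <- network$edges[match(oe, network$edges$edge_id), ]

  # shortest distance from the snapped origin to every junction: any path
  # leaves the origin edge through one of its endpoints
  du <- igraph::distances(g, v = erow$from, weights = igraph::E(g)$weight)[1, ]
  dv <- igraph::distances(g, v = erow$to, weights = igraph::E(g)$weight)[1, ]
  node_dist <- pmin(ot + du, (erow$length_m - ot) + dv)
  names(node_dist) <- names(du)

  covered <- vector("list", nrow(network$edges))
  for (i in seq_len(nrow(network$edges))) {
    e <- network$edges[i, ]
    L <- e$length_m
    iv <- matrix(numeric(0), ncol = 2)
    ra <- threshold_m - node_dist[[e$from]]
    rb <- threshold_m - node_dist[[e$to]]
    if (is.finite(ra) && ra > 0) iv <- rbind(iv, c(0, min(L, ra)))
    if (is.finite(rb) && rb > 0) iv <- rbind(iv, c(max(0, L - rb), L))
    if (e$edge_id == oe && threshold_m > 0)
      iv <- rbind(iv, c(max(0, ot - threshold_m), min(L, ot + threshold_m)))
    iv <- merge_intervals(iv)
    if (nrow(iv))
      covered[[i]] <- data.frame(edge_id = e$edge_id, start = iv[, 1], end = iv[, 2])
  }
  covered <- do.call(rbind, covered) %||%
    data.frame(edge_id = character(0), start = numeric(0), end = numeric(0))
  structure(list(school_id = school_id,
                 origin = list(edge_id = oe, t = ot,
                               x = school[1], y = school[2], snap_dist = sn$dist),
                 threshold_m = threshold_m,
                 covered = covered, node_dist = node_dist),
            class = "buffer_zone")
}

#' @export
print.buffer_zone <- function(x, ...) {
  cat("Buffer zone for", x$school_id, ":", x$threshold_m, "m threshold,",
      length(unique(x$covered$edge_id)), "edges touched,",
      round(sum(x$covered$end - x$covered$start) / 1000, 2), "km covered\n")
  invisible(x)
}

covered_length_by_edge <- function(buffer) {
  if (!nrow(buffer$covered)) return(stats::setNames(numeric(0), character(0)))
  tapply(buffer$covered$end - buffer$covered$start, buffer$covered$edge_id, sum)
}

#' Extract audit street segments from a buffer zone
#'
#' One street segment per maximal inter-junction road piece (edge)
#' intersecting the buffer. Each segment records its covered fraction,
#' whether coverage enters from both ends with a gap in the middle, and the
#' residence counts per street side (odd/even house-number parity). Segment
#' identifier codes follow the compound convention
#' `school.street.sequence`; side records append `.O` / `.E`.
#'
#' @param network A `street_network`.
#' @param buffer A `buffer_zone` computed on the same network.
#' @param school_id Identifier used in segment codes (default from buffer).
#' @return A data frame of class `segment_set`, one row per segment.
#' @export
extract_segments <- function(network, buffer, school_id = buffer$school_id) {
  eids <- unique(buffer$covered$edge_id)
  if (!length(eids))
    return(structure(empty_segment_df(), class = c("segment_set", "data.frame")))
  addr <- network$addresses
  rows <- lapply(eids, function(eid) {
    e <- network$edges[match(eid, network$edges$edge_id), ]
    iv <- buffer$covered[buffer$covered$edge_id == eid, , drop = FALSE]
    iv <- iv[order(iv$start), , drop = FALSE]
    covlen <- sum(iv$end - iv$start)
    L <- e$length_m
    eps <- 1e-6 * max(L, 1)
    both_ends <- nrow(iv) >= 2 && iv$start[1] <= eps && iv$end[nrow(iv)] >= L - eps
    a <- if (!is.null(addr)) addr[addr$edge_id == eid, , drop = FALSE] else NULL
    n_odd <- if (is.null(a)) 0L else sum(a$number %% 2 == 1)
    n_even <- if (is.null(a)) 0L else sum(a$number %% 2 == 0)
    in_iv <- function(t, k) any(t >= iv$start[k] - eps & t <= iv$end[k] + eps)
    res_start <- !is.null(a) && nrow(a) > 0 && any(vapply(a$t, in_iv, TRUE, k = 1L))
    res_end <- !is.null(a) && nrow(a) > 0 &&
      any(vapply(a$t, in_iv, TRUE, k = nrow(iv)))
    data.frame(edge_id = eid, street_id = e$street_id, length_m = L,
               from = e$from, to = e$to,
               coverage_fraction = min(covlen / L, 1),
               residences_odd = n_odd, residences_even = n_even,
               n_intervals = nrow(iv), covered_from_both_ends = both_ends,
               gap_m = if (both_ends) L - covlen else 0,
               res_at_covered_start = res_start, res_at_covered_end = res_end,
               stringsAsFactors = FALSE)
  })
  seg <- do.call(rbind, rows)
  seg <- seg[order(seg$street_id, seg$edge_id), ]
  seq_in_street <- stats::ave(seq_len(nrow(seg)), seg$street_id, FUN = seq_along)
  seg <- cbind(segment_id = sprintf("%s.%s.%02d", school_id, seg$street_id, seq_in_street),
               school_id = school_id, seg, stringsAsFactors = FALSE)
  rownames(seg) <- NULL
  structure(seg, class = c("segment_set", "data.frame"))
}

empty_segment_df <- function() {
  data.frame(segment_id = character(0), school_id = character(0),
             edge_id = character(0), street_id = character(0),
             length_m = numeric(0), from = character(0), to = character(0),
             coverage_fraction = numeric(0), residences_odd = integer(0),
             residences_even = integer(0), n_intervals = integer(0),
             covered_from_both_ends = logical(0), gap_m = numeric(0),
             res_at_covered_start = logical(0), res_at_covered_end = logical(0))
}

#' Duplicate segments into odd and even street sides
#'
#' Every segment has exactly two sides regardless of addressing: odd and
#' even, by house-number parity (the side without address points keeps its
#' canonical parity label).
#'
#' @param segments A `segment_set`.
#' @return Data frame with one row per (segment, side), `side` in
#'   `c("O", "E")` and the side's residence count.
#' @export
segment_sides <- function(segments) {
  if (!nrow(segments)) {
    return(data.frame(segment_id = character(0), side_id = character(0),
                      school_id = character(0), side = character(0),
                      residences = integer(0)))
  }
  out <- rbind(
    data.frame(segment_id = segments$segment_id, school_id = segments$school_id,
               side = "O", residences = segments$residences_odd,
               stringsAsFactors = FALSE),
    data.frame(segment_id = segments$segment_id, school_id = segments$school_id,
               side = "E", residences = segments$residences_even,
               stringsAsFactors = FALSE))
  out$side_id <- paste(out$segment_id, out$side, sep = ".")
  out[order(out$segment_id, out$side), c("segment_id", "side_id", "school_id",
                                         "side", "residences")]
}

#' Identify crossing-audit intersections inside a buffer
#'
#' Returns junctions of degree >= 3 (filtering out 'false' two-road
#' intersections) whose network distance from the school is within the
#' buffer threshold, each listing all connecting roads. The crossing-audit
#' frame is one audit per connecting road per intersection.
#'
#' @param network A `street_network`.
#' @param buffer A `buffer_zone`.
#' @return Data frame with `node_id`, `degree`, `x`, `y` and list-column
#'   `connecting_roads` (edge ids).
#' @export
identify_intersections <- function(network, buffer) {
  deg <- node_degrees(network)
  inside <- names(buffer$node_dist)[buffer$node_dist <= buffer$threshold_m]
  ids <- intersect(names(deg)[deg >= 3L], inside)
  if (!length(ids)) {
    out <- data.frame(node_id = character(0), degree = integer(0),
                      x = numeric(0), y = numeric(0))
    out$connecting_roads <- list()
    return(out)
  }
  out <- data.frame(node_id = ids,
                    degree = unname(deg[ids]),
                    x = network$nodes$x[match(ids, network$nodes$node_id)],
                    y = network$nodes$y[match(ids, network$nodes$node_id)],
                    stringsAsFactors = FALSE)
  out$connecting_roads <- lapply(ids, function(n)
    network$edges$edge_id[network$edges$from == n | network$edges$to == n])
  out
}

#' Apply the boundary inclusion/exclusion and extension protocol rules
#'
#' Two rules govern segments at the buffer boundary: (1) a partially covered
#' segment with no residence on either side is excluded from the audit and
#' logged with its length; (2) a segment covered from both ends is extended
#' to one full segment (coverage set to 1) when at least one residence lies
#' in each covered end and the majority of the segment length
#' (coverage fraction strictly > 0.5) is inside the original buffer; the
#' bridged gap length is logged. All other segments pass unchanged; fully
#' covered segments are never excluded.
#'
#' @param segments A `segment_set` from [extract_segments()].
#' @return List with `kept` (a `segment_set`), `exclusions` and `extensions`
#'   (log data frames).
#' @export
apply_protocol_rules <- function(segments) {
  stopifnot(is.data.frame(segments))
  partial <- segments$coverage_fraction < 1 - 1e-12
  no_res <- segments$residences_odd + segments$residences_even == 0
  excl <- partial & no_res
  ext <- partial & !excl & segments$covered_from_both_ends &
    segments$res_at_covered_start & segments$res_at_covered_end &
    segments$coverage_fraction > 0.5
  exclusions <- data.frame(segment_id = segments$segment_id[excl],
                           length_m = segments$length_m[excl],
                           reason = rep("boundary segment with no residence", sum(excl)),
                           stringsAsFactors = FALSE)
  extensions <- data.frame(segment_id = segments$segment_id[ext],
                           gap_m = segments$gap_m[ext],
                           reason = rep("partial coverage from both ends bridged", sum(ext)),
                           stringsAsFactors = FALSE)
  kept <- segments[!excl, , drop = FALSE]
  kept$coverage_fraction[kept$segment_id %in% extensions$segment_id] <- 1
  kept$gap_m[kept$segment_id %in% extensions$segment_id] <- 0
  rownames(kept) <- NULL
  list(kept = structure(kept, class = c("segment_set", "data.frame")),
       exclusions = exclusions, extensions = extensions)
}

#' Subdivide a long street segment into equal audit pieces
#'
#' Long segments are hard to audit consistently; the subdivision rule keeps
#' audit pieces at or below 200 m: a segment of 200 m or less stays whole,
#' between 200 and 400 m it is halved, between 400 and 600 m it is split in
#' thirds, and beyond 600 m into `ceiling(length / 200)` equal pieces (the
#' documented extrapolation of the halves/thirds rule). Pieces always sum to
#' the input length.
#'
#' @param length_m Segment length in metres (> 0).
#' @return Numeric vector of sub-segment lengths.
#' @examples
#' subdivide_segment(150)  # 150
#' subdivide_segment(350)  # 175 175
#' subdivide_segment(500)  # three equal thirds
#' @export
subdivide_segment <- function(length_m) {
  if (!is.numeric(length_m) || length(length_m) != 1L || is.na(length_m) ||
      length_m <= 0)
    stop("domain error: segment length must be a single positive number")
  n <- if (length_m <= 200) 1L
       else if (length_m <= 400) 2L
       else if (length_m <= 600) 3L
       else as.integer(ceiling(length_m / 200))
  rep(length_m / n, n)
}
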