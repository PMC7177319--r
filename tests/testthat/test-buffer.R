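test_that("service area covers whole and partial edges by shortest-path arithmetic", {
  net <- path_network()
  buf <- compute_service_area(net, c(0, 0), threshold_m = 500)
  cv <- buf$covered
  e1 <- cv[cv$edge_id == "e1", ]
  e2 <- cv[cv$edge_id == "e2", ]
  expect_equal(c(e1$start, e1$end), c(0, 300))   # O-A fully covered
  expect_equal(c(e2$start, e2$end), c(0, 200))   # A-B covered for 200 m
})

test_that("degenerate and error cases of the service area behave as specified", {
  net <- path_network()
  # threshold 0: only the origin point, no covered length
  buf0 <- compute_service_area(net, c(0, 0), threshold_m = 0)
  expect_equal(nrow(buf0$covered), 0L)
  # school too far from any road
  expect_error(compute_service_area(net, c(0, 500), threshold_m = 500),
               "geocoding")
  # mid-edge origin
  bufm <- compute_service_area(net, c(150, 0), threshold_m = 100)
  e1 <- bufm$covered[bufm$covered$edge_id == "e1", ]
  expect_equal(c(e1$start, e1$end), c(50, 250))
})

test_that("service area matches a brute-force shortest-path oracle and is monotone", {
  net <- grid_network(4, 100)
  d <- fw_distances(net)
  origin <- "n2_2"
  on <- net$nodes[net$nodes$node_id == origin, ]
  for (threshold in c(120, 300, 500)) {
    buf <- compute_service_area(net, c(on$x, on$y), threshold_m = threshold)
    for (i in seq_len(nrow(net$edges))) {
      e <- net$edges[i, ]
      for (t in seq(5, e$length_m - 5, by = 10)) {
        expect_equal(buffer_covers(buf, e$edge_id, t),
                     fw_point_covered(d, origin, e$from, e$to, e$length_m,
                                      t, threshold),
                     info = sprintf("edge %s t=%g threshold=%g", e$edge_id, t,
                                    threshold))
      }
    }
  }
  # monotonicity: the 300 m zone is strictly contained in the 500 m zone
  b300 <- compute_service_area(net, c(on$x, on$y), threshold_m = 300)
  b500 <- compute_service_area(net, c(on$x, on$y), threshold_m = 500)
  for (i in seq_len(nrow(b300$covered))) {
    cv <- b300$covered[i, ]
    big <- b500$covered[b500$covered$edge_id == cv$edge_id, ]
    expect_true(any(big$start <= cv$start + 1e-9 & big$end >= cv$end - 1e-9))
  }
  expect_lt(sum(b300$covered$end - b300$covered$start),
            sum(b500$covered$end - b500$covered$start))
})

test_that("reading GeoJSON splits roads at junction points", {
  gj <- paste0(
    '{"type":"FeatureCollection","features":[',
    '{"type":"Feature","geometry":{"type":"LineString",',
    '"coordinates":[[0,0],[100,0],[200,0]]},"properties":{"street_id":"MAIN"}},',
    '{"type":"Feature","geometry":{"type":"LineString",',
    '"coordinates":[[100,0],[100,100]]},"properties":{"street_id":"SIDE"}}]}')
  f <- withr::local_tempfile(fileext = ".geojson")
  writeLines(gj, f)
  net <- read_street_network(f)
  # the road through 3 junctions becomes 2 segments
  expect_equal(sum(net$edges$street_id == "MAIN"), 2L)
  expect_equal(nrow(net$edges), 3L)
  expect_equal(nrow(net$nodes), 4L)
})

test_that("segment extraction attaches side parity from house numbers", {
  nodes <- data.frame(node_id = c("a", "b"), x = c(0, 100), y = 0)
  edges <- data.frame(edge_id = "e1", from = "a", to = "b")
  addr <- data.frame(x = c(10, 30, 50, 20, 40), y = c(5, 5, 5, -5, -5),
                     number = c(2, 4, 6, 1, 3))
  net <- street_network(nodes, edges, addresses = addr)
  buf <- compute_service_area(net, c(0, 0), threshold_m = 200)
  seg <- extract_segments(net, buf, school_id = "S")
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$residences_even, 3L)
  expect_equal(seg$residences_odd, 2L)
  sides <- segment_sides(seg)
  expect_equal(nrow(sides), 2L)
  expect_setequal(sides$side, c("O", "E"))
})

test_that("segment extraction partitions the covered length", {
  net <- grid_network(4, 100)
  on <- net$nodes[net$nodes$node_id == "n2_2", ]
  buf <- compute_service_area(net, c(on$x, on$y), threshold_m = 250)
  seg <- extract_segments(net, buf, school_id = "S")
  expect_equal(sum(seg$length_m * seg$coverage_fraction),
               sum(buf$covered$end - buf$covered$start), tolerance = 1e-9)
  expect_false(anyDuplicated(seg$segment_id) > 0)
})

test_that("intersections are buffer-interior junctions of degree >= 3", {
  net <- grid_network(4, 100)
  on <- net$nodes[net$nodes$node_id == "n2_2", ]
  buf <- compute_service_area(net, c(on$x, on$y), threshold_m = 150)
  ints <- identify_intersections(net, buf)
  # corners have degree 2 ('false' intersections) and are never returned
  expect_false(any(c("n1_1", "n4_1", "n1_4", "n4_4") %in% ints$node_id))
  expect_true(all(ints$degree >= 3))
  expect_equal(ints$degree, lengths(ints$connecting_roads))
  # a degree-4 node inside the buffer is returned with all connecting roads
  expect_true("n2_2" %in% ints$node_id)
  d <- fw_distances(net)
  deg3plus <- names(which(table(c(net$edges$from, net$edges$to)) >= 3))
  expect_setequal(ints$node_id, intersect(deg3plus,
                                          names(which(d["n2_2", ] <= 150))))
})

make_seg <- function(coverage, odd = 0L, even = 0L, both_ends = FALSE,
                     res_start = FALSE, res_end = FALSE, len = 100,
                     id = "S.X.01") {
  s <- data.frame(segment_id = id, school_id = "S", edge_id = "e", street_id = "X",
                  length_m = len, from = "a", to = "b",
                  coverage_fraction = coverage, residences_odd = odd,
                  residences_even = even, n_intervals = if (both_ends) 2L else 1L,
                  covered_from_both_ends = both_ends,
                  gap_m = if (both_ends) (1 - coverage) * len else 0,
                  res_at_covered_start = res_start, res_at_covered_end = res_end,
                  stringsAsFactors = FALSE)
  structure(s, class = c("segment_set", "data.frame"))
}

test_that("protocol rules exclude, extend and keep segments as specified", {
  # boundary segment with no residence: excluded, logged with length
  r <- apply_protocol_rules(make_seg(0.1, len = 15))
  expect_equal(nrow(r$kept), 0L)
  expect_equal(r$exclusions$length_m, 15)

  # covered from both ends, residences at both ends, 80% covered: extended
  r <- apply_protocol_rules(make_seg(0.8, odd = 1L, even = 1L, both_ends = TRUE,
                                     res_start = TRUE, res_end = TRUE, len = 250))
  expect_equal(r$kept$coverage_fraction, 1)
  expect_equal(r$extensions$gap_m, 50)

  # fully covered segment with no residences: kept (rule is boundary-only)
  r <- apply_protocol_rules(make_seg(1))
  expect_equal(nrow(r$kept), 1L)
  expect_equal(nrow(r$exclusions), 0L)

  # exactly half coverage does not extend (majority is strict)
  r <- apply_protocol_rules(make_seg(0.5, odd = 1L, both_ends = TRUE,
                                     res_start = TRUE, res_end = TRUE))
  expect_equal(r$kept$coverage_fraction, 0.5)
  expect_equal(nrow(r$extensions), 0L)
})

test_that("protocol rule safety properties hold over generated cases", {
  set.seed(7)
  for (i in 1:200) {
    seg <- make_seg(coverage = round(stats::runif(1, 0.05, 1), 2),
                    odd = stats::rpois(1, 0.7), even = stats::rpois(1, 0.7),
                    both_ends = stats::runif(1) < 0.5,
                    res_start = stats::runif(1) < 0.5,
                    res_end = stats::runif(1) < 0.5)
    r <- apply_protocol_rules(seg)
    has_res <- seg$residences_odd + seg$residences_even > 0
    # exclusion never removes a segment containing a residence
    if (has_res) expect_equal(nrow(r$kept), 1L)
    # extension never fires at coverage <= 0.5
    if (seg$coverage_fraction <= 0.5) expect_equal(nrow(r$extensions), 0L)
  }
})

test_that("segment subdivision follows the halves/thirds rule and sums exactly", {
  expect_equal(subdivide_segment(150), 150)
  expect_equal(subdivide_segment(350), c(175, 175))
  expect_equal(subdivide_segment(500), rep(500 / 3, 3))
  expect_equal(subdivide_segment(200), 200)        # boundary: stays whole
  expect_equal(subdivide_segment(400), c(200, 200))
  expect_equal(subdivide_segment(900), rep(180, 5)) # documented extrapolation
  expect_error(subdivide_segment(0), "domain")
  expect_error(subdivide_segment(-5), "domain")
  for (L in seq(10, 1200, by = 37)) {
    pieces <- subdivide_segment(L)
    expect_equal(sum(pieces), L)
    if (L <= 600) expect_true(all(pieces <= 200 + 1e-9))
  }
})
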