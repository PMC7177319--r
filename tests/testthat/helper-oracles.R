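# Independent oracles and small fixtures shared across tests.

# Brute-force all-pairs shortest paths (Floyd-Warshall) on a small network;
# deliberately independent of the igraph-based implementation.
fw_distances <- function(network) {
  ids <- network$nodes$node_id
  n <- length(ids)
  d <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(d) <- 0
  for (i in seq_len(nrow(network$edges))) {
    e <- network$edges[i, ]
    a <- match(e$from, ids); b <- match(e$to, ids)
    d[a, b] <- min(d[a, b], e$length_m)
    d[b, a] <- d[a, b]
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# is the point at curve position t on edge (from, to, L) within threshold of
# the origin node, by brute force?
fw_point_covered <- function(d, origin, from, to, L, t, threshold) {
  min(d[origin, from] + t, d[origin, to] + (L - t)) <= threshold
}

# interval membership in a buffer_zone's covered table
buffer_covers <- function(buffer, edge_id, t, eps = 1e-9) {
  cv <- buffer$covered[buffer$covered$edge_id == edge_id, , drop = FALSE]
  nrow(cv) > 0 && any(t >= cv$start - eps & t <= cv$end + eps)
}

# simple path network O - A - B with 300 m edges
path_network <- function() {
  street_network(
    nodes = data.frame(node_id = c("O", "A", "B"), x = c(0, 300, 600), y = 0),
    edges = data.frame(edge_id = c("e1", "e2"), from = c("O", "A"),
                       to = c("A", "B")))
}

# n x n grid with `spacing` m edges
grid_network <- function(n = 4, spacing = 100) {
  idx <- function(i, j) paste0("n", i, "_", j)
  nodes <- expand.grid(i = seq_len(n), j = seq_len(n))
  nodes <- data.frame(node_id = idx(nodes$i, nodes$j),
                      x = (nodes$i - 1) * spacing, y = (nodes$j - 1) * spacing)
  eh <- expand.grid(i = seq_len(n - 1), j = seq_len(n))
  ev <- expand.grid(i = seq_len(n), j = seq_len(n - 1))
  edges <- rbind(
    data.frame(from = idx(eh$i, eh$j), to = idx(eh$i + 1, eh$j)),
    data.frame(from = idx(ev$i, ev$j), to = idx(ev$i, ev$j + 1)))
  edges$edge_id <- paste0("e", seq_len(nrow(edges)))
  street_network(nodes, edges)
}

# ANOVA mean squares via stats::aov on long data: an independent
# sums-of-squares route to the ICC ingredients
aov_mean_squares <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  long <- data.frame(value = as.vector(mat),
                     target = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
  tw <- summary(stats::aov(value ~ target + rater, data = long))[[1]]
  ow <- summary(stats::aov(value ~ target, data = long))[[1]]
  list(msr = tw["target", "Mean Sq"], msc = tw["rater", "Mean Sq"],
       mse = tw["Residuals", "Mean Sq"], msw = ow["Residuals", "Mean Sq"])
}

oracle_icc <- function(mat, model) {
  ms <- aov_mean_squares(mat)
  n <- nrow(mat); k <- ncol(mat)
  switch(model,
    one_way = (ms$msr - ms$msw) / (ms$msr + (k - 1) * ms$msw),
    two_way_consistency = (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse),
    two_way_agreement = (ms$msr - ms$mse) /
      (ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse)))
}

# raw value of an item that yields its maximum (resp. minimum) points
best_raw <- function(item) {
  if (!is.null(item$recode)) as.integer(names(item$recode)[which.max(item$recode)])
  else item$max
}
least_raw <- function(item) {
  if (!is.null(item$recode)) as.integer(names(item$recode)[which.min(item$recode)])
  else item$min
}

# audit table for `unit_ids` where every positive-sub-scale item is at its
# best raw value and every negative-sub-scale item at its least-penalising
# raw value (best_case = TRUE), or the reverse
extreme_audits <- function(scheme, kind, unit_ids, side = NULL, subunit = NULL,
                           best_case = TRUE) {
  df <- data.frame(unit_id = unit_ids, stringsAsFactors = FALSE)
  if (!is.null(side)) df$side <- side
  if (!is.null(subunit)) df$subunit <- subunit
  for (nm in scheme_item_names(scheme, kind)) {
    it <- scheme$items[[nm]]
    positive <- scheme$subscales[[it$subscale]]$sign > 0
    take_best <- xor(!positive, best_case)
    df[[nm]] <- if (take_best) best_raw(it) else least_raw(it)
  }
  as_audit_set(df, scheme)
}

# full best-case school audits: both sides of one segment, one 3-way
# intersection (three crossing audits)
best_case_school <- function(scheme) {
  list(
    route_side = extreme_audits(scheme, "route_side",
                                rep("SCH01.H01.01", 2), side = c("O", "E")),
    segment_side = extreme_audits(scheme, "segment_side",
                                  rep("SCH01.H01.01", 2), side = c("O", "E")),
    crossing = extreme_audits(scheme, "crossing", rep("N0001", 3),
                              subunit = c("e1", "e2", "e3")))
}

# audit frame with n bare segments (and optionally an intersection) for
# driving generate_audits without a network
make_seg_frame <- function(n, with_intersection = TRUE) {
  segs <- data.frame(segment_id = sprintf("S.H01.%02d", seq_len(n)),
                     stringsAsFactors = FALSE)
  ints <- NULL
  if (with_intersection) {
    ints <- data.frame(node_id = "N0001", degree = 3L, x = 0, y = 0,
                       stringsAsFactors = FALSE)
    ints$connecting_roads <- list(c("e1", "e2", "e3"))
  }
  list(segments = segs, intersections = ints, culdesacs = NULL)
}

# minimal scheme text for targeted unit tests
mini_scheme_yaml <- function(cap = 2) {
  sprintf(
"grand_max: %d
cross_domain: {}
subscales:
  - name: s1
    section: segment
    unit_kind: segment_side
    valence: positive
    cap: %d
    items:
      - {name: a, min: 0, max: 1}
      - {name: b, min: 0, max: 1}
      - {name: c, min: 0, max: 1}
", cap, cap)
}

load_scheme_text <- function(txt) {
  f <- tempfile(fileext = ".yaml")
  writeLines(txt, f)
  on.exit(unlink(f))
  load_scheme(f)
}

# shared small simulated study, built once per test session
cached_sim <- local({
  sim <- NULL
  function() {
    if (is.null(sim))
      sim <<- simulate_study(city_config(seed = 42), macro = TRUE,
                             resolution_m = 8)
    sim
  }
})
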