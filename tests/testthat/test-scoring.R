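test_that("sub-scale scores sum recoded items and truncate at the cap", {
  sch <- load_scheme_text(mini_scheme_yaml(cap = 2))
  aud <- as_audit_set(data.frame(unit_id = c("u1", "u2"), side = "O",
                                 a = c(1, 0), b = c(1, 0), c = c(1, 0)), sch)
  sc <- score_units(aud, sch)
  expect_equal(sc$raw, c(3, 0))
  expect_equal(sc$capped, c(2, 0))  # truncation at cap; zero case stays zero
})

test_that("recoded and item-capped values feed the sub-scale sums", {
  sch <- default_scheme()
  aud <- extreme_audits(sch, "segment_side", "u1", side = "O")
  # few_traffic_lanes: raw 1 lane recodes to 3 points
  expect_equal(aud$few_traffic_lanes, 1)
  df <- as.data.frame(aud)
  df$few_traffic_lanes <- 8   # 8 lanes recode to 0 points
  sc_best <- score_units(aud, sch)
  sc_worse <- score_units(as_audit_set(df, sch), sch)
  delta <- sc_best$capped[sc_best$subscale == "traffic_exposure_low"] -
    sc_worse$capped[sc_worse$subscale == "traffic_exposure_low"]
  expect_equal(delta, 3)
  # open-ended count item capped per item: 50 street trees score as 4
  raud <- extreme_audits(sch, "route_side", "u1", side = "O")
  df2 <- as.data.frame(raud)
  df2$street_trees <- 50
  sc_ref <- score_units(raud, sch)
  sc2 <- score_units(as_audit_set(df2, sch), sch)
  expect_equal(sc2$capped[sc2$subscale == "aesthetics_positive"],
               sc_ref$capped[sc_ref$subscale == "aesthetics_positive"])
})

test_that("a best-case segment-side audit attains every configured sub-scale cap", {
  sch <- default_scheme()
  sc <- score_units(extreme_audits(sch, "segment_side", "u1", side = "O"), sch)
  pos <- sc[sc$sign > 0, ]
  caps <- vapply(pos$subscale, function(nm) sch$subscales[[nm]]$cap, 0)
  expect_equal(pos$capped, unname(caps))
  neg <- sc[sc$sign < 0, ]
  expect_equal(neg$capped, rep(0, nrow(neg)))
})

test_that("the best-case school attains the scheme grand maximum and cross-domain maxima", {
  sch <- default_scheme()
  summ <- aggregate_school(best_case_school(sch), sch, side_scope = "combined")
  expect_equal(summ$grand, 210)
  expect_equal(unname(summ$cross_domain), c(27, 22, 11))
  # worst case attains the configured minimum: negative caps fully engaged
  worst <- list(
    route_side = extreme_audits(sch, "route_side", rep("s", 2),
                                side = c("O", "E"), best_case = FALSE),
    segment_side = extreme_audits(sch, "segment_side", rep("s", 2),
                                  side = c("O", "E"), best_case = FALSE),
    crossing = extreme_audits(sch, "crossing", rep("n", 3),
                              subunit = c("e1", "e2", "e3"), best_case = FALSE))
  wsumm <- aggregate_school(worst, sch)
  neg_caps <- sum(vapply(Filter(function(s) s$sign < 0 && isTRUE(s$scored),
                                sch$subscales),
                         function(s) min(s$cap, sum(vapply(s$items,
                           snaudit:::item_max_points, 0))), 0))
  expect_equal(wsumm$grand, -neg_caps)
})

test_that("improving an item never decreases the grand score (monotonicity)", {
  sch <- default_scheme()
  set.seed(11)
  cfg <- city_config(seed = 11)
  segs <- make_seg_frame(5)
  aud <- generate_audits(segs, sch, cfg, school_id = "S")
  base <- aggregate_school(aud, sch)$grand
  for (rep_i in 1:40) {
    kind <- sample(c("route_side", "segment_side", "crossing"), 1)
    items <- scheme_item_names(sch, kind)
    nm <- sample(items, 1)
    it <- sch$items[[nm]]
    df <- as.data.frame(aud[[kind]])
    row <- sample(nrow(df), 1)
    pos <- sch$subscales[[it$subscale]]$sign > 0
    target_raw <- if (pos) best_raw(it) else least_raw(it)
    df[[nm]][row] <- target_raw
    aud2 <- aud
    aud2[[kind]] <- as_audit_set(df, sch)
    expect_gte(aggregate_school(aud2, sch)$grand + 1e-12, base)
  }
})

test_that("combined section means lie between odd and even means", {
  sim <- cached_sim()
  ids <- unique(vapply(sim$summaries, `[[`, "", "school_id"))
  for (id in ids[1:4]) {
    s <- lapply(c("odd", "even", "combined"), function(sc)
      sim$summaries[[paste(id, sc, sep = ".")]])
    for (sec in c("route_dlu", "route_streetscape", "route_aesthetics", "segment")) {
      v <- vapply(s, function(x) x$sections[[sec]], 0)
      expect_gte(v[3], min(v[1:2]) - 1e-9)
      expect_lte(v[3], max(v[1:2]) + 1e-9)
    }
  }
})

test_that("the crossing component is bit-identical across side scopes", {
  sim <- cached_sim()
  ids <- unique(vapply(sim$summaries, `[[`, "", "school_id"))
  for (id in ids) {
    o <- sim$summaries[[paste(id, "odd", sep = ".")]]
    e <- sim$summaries[[paste(id, "even", sep = ".")]]
    expect_identical(o$sections[["crossing"]], e$sections[["crossing"]])
  }
})

test_that("identical audits on every unit give the single-unit score as mean", {
  sch <- default_scheme()
  one <- best_case_school(sch)
  many <- list(
    route_side = as_audit_set(do.call(rbind, lapply(1:4, function(i) {
      d <- as.data.frame(one$route_side); d$unit_id <- paste0("s", i); d
    })), sch),
    segment_side = as_audit_set(do.call(rbind, lapply(1:4, function(i) {
      d <- as.data.frame(one$segment_side); d$unit_id <- paste0("s", i); d
    })), sch),
    crossing = one$crossing)
  expect_equal(aggregate_school(many, sch)$grand,
               aggregate_school(one, sch)$grand)
})

test_that("empty sections are reported missing, never silently zero", {
  sch <- default_scheme()
  partial <- best_case_school(sch)["segment_side"]
  summ <- aggregate_school(partial, sch)
  expect_true(summ$incomplete)
  expect_true(is.na(summ$grand))
  expect_true(is.na(summ$sections[["route_dlu"]]))
  expect_false(is.na(summ$sections[["segment"]]))
})

test_that("per-intersection crossing aggregation sums connecting-road audits", {
  sch <- default_scheme()
  aud <- best_case_school(sch)
  s_audit <- aggregate_school(aud, sch, crossing_unit = "audit")
  s_int <- aggregate_school(aud, sch, crossing_unit = "intersection")
  # one 3-way intersection of best-case audits: 3 x 35 as a sum, 35 as a mean
  expect_equal(s_audit$sections[["crossing"]], 35)
  expect_equal(s_int$sections[["crossing"]], 105)
})

test_that("cross-domain scores match a direct summation oracle", {
  sch <- default_scheme()
  set.seed(3)
  cfg <- city_config(seed = 3)
  aud <- generate_audits(make_seg_frame(6), sch, cfg, school_id = "S")
  summ <- aggregate_school(aud, sch, side_scope = "combined")
  for (nm in names(sch$cross_domain)) {
    expected <- 0
    for (inm in sch$cross_domain[[nm]]$items) {
      it <- sch$items[[inm]]
      tab <- aud[[it$unit_kind]]
      vals <- pmin(if (!is.null(it$recode))
        unname(it$recode[as.character(tab[[inm]])]) else tab[[inm]], it$cap)
      expected <- expected + mean(vals)
    }
    expect_equal(unname(summ$cross_domain[nm]), expected)
  }
})

test_that("paired concordance tables have one row per school and react to sides", {
  sim <- cached_sim()
  expect_equal(nrow(sim$paired), 12L)
  expect_true(all(c("grand_odd", "grand_even", "pedestrian_design_odd",
                    "crossing_combined") %in% names(sim$paired)))
  # identical sides -> zero paired differences
  sch <- default_scheme()
  aud <- best_case_school(sch)
  summs <- lapply(c("odd", "even"), function(sc)
    aggregate_school(aud, sch, side_scope = sc, school_id = "S1"))
  p <- concordance_inputs(summs)
  expect_equal(p$grand_odd, p$grand_even)
  # missing side -> school dropped with warning
  expect_warning(p2 <- concordance_inputs(summs[1]), "lacks a side scope")
  expect_equal(nrow(p2), 0L)
})
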