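SECTION_LABELS <- c(route_dlu = "destinations_land_use",
                    route_streetscape = "positive_streetscape",
                    route_aesthetics = "aesthetics_social",
                    segment = "segment",
                    crossing = "crossing")

#' Score audited units against a scheme
#'
#' Computes every sub-scale score for every row of an audit set: member item
#' raw values are recoded (and item-capped), summed, and the sum truncated
#' at the sub-scale cap. Negative-valence sub-scales are capped first and
#' carry sign -1 into any aggregate (cap-then-negate).
#'
#' @param audits An `audit_set` (see [read_audits()], [as_audit_set()]).
#' @param scheme A `scoring_scheme`.
#' @return Long data frame: one row per (unit, sub-scale) with `unit_id`,
#'   `side`, `subunit`, `subscale`, `section`, `sign`, `raw`, `capped`,
#'   `signed` (= sign * capped) and `scored` (FALSE for recorded-only
#'   sub-scales such as cul-de-sac amenities).
#' @export
score_units <- function(audits, scheme) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  kind <- audit_unit_kind(audits)
  if (is.null(kind)) stop("audits must be an audit_set (see as_audit_set)")
  subs <- Filter(function(s) s$unit_kind == kind, scheme$subscales)
  out <- lapply(subs, function(s) {
    member <- vapply(s$items, `[[`, "", "name")
    missing_cols <- setdiff(member, names(audits))
    if (length(missing_cols))
      stop("audit table lacks item column(s) for sub-scale '", s$name, "': ",
           paste(missing_cols, collapse = ", "))
    pts <- vapply(s$items, function(it) item_points(it, audits[[it$name]]),
                  numeric(nrow(audits)))
    raw <- if (nrow(audits) == 1L) sum(pts) else rowSums(pts)
    capped <- pmin(raw, s$cap)
    data.frame(unit_id = audits$unit_id,
               side = audits$side %||% NA_character_,
               subunit = audits$subunit %||% NA_character_,
               subscale = s$name, section = s$section, sign = s$sign,
               raw = raw, capped = capped, signed = s$sign * capped,
               scored = isTRUE(s$scored), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-intersection crossing scores
#'
#' The condensed-protocol analysis cannot attribute crossing audits to a
#' street side, so crossing scores are reported per intersection as the sum
#' over that intersection's connecting-road audits.
#'
#' @param crossing_audits An `audit_set` of unit kind `crossing`
#'   (`unit_id` = intersection, `subunit` = connecting road).
#' @param scheme A `scoring_scheme`.
#' @return Data frame `intersection`, `n_roads`, `value` (signed sum over
#'   all scored crossing sub-scales of all connecting-road audits).
#' @export
crossing_scores <- function(crossing_audits, scheme) {
  sc <- score_units(crossing_audits, scheme)
  sc <- sc[sc$scored, , drop = FALSE]
  per_audit <- stats::aggregate(signed ~ unit_id + subunit, sc, sum)
  agg <- stats::aggregate(signed ~ unit_id, per_audit, sum)
  n <- stats::aggregate(subunit ~ unit_id, per_audit, length)
  data.frame(intersection = agg$unit_id, n_roads = n$subunit[match(agg$unit_id, n$unit_id)],
             value = agg$signed, stringsAsFactors = FALSE)
}

#' Aggregate audit scores to a school-level summary
#'
#' School-level sub-scale scores are unweighted means over the audited units
#' in scope; section scores are the signed sums of their sub-scale means;
#' the overall grand score is the signed sum over all scored valence
#' sub-scales. Cross-domain sub-scales are sums of school-level item
#' averages over their member items. Route and segment units are filtered by
#' street side for the `odd`/`even` scopes; crossing audits have no side, so
#' the crossing component is identical across side scopes.
#'
#' @param audits Named list of `audit_set`s, any of `route_side`,
#'   `segment_side`, `crossing`, `cul_de_sac` (cul-de-sac amenities are
#'   recorded but never scored).
#' @param scheme A `scoring_scheme`.
#' @param side_scope `"combined"` (default), `"odd"` or `"even"`.
#' @param crossing_unit Unit over which crossing scores are averaged:
#'   `"audit"` (default; one connecting-road audit is one unit, so the
#'   best-case school attains the scheme grand maximum) or `"intersection"`
#'   (per-intersection sums, the condensed-protocol reporting convention).
#' @param school_id School identifier (default taken from the audits).
#' @return An object of class `school_summary`: `school_id`, `side_scope`,
#'   `sections` (named numeric, `NA` for a section with no units in scope),
#'   `subscale_means`, `cross_domain`, `grand` (`NA` when any scored section
#'   is missing; never a silent zero), `n_units`, `incomplete`.
#' @export
aggregate_school <- function(audits, scheme,
                             side_scope = c("combined", "odd", "even"),
                             crossing_unit = c("audit", "intersection"),
                             school_id = NULL) {
  side_scope <- match.arg(side_scope)
  crossing_unit <- match.arg(crossing_unit)
  stopifnot(is.list(audits))
  if (is.null(school_id)) {
    for (a in audits) if (!is.null(a$school_id)) { school_id <- a$school_id[1]; break }
    school_id <- school_id %||% "school"
  }

  in_scope <- function(df) {
    if (side_scope == "combined" || is.null(df$side)) return(df)
    want <- if (side_scope == "odd") "O" else "E"
    df[df$side == want, , drop = FALSE]
  }

  subscale_means <- c(); n_units <- c()
  item_means <- stats::setNames(rep(NA_real_, length(scheme$items)), names(scheme$items))

  for (kind in c("route_side", "segment_side", "crossing")) {
    a <- audits[[kind]]
    subs <- Filter(function(s) s$unit_kind == kind && isTRUE(s$scored), scheme$subscales)
    if (is.null(a) || nrow(a) == 0L) {
      subscale_means[names(subs)] <- NA_real_
      n_units[kind] <- 0L
      next
    }
    a <- in_scope(a)
    if (!nrow(a)) {
      subscale_means[names(subs)] <- NA_real_
      n_units[kind] <- 0L
      next
    }
    sc <- score_units(a, scheme)
    sc <- sc[sc$scored, , drop = FALSE]
    if (kind == "crossing" && crossing_unit == "intersection") {
      # per-intersection sum of connecting-road audits, then mean over
      # intersections
      by_int <- stats::aggregate(capped ~ unit_id + subscale, sc, sum)
      m <- tapply(by_int$capped, by_int$subscale, mean)
      n_units[kind] <- length(unique(by_int$unit_id))
    } else {
      m <- tapply(sc$capped, sc$subscale, mean)
      n_units[kind] <- nrow(a)
    }
    subscale_means[names(m)] <- as.numeric(m)
    for (nm in scheme_item_names(scheme, kind)) {
      if (!is.null(a[[nm]]))
        item_means[nm] <- mean(item_points(scheme$items[[nm]], a[[nm]]))
    }
  }

  sections <- stats::setNames(rep(NA_real_, length(SECTION_LABELS)),
                              names(SECTION_LABELS))
  for (sec in names(sections)) {
    subs <- Filter(function(s) s$section == sec && isTRUE(s$scored), scheme$subscales)
    if (!length(subs)) next
    vals <- vapply(subs, function(s) s$sign * subscale_means[[s$name]], 0)
    sections[sec] <- if (anyNA(vals)) NA_real_ else sum(vals)
  }
  incomplete <- anyNA(sections)
  grand <- if (incomplete) NA_real_ else sum(sections)

  cross_domain <- vapply(names(scheme$cross_domain), function(nm) {
    v <- item_means[scheme$cross_domain[[nm]]$items]
    if (anyNA(v)) NA_real_ else sum(v)
  }, 0)

  structure(list(school_id = school_id, side_scope = side_scope,
                 crossing_unit = crossing_unit, sections = sections,
                 subscale_means = subscale_means, cross_domain = cross_domain,
                 item_means = item_means, grand = grand, n_units = n_units,
                 incomplete = incomplete),
            class = "school_summary")
}

#' @export
print.school_summary <- function(x, ...) {
  cat("School", x$school_id, "(", x$side_scope, "sides )\n")
  sec <- x$sections
  names(sec) <- SECTION_LABELS[names(sec)]
  for (nm in names(sec)) cat(sprintf("  %-24s %8.3f\n", nm, sec[nm]))
  for (nm in names(x$cross_domain))
    cat(sprintf("  %-24s %8.3f\n", nm, x$cross_domain[nm]))
  cat(sprintf("  %-24s %8.3f%s\n", "grand score", x$grand,
              if (x$incomplete) " (incomplete)" else ""))
  invisible(x)
}

#' Flatten school summaries into a score table
#'
#' @param summaries List of `school_summary` objects.
#' @return Data frame, one row per (school, side scope).
#' @export
summary_table <- function(summaries) {
  if (inherits(summaries, "school_summary")) summaries <- list(summaries)
  do.call(rbind, lapply(summaries, function(s) {
    row <- data.frame(school_id = s$school_id, side_scope = s$side_scope,
                      stringsAsFactors = FALSE)
    sec <- s$sections; names(sec) <- SECTION_LABELS[names(sec)]
    for (nm in names(sec)) row[[nm]] <- sec[[nm]]
    for (nm in names(s$cross_domain)) row[[nm]] <- s$cross_domain[[nm]]
    row$grand <- s$grand
    row
  }))
}

CONCORDANCE_MEASURES <- c("grand", "pedestrian_infrastructure",
                          "pedestrian_design", "bicycle_facilities",
                          "destinations_land_use", "positive_streetscape",
                          "aesthetics_social", "segment")

measure_value <- function(s, measure) {
  if (measure == "grand") return(s$grand)
  if (measure %in% names(s$cross_domain)) return(s$cross_domain[[measure]])
  sec <- names(SECTION_LABELS)[match(measure, SECTION_LABELS)]
  if (!is.na(sec)) return(s$sections[[sec]])
  stop("unknown measure: ", measure)
}

#' Build the paired odd-versus-even score table for concordance analysis
#'
#' One row per school; for every measure (grand score, the three
#' cross-domain sub-scales, the three route sub-sections and the overall
#' segment score) a `<measure>_odd` and `<measure>_even` column, plus the
#' side-free `crossing_combined` column (crossing audits cannot be
#' attributed to a street side and enter both side scopes with the same
#' values). Schools missing a side scope are dropped with a warning.
#'
#' @param summaries List of `school_summary` objects containing an odd-scope
#'   and an even-scope summary per school.
#' @return Data frame of paired scores, one row per school.
#' @export
concordance_inputs <- function(summaries) {
  ids <- unique(vapply(summaries, `[[`, "", "school_id"))
  pick <- function(id, scope) {
    hit <- Filter(function(s) s$school_id == id && s$side_scope == scope, summaries)
    if (length(hit)) hit[[1]] else NULL
  }
  rows <- list()
  for (id in ids) {
    o <- pick(id, "odd"); e <- pick(id, "even")
    if (is.null(o) || is.null(e)) {
      warning("school ", id, " lacks a side scope; dropped from concordance")
      next
    }
    row <- data.frame(school_id = id, stringsAsFactors = FALSE)
    for (m in CONCORDANCE_MEASURES) {
      row[[paste0(m, "_odd")]] <- measure_value(o, m)
      row[[paste0(m, "_even")]] <- measure_value(e, m)
    }
    row$crossing_combined <- o$sections[["crossing"]]
    rows[[id]] <- row
  }
  out <- do.call(rbind, rows) %||% data.frame(school_id = character(0))
  rownames(out) <- NULL
  out
}
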