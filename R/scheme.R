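#' Load a scoring scheme from a YAML configuration
#'
#' A scoring scheme maps audit items to valence sub-scales and sections, and
#' declares the three cross-domain sub-scale memberships and the grand-score
#' maximum. The scheme is validated exhaustively at load time: every item
#' must belong to exactly one sub-scale, every declared maximum (grand score
#' and the three cross-domain sub-scales) must equal the maximum achievable
#' by best-case assignment of every item, and every positive sub-scale cap
#' must be attainable from its member items.
#'
#' @param path Path to a YAML scheme file. The default is the packaged
#'   scheme, whose positive sub-scale caps sum to a grand maximum of 210
#'   points and whose cross-domain sub-scales (pedestrian infrastructure,
#'   pedestrian design, bicycle facilities) reach 27, 22 and 11 points.
#' @return An object of class `scoring_scheme`: a list with elements
#'   `subscales` (list of sub-scale definitions), `items` (named list of item
#'   definitions, each carrying its sub-scale and unit kind), `cross_domain`
#'   (named list with `max` and `items` per cross-domain sub-scale) and
#'   `grand_max`.
#' @examples
#' sch <- load_scheme()
#' scheme_max(sch)            # 210
#' cross_domain_max(sch)      # c(27, 22, 11)
#' @export
load_scheme <- function(path = system.file("extdata", "maps_global_sn_default.yaml",
                                           package = "snaudit")) {
  if (!file.exists(path)) stop("scheme file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$grand_max)) stop("scheme error: declared grand_max missing")
  if (is.null(raw$subscales)) stop("scheme error: no subscales declared")

  subscales <- lapply(raw$subscales, function(s) {
    for (f in c("name", "section", "unit_kind", "valence", "cap", "items")) {
      if (is.null(s[[f]])) stop("scheme error: sub-scale missing field '", f, "'")
    }
    s$scored <- s$scored %||% TRUE
    s$sign <- if (identical(s$valence, "negative")) -1L else 1L
    s$items <- lapply(s$items, function(it) {
      if (is.null(it$name) || is.null(it$min) || is.null(it$max))
        stop("scheme error: item in sub-scale '", s$name, "' lacks name/min/max")
      it$cap <- it$cap %||% Inf
      if (!is.null(it$recode)) {
        rk <- suppressWarnings(as.integer(names(it$recode)))
        if (anyNA(rk)) stop("scheme error: non-integer recode key in item '", it$name, "'")
        missing_keys <- setdiff(seq(it$min, it$max), rk)
        if (length(missing_keys))
          stop("scheme error: recode map of '", it$name,
               "' does not cover raw value(s) ", paste(missing_keys, collapse = ", "))
        it$recode <- stats::setNames(as.numeric(unlist(it$recode)), rk)
      }
      it
    })
    s
  })
  names(subscales) <- vapply(subscales, `[[`, "", "name")

  # flat item table; detect items assigned to two sub-scales
  items <- list()
  for (s in subscales) {
    for (it in s$items) {
      if (!is.null(items[[it$name]]))
        stop("scheme error: item '", it$name, "' belongs to two sub-scales ('",
             items[[it$name]]$subscale, "' and '", s$name, "')")
      it$subscale <- s$name
      it$unit_kind <- s$unit_kind
      items[[it$name]] <- it
    }
  }

  cross_domain <- lapply(raw$cross_domain %||% list(), function(cd) {
    list(max = cd$max, items = unlist(cd$items))
  })

  scheme <- structure(
    list(subscales = subscales, items = items, cross_domain = cross_domain,
         grand_max = raw$grand_max),
    class = "scoring_scheme")
  validate_scheme(scheme)
  scheme
}

#' @rdname load_scheme
#' @export
default_scheme <- function() load_scheme()

# maximum points obtainable from one item (best-case raw value)
item_max_points <- function(item) {
  best <- if (!is.null(item$recode)) max(item$recode) else item$max
  min(best, item$cap)
}

# minimum points obtainable from one item (least-penalising raw value)
item_min_points <- function(item) {
  worst <- if (!is.null(item$recode)) min(item$recode) else item$min
  min(worst, item$cap)
}

validate_scheme <- function(scheme) {
  for (s in scheme$subscales) {
    achievable <- sum(vapply(s$items, item_max_points, 0))
    if (s$cap > achievable)
      stop("scheme error: sub-scale '", s$name, "' cap ", s$cap,
           " exceeds achievable item total ", achievable)
  }
  for (nm in names(scheme$cross_domain)) {
    cd <- scheme$cross_domain[[nm]]
    orphan <- setdiff(cd$items, names(scheme$items))
    if (length(orphan))
      stop("scheme error: cross-domain '", nm, "' references unknown item(s) ",
           paste(orphan, collapse = ", "))
    achievable <- sum(vapply(scheme$items[cd$items], item_max_points, 0))
    if (!isTRUE(all.equal(achievable, cd$max)))
      stop("scheme error: cross-domain '", nm, "' achievable maximum ",
           achievable, " != declared maximum ", cd$max)
  }
  gm <- scheme_max(scheme)
  if (!isTRUE(all.equal(gm, scheme$grand_max)))
    stop("scheme error: achievable grand maximum ", gm,
         " != declared grand_max ", scheme$grand_max)
  invisible(scheme)
}

#' Scheme-level maxima
#'
#' `scheme_max()` computes the maximum achievable overall grand score: the
#' signed sum of best-case capped valence sub-scale scores (positive
#' sub-scales at their caps, negative sub-scales at their least-penalising
#' values). `cross_domain_max()` computes the achievable maximum of each
#' cross-domain sub-scale by best-case assignment of its member items. Both
#' are computed from the scheme, never read from its declared fields.
#'
#' @param scheme A `scoring_scheme`.
#' @param which For `cross_domain_max()`, cross-domain sub-scale name(s);
#'   default all three.
#' @return A numeric value (`scheme_max`) or named numeric vector
#'   (`cross_domain_max`).
#' @export
scheme_max <- function(scheme) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  tot <- 0
  for (s in scheme$subscales) {
    if (!isTRUE(s$scored)) next
    best_raw <- if (s$sign > 0) sum(vapply(s$items, item_max_points, 0))
                else sum(vapply(s$items, item_min_points, 0))
    tot <- tot + s$sign * min(best_raw, s$cap)
  }
  tot
}

#' @rdname scheme_max
#' @export
cross_domain_max <- function(scheme, which = names(scheme$cross_domain)) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  vapply(which, function(nm) {
    cd <- scheme$cross_domain[[nm]]
    if (is.null(cd)) stop("unknown cross-domain sub-scale: ", nm)
    sum(vapply(scheme$items[cd$items], item_max_points, 0))
  }, 0)
}

# recoded, item-capped points for raw values of one item (vectorised)
item_points <- function(item, raw) {
  pts <- if (!is.null(item$recode)) unname(item$recode[as.character(raw)]) else as.numeric(raw)
  pmin(pts, item$cap)
}

# item names per unit kind
scheme_item_names <- function(scheme, unit_kind) {
  nm <- names(scheme$items)
  nm[vapply(scheme$items, function(it) it$unit_kind == unit_kind, TRUE)]
}

#' @export
print.scoring_scheme <- function(x, ...) {
  scored <- Filter(function(s) isTRUE(s$scored), x$subscales)
  cat("Scoring scheme:", length(x$items), "items,", length(x$subscales),
      "sub-scales (", length(scored), "scored )\n")
  cat("  grand maximum:", scheme_max(x), "points\n")
  cdm <- cross_domain_max(x)
  cat("  cross-domain maxima:",
      paste(sprintf("%s=%g", names(cdm), cdm), collapse = ", "), "\n")
  invisible(x)
}
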