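#' Intraclass correlation coefficient for inter-rater reliability
#'
#' Single-rater ICC from the standard one-way / two-way ANOVA mean-square
#' decomposition (Shrout-Fleiss / McGraw-Wong forms), with exact F-based
#' 95% confidence intervals. Models: `one_way` (raters nested in targets,
#' ICC(1)), `two_way_agreement` (two-way random effects, absolute agreement,
#' ICC(A,1); the conventional choice for two fixed-protocol auditors and the
#' default) and `two_way_consistency` (ICC(C,1), insensitive to a constant
#' rater shift). Negative confidence bounds are reported as computed, not
#' truncated. Rows with missing cells are dropped with a note.
#'
#' @param ratings Numeric matrix or data frame, targets x raters (>= 2
#'   complete targets, >= 2 raters).
#' @param model One of `"two_way_agreement"`, `"two_way_consistency"`,
#'   `"one_way"`.
#' @param conf Confidence level (default 0.95).
#' @param measure Label carried into the result.
#' @return Object of class `reliability_result`: `measure`, `icc`, `ci95`,
#'   `classification` (Cicchetti), `model`, `n_targets`, `n_raters`,
#'   `rater_means`, `rater_sds`, `ms` (mean squares).
#' @export
icc <- function(ratings, model = c("two_way_agreement", "two_way_consistency",
                                   "one_way"),
                conf = 0.95, measure = "measure") {
  model <- match.arg(model)
  x <- as.matrix(ratings)
  storage.mode(x) <- "double"
  complete <- stats::complete.cases(x)
  if (any(!complete)) {
    message(sum(!complete), " target(s) with missing cells dropped")
    x <- x[complete, , drop = FALSE]
  }
  n <- nrow(x); k <- ncol(x)
  if (k < 2) stop("insufficient data: at least 2 raters required")
  if (n < 2) stop("insufficient data: fewer than 2 complete targets")

  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ss_total <- sum((x - grand)^2)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- (ss_total - ss_rows - ss_cols) / ((n - 1) * (k - 1))
  msw <- (ss_total - ss_rows) / (n * (k - 1))

  alpha <- 1 - conf
  if (ss_rows <= .Machine$double.eps * max(1, ss_total)) {
    warning("zero between-target variance; ICC reported as 0")
    est <- 0; lo <- NA_real_; hi <- NA_real_
  } else if (model == "one_way") {
    est <- (msr - msw) / (msr + (k - 1) * msw)
    f <- msr / msw
    fu <- stats::qf(1 - alpha / 2, n - 1, n * (k - 1))
    fl <- stats::qf(1 - alpha / 2, n * (k - 1), n - 1)
    lo <- (f / fu - 1) / (f / fu + k - 1)
    hi <- (f * fl - 1) / (f * fl + k - 1)
  } else if (model == "two_way_consistency") {
    est <- (msr - mse) / (msr + (k - 1) * mse)
    f <- msr / mse
    fu <- stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fl <- stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    lo <- (f / fu - 1) / (f / fu + k - 1)
    hi <- (f * fl - 1) / (f * fl + k - 1)
  } else {
    est <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    # Satterthwaite degrees of freedom for the agreement CI
    a <- (k * est) / (n * (1 - est))
    b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f1 <- stats::qf(1 - alpha / 2, n - 1, v)
    f2 <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f1 * mse) /
      (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f2 * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f2 * msr)
  }

  structure(list(measure = measure, icc = est, ci95 = c(lower = lo, upper = hi),
                 classification = classify_icc(est), model = model,
                 n_targets = n, n_raters = k,
                 rater_means = col_m, rater_sds = apply(x, 2, stats::sd),
                 ms = c(msr = msr, msc = msc, mse = mse, msw = msw)),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("%s: ICC(%s) = %.3f [%.2f, %.2f], %s (n = %d targets, %d raters)\n",
              x$measure, x$model, x$icc, x$ci95[1], x$ci95[2],
              x$classification, x$n_targets, x$n_raters))
  invisible(x)
}

#' Cicchetti classification of an ICC value
#'
#' `excellent` for ICC >= 0.75, `good` for 0.60-0.74, `fair` for 0.40-0.59
#' and `poor` below 0.40 (boundaries inclusive as printed).
#'
#' @param value ICC value(s), each <= 1.
#' @return Character vector of categories.
#' @examples
#' classify_icc(c(0.80, 0.60, 0.39))  # excellent, good, poor
#' @export
classify_icc <- function(value) {
  stopifnot(all(value <= 1 + 1e-12))
  ifelse(value >= 0.75, "excellent",
         ifelse(value >= 0.60, "good",
                ifelse(value >= 0.40, "fair", "poor")))
}

#' Correlation with two-sided p-value
#'
#' Pearson product-moment or Spearman rank correlation (average ranks for
#' ties) with the two-sided p-value from the t-approximation.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `r`, `p`, `n`, `method`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("insufficient data: need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x), method = method)
}

#' Odd-versus-even street-side concordance table
#'
#' Per-measure correlation between odd-side and even-side school scores,
#' with means and standard deviations per side and combined. Pearson
#' correlation by default; measures named in `spearman_measures` (by
#' default the two typically non-normal measures: destinations and land use,
#' and bicycle facilities) use Spearman. The crossing score cannot be
#' attributed to a street side and is reported combined-only, without a
#' correlation.
#'
#' @param paired Paired score table from [concordance_inputs()].
#' @param spearman_measures Measures analysed with Spearman rank correlation.
#' @return Data frame of class `concordance_table`: one row per measure with
#'   `odd_mean`, `odd_sd`, `even_mean`, `even_sd`, `r`, `p`, `method`,
#'   `combined_mean`, `combined_sd`, `n`.
#' @export
concordance <- function(paired,
                        spearman_measures = c("destinations_land_use",
                                              "bicycle_facilities")) {
  rows <- lapply(CONCORDANCE_MEASURES, function(m) {
    o <- paired[[paste0(m, "_odd")]]
    e <- paired[[paste0(m, "_even")]]
    if (is.null(o) || is.null(e)) return(NULL)
    method <- if (m %in% spearman_measures) "spearman" else "pearson"
    ct <- correlate(o, e, method)
    comb <- (o + e) / 2
    data.frame(measure = m, odd_mean = mean(o), odd_sd = stats::sd(o),
               even_mean = mean(e), even_sd = stats::sd(e),
               r = ct$r, p = ct$p, method = method,
               combined_mean = mean(comb), combined_sd = stats::sd(comb),
               n = ct$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(paired$crossing_combined)) {
    cc <- paired$crossing_combined
    out <- rbind(out, data.frame(
      measure = "crossing", odd_mean = NA_real_, odd_sd = NA_real_,
      even_mean = NA_real_, even_sd = NA_real_, r = NA_real_, p = NA_real_,
      method = NA_character_, combined_mean = mean(cc),
      combined_sd = stats::sd(cc), n = length(cc), stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  structure(out, class = c("concordance_table", "data.frame"))
}

#' Crossing-audit shares by intersection type
#'
#' Percentage of crossing audits conducted at each intersection type (three-,
#' four-, five-, six-way, ...). Shares are reported rounded to one decimal;
#' the unrounded values are retained and sum to exactly 100.
#'
#' @param counts Non-negative audit counts by intersection type, total > 0.
#'   Names default to `3_way`, `4_way`, ... in input order.
#' @return Data frame `type`, `count`, `share` (unrounded percent),
#'   `share_reported` (1 decimal).
#' @examples
#' crossing_type_shares(c(516, 224, 15, 12))  # 67.3, 29.2, 2.0, 1.6
#' @export
crossing_type_shares <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) <= 0) stop("all-zero counts: shares undefined")
  nms <- names(counts) %||% paste0(seq_along(counts) + 2L, "_way")
  share <- 100 * counts / sum(counts)
  data.frame(type = nms, count = as.numeric(counts), share = as.numeric(share),
             share_reported = round(as.numeric(share), 1),
             stringsAsFactors = FALSE)
}

# per-unit measure values used for inter-rater reliability: section scores,
# per-unit grand contribution and cross-domain partial sums for whatever
# items the unit kind carries
unit_measures <- function(audits, scheme) {
  kind <- audit_unit_kind(audits)
  sc <- score_units(audits, scheme)
  sc <- sc[sc$scored, , drop = FALSE]
  key <- paste(sc$unit_id, sc$side, sc$subunit, sep = "|")
  rows <- list()
  for (sec in unique(sc$section)) {
    sub <- sc[sc$section == sec, , drop = FALSE]
    v <- tapply(sub$signed, paste(sub$unit_id, sub$side, sub$subunit, sep = "|"), sum)
    rows[[length(rows) + 1L]] <- data.frame(
      unit = names(v), measure = SECTION_LABELS[[sec]], value = as.numeric(v),
      stringsAsFactors = FALSE)
  }
  v <- tapply(sc$signed, key, sum)
  rows[[length(rows) + 1L]] <- data.frame(unit = names(v), measure = "grand",
                                          value = as.numeric(v),
                                          stringsAsFactors = FALSE)
  ukey <- paste(audits$unit_id, audits$side %||% NA, audits$subunit %||% NA, sep = "|")
  for (nm in names(scheme$cross_domain)) {
    member <- intersect(scheme$cross_domain[[nm]]$items,
                        scheme_item_names(scheme, kind))
    if (!length(member)) next
    pts <- vapply(member, function(i) item_points(scheme$items[[i]], audits[[i]]),
                  numeric(nrow(audits)))
    val <- if (nrow(audits) == 1L) sum(pts) else rowSums(pts)
    rows[[length(rows) + 1L]] <- data.frame(unit = ukey, measure = nm,
                                            value = val, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Inter-rater reliability report across measures
#'
#' Computes the ICC per measure from two raters' audits of the same units:
#' route sub-section scores, overall segment score, overall crossing score,
#' per-unit grand contributions and cross-domain partial sums (each measure
#' over the audited units that carry it, matched between raters by unit
#' identifier).
#'
#' @param rater1,rater2 Named lists of `audit_set`s (as for
#'   [aggregate_school()]) covering the same units.
#' @param scheme A `scoring_scheme`.
#' @param model ICC model, see [icc()].
#' @return Data frame: one row per measure with the ICC, its 95% CI,
#'   Cicchetti classification, per-rater mean and SD, and target count.
#' @export
reliability_report <- function(rater1, rater2, scheme,
                               model = "two_way_agreement") {
  m1 <- do.call(rbind, lapply(rater1[c("route_side", "segment_side", "crossing")],
                              function(a) if (!is.null(a)) unit_measures(a, scheme)))
  m2 <- do.call(rbind, lapply(rater2[c("route_side", "segment_side", "crossing")],
                              function(a) if (!is.null(a)) unit_measures(a, scheme)))
  measures <- c("grand", names(scheme$cross_domain),
                unname(SECTION_LABELS))
  rows <- lapply(measures, function(ms) {
    a <- m1[m1$measure == ms, ]; b <- m2[m2$measure == ms, ]
    common <- intersect(a$unit, b$unit)
    if (length(common) < 2) return(NULL)
    mat <- cbind(a$value[match(common, a$unit)], b$value[match(common, b$unit)])
    r <- suppressWarnings(icc(mat, model = model, measure = ms))
    data.frame(measure = ms, icc = r$icc, ci_lower = r$ci95[1],
               ci_upper = r$ci95[2], classification = r$classification,
               rater1_mean = r$rater_means[1], rater1_sd = r$rater_sds[1],
               rater2_mean = r$rater_means[2], rater2_sd = r$rater_sds[2],
               n_targets = r$n_targets, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
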