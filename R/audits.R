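#' Read an audit table from CSV
#'
#' An audit table holds one row per audited unit of a single kind:
#' route sides and segment sides (one row per street-segment side, keyed by
#' `unit_id` and `side` = `"O"`/`"E"`), crossings (one row per connecting
#' road of an intersection, keyed by `unit_id` = intersection and `subunit` =
#' connecting-road edge) or cul-de-sacs. Columns other than the key columns
#' (`unit_id`, `side`, `subunit`, `school_id`, `auditor_id`, `audit_date`)
#' must be item names of the scheme, all belonging to a single unit kind.
#' Every value is validated against the item's declared raw range.
#'
#' @param path CSV file (comma-separated, UTF-8, header row mandatory;
#'   dates ISO-8601).
#' @param scheme A `scoring_scheme` (see [load_scheme()]).
#' @return A data frame of class `audit_set` with attribute `unit_kind`.
#' @export
read_audits <- function(path, scheme) {
  if (!file.exists(path)) stop("audit file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  as_audit_set(df, scheme)
}

key_columns <- c("unit_id", "side", "subunit", "school_id", "auditor_id", "audit_date")

#' Validate a data frame of audit rows against a scheme
#'
#' @param df Data frame with key columns and item-value columns.
#' @param scheme A `scoring_scheme`.
#' @return The validated data frame, classed `audit_set`, with attribute
#'   `unit_kind`.
#' @export
as_audit_set <- function(df, scheme) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  item_cols <- setdiff(names(df), key_columns)
  unknown <- setdiff(item_cols, names(scheme$items))
  if (length(unknown))
    stop("audit schema error: unknown item column(s): ",
         paste(unknown, collapse = ", "))
  if (!length(item_cols)) stop("audit schema error: no item columns present")
  kinds <- unique(vapply(scheme$items[item_cols], `[[`, "", "unit_kind"))
  if (length(kinds) != 1L)
    stop("audit schema error: item columns mix unit kinds: ",
         paste(kinds, collapse = ", "))
  if (is.null(df$unit_id)) stop("audit schema error: unit_id column missing")
  for (nm in item_cols) {
    v <- df[[nm]]
    if (!is.numeric(v)) stop("audit validation error: non-numeric values in item '", nm, "'")
    it <- scheme$items[[nm]]
    bad <- which(is.na(v) | v < it$min | v > it$max | v != round(v))
    if (length(bad))
      stop("audit validation error: item '", nm, "' out of range [",
           it$min, ", ", it$max, "] in row(s) ", paste(bad, collapse = ", "))
  }
  structure(df, class = c("audit_set", "data.frame"), unit_kind = kinds)
}

#' @rdname read_audits
#' @param audits An `audit_set`.
#' @export
write_audits <- function(audits, path) {
  utils::write.csv(as.data.frame(audits), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.audit_set <- function(x, ...) {
  cat("Audit set:", nrow(x), attr(x, "unit_kind"), "records\n")
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

audit_unit_kind <- function(audits) attr(audits, "unit_kind")
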