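# Behavioral trial tables: preparation, keyed merging, row exclusion.

.key_cols <- c("subject", "block", "trial")

.key_string <- function(df) {
  paste(df$subject, df$block, df$trial, sep = "/")
}

#' Prepare behavioral/experimental trial tables
#'
#' Reads one delimiter-separated table per file (header row expected),
#' optionally drops rows and columns, injects `subject` and `block` from
#' the file name when the table itself lacks them, assigns trial numbers
#' `1..n` within `(subject, block)` by row order when no `trial` column
#' exists, and concatenates everything into one table keyed by
#' `(subject, block, trial)`. What counts as an "unnecessary" row or column
#' is the analyst's call, so both are expressed as explicit arguments
#' rather than guessed.
#'
#' @param paths Character vector of file paths; each basename must satisfy
#'   the `subj`/`block` naming contract (see [parse_data_filename()]).
#' @param keep_columns Optional character vector: columns to retain (key
#'   columns are always retained). Default: all.
#' @param row_filter Optional function taking the per-file data frame and
#'   returning a logical keep-vector (applied before trial renumbering, so
#'   e.g. practice trials can be dropped and the remaining trials
#'   renumbered 1..n).
#' @return A data frame with unique `(subject, block, trial)` keys.
#' @export
prep_exp_data <- function(paths, keep_columns = NULL, row_filter = NULL) {
  stopifnot(length(paths) >= 1L)
  pieces <- lapply(paths, function(p) {
    id <- parse_data_filename(p)
    df <- as.data.frame(data.table::fread(p, showProgress = FALSE))
    if (!is.null(row_filter)) {
      keep <- row_filter(df)
      if (!is.logical(keep) || length(keep) != nrow(df)) {
        stop("row_filter must return a logical vector of length nrow (file '",
             basename(p), "')", call. = FALSE)
      }
      df <- df[keep & !is.na(keep), , drop = FALSE]
    }
    if (!"subject" %in% names(df)) df$subject <- id$subject
    if (!"block" %in% names(df)) df$block <- id$block
    if (!is.null(keep_columns)) {
      df <- df[, union(intersect(names(df), union(keep_columns, .key_cols)),
                       c("subject", "block")), drop = FALSE]
    }
    df
  })
  out <- as.data.frame(data.table::rbindlist(pieces, use.names = TRUE, fill = TRUE))
  if (!"trial" %in% names(out)) {
    out <- out[order(out$subject, out$block), , drop = FALSE]
    out$trial <- stats::ave(seq_len(nrow(out)),
                            out$subject, out$block,
                            FUN = seq_along)
  }
  dup <- duplicated(out[.key_cols])
  if (any(dup)) {
    offenders <- unique(.key_string(out[dup, , drop = FALSE]))
    stop("duplicate (subject/block/trial) keys after preparation: ",
         paste(head(offenders, 5L), collapse = ", "),
         if (length(offenders) > 5L) " ..." else "", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Combine two keyed trial tables
#'
#' Merges two tables keyed by `(subject, block, trial)` — e.g. a behavioral
#' table from [prep_exp_data()] and a force-plate statistics table from
#' [compute_bin_stats()]. When the two tables cover exactly the same keys,
#' the result is a column-wise join with one row per key; when their key
#' sets are disjoint and the columns agree, rows are stacked. Partially
#' overlapping keys on a column join are an error (silent row loss is never
#' acceptable), listing the unmatched keys. Overlapping non-key column
#' names are disambiguated with the given suffixes.
#'
#' @param a,b Data frames containing the key columns.
#' @param suffixes Length-2 suffixes for clashing non-key columns.
#' @return The combined data frame.
#' @export
combine_data <- function(a, b, suffixes = c(".a", ".b")) {
  for (nm in .key_cols) {
    if (!nm %in% names(a) || !nm %in% names(b)) {
      stop("both tables must contain key column '", nm, "'", call. = FALSE)
    }
  }
  ka <- .key_string(a); kb <- .key_string(b)
  common <- intersect(ka, kb)
  if (length(common) == length(ka) && length(common) == length(kb)) {
    out <- merge(as.data.frame(a), as.data.frame(b), by = .key_cols,
                 suffixes = suffixes, sort = FALSE)
    out <- out[order(out$subject, out$block, out$trial), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  if (length(common) == 0L) {
    cols_a <- setdiff(names(a), names(b)); cols_b <- setdiff(names(b), names(a))
    if (length(cols_a) || length(cols_b)) {
      stop("cannot stack tables with differing columns: ",
           paste(c(cols_a, cols_b), collapse = ", "), call. = FALSE)
    }
    out <- as.data.frame(data.table::rbindlist(list(as.data.frame(a), as.data.frame(b)),
                                               use.names = TRUE))
    rownames(out) <- NULL
    return(out)
  }
  unmatched <- c(setdiff(ka, kb), setdiff(kb, ka))
  stop("tables overlap on ", length(common), " key(s) but differ on ",
       length(unmatched), "; unmatched keys: ",
       paste(head(unmatched, 5L), collapse = ", "),
       if (length(unmatched) > 5L) " ..." else "", call. = FALSE)
}

#' Exclude rows by predicate
#'
#' Removes rows for which the predicate is `TRUE` and reports how many were
#' removed. Outlier and artifact exclusion criteria are study-specific, so
#' the package provides only this generic mechanism.
#'
#' @param table A data frame.
#' @param predicate Function taking the data frame and returning a logical
#'   vector (`TRUE` = remove). `NA` results are treated as `FALSE` (kept).
#' @return The filtered data frame; the number of removed rows is reported
#'   via `message()` and attached as attribute `"n_removed"`.
#' @examples
#' \dontrun{
#' clean <- exclude_rows(stats, function(d) !d$complete)
#' }
#' @export
exclude_rows <- function(table, predicate) {
  stopifnot(is.data.frame(table), is.function(predicate))
  drop <- predicate(table)
  if (!is.logical(drop) || length(drop) != nrow(table)) {
    stop("predicate must return a logical vector of length nrow(table); ",
         "check that every referenced column exists", call. = FALSE)
  }
  drop <- drop & !is.na(drop)
  out <- table[!drop, , drop = FALSE]
  rownames(out) <- NULL
  message(sum(drop), " row(s) removed, ", nrow(out), " retained")
  attr(out, "n_removed") <- sum(drop)
  out
}
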