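#' Multi-group binary response data
#'
#' Bundles a respondents-by-items matrix of 0/1 responses (NA = missing)
#' with a group identifier per row.  Validates the structural requirements
#' of the multi-group model: at least 2 groups and 2 items, every group
#' non-empty, all cells in {0, 1, NA}, and within every group each item
#' observed for at least one respondent (a group in which an item is
#' missing for everyone contributes no information on that item and is
#' rejected, mirroring the exclusion rule used with linked surveys).
#'
#' @param y numeric/integer matrix (or data frame) of 0/1/NA responses,
#'   one row per respondent, one column per item.
#' @param group vector of group labels, one per row of `y`; treated as
#'   opaque strings (never parsed).
#' @param items optional item names (default: column names of `y`).
#' @return an object of class `response_data` with elements `y` (integer
#'   matrix with NA), `group` (factor), `items`, `groups`, `group_sizes`.
#' @export
response_data <- function(y, group, items = NULL) {
  y <- as.matrix(y)
  storage.mode(y) <- "double"
  if (nrow(y) != length(group))
    stop("`group` must have one entry per row of `y`", call. = FALSE)
  bad <- which(!(is.na(y) | y == 0 | y == 1), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-binary response at row %d, column %d (value %s)",
                 bad[1, 1], bad[1, 2], format(y[bad[1, , drop = FALSE]])),
         call. = FALSE)
  items <- items %||% colnames(y) %||% paste0("Y", seq_len(ncol(y)))
  colnames(y) <- items
  ## groups keep their order of first appearance; labels are opaque and
  ## never sorted or parsed
  group <- as.character(group)
  group <- factor(group, levels = unique(group))
  if (nlevels(group) < 2) stop("need at least 2 groups", call. = FALSE)
  if (ncol(y) < 2) stop("need at least 2 items", call. = FALSE)
  for (g in levels(group)) {
    yg <- y[group == g, , drop = FALSE]
    if (nrow(yg) == 0) stop("empty group: ", g, call. = FALSE)
    allmiss <- colSums(!is.na(yg)) == 0
    if (any(allmiss))
      stop(sprintf(
        "group %s has missing data for everyone on item(s) %s; such groups cannot be compared and must be excluded",
        g, paste(items[allmiss], collapse = ", ")), call. = FALSE)
  }
  structure(
    list(y = y, group = group, items = items, groups = levels(group),
         group_sizes = as.integer(table(group))),
    class = "response_data")
}

#' @export
print.response_data <- function(x, ...) {
  cat(sprintf("response_data: %d respondents, %d items, %d groups\n",
              nrow(x$y), length(x$items), length(x$groups)))
  cat("group sizes:",
      paste(sprintf("%s=%d", x$groups, x$group_sizes), collapse = ", "), "\n")
  nm <- sum(is.na(x$y))
  if (nm > 0) cat(sprintf("missing cells: %d (%.1f%%)\n", nm,
                          100 * nm / length(x$y)))
  invisible(x)
}

## rows of one group, as a plain matrix
group_block <- function(data, g) {
  data$y[data$group == g, , drop = FALSE]
}

#' Read multi-group binary responses from a delimited file
#'
#' Reads a wide CSV/TSV file with a header, one row per respondent, a
#' group-identifier column, and 0/1 item columns.  Cells matching a
#' missing code become NA; any other non-binary cell is an error naming
#' its coordinates.
#'
#' @param path file path; `.csv` is comma-separated, anything else
#'   tab-separated.
#' @param missing_codes character vector of cell values treated as
#'   missing (default empty cell, `"NA"`, `"-9"`).
#' @param group_column name of the group-identifier column.
#' @return a [response_data()] object.
#' @export
read_responses <- function(path, missing_codes = c("", "NA", "-9"),
                           group_column = "group") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "\"",
                           comment.char = "")
  if (!group_column %in% names(raw))
    stop(sprintf("missing group column '%s' in %s", group_column, path),
         call. = FALSE)
  group <- raw[[group_column]]
  itemcols <- setdiff(names(raw), group_column)
  y <- matrix(NA_real_, nrow(raw), length(itemcols),
              dimnames = list(NULL, itemcols))
  for (j in seq_along(itemcols)) {
    v <- trimws(raw[[itemcols[j]]])
    miss <- v %in% missing_codes
    ok <- miss | v %in% c("0", "1")
    if (!all(ok)) {
      i <- which(!ok)[1]
      stop(sprintf("invalid response '%s' at row %d, column '%s' of %s",
                   v[i], i, itemcols[j], path), call. = FALSE)
    }
    y[!miss, j] <- as.numeric(v[!miss])
  }
  response_data(y, group, items = itemcols)
}
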