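#' Read a supplementary-style profile table
#'
#' Reads a delimited text file with one row per sample into a
#' [profile_table()]. The default schema expects a `label` column, the four
#' sugar columns by name, and organic columns named `<channel>@<Rf>` (as
#' written by [write_profile_table()]). A custom schema adapts other
#' layouts: supplementary exports vary, so column mapping is configurable.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema List with entries `label` (label column name), `sugars`
#'   (named character vector mapping fructose/glucose/maltose/sucrose to
#'   file columns) and `organic_pattern` (regex with two capture groups,
#'   channel then Rf, matched against remaining column names).
#' @param delimiter Field delimiter (default comma).
#' @return A validated [profile_table()].
#' @export
read_profile_table <- function(path, schema = default_table_schema(),
                               delimiter = ",") {
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty table: ", path, call. = FALSE)
  if (!schema$label %in% names(df))
    stop("missing label column '", schema$label, "'", call. = FALSE)
  for (s in sugar_names())
    if (!schema$sugars[[s]] %in% names(df))
      stop("missing sugar column '", schema$sugars[[s]], "'", call. = FALSE)
  labels <- as.character(df[[schema$label]])
  parse_sample_label(labels)  # validates the naming scheme
  sugars <- as.matrix(df[, unname(schema$sugars[sugar_names()]), drop = FALSE])
  if (!is.numeric(sugars)) stop("non-numeric sugar values", call. = FALSE)
  colnames(sugars) <- sugar_names()
  rest <- setdiff(names(df), c(schema$label, unname(schema$sugars)))
  meta <- parse_columns_by_pattern(rest, schema$organic_pattern)
  organic_cols <- meta$name[!is.na(meta$channel)]
  extra_cols <- setdiff(rest, organic_cols)
  organics <- as.matrix(df[, organic_cols, drop = FALSE])
  if (length(organic_cols) && !is.numeric(organics))
    stop("non-numeric AU values", call. = FALSE)
  message(sprintf("read_profile_table: %d rows, %d sugar + %d organic columns (%s)",
                  nrow(df), ncol(sugars), ncol(organics), path))
  profile_table(labels, sugars, organics,
                meta[!is.na(meta$channel), c("channel", "rf")],
                provenance = path,
                extra = if (length(extra_cols)) df[, extra_cols, drop = FALSE])
}

#' @rdname read_profile_table
#' @export
default_table_schema <- function() {
  list(label = "label",
       sugars = stats::setNames(sugar_names(), sugar_names()),
       organic_pattern = "^([A-Za-z0-9_]+)@([0-9.]+)$")
}

parse_columns_by_pattern <- function(cols, pattern) {
  if (!length(cols))
    return(data.frame(name = character(), channel = character(),
                      rf = numeric(), stringsAsFactors = FALSE))
  m <- regmatches(cols, regexec(pattern, cols))
  ok <- lengths(m) >= 3L
  channel <- rep(NA_character_, length(cols)); rf <- rep(NA_real_, length(cols))
  channel[ok] <- vapply(m[ok], `[`, "", 2L)
  rf[ok] <- as.numeric(vapply(m[ok], `[`, "", 3L))
  bad <- ok & !channel %in% channel_codes()
  channel[bad] <- NA_character_; rf[bad] <- NA_real_
  data.frame(name = cols, channel = channel, rf = rf, stringsAsFactors = FALSE)
}

#' Write a profile table to delimited text
#'
#' One row per sample with a deterministic column order (label, sugars,
#' organic columns by channel then Rf, any pass-through extras).
#' [read_profile_table()] inverts the write for the default schema.
#'
#' @param table A [profile_table()].
#' @param path Output path.
#' @param delimiter Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(table, path, delimiter = ",") {
  stopifnot(inherits(table, "profile_table"))
  if (ncol(table$sugars) + ncol(table$organics) == 0L)
    stop("refusing to write a table with no data columns", call. = FALSE)
  df <- as.data.frame(table)
  utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                     col.names = TRUE, qmethod = "double", quote = 1L,
                     fileEncoding = "UTF-8")
  message(sprintf("write_profile_table: %d rows, %d columns -> %s",
                  nrow(df), ncol(df), path))
  invisible(path)
}
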