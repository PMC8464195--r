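#' Restrict a profile table to an Rf window
#'
#' Drops organic columns whose Rf lies outside the closed interval
#' `[low, high]`; sugar columns are untouched. The study convention keeps
#' only bands between Rf 0.05 and Rf 0.60, which captures the majority of
#' detected bands; both boundaries are retained.
#'
#' @param table A [profile_table()].
#' @param low,high Window bounds, `0 <= low < high <= 1`.
#' @return A [profile_table()] with the filtered organic column set.
#' @export
restrict_rf_window <- function(table, low = 0.05, high = 0.60) {
  stopifnot(inherits(table, "profile_table"))
  if (!(low >= 0 && low < high && high <= 1))
    stop("require 0 <= low < high <= 1", call. = FALSE)
  keep <- table$organic_meta$rf >= low & table$organic_meta$rf <= high
  profile_table(table$labels, table$sugars,
                table$organics[, keep, drop = FALSE],
                table$organic_meta[keep, , drop = FALSE],
                provenance = table$provenance, extra = table$extra)
}

#' Rf grid specification
#'
#' A shared per-channel grid of equally spaced Rf positions onto which band
#' intensities are resampled. The default (0.05 to 0.60 in steps of 0.005,
#' 111 points per channel) is a desk-scale stand-in for dense densitogram
#' exports; the step is configurable to match deposited data.
#'
#' @param low,high Grid extent in Rf units.
#' @param step Grid spacing in Rf units.
#' @param channels Channels to grid (default all four).
#' @return An object of class `rf_grid`.
#' @export
rf_grid <- function(low = 0.05, high = 0.60, step = 0.005,
                    channels = channel_codes()) {
  stopifnot(low < high, step > 0, length(channels) >= 1L)
  points <- seq(low, high, by = step)
  if (!length(points)) stop("empty grid", call. = FALSE)
  structure(list(low = low, high = high, step = step,
                 points = points, channels = channels),
            class = "rf_grid")
}

#' Assemble the modelling feature matrix
#'
#' Resamples every organic band onto the Rf grid of its channel (nearest
#' grid point; bands mapping to the same point keep the maximum AU) and
#' appends the four sugar columns, giving
#' `4 + channels x grid length` features. Bands falling more than half a
#' grid step outside the grid extent are dropped.
#'
#' @param table A [profile_table()].
#' @param grid An [rf_grid()]; every grid channel must occur in the table.
#' @return An object of class `feature_matrix` with fields `values`
#'   (samples x features), `meta` (per-column kind/channel/Rf), `labels`,
#'   `standardised` and `scaling`.
#' @export
assemble_features <- function(table, grid = rf_grid()) {
  stopifnot(inherits(table, "profile_table"), inherits(grid, "rf_grid"))
  missing_ch <- setdiff(grid$channels, unique(table$organic_meta$channel))
  if (length(missing_ch))
    stop("channel absent from table: ", paste(missing_ch, collapse = ", "),
         call. = FALSE)
  n <- length(table$labels); g <- length(grid$points)
  organ <- matrix(0, n, length(grid$channels) * g)
  meta_ch <- rep(grid$channels, each = g)
  meta_rf <- rep(grid$points, times = length(grid$channels))
  for (ci in seq_along(grid$channels)) {
    ch <- grid$channels[ci]
    sel <- which(table$organic_meta$channel == ch)
    if (!length(sel)) next
    idx <- round((table$organic_meta$rf[sel] - grid$low) / grid$step) + 1L
    ok <- idx >= 1L & idx <= g
    for (j in seq_along(sel)[ok]) {
      col <- (ci - 1L) * g + idx[j]
      organ[, col] <- pmax(organ[, col], table$organics[, sel[j]])
    }
  }
  values <- cbind(table$sugars, organ)
  meta <- data.frame(
    kind = c(rep("sugar", 4L), rep("organic", ncol(organ))),
    name = c(sugar_names(), organic_column_name(meta_ch, meta_rf)),
    channel = c(rep(NA_character_, 4L), meta_ch),
    rf = c(rep(NA_real_, 4L), meta_rf),
    stringsAsFactors = FALSE)
  colnames(values) <- meta$name
  rownames(values) <- table$labels
  new_feature_matrix(values, meta, table$labels)
}

#' Wrap an existing samples-x-features matrix as a feature matrix
#'
#' For data that arrives already assembled (e.g. a deposited standardized
#' table). Column kinds are inferred from the column names: the four sugar
#' names are sugar features, names of the form `<channel>@<Rf>` are organic
#' features, anything else is carried as kind `"other"` (used by distance
#' and projection methods, ignored by channel-wise operations).
#'
#' @param values Numeric matrix with column names; row names (or `labels`)
#'   identify samples.
#' @param labels Sample labels (default: row names).
#' @param standardised Whether the values are already on a standardised
#'   scale.
#' @return A `feature_matrix`.
#' @export
as_feature_matrix <- function(values, labels = rownames(values),
                              standardised = FALSE) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("V%d", seq_len(ncol(values)))
  if (is.null(labels)) labels <- sprintf("sample%d", seq_len(nrow(values)))
  org <- parse_organic_column_name(colnames(values))
  kind <- ifelse(colnames(values) %in% sugar_names(), "sugar",
                 ifelse(!is.na(org$channel) & org$channel %in% channel_codes(),
                        "organic", "other"))
  meta <- data.frame(kind = kind, name = colnames(values),
                     channel = ifelse(kind == "organic", org$channel, NA),
                     rf = ifelse(kind == "organic", org$rf, NA),
                     stringsAsFactors = FALSE)
  rownames(values) <- labels
  new_feature_matrix(values, meta, labels, standardised = standardised)
}

new_feature_matrix <- function(values, meta, labels,
                               standardised = FALSE, scaling = NULL) {
  stopifnot(nrow(meta) == ncol(values), !anyNA(values))
  structure(list(values = values, meta = meta, labels = labels,
                 standardised = standardised, scaling = scaling),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix:", nrow(x$values), "samples x", ncol(x$values),
      "features (", sum(x$meta$kind == "sugar"), "sugar,",
      sum(x$meta$kind == "organic"), "organic ),",
      if (x$standardised) "standardised" else "raw", "\n")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Min-max standardisation of a feature matrix
#'
#' Rescales every column to `[0, 1]` (constant columns map to 0); the
#' per-column minima and ranges are retained so the transform can be
#' inverted. All downstream multivariate methods in this package expect
#' the standardised scale; ANN inputs in particular naturally live in
#' `[0, 1]`.
#'
#' @param matrix A raw [assemble_features()] matrix.
#' @return A `feature_matrix` with `standardised = TRUE`.
#' @export
standardise <- function(matrix) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (ncol(matrix$values) == 0L) stop("empty matrix", call. = FALSE)
  if (matrix$standardised)
    stop("matrix is already standardised", call. = FALSE)
  mins <- apply(matrix$values, 2L, min)
  ranges <- apply(matrix$values, 2L, max) - mins
  div <- ifelse(ranges > 0, ranges, 1)
  vals <- sweep(sweep(matrix$values, 2L, mins, "-"), 2L, div, "/")
  new_feature_matrix(vals, matrix$meta, matrix$labels, standardised = TRUE,
                     scaling = list(min = mins, range = ranges))
}

#' @rdname standardise
#' @param matrix A standardised `feature_matrix`.
#' @export
inverse_standardise <- function(matrix) {
  stopifnot(inherits(matrix, "feature_matrix"), matrix$standardised)
  s <- matrix$scaling
  vals <- sweep(sweep(matrix$values, 2L, ifelse(s$range > 0, s$range, 1), "*"),
                2L, s$min, "+")
  new_feature_matrix(vals, matrix$meta, matrix$labels)
}

#' Select a feature subset by kind
#'
#' @param matrix A `feature_matrix`.
#' @param feature_set One of `"combined"`, `"sugars"`, `"organics"`.
#' @return A `feature_matrix` restricted to the requested columns.
#' @export
select_features <- function(matrix,
                            feature_set = c("combined", "sugars", "organics")) {
  feature_set <- match.arg(feature_set)
  keep <- switch(feature_set,
                 combined = rep(TRUE, nrow(matrix$meta)),
                 sugars = matrix$meta$kind == "sugar",
                 organics = matrix$meta$kind == "organic")
  new_feature_matrix(matrix$values[, keep, drop = FALSE],
                     matrix$meta[keep, , drop = FALSE], matrix$labels,
                     matrix$standardised,
                     if (!is.null(matrix$scaling))
                       lapply(matrix$scaling, `[`, keep))
}

#' Serialise / deserialise a feature matrix
#'
#' Values go to CSV (one row per sample, label column first); column
#' metadata, the standardisation flag and scaling parameters go to a JSON
#' sidecar `<path>.json`.
#'
#' @param matrix A `feature_matrix`.
#' @param path CSV path; the sidecar is `<path>.json`.
#' @return `path` (write) or a `feature_matrix` (read).
#' @export
write_feature_matrix <- function(matrix, path) {
  df <- data.frame(label = matrix$labels, matrix$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(meta = matrix$meta, standardised = matrix$standardised,
               scaling = matrix$scaling)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  message(sprintf("write_feature_matrix: %d rows, %d columns -> %s",
                  nrow(df), ncol(df), path))
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$label
  meta <- as.data.frame(side$meta, stringsAsFactors = FALSE)
  scaling <- if (!is.null(side$scaling))
    list(min = stats::setNames(as.numeric(side$scaling$min), meta$name),
         range = stats::setNames(as.numeric(side$scaling$range), meta$name))
  new_feature_matrix(vals, meta, df$label,
                     standardised = isTRUE(side$standardised),
                     scaling = scaling)
}
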