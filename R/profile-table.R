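#' Construct a profile table
#'
#' A profile table holds, for each sample, the four quantified sugars and
#' the organic-extract band intensities of the four imaging channels. Band
#' columns are identified by `(channel, Rf)`; every row shares the same
#' column set, with 0 AU where a sample lacks a band.
#'
#' @param labels Character vector of canonical sample labels.
#' @param sugars Numeric matrix (samples x 4) with columns
#'   `fructose`, `glucose`, `maltose`, `sucrose`; quantification units
#'   (dynamic range of the study data: 0 to ~2,000).
#' @param organics Numeric matrix (samples x bands) of AU intensities in
#'   `[0, 1]`.
#' @param organic_meta Data frame with one row per organic column:
#'   `channel` (one of [channel_codes()]) and `rf` in `[0, 1]`.
#' @param provenance Free-text origin (source file or generator seed).
#' @param extra Optional data frame of pass-through columns excluded from
#'   modelling.
#' @return An object of class `profile_table`.
#' @export
profile_table <- function(labels, sugars, organics, organic_meta,
                          provenance = "constructed", extra = NULL) {
  sugars <- as.matrix(sugars); organics <- as.matrix(organics)
  if (length(labels) != nrow(sugars) || nrow(sugars) != nrow(organics))
    stop("labels, sugars and organics disagree on sample count", call. = FALSE)
  if (anyDuplicated(labels))
    stop("duplicate sample label: ",
         labels[duplicated(labels)][1], call. = FALSE)
  if (!identical(colnames(sugars), sugar_names()))
    stop("sugar columns must be exactly ",
         paste(sugar_names(), collapse = ", "), call. = FALSE)
  if (ncol(organics) != nrow(organic_meta))
    stop("organic_meta must describe every organic column", call. = FALSE)
  if (anyNA(sugars) || anyNA(organics))
    stop("missing values are not allowed", call. = FALSE)
  if (any(sugars < 0)) stop("negative sugar quantity", call. = FALSE)
  if (any(organics < 0)) stop("negative AU intensity", call. = FALSE)
  if (any(organic_meta$rf < 0 | organic_meta$rf > 1))
    stop("Rf values must lie in [0, 1]", call. = FALSE)
  if (!all(organic_meta$channel %in% channel_codes()))
    stop("unknown channel in organic_meta", call. = FALSE)
  ord <- order(match(organic_meta$channel, channel_codes()), organic_meta$rf)
  organic_meta <- organic_meta[ord, , drop = FALSE]
  organics <- organics[, ord, drop = FALSE]
  colnames(organics) <- organic_column_name(organic_meta$channel, organic_meta$rf)
  rownames(sugars) <- rownames(organics) <- labels
  structure(list(labels = labels, sugars = sugars, organics = organics,
                 organic_meta = organic_meta, provenance = provenance,
                 extra = extra),
            class = "profile_table")
}

sugar_names <- function() c("fructose", "glucose", "maltose", "sucrose")

#' Canonical organic column names: `<channel>@<Rf to 4 decimals>`
#' @param channel,rf Vectors of channel codes and Rf values.
#' @return Character vector like `"R366@0.4100"`.
#' @export
organic_column_name <- function(channel, rf) sprintf("%s@%.4f", channel, rf)

parse_organic_column_name <- function(x) {
  m <- regmatches(x, regexec("^([A-Za-z0-9_]+)@(0?\\.[0-9]+|[01](\\.[0-9]+)?)$", x))
  ok <- lengths(m) >= 3L
  data.frame(name = x,
             channel = ifelse(ok, vapply(m, function(v) if (length(v) >= 3) v[2] else NA_character_, ""), NA_character_),
             rf = ifelse(ok, as.numeric(vapply(m, function(v) if (length(v) >= 3) v[3] else NA_character_, "")), NA_real_),
             stringsAsFactors = FALSE)
}

#' @export
print.profile_table <- function(x, ...) {
  cat("profile_table:", length(x$labels), "samples,",
      ncol(x$sugars), "sugars,", ncol(x$organics), "organic bands\n")
  cat("channels:", paste(unique(x$organic_meta$channel), collapse = ", "), "\n")
  cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
dim.profile_table <- function(x) {
  c(length(x$labels), ncol(x$sugars) + ncol(x$organics))
}

#' @export
as.data.frame.profile_table <- function(x, ...) {
  df <- data.frame(label = x$labels, x$sugars, x$organics,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(x$extra)) df <- cbind(df, x$extra)
  rownames(df) <- NULL
  df
}
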