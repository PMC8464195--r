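#' Augmentation configuration
#'
#' Parameters of the run-to-run variability model used to expand a plate
#' study: uniform Rf drift of every band within `+/- rf_drift_bound`,
#' Gaussian intensity noise with standard deviation
#' `au_noise_multiplier x (per-channel SD of the input AU values)`, and
#' Gaussian sugar noise with standard deviation
#' `sugar_noise_fraction x value`; all draws truncated at 0. Each input row
#' is replicated `outer_repeats x inner_repeats` times; with the defaults a
#' 68-row study becomes `50 x 21 x 68 + 68 = 71,468` rows. The factor 21 is
#' exposed as `inner_repeats` because only the product is documented for
#' the original study.
#'
#' @param rf_drift_bound Drift half-width in Rf units (default 0.0173).
#' @param au_noise_multiplier Multiplier on the per-channel SD
#'   (default 1.25).
#' @param sugar_noise_fraction Relative sugar noise (default 0.05).
#' @param outer_repeats,inner_repeats Replication counts (defaults 50, 21).
#' @param keep_originals Keep the unperturbed input rows (default `TRUE`).
#' @param drift_distribution `"uniform"` (default) or `"gaussian"` (SD =
#'   bound / 2, still truncated to the bound).
#' @param seed Integer seed; augmentation is deterministic given the seed.
#' @return An object of class `augmentation_config`.
#' @export
augmentation_config <- function(rf_drift_bound = 0.0173,
                                au_noise_multiplier = 1.25,
                                sugar_noise_fraction = 0.05,
                                outer_repeats = 50L,
                                inner_repeats = 21L,
                                keep_originals = TRUE,
                                drift_distribution = c("uniform", "gaussian"),
                                seed = 1L) {
  if (rf_drift_bound < 0 || au_noise_multiplier < 0 || sugar_noise_fraction < 0)
    stop("noise parameters must be non-negative", call. = FALSE)
  if (outer_repeats < 0 || inner_repeats < 0)
    stop("repeat counts must be non-negative", call. = FALSE)
  structure(list(rf_drift_bound = rf_drift_bound,
                 au_noise_multiplier = au_noise_multiplier,
                 sugar_noise_fraction = sugar_noise_fraction,
                 outer_repeats = as.integer(outer_repeats),
                 inner_repeats = as.integer(inner_repeats),
                 keep_originals = isTRUE(keep_originals),
                 drift_distribution = match.arg(drift_distribution),
                 seed = as.integer(seed)),
            class = "augmentation_config")
}

#' Per-channel standard deviation of organic intensities
#'
#' One SD per imaging channel, computed over all AU values (all grid
#' columns of that channel, all samples). This calibrates the intensity
#' noise of [augment()].
#'
#' @param matrix A `feature_matrix` with channel-tagged organic columns.
#' @return Named numeric vector, one SD per channel present.
#' @export
channel_sd <- function(matrix) {
  stopifnot(inherits(matrix, "feature_matrix"))
  org <- matrix$meta$kind == "organic"
  if (!any(org)) stop("no channel-tagged organic features", call. = FALSE)
  chans <- unique(matrix$meta$channel[org])
  vapply(chans, function(ch) {
    v <- matrix$values[, org & matrix$meta$channel == ch, drop = FALSE]
    if (length(v) < 2L)
      stop("channel ", ch, " has fewer than 2 values", call. = FALSE)
    stats::sd(as.vector(v))
  }, numeric(1L))
}

#' Augment a feature matrix by simulated run-to-run variability
#'
#' Every input row is copied `outer_repeats x inner_repeats` times. In each
#' copy the Rf position of every organic band is shifted by an independent
#' draw from `Uniform(-bound, +bound)` and re-assigned to the nearest grid
#' point (co-located bands keep the maximum, as in [assemble_features()];
#' bands drifting off the grid are lost); every organic cell then receives
#' Gaussian noise with SD `au_noise_multiplier x channel SD`, and every
#' sugar Gaussian noise with SD `sugar_noise_fraction x value`, all
#' truncated at 0. Labels are copied from the source rows, so class
#' multiplicities stay balanced.
#'
#' @param matrix A `feature_matrix` (raw or standardised) whose organic
#'   columns form per-channel Rf grids.
#' @param config An [augmentation_config()].
#' @return A `feature_matrix` with
#'   `outer x inner x n (+ n if keep_originals)` rows; the applied
#'   configuration is attached as attribute `"augmentation"`.
#' @export
augment <- function(matrix, config = augmentation_config()) {
  stopifnot(inherits(matrix, "feature_matrix"),
            inherits(config, "augmentation_config"))
  org <- which(matrix$meta$kind == "organic")
  sug <- which(matrix$meta$kind == "sugar")
  if (!length(org) || anyNA(matrix$meta$channel[org]))
    stop("missing channel tags on organic features", call. = FALSE)
  n <- nrow(matrix$values)
  reps <- config$outer_repeats * config$inner_repeats
  sds <- if (length(org)) channel_sd(matrix)

  out <- withr::with_seed(config$seed,
                          augment_draws(matrix, config, org, sug, sds, reps))
  labels <- rep(matrix$labels, each = if (reps > 0L) reps else 0L)
  if (reps > 0L)
    rownames(out) <- sprintf("%s#%d", labels, rep(seq_len(reps), times = n))
  if (config$keep_originals) {
    out <- rbind(matrix$values, out)
    labels <- c(matrix$labels, labels)
  }
  res <- new_feature_matrix(out, matrix$meta, labels,
                            standardised = matrix$standardised,
                            scaling = matrix$scaling)
  attr(res, "augmentation") <- config
  res
}

# All random draws of one augmentation pass; called inside a fixed-seed
# context. Works channel-block-wise to avoid repeated full-matrix copies.
augment_draws <- function(matrix, config, org, sug, sds, reps) {
  n <- nrow(matrix$values)
  if (reps == 0L) return(matrix$values[0L, , drop = FALSE])
  src <- rep(seq_len(n), each = reps)
  vals <- matrix$values[src, , drop = FALSE]
  nr <- nrow(vals)
  chans <- unique(matrix$meta$channel[org])
  for (ch in chans) {
    cols <- org[matrix$meta$channel[org] == ch]
    rfs <- matrix$meta$rf[cols]
    step <- if (length(rfs) > 1L) min(diff(sort(rfs))) else 1
    a <- vals[, cols, drop = FALSE]
    if (config$rf_drift_bound > 0) {
      b <- config$rf_drift_bound
      # only columns that carry a band anywhere can move anything
      active <- which(colSums(matrix$values[, cols, drop = FALSE]) > 0)
      if (length(active)) {
        drift <- if (config$drift_distribution == "uniform")
          stats::runif(nr * length(active), -b, b)
        else pmin(pmax(stats::rnorm(nr * length(active), 0, b / 2), -b), b)
        d <- as.integer(round(drift / step))
        dim(d) <- c(nr, length(active))
        shifted <- base::matrix(0, nr, ncol(a))
        for (off in unique(as.vector(d))) {
          tc <- active + off
          keep <- tc >= 1L & tc <= ncol(a)
          if (!any(keep)) next
          contrib <- a[, active[keep], drop = FALSE] *
            (d[, keep, drop = FALSE] == off)
          shifted[, tc[keep]] <- pmax(shifted[, tc[keep], drop = FALSE],
                                      contrib)
        }
        a <- shifted
      }
    }
    if (config$au_noise_multiplier > 0)
      a <- a + stats::rnorm(length(a), 0, config$au_noise_multiplier * sds[[ch]])
    vals[, cols] <- pmax(a, 0)
  }
  if (length(sug) && config$sugar_noise_fraction > 0) {
    s <- vals[, sug, drop = FALSE]
    s <- s + stats::rnorm(length(s), 0, config$sugar_noise_fraction * abs(s))
    vals[, sug] <- pmax(s, 0)
  }
  vals
}
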