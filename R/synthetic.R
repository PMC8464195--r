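#' Blend a honey with a syrup at a mass fraction
#'
#' Linear mixing: every sugar and every organic band intensity of the blend
#' is `(1 - fraction) * honey + fraction * syrup`, over the union of band
#' positions. Increasing adulterant fractions therefore dilute the honey's
#' bands proportionally while the adulterant's marker sugars rise.
#'
#' @param honey,syrup [sample_record()] objects; the honey's base must be a
#'   honey code and the syrup a pure syrup.
#' @param fraction Adulterant mass fraction in `[0, 1]`.
#' @return A [sample_record()] labelled `<honey>-<syrup> <level>%` (or the
#'   pure parent at fractions 0 and 1).
#' @export
blend <- function(honey, syrup, fraction) {
  stopifnot(inherits(honey, "sample_record"), inherits(syrup, "sample_record"))
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1)
    stop("fraction must lie in [0, 1]", call. = FALSE)
  hl <- parse_sample_label(honey$label); sl <- parse_sample_label(syrup$label)
  if (!hl$base %in% honey_codes() || !is.na(hl$adulterant))
    stop("blend base must be a pure honey", call. = FALSE)
  if (!sl$base %in% syrup_codes() || !is.na(sl$adulterant))
    stop("blend adulterant must be a pure syrup", call. = FALSE)
  sugars <- (1 - fraction) * honey$sugars + fraction * syrup$sugars
  sugar_cvs <- (1 - fraction) * honey$sugar_cvs + fraction * syrup$sugar_cvs
  key <- function(b) paste(b$channel, sprintf("%.6f", b$rf))
  hb <- honey$bands; sb <- syrup$bands
  keys <- union(key(hb), key(sb))
  hau <- stats::setNames(rep(0, length(keys)), keys); sau <- hau
  hcv <- stats::setNames(rep(NA_real_, length(keys)), keys); scv <- hcv
  hau[key(hb)] <- hb$au; sau[key(sb)] <- sb$au
  hcv[key(hb)] <- hb$cv; scv[key(sb)] <- sb$cv
  au <- (1 - fraction) * hau + fraction * sau
  cv <- ifelse(is.na(hcv), scv, ifelse(is.na(scv), hcv,
               (1 - fraction) * hcv + fraction * scv))
  parts <- do.call(rbind, strsplit(keys, " ", fixed = TRUE))
  bands <- data.frame(channel = parts[, 1], rf = as.numeric(parts[, 2]),
                      au = unname(au), cv = unname(cv),
                      stringsAsFactors = FALSE)
  bands <- bands[order(match(bands$channel, channel_codes()), bands$rf), ]
  rownames(bands) <- NULL
  label <- if (fraction == 0) honey$label else if (fraction == 1) syrup$label
           else format_sample_label(hl$base, sl$base, round(100 * fraction))
  sample_record(label, sugars, bands, sugar_cvs)
}

#' Study design configuration
#'
#' The default design reproduces the canonical 68-sample study: 2 honeys +
#' 6 syrups + 2 x 6 x 5 blends at 10-50% w/w, with 5% multiplicative
#' truncated-Gaussian measurement noise on sugars and band intensities.
#'
#' @param honeys,syrups Product codes present in `templates`.
#' @param levels Adulteration levels, percent w/w.
#' @param templates Named list of [product_template()] objects.
#' @param noise_scale Global multiplier on the templates' dispersions
#'   (0 gives the noiseless mixing rule exactly).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return An object of class `study_design_config`.
#' @export
study_design_config <- function(honeys = honey_codes(),
                                syrups = syrup_codes(),
                                levels = adulteration_levels(),
                                templates = default_templates(),
                                noise_scale = 1,
                                seed = 1L) {
  if (anyDuplicated(c(honeys, syrups)))
    stop("duplicate product codes in design", call. = FALSE)
  stopifnot(all(c(honeys, syrups) %in% names(templates)), noise_scale >= 0)
  structure(list(honeys = honeys, syrups = syrups, levels = levels,
                 templates = templates, noise_scale = noise_scale,
                 seed = as.integer(seed)),
            class = "study_design_config")
}

#' Generate a synthetic study profile table
#'
#' Builds the noiseless profile of every pure product and every
#' (honey, syrup, level) blend by the linear mixing rule of [blend()], then
#' applies per-sample measurement noise: each sugar and band intensity is
#' multiplied by a truncated-Gaussian factor `max(0, N(1, cv *
#' noise_scale))` (band AU additionally capped at 1). With the default
#' design this yields 68 rows, of which 60 are blends.
#'
#' @param config A [study_design_config()].
#' @return A [profile_table()] with one row per sample.
#' @export
generate_study <- function(config = study_design_config()) {
  stopifnot(inherits(config, "study_design_config"))
  tpl <- config$templates
  pure <- lapply(c(config$honeys, config$syrups),
                 function(code) template_record(tpl[[code]]))
  names(pure) <- c(config$honeys, config$syrups)
  recs <- pure
  for (h in config$honeys)
    for (s in config$syrups)
      for (lv in config$levels)
        recs[[format_sample_label(h, s, lv)]] <- blend(pure[[h]], pure[[s]], lv / 100)
  # union band grid across all samples
  allb <- unique(do.call(rbind, lapply(recs, function(r)
    r$bands[, c("channel", "rf")])))
  allb <- allb[order(match(allb$channel, channel_codes()), allb$rf), ]
  rownames(allb) <- NULL
  key <- paste(allb$channel, sprintf("%.6f", allb$rf))
  fill <- function(r, col) {
    v <- stats::setNames(rep(0, length(key)), key)
    v[paste(r$bands$channel, sprintf("%.6f", r$bands$rf))] <- r$bands[[col]]
    v
  }
  organics <- t(vapply(recs, fill, numeric(length(key)), col = "au"))
  band_cvs <- t(vapply(recs, fill, numeric(length(key)), col = "cv"))
  sugars <- t(vapply(recs, function(r) r$sugars, numeric(4L)))
  sugar_cvs <- t(vapply(recs, function(r) r$sugar_cvs, numeric(4L)))
  colnames(sugars) <- sugar_names()

  if (config$noise_scale > 0) {
    withr::with_seed(config$seed, {
      # multiplicative truncated-Gaussian measurement noise, per value,
      # at the template-lineage dispersion scaled by noise_scale
      sugars <- sugars * pmax(0, matrix(
        stats::rnorm(length(sugars), 1, config$noise_scale * sugar_cvs),
        nrow(sugars)))
      organics <- organics * pmax(0, matrix(
        stats::rnorm(length(organics), 1, config$noise_scale * band_cvs),
        nrow(organics)))
      organics <- pmin(organics, 1)
    })
  }
  profile_table(names(recs), sugars, organics,
                data.frame(channel = allb$channel, rf = allb$rf,
                           stringsAsFactors = FALSE),
                provenance = sprintf("synthetic study (seed %d, noise %.3g)",
                                     config$seed, config$noise_scale))
}
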