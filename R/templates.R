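#' Product template
#'
#' Describes one pure product: mean sugar quantities (with per-sugar
#' coefficients of variation) and its organic-extract band set, one entry
#' per (channel, Rf) with a mean AU in `[0, 1]` and a relative AU
#' dispersion.
#'
#' @param code Product code.
#' @param sugar_means Named numeric vector over
#'   fructose/glucose/maltose/sucrose, all `>= 0`.
#' @param sugar_cvs Per-sugar coefficient of variation (recycled).
#' @param bands Data frame with columns `channel`, `rf` (in `(0, 1)`),
#'   `au` (mean intensity in `[0, 1]`) and `cv` (relative dispersion).
#' @return An object of class `product_template`.
#' @export
product_template <- function(code, sugar_means, sugar_cvs = 0.05, bands) {
  sugar_means <- sugar_means[sugar_names()]
  stopifnot(!anyNA(sugar_means), all(sugar_means >= 0))
  if (nrow(bands)) {
    stopifnot(all(bands$rf > 0 & bands$rf < 1),
              all(bands$au >= 0 & bands$au <= 1),
              all(bands$channel %in% channel_codes()))
  }
  structure(list(code = code, sugar_means = sugar_means,
                 sugar_cvs = rep_len(sugar_cvs, 4L),
                 bands = bands),
            class = "product_template")
}

band_set <- function(channel, rf, au, cv = 0.05) {
  data.frame(channel = channel, rf = rf, au = au, cv = cv,
             stringsAsFactors = FALSE)
}

#' Default product templates of the 68-sample study design
#'
#' Eight templates: the honeys MAN and JAR are fructose/glucose dominant
#' with trace maltose and no quantifiable sucrose, and each carries a rich,
#' distinctive organic fingerprint (six bands per imaging channel). Jarrah
#' is modelled with a markedly higher fructose/glucose ratio than Manuka,
#' the documented compositional contrast between the two honeys. The
#' maltose-rich syrups (RIC, COR, GLU) and sucrose-rich syrups (GOL, TRE,
#' MAP) carry realistic, mutually distinct marker-sugar loads; maple syrup
#' additionally shows its signifying organic band at Rf 0.41. Syrups
#' otherwise present no major organic bands, only faint traces.
#'
#' Sugar quantities are on the study's quantification scale (dynamic range
#' 0 to ~2,000); they are realistic stand-ins, not measured values.
#'
#' @return Named list of eight [product_template()] objects.
#' @export
default_templates <- function() {
  s <- function(f, g, m, su) c(fructose = f, glucose = g, maltose = m, sucrose = su)
  ch <- channel_codes()
  # Honey fingerprints: 6 bands per channel inside the modelled Rf window,
  # partially overlapping positions between the two honeys but with
  # different intensities, plus honey-specific positions.
  man_bands <- band_set(
    channel = rep(ch, each = 6L),
    rf = c(0.08, 0.14, 0.22, 0.33, 0.45, 0.55,
           0.10, 0.18, 0.27, 0.38, 0.48, 0.58,
           0.07, 0.16, 0.25, 0.36, 0.47, 0.57,
           0.09, 0.20, 0.30, 0.40, 0.50, 0.59),
    au = c(0.55, 0.80, 0.40, 0.70, 0.35, 0.60,
           0.65, 0.45, 0.85, 0.50, 0.75, 0.30,
           0.50, 0.70, 0.35, 0.80, 0.45, 0.55,
           0.60, 0.40, 0.75, 0.55, 0.65, 0.35))
  jar_bands <- band_set(
    channel = rep(ch, each = 6L),
    rf = c(0.11, 0.14, 0.24, 0.33, 0.42, 0.52,
           0.12, 0.21, 0.27, 0.35, 0.44, 0.54,
           0.13, 0.16, 0.28, 0.39, 0.49, 0.53,
           0.15, 0.23, 0.30, 0.37, 0.46, 0.56),
    au = c(0.70, 0.45, 0.60, 0.35, 0.80, 0.50,
           0.40, 0.75, 0.55, 0.85, 0.30, 0.65,
           0.75, 0.35, 0.65, 0.45, 0.70, 0.40,
           0.35, 0.80, 0.45, 0.70, 0.50, 0.60))
  list(
    MAN = product_template("MAN", s(820, 700, 30, 0), bands = man_bands),
    JAR = product_template("JAR", s(1050, 520, 25, 0), bands = jar_bands),
    # maltose-rich syrups: faint organic traces only
    RIC = product_template("RIC", s(30, 250, 550, 10),
                           bands = band_set("TW_D", 0.19, 0.06)),
    COR = product_template("COR", s(40, 350, 700, 15),
                           bands = band_set("TW_D", 0.26, 0.05)),
    GLU = product_template("GLU", s(20, 550, 420, 5),
                           bands = band_set("TW_D", 0.31, 0.04)),
    # sucrose-rich syrups: cane colourant traces, plus the maple marker
    GOL = product_template("GOL", s(350, 380, 20, 850),
                           bands = band_set(c("R366", "TW_D"),
                                            c(0.29, 0.34), c(0.12, 0.10))),
    TRE = product_template("TRE", s(300, 330, 25, 650),
                           bands = band_set(c("R366", "TW_D"),
                                            c(0.24, 0.43), c(0.15, 0.12))),
    MAP = product_template("MAP", s(60, 80, 10, 1450),
                           bands = band_set(c("R366", "R366_D", "TW_D"),
                                            c(0.41, 0.41, 0.12),
                                            c(0.80, 0.55, 0.08)))
  )
}

#' A single sample's profile
#'
#' @param label Canonical sample label.
#' @param sugars Named numeric vector over the four sugars.
#' @param bands Data frame `channel`, `rf`, `au` and (optionally) `cv`.
#' @param sugar_cvs Per-sugar relative measurement dispersion.
#' @return An object of class `sample_record`.
#' @export
sample_record <- function(label, sugars, bands, sugar_cvs = rep(0.05, 4L)) {
  if (!"cv" %in% names(bands)) bands$cv <- 0.05
  structure(list(label = label, sugars = sugars[sugar_names()], bands = bands,
                 sugar_cvs = rep_len(sugar_cvs, 4L)),
            class = "sample_record")
}

template_record <- function(tpl) {
  sample_record(tpl$code, tpl$sugar_means,
                tpl$bands[, c("channel", "rf", "au", "cv"), drop = FALSE],
                sugar_cvs = tpl$sugar_cvs)
}
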