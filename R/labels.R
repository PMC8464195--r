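#' Product codes used throughout the study design
#'
#' Two honeys (`MAN` Manuka, `JAR` Jarrah) and six syrup adulterants
#' (`RIC` rice, `COR` corn, `GOL` golden, `TRE` treacle, `GLU` glucose,
#' `MAP` maple).
#'
#' @format Character vectors of product codes.
#' @name product_codes
NULL

#' @rdname product_codes
#' @export
honey_codes <- function() c("MAN", "JAR")

#' @rdname product_codes
#' @export
syrup_codes <- function() c("RIC", "COR", "GOL", "TRE", "GLU", "MAP")

#' @rdname product_codes
#' @export
adulteration_levels <- function() c(10L, 20L, 30L, 40L, 50L)

#' The four HPTLC imaging channels
#'
#' 254 nm and 366 nm before derivatisation, transmittance white light and
#' 366 nm after derivatisation.
#'
#' @return Character vector of channel codes.
#' @export
channel_codes <- function() c("R254", "R366", "TW_D", "R366_D")

#' Parse a sample label of the study's naming scheme
#'
#' Labels are either a pure product code (`"JAR"`) or
#' `"<BASE>-<ADULTERANT> <LEVEL>%"` (`"MAN-RIC 10%"`). The separator
#' between base and adulterant may be a hyphen, space or underscore, and
#' the one before the level a space, hyphen or underscore; the trailing
#' `%` is optional.
#'
#' @param text Character vector of labels.
#' @return A data frame with columns `base`, `adulterant` (`NA` for pure
#'   products) and `level` (percent w/w, 0 for pure products).
#' @examples
#' parse_sample_label(c("MAN-RIC 10%", "JAR", "MAN-TRE 10%"))
#' @export
parse_sample_label <- function(text) {
  stopifnot(is.character(text), length(text) >= 1L)
  codes <- c(honey_codes(), syrup_codes())
  out <- data.frame(base = character(length(text)),
                    adulterant = NA_character_,
                    level = integer(length(text)),
                    stringsAsFactors = FALSE)
  txt <- trimws(text)
  for (i in seq_along(txt)) {
    s <- txt[i]
    if (grepl("^[A-Z]{3}$", s)) {
      if (!s %in% codes)
        stop("unknown product code: '", s, "'", call. = FALSE)
      out$base[i] <- s
      out$level[i] <- 0L
      next
    }
    m <- regmatches(s, regexec("^([A-Z]{3})[-_ ]([A-Z]{3})[-_ ]?([0-9]+)%?$", s))[[1]]
    if (length(m) != 4L)
      stop("cannot parse sample label: '", s, "'", call. = FALSE)
    base <- m[2]; adult <- m[3]; level <- as.integer(m[4])
    if (!base %in% codes) stop("unknown product code: '", base, "'", call. = FALSE)
    if (!adult %in% syrup_codes())
      stop("unknown adulterant code: '", adult, "'", call. = FALSE)
    if (!base %in% honey_codes())
      stop("adulterant given on a syrup base: '", s, "'", call. = FALSE)
    if (!level %in% adulteration_levels())
      stop("adulteration level outside 10-50%: '", s, "'", call. = FALSE)
    out$base[i] <- base; out$adulterant[i] <- adult; out$level[i] <- level
  }
  out
}

#' Format a sample label canonically
#'
#' The canonical form is `"MAN-RIC 10%"` for blends and the bare product
#' code for pure products. `parse_sample_label()` is a left inverse of this
#' formatter.
#'
#' @param base Product code(s).
#' @param adulterant Syrup code(s) or `NA` for pure products.
#' @param level Percent w/w (0 for pure products).
#' @return Character vector of canonical labels.
#' @export
format_sample_label <- function(base, adulterant = NA_character_, level = 0L) {
  n <- max(length(base), length(adulterant), length(level))
  base <- rep_len(base, n); adulterant <- rep_len(adulterant, n)
  level <- rep_len(as.integer(level), n)
  pure <- is.na(adulterant) | adulterant == ""
  if (any(pure & level != 0L) || any(!pure & level == 0L))
    stop("level must be 0 iff adulterant is absent", call. = FALSE)
  ifelse(pure, base, sprintf("%s-%s %d%%", base, adulterant, level))
}

#' All 68 sample labels of the full study design
#'
#' 2 honeys + 6 syrups + 2 x 6 x 5 blends, in deterministic order
#' (pure honeys, pure syrups, then blends by honey, syrup, level).
#'
#' @return Character vector of 68 canonical labels.
#' @export
design_labels <- function() {
  blends <- expand.grid(level = adulteration_levels(),
                        adulterant = syrup_codes(),
                        base = honey_codes(),
                        stringsAsFactors = FALSE)
  c(honey_codes(), syrup_codes(),
    format_sample_label(blends$base, blends$adulterant, blends$level))
}
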