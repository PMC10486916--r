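#' Estimated daily intake (EDI)
#'
#' Body-weight-normalised daily dose of an element through food
#' consumption, in mg/kg/day:
#'
#' \deqn{EDI = \frac{C \times EF \times ED \times IR \times f}{BW \times AT
#'   \times 1000}}
#'
#' where `C` is the element concentration in the food (mg/kg), `EF` the
#' exposure frequency (day/year), `ED` the exposure duration (year), `IR`
#' the ingestion rate (g/day), `f` the dimensionless toxic-fraction
#' multiplier (e.g. the inorganic fraction of total As), `BW` the body
#' weight (kg) and `AT` the averaging time (day). The factor 1000 converts
#' the ingestion rate from grams to kilograms. All arguments are vectorised
#' and recycled.
#'
#' @param c_metal Concentration, mg/kg (>= 0).
#' @param ef Exposure frequency, day/year (> 0).
#' @param ed Exposure duration, year (> 0).
#' @param ir Ingestion rate, g/day (> 0).
#' @param bw Body weight, kg (> 0).
#' @param at Averaging time, day (> 0).
#' @param f Toxic-fraction multiplier in (0, 1]; default 1.
#' @return Numeric vector of EDI values, mg/kg/day.
#' @examples
#' # mean-parameter Cd intake for children
#' edi(0.0379, ef = 296.667, ed = 4, ir = 32.9, bw = 16.68, at = 2190)
#' @export
edi <- function(c_metal, ef, ed, ir, bw, at, f = 1) {
  if (any(!is.finite(bw)) || any(bw <= 0)) {
    abort("body weight `bw` must be finite and > 0")
  }
  if (any(!is.finite(at)) || any(at <= 0)) {
    abort("averaging time `at` must be finite and > 0")
  }
  if (any(c_metal < 0, na.rm = TRUE)) {
    abort("concentration `c_metal` must be >= 0")
  }
  for (nm in c("ef", "ed", "ir", "f")) {
    v <- get(nm)
    if (any(!is.finite(v) | v <= 0)) {
      abort(paste0("`", nm, "` must be finite and > 0"))
    }
  }
  c_metal * ef * ed * ir * f / (bw * at * 1000)
}

#' Target hazard quotient (THQ)
#'
#' Ratio of the estimated daily intake to the element's reference dose
#' (or tolerable daily intake, used in the same slot for Pb). Values above
#' 1 flag potential non-carcinogenic risk.
#'
#' @param edi_value EDI, mg/kg/day (>= 0), vectorised.
#' @param rfd Reference dose (or TDI), mg/kg/day (> 0).
#' @param element Optional element name used in error messages.
#' @return Numeric vector of dimensionless quotients.
#' @examples
#' thq(4.05e-5, rfd = 1e-4)   # children mean-parameter Cd
#' @export
thq <- function(edi_value, rfd, element = NULL) {
  if (length(rfd) == 0 || any(is.na(rfd))) {
    abort(paste0("missing reference dose",
                 if (!is.null(element)) paste0(" for element '", element, "'")))
  }
  if (any(rfd <= 0)) {
    abort(paste0("reference dose must be > 0",
                 if (!is.null(element)) paste0(" (element '", element, "')")))
  }
  edi_value / rfd
}

#' Hazard index (HI)
#'
#' Sum of the individual target hazard quotients across elements; the
#' multi-contaminant non-carcinogenic risk metric. Order-independent.
#'
#' @param thqs Non-empty numeric vector of finite, non-negative THQs.
#' @return The arithmetic sum.
#' @examples
#' hazard_index(c(0.14, 0.43, 0, 0.02, 0.01))
#' @export
hazard_index <- function(thqs) {
  if (length(thqs) == 0) abort("`thqs` must be a non-empty numeric vector")
  if (any(!is.finite(thqs)) || any(thqs < 0)) {
    abort("all THQ values must be finite and >= 0")
  }
  sum(thqs)
}

#' Carcinogenic risk (CR)
#'
#' Lifetime incremental cancer probability, the estimated daily intake of
#' the carcinogen multiplied by its oral slope factor. The commonly used
#' acceptable band is 1e-6 to 1e-4.
#'
#' @param edi_value EDI of the carcinogenic species, mg/kg/day, vectorised.
#' @param sf Oral slope factor, (mg/kg/day)^-1 (> 0).
#' @param element Optional element name used in error messages.
#' @return Numeric vector of dimensionless risks.
#' @examples
#' carcinogenic_risk(1.47e-5, sf = 1.5)   # adult mean-parameter inorganic As
#' @export
carcinogenic_risk <- function(edi_value, sf, element = NULL) {
  if (length(sf) == 0 || any(is.na(sf))) {
    abort(paste0("missing slope factor",
                 if (!is.null(element)) paste0(" for element '", element, "'")))
  }
  if (any(sf <= 0)) {
    abort(paste0("slope factor must be > 0",
                 if (!is.null(element)) paste0(" (element '", element, "')")))
  }
  edi_value * sf
}
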