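## Heat production from open-circuit respiration-chamber gas exchange:
## Brouwer equation, methane energy, respiratory quotient, and extrapolation
## of the fasting window to a daily basis.

#' Gas-exchange window
#'
#' One measurement window in a respiration chamber: cumulative oxygen
#' consumption, carbon dioxide and methane production, urinary nitrogen
#' excreted over the window, the window duration, and the pig's body weight
#' for metabolic scaling.
#'
#' @param o2 O2 consumed, litres.
#' @param co2 CO2 produced, litres.
#' @param ch4 CH4 produced, litres.
#' @param urinary_n Urinary nitrogen excreted over the window, g.
#' @param duration Window duration, hours.
#' @param bw Body weight, kg.
#' @return An object of class `gas_window`.
#' @examples
#' w <- gas_window(o2 = 500, co2 = 535, ch4 = 10, urinary_n = 8,
#'                 duration = 24, bw = 40)
#' brouwer_hp(w)
#' @export
gas_window <- function(o2, co2, ch4 = 0, urinary_n = 0, duration = 24, bw = NA) {
  vols <- c(o2 = o2, co2 = co2, ch4 = ch4)
  if (any(vols < 0)) stop("gas volumes must be nonnegative")
  if (urinary_n < 0) stop("urinary nitrogen must be nonnegative")
  if (duration <= 0) stop("duration must be positive")
  structure(list(o2 = o2, co2 = co2, ch4 = ch4, urinary_n = urinary_n,
                 duration = duration, bw = bw), class = "gas_window")
}

#' Heat production by the Brouwer equation
#'
#' HP (kJ) = 16.18 O2 (L) + 5.02 CO2 (L) - 2.17 CH4 (L) - 5.99 urinary N (g).
#'
#' @param o2 A `gas_window`, or O2 consumed in litres.
#' @param co2,ch4,urinary_n CO2 and CH4 produced (L) and urinary N (g);
#'   ignored when `o2` is a `gas_window`.
#' @return Heat production over the window, kJ.
#' @examples
#' brouwer_hp(500, 535, 10, 8)
#' @export
brouwer_hp <- function(o2, co2 = NULL, ch4 = 0, urinary_n = 0) {
  if (inherits(o2, "gas_window")) {
    w <- o2
    o2 <- w$o2; co2 <- w$co2; ch4 <- w$ch4; urinary_n <- w$urinary_n
  }
  stopifnot(is.numeric(o2), is.numeric(co2))
  16.18 * o2 + 5.02 * co2 - 2.17 * ch4 - 5.99 * urinary_n
}

#' Energy lost as methane
#'
#' Methane energy (kJ) = 39.5 kJ/L x CH4 volume (L).
#'
#' @param ch4 Methane produced, litres.
#' @return Energy, kJ.
#' @examples
#' methane_energy(12.4)
#' @export
methane_energy <- function(ch4) {
  stopifnot(is.numeric(ch4))
  if (any(ch4 < 0)) stop("CH4 volume must be nonnegative")
  CH4_KJ_PER_L * ch4
}

#' Respiratory quotient
#'
#' Ratio between CO2 production and O2 consumption.
#'
#' @param o2 A `gas_window`, or O2 consumed (L); must be positive.
#' @param co2 CO2 produced (L); ignored when `o2` is a `gas_window`.
#' @return RQ, dimensionless.
#' @examples
#' respiratory_quotient(400, 428)
#' @export
respiratory_quotient <- function(o2, co2 = NULL) {
  if (inherits(o2, "gas_window")) {
    co2 <- o2$co2; o2 <- o2$o2
  }
  if (any(o2 <= 0)) stop("O2 consumption must be positive")
  co2 / o2
}

#' Heat production result for a window
#'
#' Computes window heat production (Brouwer), its daily extrapolation
#' HP x (24 / duration), metabolic scaling by kg BW^0.60, and the
#' respiratory quotient.
#'
#' @param window A `gas_window` with `bw` set for metabolic scaling.
#' @return A list of class `hp_result` with `HP` (kJ/window), `HP_daily`
#'   (kJ/d), `HP_metabolic` (kJ/kg BW^0.60/d, `NA` without body weight) and
#'   `RQ`.
#' @export
heat_production <- function(window) {
  stopifnot(inherits(window, "gas_window"))
  hp <- brouwer_hp(window)
  hp_daily <- hp * 24 / window$duration
  structure(list(
    HP = hp,
    HP_daily = hp_daily,
    HP_metabolic = if (is.na(window$bw)) NA_real_ else
      hp_daily / metabolic_bw(window$bw),
    RQ = if (window$o2 > 0) respiratory_quotient(window) else NA_real_
  ), class = "hp_result")
}

#' @export
print.hp_result <- function(x, ...) {
  cat(sprintf("HP %.1f kJ | %.1f kJ/d | %s kJ/kg BW^0.6/d | RQ %s\n",
              x$HP, x$HP_daily,
              ifelse(is.na(x$HP_metabolic), "-", sprintf("%.1f", x$HP_metabolic)),
              ifelse(is.na(x$RQ), "-", sprintf("%.3f", x$RQ))))
  invisible(x)
}

#' Fasting heat production extrapolated to 24 h
#'
#' Fasting heat production (FHP) is measured over a short overnight window
#' (8 h by protocol) at the end of the chamber stay; to put it on the same
#' basis as total heat production it is extrapolated to a 24-h period:
#' FHP_daily = window HP x (24 / duration).
#'
#' @param fasting_window A `gas_window` for the fasting period; its
#'   `urinary_n` is the nitrogen excreted during that window.
#' @return An `hp_result` (see [heat_production()]) on the daily basis.
#' @examples
#' w <- gas_window(o2 = 120, co2 = 98, urinary_n = 1.5, duration = 8, bw = 40)
#' extrapolate_fhp(w)$HP_daily
#' @export
extrapolate_fhp <- function(fasting_window) {
  heat_production(fasting_window)
}

#' Gas volumes from a target heat production (Brouwer inversion)
#'
#' Solves the Brouwer equation for O2 at a given respiratory quotient:
#' O2 = (HP + 2.17 CH4 + 5.99 N) / (16.18 + 5.02 RQ), CO2 = RQ x O2. Used by
#' the simulator to construct gas volumes consistent with a target HP.
#'
#' @param hp Target heat production over the window, kJ.
#' @param rq Respiratory quotient.
#' @param ch4 Methane produced, litres.
#' @param urinary_n Urinary nitrogen, g.
#' @return List with `o2` and `co2`, litres.
#' @export
invert_brouwer <- function(hp, rq, ch4 = 0, urinary_n = 0) {
  if (any(hp < 0)) stop("target HP must be nonnegative")
  if (any(rq <= 0)) stop("RQ must be positive")
  o2 <- (hp + 2.17 * ch4 + 5.99 * urinary_n) / (16.18 + 5.02 * rq)
  list(o2 = o2, co2 = rq * o2)
}
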