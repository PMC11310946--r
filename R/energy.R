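#' Energy-model parameters
#'
#' One container for every coefficient of the energy mathematics, so that a
#' run can log (and override) the exact model it used.
#'
#' The behavior equations are, with `Ta` ambient temperature (deg C), `W`
#' body weight (kg) and `DBA` the interval mean VeDBA in `dba_unit`:
#' \itemize{
#'   \item standing / eating / ruminating:
#'     `E = c0 + ct2*Ta^2 - ct1*Ta + W + DBA`
#'   \item lying: the same base expression multiplied by `f_lying` (0.29)
#'   \item walking: `E = w0 + w1*DBA + Ta + W`
#'   \item running (optional): `f_run` (2.5) times walking
#' }
#' The equations are dimensionally inhomogeneous (kg, deg C and acceleration
#' are added), so the result is a nominal energy indicator treated as J per
#' aggregation interval, not a calibrated measurement; coefficients are
#' applied exactly as printed.
#'
#' The VO2 pathway (an immobile animal consumes `vo2_rest` mL O2/kg/min;
#' walking adds `vo2_level` or `vo2_incline` per g of VeDBA) and the
#' respiratory equivalent `re` (litres O2 per unit energy, near 5 for a
#' protein-dominated pasture diet) are kept alongside for analysis; the
#' pipeline itself uses the behavior equations.
#'
#' @param c0,ct2,ct1 base-expression coefficients (66.98, 0.15 per degC^2,
#'   7.97 per degC).
#' @param f_lying lying multiplier, in (0,1); default 0.29.
#' @param w0,w1 walking intercept and DBA slope (-75.622, 642.345 per DBA
#'   unit).
#' @param f_run running multiplier (> 1); default 2.5.
#' @param vo2_rest,vo2_level,vo2_incline VO2 coefficients (3.67 mL O2/kg/min
#'   at rest; slopes 13.72 and 36.31 per g of VeDBA).
#' @param re respiratory equivalent, litres O2 per unit energy; validated to
#'   lie in `[4.3, 5]` by default.
#' @param dba_unit unit in which DBA enters the behavior equations: `"mG"`
#'   (default) or `"g"`. See the package vignette for why mG is the default.
#' @param lying_factor_mode `"multiply_0.29"` (default; the printed lying
#'   equation multiplies the whole base expression by 0.29) or
#'   `"reduce_29pct"` (the prose reading: 29% less than standing, i.e. x0.71).
#' @return an `energy_params` list.
#' @export
energy_params <- function(c0 = 66.98, ct2 = 0.15, ct1 = 7.97,
                          f_lying = 0.29,
                          w0 = -75.622, w1 = 642.345,
                          f_run = 2.5,
                          vo2_rest = 3.67, vo2_level = 13.72,
                          vo2_incline = 36.31,
                          re = 5,
                          dba_unit = c("mG", "g"),
                          lying_factor_mode = c("multiply_0.29",
                                                "reduce_29pct")) {
  dba_unit <- match.arg(dba_unit)
  lying_factor_mode <- match.arg(lying_factor_mode)
  p <- list(c0 = c0, ct2 = ct2, ct1 = ct1, f_lying = f_lying,
            w0 = w0, w1 = w1, f_run = f_run,
            vo2_rest = vo2_rest, vo2_level = vo2_level,
            vo2_incline = vo2_incline, re = re,
            dba_unit = dba_unit, lying_factor_mode = lying_factor_mode)
  nums <- unlist(p[sapply(p, is.numeric)])
  if (!all(is.finite(nums))) stop("all coefficients must be finite", call. = FALSE)
  if (p$f_lying <= 0 || p$f_lying >= 1) {
    stop("f_lying must lie in (0, 1)", call. = FALSE)
  }
  if (p$f_run <= 1) stop("f_run must exceed 1", call. = FALSE)
  if (p$re < 4.3 || p$re > 5) {
    stop("re outside the plausible [4.3, 5] L O2 per unit energy range",
         call. = FALSE)
  }
  structure(p, class = "energy_params")
}

#' Mass-specific oxygen-consumption rate
#'
#' Treadmill-derived VO2 models: an immobile animal consumes a fixed rate;
#' walking on level or inclined ground adds a linear VeDBA term. VeDBA is in
#' g here (these models were fitted in g).
#'
#' @param vedba_g VeDBA in g; must be non-negative.
#' @param mode `"stationary"`, `"level_walk"` or `"incline_walk"`.
#' @param params an [energy_params()] object.
#' @return VO2 rate in mL O2 per kg per minute (vectorized over `vedba_g`).
#' @export
#' @examples
#' vo2_rate(0, "stationary")    # 3.67
#' vo2_rate(1, "level_walk")    # 17.39
vo2_rate <- function(vedba_g,
                     mode = c("stationary", "level_walk", "incline_walk"),
                     params = energy_params()) {
  mode <- match.arg(mode)
  if (any(vedba_g < 0)) stop("vedba_g must be non-negative", call. = FALSE)
  switch(mode,
    stationary = rep(params$vo2_rest, length(vedba_g)),
    level_walk = params$vo2_level * vedba_g + params$vo2_rest,
    incline_walk = params$vo2_incline * vedba_g + params$vo2_rest
  )
}

#' Convert an oxygen volume to energy via the respiratory equivalent
#'
#' The respiratory equivalent RE is the volume of oxygen consumed per unit
#' of energy produced, so `energy = VO2 / RE`.
#'
#' @param vo2_volume litres of O2 consumed.
#' @param re respiratory equivalent (litres O2 per unit energy); must be
#'   positive.
#' @return energy in the unit implied by `re`.
#' @export
re_convert <- function(vo2_volume, re = energy_params()$re) {
  if (any(re <= 0)) stop("re must be positive", call. = FALSE)
  vo2_volume / re
}

#' Quadratic temperature term of the base energy equation
#'
#' `ct2 * Ta^2 - ct1 * Ta`; with the default coefficients its minimum sits
#' at 26.57 deg C, inside the 22-30 deg C thermal comfort zone of sheep —
#' energy cost rises as temperature departs the comfort zone in either
#' direction.
#'
#' @param ta ambient temperature in deg C (vectorized).
#' @param params an [energy_params()] object.
#' @return numeric vector.
#' @export
temperature_term <- function(ta, params = energy_params()) {
  params$ct2 * ta^2 - params$ct1 * ta
}

#' Behavior-conditioned energy for one aggregation interval
#'
#' Applies the behavior equation for each interval's predominant behavior.
#' E, R and S share the base expression; L multiplies it by `f_lying`; W uses
#' the walking expression; RUN is `f_run` times walking. Negative results
#' (possible for walking at tiny DBA) are returned as-is and flagged via the
#' `"flagged"` attribute — never clamped.
#'
#' @param behavior character vector of behavior codes (see
#'   [behavior_codes()], `RUN` allowed).
#' @param ta ambient temperature(s), deg C.
#' @param weight_kg body weight(s), kg, positive.
#' @param dba interval DBA (mean VeDBA), non-negative, expressed in
#'   `params$dba_unit`.
#' @param params an [energy_params()] object.
#' @return numeric vector of nominal energy per interval (treated as J);
#'   attribute `"flagged"` is a logical vector marking negative values.
#' @export
#' @examples
#' behavior_energy("S", ta = 0, weight_kg = 60, dba = 0)
#' behavior_energy("L", 15, 60, 100) / behavior_energy("S", 15, 60, 100) # 0.29
behavior_energy <- function(behavior, ta, weight_kg, dba,
                            params = energy_params()) {
  assert_behaviors(behavior)
  if (any(weight_kg <= 0)) stop("weight_kg must be positive", call. = FALSE)
  if (any(dba < 0)) stop("dba must be non-negative", call. = FALSE)
  n <- max(length(behavior), length(ta), length(weight_kg), length(dba))
  behavior <- rep_len(behavior, n)
  ta <- rep_len(ta, n)
  weight_kg <- rep_len(weight_kg, n)
  dba <- rep_len(dba, n)

  base <- params$c0 + temperature_term(ta, params) + weight_kg + dba
  walking <- params$w0 + params$w1 * dba + ta + weight_kg
  lf <- if (params$lying_factor_mode == "multiply_0.29") {
    params$f_lying
  } else {
    1 - params$f_lying
  }

  e <- numeric(n)
  is_base <- behavior %in% c("E", "R", "S")
  e[is_base] <- base[is_base]
  e[behavior == "L"] <- base[behavior == "L"] * lf
  e[behavior == "W"] <- walking[behavior == "W"]
  e[behavior == "RUN"] <- params$f_run * walking[behavior == "RUN"]

  flagged <- e < 0
  if (any(flagged)) {
    warning(sum(flagged), " negative energy value(s) flagged (not clamped)",
            call. = FALSE)
  }
  attr(e, "flagged") <- flagged
  e
}
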