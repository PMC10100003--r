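# Response-curve primitives: the four-parameter VOD->AGC calibration curve,
# the Chapman-Richards secondary-forest regrowth curve and the saturating
# forest-edge loss curve. These parameterizations are shared by the synthetic
# truth generator and the bookkeeping model so closed-loop tests are exact.

OVERFLOW_SENTINEL <- 1e10

#' Four-parameter VOD-to-AGC calibration curve
#'
#' Saturating logistic `AGC(V) = d + (a - d) / (1 + exp(-b (V - c)))` mapping
#' an annual L-VOD index to above-ground carbon density (Mg C ha^-1). `d` is
#' the low-VOD floor, `a` the high-VOD asymptote, `c` the inflection VOD and
#' `b` the steepness. The functional body is pluggable: any strategy with the
#' same four-parameter signature can replace it via `form`.
#'
#' @param a,b,c,d Curve parameters.
#' @param se Optional named numeric vector of standard errors (a, b, c, d).
#' @param index_method Which annual index the curve was fitted on
#'   (`"max_smooth"`, `"mean_smooth"`, `"mean_trend"`, or `"truth"`).
#' @param form Either `"logistic"` (default) or a function `(vod, a, b, c, d)`.
#' @return Object of class `calibration_curve`.
#' @export
#' @examples
#' cc <- calibration_curve(a = 180, b = 12, c = 0.45, d = 0)
#' vod_to_agc(cc, c(0.3, 0.5, 0.7))
calibration_curve <- function(a, b, c, d, se = NULL,
                              index_method = "truth", form = "logistic") {
  fun <- if (is.function(form)) {
    form
  } else if (identical(form, "logistic")) {
    function(vod, a, b, c, d) d + (a - d) / (1 + exp(-b * (vod - c)))
  } else {
    stop("unknown calibration form: ", form)
  }
  structure(
    list(a = a, b = b, c = c, d = d, se = se, index_method = index_method,
         form = if (is.function(form)) "custom" else form, fun = fun,
         overflow_sentinel = OVERFLOW_SENTINEL),
    class = "calibration_curve"
  )
}

#' Evaluate a calibration curve (VOD index -> AGC density)
#'
#' Non-finite curve output is replaced by the overflow sentinel 1e10; negative
#' output is clipped to zero and counted in the `"clipped"` attribute.
#'
#' @param curve A [calibration_curve()].
#' @param vod Numeric vector of VOD index values (must be finite).
#' @return AGC densities in Mg C ha^-1. Negative evaluations are clipped to
#'   0 with a warning reporting the count.
#' @export
vod_to_agc <- function(curve, vod) {
  stopifnot(inherits(curve, "calibration_curve"), all(is.finite(vod)))
  out <- curve$fun(vod, curve$a, curve$b, curve$c, curve$d)
  out[!is.finite(out)] <- curve$overflow_sentinel
  n_clip <- sum(out < 0)
  if (n_clip > 0) {
    warning(n_clip, " negative AGC value(s) clipped to 0")
    out[out < 0] <- 0
  }
  out
}

#' Invert a calibration curve (AGC density -> VOD index)
#'
#' Analytic inverse of the logistic form; used by the synthetic L-VOD
#' generator. Densities must lie strictly inside (d, a).
#'
#' @param curve A logistic [calibration_curve()].
#' @param agc AGC densities, Mg C ha^-1.
#' @return VOD index values.
#' @export
agc_to_vod <- function(curve, agc) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!identical(curve$form, "logistic")) {
    stop("analytic inverse only available for the logistic form")
  }
  lo <- min(curve$d, curve$a); hi <- max(curve$d, curve$a)
  if (any(agc <= lo | agc >= hi)) {
    stop("calibration curve not invertible at the requested AGC density ",
         "(outside (", lo, ", ", hi, "))")
  }
  curve$c - log((curve$a - curve$d) / (agc - curve$d) - 1) / curve$b
}

#' Chapman-Richards secondary-forest regrowth curve
#'
#' `AGC(t) = A (1 - exp(-k t))^theta`: AGC density of secondary forest as a
#' function of stand age in years. AGC(0) = 0, non-decreasing, asymptote `A`.
#'
#' @param A Asymptotic AGC density, Mg C ha^-1.
#' @param k Rate constant, yr^-1.
#' @param theta Shape parameter (>= 1 gives the usual sigmoid onset).
#' @return Object of class `growth_curve`, callable via [growth_agc()].
#' @export
growth_curve <- function(A = 110, k = 0.035, theta = 1.6) {
  stopifnot(A >= 0, k >= 0, theta > 0)
  structure(list(A = A, k = k, theta = theta), class = "growth_curve")
}

#' Secondary-forest AGC density at a given age
#' @param curve A [growth_curve()].
#' @param age Stand age in years (>= 0).
#' @return AGC density, Mg C ha^-1.
#' @export
growth_agc <- function(curve, age) {
  stopifnot(inherits(curve, "growth_curve"), all(age >= 0))
  curve$A * (1 - exp(-curve$k * age))^curve$theta
}

#' Saturating forest-edge biomass-loss curve
#'
#' `loss(a) = L_inf (1 - exp(-r a))`: cumulative fraction of the old-growth
#' reference AGC lost in edge-affected forest as a function of edge age.
#' loss(0) = 0, non-decreasing, asymptote `L_inf` < 1.
#'
#' @param L_inf Asymptotic cumulative loss fraction.
#' @param r Rate constant, yr^-1.
#' @return Object of class `edge_loss_curve`, callable via [edge_loss()].
#' @export
edge_loss_curve <- function(L_inf = 0.36, r = 0.2) {
  stopifnot(L_inf >= 0, L_inf < 1, r >= 0)
  structure(list(L_inf = L_inf, r = r), class = "edge_loss_curve")
}

#' Cumulative edge loss fraction at a given edge age
#'
#' With `floor_frac` > 0 the cumulative loss is `max(floor_frac, loss(a))`:
#' used for edge pixels that already carried the non-edge degradation loss
#' when the edge reached them, so further edge increments only accrue beyond
#' the loss already incurred (keeps increments <= 0 in the bookkeeping).
#'
#' @param curve An [edge_loss_curve()].
#' @param age Edge age in years (>= 0).
#' @param floor_frac Pre-existing loss fraction (scalar or vector).
#' @return Cumulative loss fraction in `[0, 1)`.
#' @export
edge_loss <- function(curve, age, floor_frac = 0) {
  stopifnot(inherits(curve, "edge_loss_curve"), all(age >= 0))
  pmax(floor_frac, curve$L_inf * (1 - exp(-curve$r * age)))
}

#' Persist a calibration curve to YAML
#' @param curve A [calibration_curve()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_calibration_curve <- function(curve, path) {
  obj <- curve[c("a", "b", "c", "d", "index_method", "form",
                 "overflow_sentinel")]
  obj$se <- as.list(curve$se)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a calibration curve from YAML
#' @param path File written by [write_calibration_curve()].
#' @return A [calibration_curve()].
#' @export
read_calibration_curve <- function(path) {
  obj <- yaml::read_yaml(path)
  calibration_curve(obj$a, obj$b, obj$c, obj$d,
                    se = unlist(obj$se), index_method = obj$index_method,
                    form = obj$form)
}
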