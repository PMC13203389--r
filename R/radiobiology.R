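#' Dose-volume histogram bins
#'
#' @param vol volumes per bin (absolute or fractional, >= 0).
#' @param dose dose per bin in Gy (>= 0).
#' @param vol_ref reference (whole-organ) volume; defaults to `sum(vol)`.
#' @return object of class `dvh_bins`.
#' @export
dvh_bins <- function(vol, dose, vol_ref = sum(vol)) {
  if (length(vol) != length(dose)) stop("vol and dose must align")
  if (any(vol < 0) || any(dose < 0)) stop("volumes and doses must be >= 0")
  if (sum(vol) > vol_ref * (1 + 1e-9))
    stop("bin volumes exceed the reference volume")
  structure(list(vol = as.numeric(vol), dose = as.numeric(dose),
                 vol_ref = vol_ref),
            class = "dvh_bins")
}

#' LKB model parameters
#'
#' @param n volume-effect parameter (> 0; 1 = parallel architecture,
#'   small n = serial).
#' @param m slope parameter (> 0, inversely related to the dose-response
#'   steepness).
#' @param TD50 dose with 50 percent complication probability, Gy.
#' @return object of class `lkb_params`.
#' @export
lkb_params <- function(n, m, TD50) {
  if (n <= 0 || m <= 0 || TD50 <= 0) stop("n, m and TD50 must be positive")
  structure(list(n = n, m = m, TD50 = TD50), class = "lkb_params")
}

#' LKB effective volume
#'
#' DVH reduction `Voleff = (1/Volref) * sum Vol_i * (D_i / Dmax)^(1/n)`:
#' the whole-organ partial volume that, irradiated uniformly at Dmax, is
#' biologically equivalent to the histogram.
#'
#' @param bins a [dvh_bins()].
#' @param Dmax maximal organ dose in Gy (>= every bin dose).
#' @param n LKB volume-effect parameter.
#' @return effective volume as a fraction of the reference volume.
#' @export
effective_volume <- function(bins, Dmax, n) {
  if (Dmax < max(bins$dose)) stop("Dmax must be >= the largest bin dose")
  if (Dmax <= 0) stop("Dmax must be positive")
  sum(bins$vol * (bins$dose / Dmax)^(1 / n)) / bins$vol_ref
}

#' LKB intermediate variable t
#'
#' `t = (Dmax - TD50(Voleff)) / (m * TD50(Voleff))` with the standard
#' power-law volume dependence `TD50(v) = TD50 * v^(-n)`.
#'
#' @param Dmax maximal organ dose, Gy.
#' @param params an [lkb_params()].
#' @param Voleff effective volume fraction (> 0).
#' @return dimensionless t.
#' @export
lkb_t <- function(Dmax, params, Voleff) {
  if (Voleff <= 0) stop("Voleff must be positive")
  td50v <- params$TD50 * Voleff^(-params$n)
  (Dmax - td50v) / (params$m * td50v)
}

#' Normal tissue complication probability
#'
#' The LKB sigmoid `0.5 + erf(t / sqrt(2)) / 2`, i.e. the standard normal
#' CDF of t.
#'
#' @param t value from [lkb_t()]; vectorised.
#' @return probability in [0, 1].
#' @export
ntcp <- function(t) stats::pnorm(t)

#' Serial-organ beam intersection flags
#'
#' For each organ with serial architecture, reports whether the beam axis
#' traverses it and, if so, the location of the maximum-PDD point within
#' the traversed interval: the effective depth clamped to the peak depth
#' dmax (the peak itself when the interval straddles it, the interval
#' entry when the whole interval lies beyond the peak, the exit when it
#' lies before).
#'
#' @param r a [ray()].
#' @param organs organ list as for [trace_beam()], with an `architecture`
#'   field per organ.
#' @param model a [pdd_model()].
#' @param segments optional precomputed [trace_beam()] output over all
#'   organs (recomputed when NULL).
#' @return data.frame with one row per serial organ: `label`, `hit`,
#'   `deff_in_cm`, `deff_out_cm`, `deff_peak_cm`, `pdd_peak_pct`.
#' @export
serial_organ_hits <- function(r, organs, model, segments = NULL) {
  serial <- Filter(function(o) identical(o$architecture, "serial"), organs)
  if (!length(serial))
    return(data.frame(label = integer(0), hit = logical(0),
                      deff_in_cm = numeric(0), deff_out_cm = numeric(0),
                      deff_peak_cm = numeric(0), pdd_peak_pct = numeric(0)))
  if (is.null(segments)) segments <- trace_beam(r, organs)
  rows <- lapply(serial, function(o) {
    seg <- segments[segments$label == o$label, , drop = FALSE]
    if (!nrow(seg))
      return(data.frame(label = o$label, hit = FALSE, deff_in_cm = NA_real_,
                        deff_out_cm = NA_real_, deff_peak_cm = NA_real_,
                        pdd_peak_pct = NA_real_))
    d_in <- effective_depth(segments, min(seg$t_in))
    d_out <- effective_depth(segments, max(seg$t_out))
    d_peak <- min(max(model$dmax, d_in), d_out)
    data.frame(label = o$label, hit = TRUE, deff_in_cm = d_in,
               deff_out_cm = d_out, deff_peak_cm = d_peak,
               pdd_peak_pct = pdd(d_peak, model))
  })
  do.call(rbind, rows)
}

#' Area under a depth-versus-gantry-angle profile
#'
#' Trapezoidal integral of tumour depth over gantry angle, a proxy for the
#' irradiated normal-tissue volume: lower is better when ranking beam
#' arrangements for parallel organs.
#'
#' @param profile data.frame with columns `angle` (degrees, strictly
#'   increasing, spanning at most 360) and `depth` (cm).
#' @return area in degree-cm.
#' @export
depth_angle_auc <- function(profile) {
  a <- profile$angle; d <- profile$depth
  if (is.unsorted(a, strictly = TRUE)) stop("angles must be strictly increasing")
  if (diff(range(a)) > 360) stop("angles must span at most 360 degrees")
  sum(diff(a) * (d[-1] + d[-length(d)]) / 2)
}
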