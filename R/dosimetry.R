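#' Raw buildup-tail depth-dose shape
#'
#' The unnormalised shape `d / (d^2 + n) * exp(-mu * d)`: a quadratic
#' buildup toward the peak multiplied by an exponential attenuation tail.
#'
#' @param d depth in cm (>= 0); vectorised.
#' @param n diffusion parameter (cm^2), > 0.
#' @param mu linear attenuation coefficient (1/cm), > 0.
#' @return dimensionless shape values.
#' @export
buildup_tail_raw <- function(d, n, mu) {
  if (any(d < 0)) stop("depth must be >= 0")
  d / (d^2 + n) * exp(-mu * d)
}

#' Depth of maximum dose
#'
#' Locates the unique maximum of the buildup-tail shape on (0, 50] cm by
#' golden-section search (uniqueness for this model family is checked by
#' grid scans in the test suite). In the mu -> 0 limit the peak is at
#' sqrt(n).
#'
#' @param n,mu buildup-tail parameters.
#' @return dmax in cm.
#' @export
find_dmax <- function(n, mu) {
  if (n <= 0 || mu <= 0) stop("n and mu must be positive")
  optimize(function(d) buildup_tail_raw(d, n, mu),
           interval = c(1e-9, 50), maximum = TRUE, tol = 1e-9)$maximum
}

#' Percentage depth dose model
#'
#' A buildup-tail shape normalised to 100 percent at its own depth of
#' maximum dose, keyed by photon energy and field size.
#'
#' @param n diffusion parameter (cm^2).
#' @param mu attenuation coefficient (1/cm).
#' @param energy_tag free-text beam energy label (e.g. "6MV").
#' @param field_size field size in cm (metadata; no analytic field-size
#'   dependence is modelled).
#' @return object of class `pdd_model` with cached `dmax`.
#' @export
pdd_model <- function(n = 2.25, mu = 0.0465, energy_tag = "6MV",
                      field_size = 10) {
  if (n <= 0 || mu <= 0) stop("n and mu must be positive")
  structure(list(n = n, mu = mu, dmax = find_dmax(n, mu),
                 energy_tag = energy_tag, field_size = field_size),
            class = "pdd_model")
}

#' @export
print.pdd_model <- function(x, ...) {
  cat(sprintf("<pdd_model> %s, n = %g cm^2, mu = %g /cm, dmax = %.3f cm\n",
              x$energy_tag, x$n, x$mu, x$dmax))
  invisible(x)
}

#' Machine calibration factors
#'
#' @param Dref calibration dose in cGy/MU at reference depth.
#' @param dref reference depth in cm.
#' @param SSD0 reference source-to-surface distance in cm.
#' @param Scrc collimator scatter factor.
#' @param Spr phantom scatter factor.
#' @param Ks scatter factor between depth d and dmax (defaults to 1; it is
#'   a named calibration input with no universal value).
#' @return object of class `machine_calibration`.
#' @export
machine_calibration <- function(Dref = 1, dref = 10, SSD0 = 100,
                                Scrc = 1, Spr = 1, Ks = 1) {
  vals <- c(Dref, dref, SSD0, Scrc, Spr, Ks)
  if (any(vals <= 0)) stop("all calibration factors must be positive")
  structure(list(Dref = Dref, dref = dref, SSD0 = SSD0, Scrc = Scrc,
                 Spr = Spr, Ks = Ks),
            class = "machine_calibration")
}

#' Percentage depth dose
#'
#' `100 * shape(d) / shape(dmax)`; 100 at dmax, 0 at the surface, strictly
#' decreasing beyond the peak.
#'
#' @param d depth in cm (vectorised).
#' @param model a [pdd_model()].
#' @return PDD in percent, within [0, 100].
#' @export
pdd <- function(d, model) {
  100 * buildup_tail_raw(d, model$n, model$mu) /
    buildup_tail_raw(model$dmax, model$n, model$mu)
}

#' PDD at an explicit source-to-surface distance
#'
#' Inverse-square plus attenuation form
#' `100 * ((SSD + dmax) / (SSD + d))^2 * exp(-mu (d - dmax)) * Ks`.
#' Raw (unclipped) by default; `clip = TRUE` caps the buildup region at
#' 100.
#'
#' @param d depth in cm.
#' @param ssd source-to-surface distance in cm.
#' @param model a [pdd_model()].
#' @param cal a [machine_calibration()] supplying Ks.
#' @param clip cap values at 100 for d < dmax.
#' @return PDD in percent.
#' @export
pdd_at_ssd <- function(d, ssd, model, cal = machine_calibration(),
                       clip = FALSE) {
  if (any(d < 0) || any(ssd <= 0)) stop("d >= 0 and ssd > 0 required")
  v <- 100 * ((ssd + model$dmax) / (ssd + d))^2 *
    exp(-model$mu * (d - model$dmax)) * cal$Ks
  if (clip) v <- ifelse(d < model$dmax, pmin(v, 100), v)
  v
}

#' Mayneord SSD-correction factor
#'
#' `F = ((SSD2 + dmax)/(SSD1 + dmax))^2 * ((SSD1 + d)/(SSD2 + d))^2`,
#' converting PDD measured at SSD1 to SSD2. Identity when the SSDs agree or
#' at the peak depth; reciprocal when the SSDs are swapped.
#'
#' @param ssd1,ssd2 source-to-surface distances in cm.
#' @param d depth in cm.
#' @param dmax peak depth in cm.
#' @return dimensionless factor.
#' @export
mayneord_factor <- function(ssd1, ssd2, d, dmax) {
  if (any(c(ssd1, ssd2, d, dmax) <= 0)) stop("all arguments must be positive")
  ((ssd2 + dmax) / (ssd1 + dmax))^2 * ((ssd1 + d) / (ssd2 + d))^2
}

#' Water-equivalent (effective) depth along a beam
#'
#' Sums `z_i * eta_i` over the traversed path up to a target distance along
#' the ray, starting at the first segment entry (the skin). Gaps between
#' segments inside the body are counted at water equivalence (eta = 1).
#' Geometry is in mm; the result is in cm.
#'
#' @param segments data.frame from [trace_beam()] (sorted, overlap-free).
#' @param up_to target distance along the ray in mm.
#' @return effective depth in cm.
#' @export
effective_depth <- function(segments, up_to) {
  if (!nrow(segments)) stop("no segments: beam misses the body")
  entry <- segments$t_in[1]
  if (up_to < entry - 1e-9)
    stop("target lies before the body entry point")
  zeff_mm <- 0
  cursor <- entry
  for (i in seq_len(nrow(segments))) {
    a <- segments$t_in[i]; b <- segments$t_out[i]
    if (a > cursor) {        # gap inside the body: water-equivalent
      g <- min(a, up_to) - cursor
      if (g > 0) zeff_mm <- zeff_mm + g
      cursor <- min(a, up_to)
    }
    if (up_to <= a) break
    len <- min(b, up_to) - a
    if (len > 0) zeff_mm <- zeff_mm + len * segments$eta[i]
    cursor <- max(cursor, min(b, up_to))
    if (up_to <= b) break
  }
  if (up_to > cursor) zeff_mm <- zeff_mm + (up_to - cursor)  # past last exit
  zeff_mm / 10
}

#' SSD output factor
#'
#' Distance correction `((SSD0 + dref)/(SSD + dref))^exponent`. The
#' inverse-square exponent 2 is the default; see the methods vignette for
#' the first-power variant some formularies print.
#'
#' @param ssd source-to-surface distance in cm.
#' @param cal a [machine_calibration()].
#' @param exponent distance-correction exponent (default 2).
#' @return dimensionless factor (1 at the reference SSD).
#' @export
ssd_factor <- function(ssd, cal = machine_calibration(), exponent = 2) {
  if (any(ssd <= 0)) stop("ssd must be positive")
  ((cal$SSD0 + cal$dref) / (ssd + cal$dref))^exponent
}

#' Monitor units to absorbed dose at a point
#'
#' `TD = MU * Dref * PDD/100 * Scrc * Spr * SSDfactor(SSD)`, in cGy.
#'
#' @param MU monitor units.
#' @param cal a [machine_calibration()].
#' @param pdd_percent PDD at the target depth, percent.
#' @param ssd source-to-surface distance in cm.
#' @param exponent SSD-factor exponent (default 2).
#' @return dose in cGy.
#' @export
dose_at_point <- function(MU, cal, pdd_percent, ssd, exponent = 2) {
  if (MU < 0) stop("MU must be >= 0")
  MU * cal$Dref * (pdd_percent / 100) * cal$Scrc * cal$Spr *
    ssd_factor(ssd, cal, exponent)
}

#' Fit the buildup-tail model to measured PDD samples
#'
#' Least-squares fit of the normalised buildup-tail curve to
#' (depth, percent) samples, by Levenberg-Marquardt. Samples must span
#' both sides of the dose peak for (n, mu) to be identifiable.
#'
#' @param samples data.frame with columns `depth_cm` and `pdd_pct`.
#' @param init length-2 numeric starting values `c(n, mu)`.
#' @return a [pdd_model()] with attribute `rms` (residual root mean
#'   square, percentage points).
#' @export
fit_pdd <- function(samples, init = c(n = 2, mu = 0.05)) {
  if (nrow(samples) < 4L) stop("fit requires at least 4 samples")
  if (length(unique(samples$depth_cm)) < 3L)
    stop("fit-failure: depths do not span the curve (unidentifiable)")
  f <- function(d, n, mu)
    100 * buildup_tail_raw(d, n, mu) /
      buildup_tail_raw(find_dmax(n, mu), n, mu)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      pdd_pct ~ f(depth_cm, n, mu), data = samples,
      start = list(n = init[[1]], mu = init[[2]]),
      lower = c(1e-6, 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("fit-failure: ", conditionMessage(e)))
  cf <- stats::coef(fit)
  model <- pdd_model(n = cf[["n"]], mu = cf[["mu"]])
  attr(model, "rms") <- sqrt(mean(stats::resid(fit)^2))
  model
}

#' Material map: organ label to water-equivalence coefficient
#'
#' @param eta named numeric vector, names are organ labels as characters.
#' @param default eta for unlisted labels (water, 1).
#' @return function mapping integer labels to eta values.
#' @export
material_map <- function(eta = c(), default = 1) {
  if (length(eta) && any(eta <= 0)) stop("eta values must be positive")
  function(label) {
    out <- eta[as.character(label)]
    out[is.na(out)] <- default
    unname(out)
  }
}
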