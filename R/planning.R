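#' Beam specification
#'
#' @param gantry_angle gantry angle in degrees (normalised to [0, 360)).
#' @param isocenter length-3 isocenter in mm.
#' @param SAD source-to-axis distance in mm (> 0).
#' @param field_size field size in cm (metadata).
#' @param MU monitor units (>= 0).
#' @param energy_tag beam energy label.
#' @return object of class `beam_spec`.
#' @export
beam_spec <- function(gantry_angle = 0, isocenter = c(0, 0, 0), SAD = 1000,
                      field_size = 10, MU = 100, energy_tag = "6MV") {
  if (SAD <= 0) stop("SAD must be positive")
  if (MU < 0) stop("MU must be >= 0")
  structure(list(gantry_angle = gantry_angle %% 360,
                 isocenter = as.numeric(isocenter), SAD = SAD,
                 field_size = field_size, MU = MU, energy_tag = energy_tag),
            class = "beam_spec")
}

#' Beam axis ray from a beam specification
#'
#' Gantry convention (declared, IEC-style): rotation in the axial x-y
#' plane about the patient's longitudinal z axis; at 0 degrees the source
#' sits at `isocenter + (0, -SAD, 0)` and the beam enters anteriorly,
#' angles increase toward the patient's left (+x).
#'
#' @param spec a [beam_spec()].
#' @return a [ray()] from the source toward the isocenter.
#' @export
beam_ray <- function(spec) {
  th <- spec$gantry_angle * pi / 180
  u <- c(sin(th), -cos(th), 0)
  src <- spec$isocenter + spec$SAD * u
  ray(src, spec$isocenter - src)
}

#' Source-to-surface distance against the body mesh
#'
#' Distance along the beam axis from the source to the first body-surface
#' crossing.
#'
#' @param r a [ray()] (source at the origin of the ray).
#' @param body_mesh closed body [surface_mesh()].
#' @return SSD in mm.
#' @export
compute_ssd <- function(r, body_mesh) {
  h <- ray_mesh_intersections(r, body_mesh)
  if (!nrow(h)) stop("beam misses the patient surface")
  h$t[1]
}

#' Geometric tumour depth along the beam axis
#'
#' Distance from the skin-entry point to the tumour centre along the ray;
#' an off-axis centre is projected onto the ray with a warning.
#'
#' @param r a [ray()].
#' @param body_mesh closed body [surface_mesh()].
#' @param tumor_center length-3 mm.
#' @param tol off-axis tolerance in mm before the projection warning.
#' @return depth in cm.
#' @export
tumor_depth <- function(r, body_mesh, tumor_center, tol = 1e-6) {
  v <- as.numeric(tumor_center) - r$origin
  t_c <- sum(v * r$direction)
  offax <- sqrt(max(sum(v^2) - t_c^2, 0))
  if (offax > tol)
    warning(sprintf("tumour centre is %.3g mm off-axis; projected onto the ray",
                    offax))
  ssd <- compute_ssd(r, body_mesh)
  (t_c - ssd) / 10
}

#' Gantry-angle sweep
#'
#' For each angle: build the beam axis, trace it through the organ meshes,
#' compute SSD, geometric and effective tumour depth, PDD at the effective
#' depth, and the delivered dose; flag serial organ-at-risk traversals.
#' Beams that miss the patient are reported as NA rows, not errors.
#'
#' @param plan a [beam_spec()] template (its angle is replaced per sweep
#'   entry; beams are aimed at the isocenter, so place the isocenter at
#'   the tumour centre for isocentric plans).
#' @param organs organ list as for [trace_beam()] (body must carry the
#'   label `body_label`), each entry with `architecture`.
#' @param cal a [machine_calibration()].
#' @param model a [pdd_model()].
#' @param angles gantry angles in degrees.
#' @param body_label label of the body/skin mesh (default 1).
#' @return data.frame with one row per angle: `angle`, `ssd_mm`,
#'   `depth_cm`, `deff_cm`, `pdd_pct`, `dose_cgy`, `serial_hits`.
#' @export
sweep_angles <- function(plan, organs, cal, model, angles,
                         body_label = 1L) {
  if (!length(angles)) stop("angles must be non-empty")
  body <- Filter(function(o) o$label == body_label, organs)
  if (!length(body)) stop("no organ carries the body label ", body_label)
  body_mesh <- body[[1]]$mesh
  rows <- lapply(angles, function(a) {
    spec <- plan
    spec$gantry_angle <- a %% 360
    r <- beam_ray(spec)
    h <- ray_mesh_intersections(r, body_mesh)
    if (!nrow(h))
      return(data.frame(angle = a, ssd_mm = NA_real_, depth_cm = NA_real_,
                        deff_cm = NA_real_, pdd_pct = NA_real_,
                        dose_cgy = NA_real_, serial_hits = ""))
    ssd <- h$t[1]
    t_iso <- sqrt(sum((spec$isocenter - r$origin)^2))
    seg <- trace_beam(r, organs)
    depth <- (t_iso - ssd) / 10
    deff <- effective_depth(seg, t_iso)
    p <- pdd(deff, model)
    dose <- dose_at_point(spec$MU, cal, p, ssd / 10)
    ser <- serial_organ_hits(r, organs, model, segments = seg)
    hitlab <- ser$label[ser$hit]
    data.frame(angle = a, ssd_mm = ssd, depth_cm = depth, deff_cm = deff,
               pdd_pct = p, dose_cgy = dose,
               serial_hits = paste(hitlab, collapse = ";"))
  })
  do.call(rbind, rows)
}

#' Percent difference against a reference dose
#'
#' `100 * |model - reference| / reference`; the displayed value is rounded
#' to one decimal, full precision kept in the `"exact"` attribute.
#'
#' @param model_dose computed dose, Gy.
#' @param reference_dose reference (e.g. treatment planning system) dose,
#'   Gy, > 0.
#' @return percent difference rounded to one decimal, with attribute
#'   `exact`.
#' @export
percent_difference <- function(model_dose, reference_dose) {
  if (any(reference_dose <= 0)) stop("reference dose must be positive")
  exact <- 100 * abs(model_dose - reference_dose) / reference_dose
  out <- round(exact, 1)
  attr(out, "exact") <- exact
  out
}
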