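# Deviation geometry between planned and placed implants.
#
# An implant is reduced to its two centers: the platform (coronal) and the
# apex (apical end). The implant axis points platform -> apex, i.e. in the
# apical direction, so a positive depth deviation means the placed implant
# sits deeper than planned.

.vnorm <- function(v) sqrt(sum(v^2))

.row_norms <- function(m) sqrt(rowSums(m^2))

.check_finite_point <- function(p, what) {
  if (length(p) != 3L || !all(is.finite(p))) {
    abort_geometry(paste0(what, " must be a finite 3-D point."))
  }
}

#' Implant axis direction
#'
#' Unit vector from the platform center to the apex center (the apical
#' direction of the fixture).
#'
#' @param platform,apex Numeric length-3 centers in mm.
#' @return A unit length-3 vector.
#' @examples
#' implant_axis(c(0, 0, 0), c(0, 0, -10))
#' @export
implant_axis <- function(platform, apex) {
  .check_finite_point(platform, "`platform`")
  .check_finite_point(apex, "`apex`")
  d <- as.numeric(apex) - as.numeric(platform)
  n <- .vnorm(d)
  if (n == 0) {
    abort_geometry("Degenerate implant: platform and apex coincide.")
  }
  d / n
}

#' Global (3-D) deviation between two centers
#'
#' Euclidean distance between corresponding planned and placed implant
#' centers, the standard "global deviation" of guided-surgery accuracy
#' studies.
#'
#' @param planned_center,placed_center Numeric length-3 centers in mm.
#' @return Distance in mm (nonnegative).
#' @export
global_deviation <- function(planned_center, placed_center) {
  .check_finite_point(planned_center, "`planned_center`")
  .check_finite_point(placed_center, "`placed_center`")
  .vnorm(as.numeric(placed_center) - as.numeric(planned_center))
}

#' Lateral/depth decomposition of a center displacement
#'
#' Splits the planned-to-placed center displacement into the component along
#' the planned implant axis (signed depth, positive = deeper/apical) and the
#' perpendicular component (lateral). By construction
#' `lateral^2 + depth^2 = global^2`.
#'
#' @param planned_platform,planned_apex Centers defining the planned implant
#'   (the axis is platform -> apex).
#' @param planned_center Planned center at the level of interest (platform or
#'   apex).
#' @param placed_center Corresponding placed center.
#' @return A named list with `lateral_mm` (>= 0) and `depth_mm` (signed).
#' @export
decompose_deviation <- function(planned_platform, planned_apex,
                                planned_center, placed_center) {
  a <- implant_axis(planned_platform, planned_apex)
  .check_finite_point(planned_center, "`planned_center`")
  .check_finite_point(placed_center, "`placed_center`")
  d <- as.numeric(placed_center) - as.numeric(planned_center)
  axial <- sum(d * a)
  lateral <- .vnorm(d - axial * a)
  list(lateral_mm = lateral, depth_mm = axial)
}

#' Angular deviation between two implant axes
#'
#' The 3-D angle between the planned and placed platform-to-apex axes.
#'
#' @param planned_platform,planned_apex,placed_platform,placed_apex Centers
#'   in mm.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
angular_deviation <- function(planned_platform, planned_apex,
                              placed_platform, placed_apex) {
  a <- implant_axis(planned_platform, planned_apex)
  b <- implant_axis(placed_platform, placed_apex)
  # atan2(|a x b|, a.b) is well-conditioned near 0 and 180 deg, where acos
  # of the clamped dot product loses half the significant digits
  cross <- c(a[2] * b[3] - a[3] * b[2],
             a[3] * b[1] - a[1] * b[3],
             a[1] * b[2] - a[2] * b[1])
  atan2(.vnorm(cross), sum(a * b)) * 180 / pi
}

.implant_cols <- c("px", "py", "pz", "ax", "ay", "az")

.check_implant_df <- function(df, what) {
  missing <- setdiff(c("id", .implant_cols), names(df))
  if (length(missing)) {
    abort_parse(paste0(what, " is missing column(s): ",
                       paste(missing, collapse = ", "), "."))
  }
  m <- as.matrix(df[, .implant_cols])
  if (!all(is.finite(m))) {
    abort_geometry(paste0(what, " contains non-finite coordinates."))
  }
  len <- .row_norms(m[, 4:6, drop = FALSE] - m[, 1:3, drop = FALSE])
  if (any(len == 0)) {
    abort_geometry(paste0(what, " contains degenerate implants (platform = apex): id ",
                          paste(df$id[len == 0], collapse = ", "), "."))
  }
  invisible(df)
}

#' Measure planned-versus-placed implant deviations
#'
#' Computes, for each implant id present in both tables, the six standard
#' accuracy outcomes: global and lateral deviation at the platform, global and
#' lateral deviation at the apex, signed depth deviation (positive = placed
#' deeper than planned, measured along the planned axis at the platform), and
#' the angular deviation between the axes. Any non-coordinate columns of
#' `planned` (factor labels such as registration method, jaw, or guide
#' support) are carried into the result.
#'
#' @param planned,placed Implant data frames with columns `id`, `px`, `py`,
#'   `pz` (platform center, mm) and `ax`, `ay`, `az` (apex center, mm).
#' @param allow_partial If `FALSE` (default), ids present in only one table
#'   are an error; if `TRUE` they are dropped with a warning.
#' @return A tibble with one row per implant: `id`, `global_platform_mm`,
#'   `lateral_platform_mm`, `global_apex_mm`, `lateral_apex_mm`, `depth_mm`,
#'   `angular_deg`, plus the factor columns of `planned`.
#' @examples
#' planned <- data.frame(id = "i1", px = 0, py = 0, pz = 0,
#'                       ax = 0, ay = 0, az = -10)
#' placed <- planned
#' placed$px <- 0.3  # 0.3 mm lateral offset
#' placed$ax <- 0.3
#' measure_deviations(planned, placed)
#' @export
measure_deviations <- function(planned, placed, allow_partial = FALSE) {
  .check_implant_df(planned, "`planned`")
  .check_implant_df(placed, "`placed`")
  only_planned <- setdiff(planned$id, placed$id)
  only_placed <- setdiff(placed$id, planned$id)
  if (length(only_planned) || length(only_placed)) {
    msg <- paste0("Unmatched implant ids: ",
                  paste(c(only_planned, only_placed), collapse = ", "), ".")
    if (!allow_partial) abort_parse(msg)
    warning(msg, call. = FALSE)
  }
  ids <- intersect(planned$id, placed$id)
  if (!length(ids)) abort_parse("No implant ids in common.")
  pl <- planned[match(ids, planned$id), , drop = FALSE]
  pc <- placed[match(ids, placed$id), , drop = FALSE]

  P1 <- as.matrix(pl[, c("px", "py", "pz")])
  A1 <- as.matrix(pl[, c("ax", "ay", "az")])
  P2 <- as.matrix(pc[, c("px", "py", "pz")])
  A2 <- as.matrix(pc[, c("ax", "ay", "az")])

  axis1 <- (A1 - P1) / .row_norms(A1 - P1)
  axis2 <- (A2 - P2) / .row_norms(A2 - P2)

  dP <- P2 - P1
  dA <- A2 - A1
  depth <- rowSums(dP * axis1)
  lat_p <- .row_norms(dP - depth * axis1)
  ax_a <- rowSums(dA * axis1)
  lat_a <- .row_norms(dA - ax_a * axis1)
  cross <- cbind(axis1[, 2] * axis2[, 3] - axis1[, 3] * axis2[, 2],
                 axis1[, 3] * axis2[, 1] - axis1[, 1] * axis2[, 3],
                 axis1[, 1] * axis2[, 2] - axis1[, 2] * axis2[, 1])
  ang <- atan2(.row_norms(cross), rowSums(axis1 * axis2))

  out <- tibble::tibble(
    id = ids,
    global_platform_mm = unname(.row_norms(dP)),
    lateral_platform_mm = unname(lat_p),
    global_apex_mm = unname(.row_norms(dA)),
    lateral_apex_mm = unname(lat_a),
    depth_mm = unname(depth),
    angular_deg = unname(ang * 180 / pi)
  )
  factor_cols <- setdiff(names(pl), c("id", .implant_cols))
  if (length(factor_cols)) out <- dplyr::bind_cols(out, pl[, factor_cols, drop = FALSE])
  out
}

#' Safety-margin flags for a deviation table
#'
#' Flags implants whose deviations exceed a planning safety margin (strict
#' `>`; a deviation exactly at the margin is not flagged). The commonly
#' recommended margin in guided surgery is 2 mm overall; flags against the
#' EAO-style expected system error (1.2 mm horizontal, 0.5 mm vertical) are
#' reported alongside.
#'
#' @param deviations A deviation tibble from [measure_deviations()].
#' @param lateral_margin_mm,depth_margin_mm Safety margins in mm (defaults
#'   2.0). Depth is compared on absolute value.
#' @param horizontal_bound_mm,vertical_bound_mm Expected-system-error bounds
#'   used for the guideline flags (defaults 1.2 and 0.5 mm).
#' @return The input tibble with added logical columns `flag_global_platform`,
#'   `flag_lateral_platform`, `flag_global_apex`, `flag_lateral_apex`,
#'   `flag_depth` (against the margins) and `guideline_lateral`,
#'   `guideline_depth` (against the system-error bounds).
#' @export
safety_flags <- function(deviations, lateral_margin_mm = 2,
                         depth_margin_mm = 2,
                         horizontal_bound_mm = 1.2,
                         vertical_bound_mm = 0.5) {
  for (m in c(lateral_margin_mm, depth_margin_mm,
              horizontal_bound_mm, vertical_bound_mm)) {
    if (!is.finite(m) || m <= 0) abort_config("Safety margins must be positive.")
  }
  dplyr::mutate(
    tibble::as_tibble(deviations),
    flag_global_platform = .data$global_platform_mm > lateral_margin_mm,
    flag_lateral_platform = .data$lateral_platform_mm > lateral_margin_mm,
    flag_global_apex = .data$global_apex_mm > lateral_margin_mm,
    flag_lateral_apex = .data$lateral_apex_mm > lateral_margin_mm,
    flag_depth = abs(.data$depth_mm) > depth_margin_mm,
    guideline_lateral = .data$lateral_platform_mm > horizontal_bound_mm |
      .data$lateral_apex_mm > horizontal_bound_mm,
    guideline_depth = abs(.data$depth_mm) > vertical_bound_mm
  )
}
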