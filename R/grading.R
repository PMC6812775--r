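# Traffic-light bleb grading: iso-pressure contours of the purse law in
# the (radius, height) plane, zone classification, and chart rendering.
# This module works in clinical units (mm, mmHg); the calibration object
# stores the lumped stiffness in SI internally.

#' Effective radius of a non-circular bleb
#'
#' Clinical blebs are rarely circular; the working rule is to average the
#' maximum horizontal and vertical extents and halve the result:
#' R = ((L_h + L_v) / 2) / 2.
#'
#' @param l_horizontal,l_vertical maximum extents along the horizontal and
#'   vertical directions (any consistent length unit, > 0).
#' @return effective radius in the same unit.
#' @examples
#' effective_radius(10, 6)  # 4
#' @export
effective_radius <- function(l_horizontal, l_vertical) {
  if (any(l_horizontal <= 0) || any(l_vertical <= 0)) {
    stop("bleb extents must be positive")
  }
  (l_horizontal + l_vertical) / 4
}

#' Calibrate the grading chart from one reference bleb
#'
#' The chart needs only the lumped stiffness c2*E*T of the conjunctiva,
#' fixed by a single reference point through the purse law:
#' c2*E*T = P_ref * R_ref^4 / H_ref^3. Two conventional references are
#' available via `preset_calibration()`.
#'
#' @param r_ref_mm reference radius, mm.
#' @param h_ref_mm reference height, mm.
#' @param p_ref_mmhg reference pressure, mmHg.
#' @return an object of class `chart_calibration`: list with `c2et` (the
#'   lumped stiffness, Pa m) and the reference point.
#' @examples
#' calibrate_chart(4, 1, 3)  # c2*E*T ~ 102.4 Pa m
#' @export
calibrate_chart <- function(r_ref_mm = 4, h_ref_mm = 1, p_ref_mmhg = 3) {
  stopifnot(r_ref_mm > 0, p_ref_mmhg > 0)
  if (h_ref_mm <= 0) stop("reference height must be positive")
  c2et <- mmhg_to_pa(p_ref_mmhg) * mm_to_m(r_ref_mm)^4 / mm_to_m(h_ref_mm)^3
  structure(
    list(c2et = c2et,
         reference = c(r_mm = r_ref_mm, h_mm = h_ref_mm, p_mmhg = p_ref_mmhg)),
    class = "chart_calibration"
  )
}

#' Built-in chart calibrations
#'
#' `"worked_example"`: 3 mmHg at R = 4 mm, H = 1 mm — the human-scale
#' post-operative example used for the fill-time estimate.
#' `"chart"`: 10 mmHg at R = 4.5 mm, H = 1 mm — consistent with the
#' green-zone narrative (target IOP ~10 mmHg for a moderate-height,
#' relatively large bleb). The two differ by a factor ~5 in lumped
#' stiffness; the discrepancy reflects genuine between-eye variability in
#' c2*E*T and is deliberately surfaced rather than averaged away.
#'
#' @param name `"worked_example"` or `"chart"`.
#' @return a `chart_calibration`.
#' @export
preset_calibration <- function(name = c("worked_example", "chart")) {
  name <- match.arg(name)
  switch(name,
    worked_example = calibrate_chart(4, 1, 3),
    chart = calibrate_chart(4.5, 1, 10)
  )
}

#' @export
print.chart_calibration <- function(x, ...) {
  cat("Chart calibration: c2*E*T =", format(x$c2et, digits = 5), "Pa m",
      "( reference:", x$reference["p_mmhg"], "mmHg at R =",
      x$reference["r_mm"], "mm, H =", x$reference["h_mm"], "mm )\n")
  invisible(x)
}

#' Model pressure of a bleb on the grading chart
#'
#' Purse-law pressure c2*E*T * H^3 / R^4 at the calibrated lumped
#' stiffness, in clinical units.
#'
#' @param r_mm effective radius, mm (> 0); vectorised.
#' @param h_mm bleb height, mm (> 0); vectorised.
#' @param calib a [calibrate_chart()] calibration.
#' @return model pressure in mmHg.
#' @examples
#' calib <- preset_calibration("worked_example")
#' chart_pressure(2, 1, calib)    # 48 mmHg: small blebs run very high
#' chart_pressure(8, 0.5, calib)  # ~0.023 mmHg: large flat blebs run low
#' @export
chart_pressure <- function(r_mm, h_mm, calib) {
  stopifnot(inherits(calib, "chart_calibration"))
  if (any(r_mm <= 0)) stop("radius must be positive")
  if (any(h_mm < 0)) stop("height must be non-negative")
  pa_to_mmhg(calib$c2et * mm_to_m(h_mm)^3 / mm_to_m(r_mm)^4)
}

#' Iso-pressure contour in the (radius, height) plane
#'
#' Heights tracing a constant model pressure P along a radius grid:
#' H(R) = (P R^4 / (c2*E*T))^(1/3), so H grows like R^(4/3) along any
#' contour.
#'
#' @param p_mmhg contour pressure, mmHg (>= 0).
#' @param r_grid_mm radii at which to evaluate, mm (> 0).
#' @param calib a [calibrate_chart()] calibration.
#' @return heights in mm, one per grid point.
#' @export
iso_pressure_curve <- function(p_mmhg, r_grid_mm, calib) {
  stopifnot(inherits(calib, "chart_calibration"))
  if (p_mmhg < 0) stop("contour pressure must be non-negative")
  if (any(r_grid_mm <= 0)) stop("radius grid must be positive")
  m_to_mm((mmhg_to_pa(p_mmhg) * mm_to_m(r_grid_mm)^4 / calib$c2et)^(1 / 3))
}

#' Traffic-light zone thresholds
#'
#' Pressure bands partitioning the chart: green for the target band around
#' 10 mmHg, red for dangerously low (hypotony) or high pressure or for very
#' tall blebs regardless of pressure, orange for the transition between.
#' The numeric defaults are conventions of this package (the published
#' chart is graphical only): green = \[5, 15\] mmHg, red below 2 and above
#' 25 mmHg, height cap 3 mm.
#'
#' @param green_low,green_high bounds of the green band, mmHg.
#' @param red_low,red_high red-zone cutoffs, mmHg.
#' @param height_cap_mm heights above this are red regardless of pressure, mm.
#' @return an object of class `zone_thresholds`.
#' @export
zone_thresholds <- function(green_low = 5, green_high = 15,
                            red_low = 2, red_high = 25, height_cap_mm = 3) {
  if (!(red_low < green_low && green_low < green_high && green_high < red_high)) {
    stop("invalid thresholds: need red_low < green_low < green_high < red_high")
  }
  stopifnot(red_low >= 0, height_cap_mm > 0)
  structure(
    list(green_low = green_low, green_high = green_high,
         red_low = red_low, red_high = red_high, height_cap_mm = height_cap_mm),
    class = "zone_thresholds"
  )
}

#' Classify a bleb into a traffic-light zone
#'
#' Red if the model pressure is below `red_low` (hypotony risk) or above
#' `red_high`, or the bleb is taller than the height cap; green if the
#' pressure lies in the green band and the height is under the cap;
#' orange otherwise. The three zones tile the positive quadrant exactly.
#'
#' @param r_mm effective radius, mm (> 0); vectorised.
#' @param h_mm height, mm (> 0); vectorised.
#' @param calib a [calibrate_chart()] calibration.
#' @param thresholds a [zone_thresholds()] object.
#' @return factor with levels `green`, `orange`, `red`.
#' @export
classify_bleb <- function(r_mm, h_mm, calib, thresholds = zone_thresholds()) {
  stopifnot(inherits(thresholds, "zone_thresholds"))
  p <- chart_pressure(r_mm, h_mm, calib)
  zone <- ifelse(
    p < thresholds$red_low | p > thresholds$red_high |
      h_mm > thresholds$height_cap_mm,
    "red",
    ifelse(p >= thresholds$green_low & p <= thresholds$green_high,
           "green", "orange")
  )
  factor(zone, levels = c("green", "orange", "red"))
}

#' Grade a table of clinical bleb observations
#'
#' Adds the purse-law model pressure and traffic-light zone to each
#' observation. Leaking blebs are still placed on the chart but flagged:
#' a leak breaks the purse assumption, so their model pressure must not be
#' read as an IOP estimate.
#'
#' @param observations a data frame with columns `radius_mm`, `height_mm`,
#'   and optionally `iop_mmHg`, `n_drop_types`, `leaking`.
#' @param calib a [calibrate_chart()] calibration.
#' @param thresholds a [zone_thresholds()] object.
#' @return the input as a tibble with added columns `model_pressure_mmHg`,
#'   `zone`, and `pressure_valid` (FALSE for leaking blebs).
#' @export
grade_blebs <- function(observations, calib, thresholds = zone_thresholds()) {
  need <- c("radius_mm", "height_mm")
  if (!all(need %in% names(observations))) {
    stop("observations must have columns radius_mm and height_mm")
  }
  if (nrow(observations) == 0L) stop("no observations to grade")
  out <- tibble::as_tibble(observations)
  out$model_pressure_mmHg <- chart_pressure(out$radius_mm, out$height_mm, calib)
  out$zone <- classify_bleb(out$radius_mm, out$height_mm, calib, thresholds)
  leaking <- if ("leaking" %in% names(out)) as.logical(out$leaking) else FALSE
  out$pressure_valid <- !leaking
  if (any(leaking)) {
    warning(sum(leaking), " leaking bleb(s): purse-law pressure is not a ",
            "valid IOP estimate for these and they are flagged, not graded by pressure")
  }
  out
}

#' Render the traffic-light grading chart
#'
#' Draws the (radius, height) plane tiled by zone colour, dashed
#' iso-pressure contours, and the supplied observations: each marker is
#' coloured by its zone, annotated with measured IOP (when present), one
#' star per glaucoma drop type, and an "L" tag for leaking blebs. Writes
#' the figure to `path` (format from the file extension, e.g. png or pdf).
#'
#' @param graded a data frame from [grade_blebs()] (may have zero rows via
#'   `allow_empty = TRUE` semantics: pass `NULL` to draw zones and contours
#'   only).
#' @param calib a [calibrate_chart()] calibration.
#' @param thresholds a [zone_thresholds()] object.
#' @param path output file path.
#' @param r_range,h_range chart extents in mm.
#' @param contours_mmhg pressures of the dashed contours; defaults to the
#'   zone cutoffs plus the 10 mmHg target.
#' @return the output path, invisibly.
#' @export
render_chart <- function(graded, calib, thresholds = zone_thresholds(), path,
                         r_range = c(0.5, 8), h_range = c(0.05, 4),
                         contours_mmhg = NULL) {
  stopifnot(inherits(calib, "chart_calibration"), inherits(thresholds, "zone_thresholds"))
  if (is.null(contours_mmhg)) {
    contours_mmhg <- c(thresholds$red_low, thresholds$green_low, 10,
                       thresholds$green_high, thresholds$red_high)
  }
  grid <- expand.grid(
    radius_mm = seq(r_range[1], r_range[2], length.out = 220),
    height_mm = seq(h_range[1], h_range[2], length.out = 220)
  )
  grid$zone <- classify_bleb(grid$radius_mm, grid$height_mm, calib, thresholds)

  contour_df <- do.call(rbind, lapply(contours_mmhg, function(p) {
    r <- seq(r_range[1], r_range[2], length.out = 200)
    data.frame(radius_mm = r,
               height_mm = iso_pressure_curve(p, r, calib),
               p_mmhg = p)
  }))
  contour_df <- contour_df[contour_df$height_mm <= h_range[2] * 1.02, ]

  zone_cols <- c(green = "#66bb6a", orange = "#ffa726", red = "#ef5350")
  gg <- ggplot2::ggplot() +
    ggplot2::geom_raster(
      data = grid,
      ggplot2::aes(x = .data$radius_mm, y = .data$height_mm, fill = .data$zone),
      alpha = 0.45
    ) +
    ggplot2::geom_line(
      data = contour_df,
      ggplot2::aes(x = .data$radius_mm, y = .data$height_mm,
                   group = .data$p_mmhg),
      linetype = "dashed", colour = "grey20", linewidth = 0.3
    ) +
    ggplot2::scale_fill_manual(values = zone_cols, name = "zone") +
    ggplot2::coord_cartesian(xlim = r_range, ylim = h_range, expand = FALSE) +
    ggplot2::labs(
      x = "effective radius (mm)", y = "bleb height (mm)",
      title = "Traffic-light bleb grading",
      subtitle = sprintf(
        "iso-pressure contours at %s mmHg; green band %g-%g mmHg",
        paste(contours_mmhg, collapse = ", "),
        thresholds$green_low, thresholds$green_high
      )
    ) +
    ggplot2::theme_minimal()

  if (!is.null(graded) && nrow(graded) > 0L) {
    pts <- tibble::as_tibble(graded)
    pts$label <- ""
    if ("iop_mmHg" %in% names(pts)) {
      pts$label <- sprintf("%.0f", pts$iop_mmHg)
    }
    if ("n_drop_types" %in% names(pts)) {
      pts$label <- paste0(pts$label, vapply(pts$n_drop_types, function(k) {
        strrep("*", max(k, 0))
      }, character(1)))
    }
    if ("leaking" %in% names(pts)) {
      pts$label <- paste0(pts$label, ifelse(pts$leaking, " L", ""))
    }
    gg <- gg +
      ggplot2::geom_point(
        data = pts,
        ggplot2::aes(x = .data$radius_mm, y = .data$height_mm,
                     colour = .data$zone),
        size = 2, show.legend = FALSE
      ) +
      ggplot2::scale_colour_manual(values = c(green = "#1b5e20",
                                              orange = "#e65100",
                                              red = "#b71c1c")) +
      ggplot2::geom_text(
        data = pts,
        ggplot2::aes(x = .data$radius_mm, y = .data$height_mm,
                     label = .data$label),
        colour = "blue", size = 2.3, vjust = -0.8
      )
  }

  ggplot2::ggsave(path, gg, width = 7, height = 5, dpi = 150)
  invisible(path)
}
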