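# Division-orientation geometry: angle classification, vertical:horizontal
# ratios, densities and rose-plot binning. Angles are degrees between the
# pial surface and the plane of division, folded to [0, 90] (the angle is
# axial: theta and 180 - theta describe the same plane).

#' Classify division angles
#'
#' `horizontal` (parallel to the surface) when `angle <= horiz_max`,
#' `vertical` (perpendicular) when `angle >= vert_min`, otherwise
#' `oblique`. The default 30/60 cutoffs are symmetric thirds of the
#' quarter-circle and are exposed as parameters.
#'
#' @param angle Numeric vector of angles in degrees, in \[0, 90\].
#' @param horiz_max,vert_min Classification cutoffs in degrees.
#' @return Character vector of classes.
#' @export
classify_division <- function(angle, horiz_max = 30, vert_min = 60) {
  if (!(horiz_max >= 0 && horiz_max < vert_min && vert_min <= 90)) {
    abort("need 0 <= horiz_max < vert_min <= 90")
  }
  if (any(angle < 0 | angle > 90)) abort("angles must lie in [0, 90]")
  ifelse(angle <= horiz_max, "horizontal",
         ifelse(angle >= vert_min, "vertical", "oblique"))
}

#' Vertical:horizontal division ratio within a stratum
#'
#' Pools events for the requested sectioning plane and condition, computes
#' the pooled vertical:horizontal count ratio, and also aggregates per
#' animal first to report mean ratio and its standard error across animals
#' (horizontal divisions act as the normalising factor).
#'
#' @param events Division-event tibble (`plane`, `condition`, `animal_id`,
#'   `angle`).
#' @param plane,condition Stratum selectors; `NULL` keeps all.
#' @param horiz_max,vert_min Classification cutoffs (see
#'   [classify_division()]).
#' @return Object of class `vh_ratio`: pooled ratio, per-animal tibble,
#'   mean and s.e.m. across animals, and counts. A stratum with zero
#'   horizontal divisions yields an `NA` ratio with a warning.
#' @export
vh_ratio <- function(events, plane = NULL, condition = NULL,
                     horiz_max = 30, vert_min = 60) {
  if (!is.null(plane)) events <- filter(events, .data$plane == .env$plane)
  if (!is.null(condition)) events <- filter(events, .data$condition == .env$condition)
  if (nrow(events) == 0) abort("no events in the requested stratum")
  cls <- classify_division(events$angle, horiz_max, vert_min)
  n_v <- sum(cls == "vertical"); n_h <- sum(cls == "horizontal")
  if (n_h == 0) {
    warn("no horizontal divisions in stratum; ratio undefined")
    pooled <- NA_real_
  } else {
    pooled <- n_v / n_h
  }
  per_animal <- tibble(animal_id = events$animal_id, class = cls) %>%
    group_by(.data$animal_id) %>%
    summarise(n_vertical = sum(.data$class == "vertical"),
              n_horizontal = sum(.data$class == "horizontal"),
              ratio = ifelse(.data$n_horizontal > 0,
                             .data$n_vertical / .data$n_horizontal, NA_real_),
              .groups = "drop")
  ok <- !is.na(per_animal$ratio)
  structure(list(
    pooled_ratio = pooled,
    per_animal = per_animal,
    mean_ratio = if (any(ok)) mean(per_animal$ratio[ok]) else NA_real_,
    sem_ratio = if (sum(ok) > 1) sd(per_animal$ratio[ok]) / sqrt(sum(ok)) else NA_real_,
    n_vertical = n_v, n_horizontal = n_h, n_events = nrow(events)
  ), class = "vh_ratio")
}

#' @export
print.vh_ratio <- function(x, ...) {
  cat(sprintf("vertical:horizontal ratio %.3f (%d V / %d H of %d events); per-animal mean %.3f +/- %.3f s.e.m.\n",
              x$pooled_ratio, x$n_vertical, x$n_horizontal, x$n_events,
              x$mean_ratio, x$sem_ratio))
  invisible(x)
}

#' Division density per 100 square micrometres
#'
#' @param count Number of dividing cells.
#' @param area_um2 Measured area in square micrometres.
#' @return Cells per 100 um^2.
#' @export
division_density <- function(count, area_um2) {
  if (any(area_um2 <= 0)) abort("area must be positive")
  count / (area_um2 / 100)
}

#' Rose-plot binning of division angles
#'
#' Half-open bins `[b, b + width)` over \[0, 90\]; the final bin is closed
#' at 90 so counts always sum to the number of angles.
#'
#' @param angles Numeric vector of angles in degrees.
#' @param bin_width Bin width in degrees; must divide 90.
#' @return Tibble with `bin_start`, `bin_end`, `count`; class
#'   `rose_histogram` for [autoplot()].
#' @export
rose_histogram <- function(angles, bin_width = 10) {
  if (90 %% bin_width != 0) abort("bin_width must divide 90")
  if (any(angles < 0 | angles > 90)) abort("angles must lie in [0, 90]")
  starts <- seq(0, 90 - bin_width, by = bin_width)
  idx <- pmin(floor(angles / bin_width), length(starts) - 1) + 1
  counts <- tabulate(idx, nbins = length(starts))
  out <- tibble(bin_start = starts, bin_end = starts + bin_width, count = counts)
  class(out) <- c("rose_histogram", class(out))
  out
}
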