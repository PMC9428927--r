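# Joint-spacing sweeps: run the 4-DOF regime over a ladder of static
# translations (each a candidate articular-cartilage thickness), summarise
# viable-pose counts and alpha-shape volumes, and characterise the
# spacing-mobility relationship (linear + quadratic trends, plateau).

#' Cartilage thickness as a percentage of femoral length
#'
#' Comparative thickness measurements are transferred between specimens by
#' scaling with femoral length.
#'
#' @param thickness cartilage thickness / joint spacing, mm.
#' @param femur_length femoral length, mm (e.g. 289 for a small hominin
#'   reconstruction).
#' @return `100 * thickness / femur_length`, rounded to 3 decimals.
#' @export
pct_of_femur <- function(thickness, femur_length) {
  if (femur_length <= 0) stop("femur length must be > 0")
  round(100 * thickness / femur_length, 3)
}

#' Spacing sweep configuration
#'
#' @param spacings joint spacings to test, mm.
#' @param femur_length femoral length used for percentage scaling, mm.
#' @param labels optional per-spacing provenance labels (e.g. which species
#'   / statistic a thickness came from).
#' @export
spacing_config <- function(spacings, femur_length = 289,
                           labels = NULL) {
  spacings <- as.numeric(spacings)
  if (any(spacings < 0)) stop("spacings must be >= 0")
  if (femur_length <= 0) stop("femur_length must be > 0")
  if (is.null(labels)) labels <- sprintf("spacing_%g_mm", spacings)
  if (length(labels) != length(spacings))
    stop("one label per spacing required")
  structure(list(femur_length = femur_length, spacings = spacings,
                 labels = labels),
            class = "spacing_config")
}

#' Sweep joint spacing with 4-DOF sampling
#'
#' For each spacing, runs [classify_poses()] in the 4-DOF regime with that
#' static translation along `offset_direction`, maps the viable poses
#' through [cosine_correct()] and computes the [alpha_volume()].
#'
#' @param rig a [joint_rig()].
#' @param grid a [pose_grid()].
#' @param config a [spacing_config()] (or a numeric vector of spacings).
#' @param alpha alpha radius for volumes; default [default_alpha()] of the
#'   grid.
#' @param offset_direction translation direction in ACS axes (unit vector);
#'   default +Y, the single translation axis. Pass the out-of-socket
#'   direction of your joint (the sign/axis that moves the distal element
#'   away from the joint center).
#' @param tol collision contact tolerance (mm).
#' @return a `spacing_scan`: data.frame `rows` with spacing (mm),
#'   viable count, volume (degree^3, NA when fewer than 4 non-coplanar
#'   viable poses), percent of femur length, label; plus the settings used.
#' @export
scan_spacing <- function(rig, grid, config, alpha = NULL,
                         offset_direction = c(0, 1, 0), tol = 0) {
  if (!inherits(config, "spacing_config")) config <- spacing_config(config)
  if (is.null(alpha)) alpha <- default_alpha(grid)
  ord <- order(config$spacings)
  spacings <- config$spacings[ord]
  labels <- config$labels[ord]
  rows <- lapply(seq_along(spacings), function(i) {
    map <- classify_poses(rig, grid, "4dof", static_offset = spacings[i],
                          offset_direction = offset_direction, tol = tol)
    n <- sum(map$viable)
    vol <- NA_real_
    if (n >= 4) {
      vol <- tryCatch(
        alpha_volume(cosine_correct(map), alpha)$volume,
        error = function(e) NA_real_) # e.g. all viable poses coplanar
    } else if (n == 0) vol <- 0
    data.frame(spacing = spacings[i], viable_count = n, volume = vol,
               pct_femur = pct_of_femur(spacings[i], config$femur_length),
               label = labels[i], stringsAsFactors = FALSE)
  })
  structure(list(rows = do.call(rbind, rows), alpha = alpha,
                 grid = grid, femur_length = config$femur_length,
                 offset_direction = offset_direction),
            class = "spacing_scan")
}

#' @export
print.spacing_scan <- function(x, ...) {
  cat(sprintf("<spacing_scan: %d spacings, alpha=%g>\n", nrow(x$rows),
              x$alpha))
  print(x$rows)
  invisible(x)
}

#' Spacing-mobility trend report
#'
#' Ordinary least-squares linear and quadratic fits of viable-pose count
#' (and volume) on joint spacing. The quadratic's stationary point is
#' reported as a plateau estimate when it falls inside the spacing range; a
#' descriptive plateau onset is also reported as the first spacing at which
#' the increment in viable count drops below 1% of the grid size.
#'
#' @param scan a `spacing_scan` (>= 3 rows, non-constant spacing).
#' @return a `trend_report` list with one element per response (`count`,
#'   `volume`): slope, adjusted R^2, two-sided p-value of the linear slope,
#'   quadratic coefficients and plateau estimates.
#' @export
fit_trends <- function(scan) {
  rows <- if (inherits(scan, "spacing_scan")) scan$rows else as.data.frame(scan)
  if (nrow(rows) < 3) stop("need at least 3 spacings to fit trends")
  if (sd(rows$spacing) == 0) stop("spacing values are constant")
  gsize <- if (inherits(scan, "spacing_scan")) grid_size(scan$grid) else NA
  one <- function(y) {
    keep <- is.finite(y)
    x <- rows$spacing[keep]
    y <- y[keep]
    if (length(y) < 3) return(NULL)
    lin <- lm(y ~ x)
    # summary.lm warns on exact fits; exact fixtures are legitimate input
    slin <- suppressWarnings(summary(lin))
    pval <- if (nrow(slin$coefficients) > 1) slin$coefficients[2, 4] else NA
    quad <- if (length(y) >= 4) lm(y ~ x + I(x^2)) else NULL
    vertex <- NA_real_
    if (!is.null(quad)) {
      cf <- coef(quad)
      if (is.finite(cf[3]) && abs(cf[3]) > 1e-12) {
        v <- -cf[2] / (2 * cf[3])
        if (v >= min(x) && v <= max(x)) vertex <- unname(v)
      }
    }
    list(slope = unname(coef(lin)[2]),
         intercept = unname(coef(lin)[1]),
         adj_r2 = slin$adj.r.squared,
         p_value = unname(pval),
         quad_coefficients = if (is.null(quad)) NULL else unname(coef(quad)),
         quad_adj_r2 = if (is.null(quad)) NA else
           suppressWarnings(summary(quad))$adj.r.squared,
         plateau_vertex = vertex)
  }
  out <- list(count = one(rows$viable_count), volume = one(rows$volume))
  # descriptive plateau: first spacing whose count increment is < 1% of grid
  onset <- NA_real_
  if (!is.na(gsize) && nrow(rows) >= 2) {
    inc <- diff(rows$viable_count)
    small <- which(inc < 0.01 * gsize)
    if (length(small) > 0) onset <- rows$spacing[small[1] + 1]
  }
  out$plateau_onset <- onset
  class(out) <- "trend_report"
  out
}

#' @export
print.trend_report <- function(x, ...) {
  for (resp in c("count", "volume")) {
    r <- x[[resp]]
    if (is.null(r)) next
    cat(sprintf("%s: slope %.3f, adj R^2 %.3f, p %.3g", resp, r$slope,
                r$adj_r2, r$p_value))
    if (is.finite(r$plateau_vertex))
      cat(sprintf(", quadratic plateau at %.3f mm", r$plateau_vertex))
    cat("\n")
  }
  if (is.finite(x$plateau_onset))
    cat(sprintf("plateau onset (increment < 1%% of grid): %.3f mm\n",
                x$plateau_onset))
  invisible(x)
}

#' Plot a spacing scan (count and volume vs spacing)
#'
#' Linear fits drawn solid, quadratic fits dashed.
#'
#' @param scan a `spacing_scan`.
#' @param response "viable_count" or "volume".
#' @return a ggplot object.
#' @export
plot_spacing_scan <- function(scan, response = c("viable_count", "volume")) {
  response <- match.arg(response)
  rows <- scan$rows
  df <- data.frame(spacing = rows$spacing, y = rows[[response]])
  ggplot2::ggplot(df, ggplot2::aes(x = spacing, y = y)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "black") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x + I(x^2), se = FALSE,
                         linetype = "dashed", linewidth = 0.5,
                         colour = "grey40") +
    ggplot2::labs(x = "joint spacing (mm)",
                  y = if (response == "viable_count") "viable poses"
                      else "volume (degree^3)") +
    ggplot2::theme_classic()
}
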