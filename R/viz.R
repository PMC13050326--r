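# Safety-landscape graphics. Every render_* function writes the figure
# plus a machine-readable JSON sidecar holding the exact numbers plotted;
# the figures are never the source of truth.

ZONE_COLORS <- c(rule_out = "#2166ac", gray = "#8c8c8c", rule_in = "#b2182b")
ZONE_LABELS <- c(rule_out = "Rule-out Safe", gray = "Gray", rule_in = "Rule-in Safe")

# ROC polyline with each segment attributed to the zone of its threshold.
.saroc_segments <- function(cohort, alpha_plus, alpha_minus) {
  tt <- .thresh_table(cohort$score, cohort$label)
  b <- .boundaries(tt, alpha_plus, alpha_minus, warn_clip = FALSE)
  m <- length(tt$tau)
  # ROC points run from (1,1) at the low sentinel to (0,0) at the high one;
  # the segment between consecutive candidates carries the zone of the
  # segment's upper threshold (the cutoff actually applied on it).
  tibble::tibble(
    tau = tt$tau[-1L],
    x = tt$fpr[-m], y = tt$tpr[-m],
    xend = tt$fpr[-1L], yend = tt$tpr[-1L],
    zone = .zone_of(tt$tau[-1L], b$tau_plus, b$tau_minus)
  )
}

#' SA-ROC curve
#'
#' The empirical ROC curve with segments colored by the safety zone of
#' their threshold, the Gray Zone Area rectangle anchored at the top-left
#' corner, and a marker at the Youden-optimal (or user-supplied) threshold.
#' With several `alpha_levels`, zones are drawn nested from the most
#' lenient (widest lines) to the most stringent.
#'
#' @param cohort A cohort tibble with both classes present.
#' @param alpha_levels Symmetric safety levels to display (default 1.0).
#' @param theta Optional decision threshold to mark; defaults to the
#'   Youden-optimal threshold.
#' @return A ggplot object.
#' @export
plot_saroc <- function(cohort, alpha_levels = 1, theta = NULL) {
  cohort <- check_cohort(cohort, require_both_classes = TRUE)
  if (length(alpha_levels) < 1) stop_usage("Provide at least one alpha level.")
  alpha_levels <- sort(alpha_levels)
  theta <- theta %||% youden_threshold(cohort)$theta
  th_pt <- roc_point_at(cohort, theta)

  segs <- purrr::map(alpha_levels, function(a) {
    dplyr::mutate(.saroc_segments(cohort, a, a), alpha_level = a)
  }) |> dplyr::bind_rows()
  segs$level_rank <- match(segs$alpha_level, alpha_levels)

  rects <- purrr::map(alpha_levels, function(a) {
    part <- suppressWarnings(make_partition(cohort, a, a))
    tibble::tibble(
      alpha_level = a,
      fpr_minus = .fpr_at(cohort$score, cohort$label, .eff_minus(part$tau_minus_raw)),
      tpr_plus = .tpr_at(cohort$score, cohort$label, .eff_plus(part$tau_plus)),
      gamma_area = glance(part)$gamma_area
    )
  }) |> dplyr::bind_rows()

  ggplot2::ggplot() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         color = "grey70") +
    ggplot2::geom_rect(
      data = rects,
      ggplot2::aes(xmin = 0, xmax = .data$fpr_minus,
                   ymin = .data$tpr_plus, ymax = 1),
      fill = "grey40", alpha = 0.15, color = NA
    ) +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, color = .data$zone,
                   linewidth = -.data$level_rank)
    ) +
    ggplot2::geom_point(data = th_pt,
                        ggplot2::aes(x = .data$fpr, y = .data$tpr),
                        shape = 21, size = 3, fill = "white") +
    ggplot2::scale_color_manual(values = ZONE_COLORS, labels = ZONE_LABELS,
                                name = "Zone", drop = FALSE) +
    ggplot2::scale_linewidth(range = c(0.6, 1.8), guide = "none") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = "SA-ROC curve",
      subtitle = sprintf(
        "alpha = %s;  Gamma_Area = %s",
        paste(format(alpha_levels), collapse = ", "),
        paste(format(round(rects$gamma_area, 4)), collapse = ", ")
      )
    ) +
    ggplot2::theme_minimal()
}

#' Safety Profile Curve
#'
#' Gray-Zone fraction (top) and Gray Zone Area (bottom) against the safety
#' level. Several profiles (e.g. two models) can be overlaid by passing a
#' named list.
#'
#' @param profile An `sa_profile` from [safety_profile()], or a named list
#'   of them.
#' @return A ggplot object.
#' @export
plot_safety_profile <- function(profile) {
  profiles <- if (inherits(profile, "sa_profile")) list(profile = profile) else profile
  if (!length(profiles) || !all(purrr::map_lgl(profiles, inherits, "sa_profile"))) {
    stop_usage("`profile` must be an sa_profile or a named list of them.")
  }
  long <- purrr::imap(profiles, function(p, nm) {
    tibble::as_tibble(p) |>
      dplyr::select("alpha", "gray_fraction", "gamma_area") |>
      tidyr::pivot_longer(c("gray_fraction", "gamma_area"),
                          names_to = "metric", values_to = "value") |>
      dplyr::mutate(model = nm)
  }) |> dplyr::bind_rows()
  long$metric <- factor(long$metric, levels = c("gray_fraction", "gamma_area"),
                        labels = c("Gray-Zone fraction", "Gamma_Area"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$alpha, y = .data$value,
                                          color = .data$model)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Safety level alpha", y = NULL,
                  title = "Safety Profile Curve") +
    ggplot2::theme_minimal()
  if (length(profiles) == 1) p + ggplot2::guides(color = "none") else p
}

#' @export
autoplot.sa_profile <- function(object, ...) plot_safety_profile(object)

#' @export
autoplot.sa_partition <- function(object, ...) {
  plot_saroc(object$data, alpha_levels = object$alpha_plus)
}

#' Two-model Safe-Zone grid
#'
#' Scatter of paired case scores under two models, with each model's
#' rule-out/rule-in boundaries at the given symmetric safety level drawn as
#' grid lines and the joint-zone cells shaded.
#'
#' @param cohort_a,cohort_b Cohort tibbles over identical cases.
#' @param alpha Symmetric safety level.
#' @return A ggplot object.
#' @export
plot_two_model_grid <- function(cohort_a, cohort_b, alpha = 1) {
  pair <- .check_paired(cohort_a, cohort_b)
  pa <- make_partition(pair$a, alpha, alpha)
  pb <- make_partition(pair$b, alpha, alpha)
  pts <- tibble::tibble(
    case_id = pair$a$case_id,
    score_a = pair$a$score,
    score_b = pair$b$score,
    label = factor(pair$a$label, levels = c(0, 1),
                   labels = c("negative", "positive"))
  )
  brk_a <- c(0, sort(unique(c(.eff_minus(pa$tau_minus), .eff_plus(pa$tau_plus)))), 1)
  brk_b <- c(0, sort(unique(c(.eff_minus(pb$tau_minus), .eff_plus(pb$tau_plus)))), 1)
  clamp <- function(v) pmin(pmax(v, 0), 1)
  cells <- tidyr::expand_grid(
    ia = seq_len(length(brk_a) - 1), ib = seq_len(length(brk_b) - 1)
  ) |>
    dplyr::mutate(
      xmin = clamp(brk_a[.data$ia]), xmax = clamp(brk_a[.data$ia + 1]),
      ymin = clamp(brk_b[.data$ib]), ymax = clamp(brk_b[.data$ib + 1]),
      zone_a = as.character(.zone_of((.data$xmin + .data$xmax) / 2, pa$tau_plus, pa$tau_minus)),
      zone_b = as.character(.zone_of((.data$ymin + .data$ymax) / 2, pb$tau_plus, pb$tau_minus)),
      agree = .data$zone_a == .data$zone_b
    ) |>
    dplyr::filter(.data$xmax > .data$xmin, .data$ymax > .data$ymin)
  ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = cells,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, ymin = .data$ymin,
                   ymax = .data$ymax, fill = .data$zone_a,
                   alpha = ifelse(.data$agree, 0.25, 0.08)),
      color = "grey85"
    ) +
    ggplot2::geom_point(
      data = pts,
      ggplot2::aes(x = .data$score_a, y = .data$score_b, shape = .data$label),
      size = 1.6, color = "grey15"
    ) +
    ggplot2::scale_fill_manual(values = ZONE_COLORS, labels = ZONE_LABELS,
                               name = "Model A zone") +
    ggplot2::scale_alpha_identity() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Model A score", y = "Model B score",
                  title = sprintf("Safe-Zone grid at alpha = %s", format(alpha))) +
    ggplot2::theme_minimal()
}

.save_figure <- function(plot, path, width = 7, height = 6) {
  .check_writable(path)
  ggplot2::ggsave(path, plot = plot, width = width, height = height,
                  dpi = 150)
  invisible(path)
}

.sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Render the SA-ROC curve to a figure file with a JSON sidecar
#'
#' @inheritParams plot_saroc
#' @param path Output figure path (`.pdf`, `.png` or `.svg`).
#' @return Invisibly, a list with `figure` and `sidecar` paths. The sidecar
#'   records, per safety level, the boundaries, the Gray Zone Area, and the
#'   zone of every threshold segment, exactly as computed by
#'   [make_partition()].
#' @export
render_saroc <- function(cohort, alpha_levels = 1, theta = NULL, path) {
  cohort <- check_cohort(cohort, require_both_classes = TRUE)
  plot <- plot_saroc(cohort, alpha_levels = alpha_levels, theta = theta)
  .save_figure(plot, path)
  theta_used <- theta %||% youden_threshold(cohort)$theta
  levels_info <- purrr::map(sort(alpha_levels), function(a) {
    g <- glance(make_partition(cohort, a, a))
    segs <- .saroc_segments(cohort, a, a)
    list(
      alpha = a, tau_plus = g$tau_plus, tau_minus = g$tau_minus,
      gamma_area = g$gamma_area, gray_fraction = g$gray_fraction,
      segments = data.frame(tau = segs$tau, zone = as.character(segs$zone))
    )
  })
  sidecar <- .sidecar_path(path)
  jsonlite::write_json(
    list(figure = basename(path), theta = theta_used, levels = levels_info),
    sidecar, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(list(figure = path, sidecar = sidecar))
}

#' Render the Safety Profile Curve with a JSON sidecar
#'
#' @inheritParams plot_safety_profile
#' @param path Output figure path.
#' @return Invisibly, `figure` and `sidecar` paths; the sidecar holds the
#'   plotted profile rows exactly.
#' @export
render_safety_profile <- function(profile, path) {
  plot <- plot_safety_profile(profile)
  .save_figure(plot, path)
  profiles <- if (inherits(profile, "sa_profile")) list(profile = profile) else profile
  sidecar <- .sidecar_path(path)
  jsonlite::write_json(
    purrr::map(profiles, ~ as.data.frame(tibble::as_tibble(.x))),
    sidecar, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(list(figure = path, sidecar = sidecar))
}

#' Render the two-model Safe-Zone grid with a JSON sidecar
#'
#' @inheritParams plot_two_model_grid
#' @param path Output figure path.
#' @return Invisibly, `figure` and `sidecar` paths; the sidecar holds the
#'   cross-model zone concordance counts.
#' @export
render_two_model_grid <- function(cohort_a, cohort_b, alpha = 1, path) {
  pair <- .check_paired(cohort_a, cohort_b)
  plot <- plot_two_model_grid(pair$a, pair$b, alpha = alpha)
  .save_figure(plot, path)
  conc <- zone_concordance(
    make_partition(pair$a, alpha, alpha),
    make_partition(pair$b, alpha, alpha)
  )
  sidecar <- .sidecar_path(path)
  jsonlite::write_json(
    list(alpha = alpha,
         concordance = data.frame(zone_a = as.character(conc$zone_a),
                                  zone_b = as.character(conc$zone_b),
                                  n = conc$n)),
    sidecar, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(list(figure = path, sidecar = sidecar))
}
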