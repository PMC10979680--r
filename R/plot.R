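## DGR plot rendering: the (BG, RoC) plane with the five colored regions,
## RoC-BG pairs or curves, a side panel with per-region percentages, and an
## optional elimination-ellipse overlay.

.REGION_FILLS <- c(
  BG_LOW = "#f6b26b", BG_HIGH = "#f6b26b",
  ALERT_LOW = "#e06666", ALERT_HIGH = "#e06666",
  NEUTRAL = "#b6d7a8"
)

## polygons of the five regions over the plotted window
.regionPolygons <- function(cfg, bgRange, rocRange) {
  bgs <- seq(max(bgRange[1L], cfg@bgLow), min(bgRange[2L], cfg@bgHigh),
    length.out = 200L
  )
  lowBorder <- pmin(cfg@alertLowRoC, (cfg@hypoTarget - bgs) / cfg@horizon)
  highBorder <- pmax(cfg@alertHighRoC, (cfg@hyperTarget - bgs) / cfg@horizon)

  polys <- list(
    data.frame(
      region = "BG_LOW",
      bg = c(bgRange[1L], cfg@bgLow, cfg@bgLow, bgRange[1L]),
      roc = c(rocRange[1L], rocRange[1L], rocRange[2L], rocRange[2L])
    ),
    data.frame(
      region = "BG_HIGH",
      bg = c(cfg@bgHigh, bgRange[2L], bgRange[2L], cfg@bgHigh),
      roc = c(rocRange[1L], rocRange[1L], rocRange[2L], rocRange[2L])
    ),
    data.frame(
      region = "ALERT_LOW",
      bg = c(bgs, rev(bgs)),
      roc = c(pmax(rocRange[1L], pmin(lowBorder, rocRange[2L])),
              rep(rocRange[1L], length(bgs)))
    ),
    data.frame(
      region = "ALERT_HIGH",
      bg = c(bgs, rev(bgs)),
      roc = c(pmin(rocRange[2L], pmax(highBorder, rocRange[1L])),
              rep(rocRange[2L], length(bgs)))
    ),
    data.frame(
      region = "NEUTRAL",
      bg = c(bgs, rev(bgs)),
      roc = c(pmax(rocRange[1L], pmin(lowBorder, rocRange[2L])),
              rev(pmin(rocRange[2L], pmax(highBorder, rocRange[1L]))))
    )
  )
  do.call(rbind, polys)
}

.ellipsePath <- function(cfg, d) {
  t <- seq(0, 2 * pi, length.out = 181L)
  data.frame(
    bg = cfg@bgCenter + d * cfg@b * cos(t),
    roc = d * cfg@a * sin(t)
  )
}

#' Render a dynamic glucose region plot
#'
#' Draws the five DGR regions as a colored background (orange BG low/high,
#' red alert low/high, green neutral, tilted alert borders drawn exactly
#' from the region configuration), overlays the RoC-BG pairs, and attaches
#' a side panel listing per-region percentages against the recommended
#' minimum, the number of pairs and the MARoC. Axes are mg/dL and
#' mg/(dL*min) with secondary mmol-based labels. For an
#' [EliminationResult-class], excluded pairs are crossed out and the
#' minimal elimination ellipse (through the largest excluded D) is
#' overlaid.
#'
#' Rendering never mutates the pair data.
#'
#' @param x a [PairSet-class] or an [EliminationResult-class].
#' @param cfg a [RegionConfig-class].
#' @param req a [DistributionRequirements-class] (for the side panel).
#' @param elimCfg an [EliminationConfig-class] (ellipse geometry).
#' @param bgRange,rocRange plotted axis spans (defaults 40-400 mg/dL and
#'   -5 to +5 mg/(dL*min)).
#' @param showPanel attach the side panel (default TRUE).
#' @param curve optional data.frame with `bg` and `roc` columns to draw as
#'   a connected curve (e.g. from [projectSummaryToDGR()]).
#' @return A ggplot/patchwork object.
#' @examples
#' s <- generateSession(SessionParams(manipulationFraction = 1), seed = 1)
#' p <- renderDGRPlot(computePairs(s))
#' @export
renderDGRPlot <- function(x, cfg = RegionConfig(),
                          req = DistributionRequirements(),
                          elimCfg = EliminationConfig(),
                          bgRange = c(40, 400), rocRange = c(-5, 5),
                          showPanel = TRUE, curve = NULL) {
  elim <- NULL
  if (methods::is(x, "EliminationResult")) {
    elim <- x
    pairs <- PairSet(rbind(
      pairData(elim@kept),
      elim@excluded[, .PAIR_COLUMNS, drop = FALSE]
    ))
  } else {
    pairs <- x
  }
  p <- pairData(pairs)
  if (!nrow(p)) stop("empty input: nothing to plot")

  polys <- .regionPolygons(cfg, bgRange, rocRange)
  gg <- ggplot2::ggplot() +
    ggplot2::geom_polygon(
      data = polys,
      ggplot2::aes(x = .data$bg, y = .data$roc, fill = .data$region),
      alpha = 0.55, show.legend = FALSE
    ) +
    ggplot2::scale_fill_manual(values = .REGION_FILLS) +
    ggplot2::geom_point(
      data = p, ggplot2::aes(x = .data$bg, y = .data$roc),
      size = 1, alpha = 0.6
    ) +
    ggplot2::scale_x_continuous(
      name = "BG [mg/dL]",
      sec.axis = ggplot2::sec_axis(
        ~ . / MGDL_PER_MMOLL, name = "BG [mmol/L]",
        labels = function(v) sprintf("%.1f", v)
      )
    ) +
    ggplot2::scale_y_continuous(
      name = "RoC [mg/(dL·min)]",
      sec.axis = ggplot2::sec_axis(
        ~ . / MGDL_PER_MMOLL, name = "RoC [mmol/(L·min)]",
        labels = function(v) sprintf("%.2f", v)
      )
    ) +
    ggplot2::coord_cartesian(xlim = bgRange, ylim = rocRange, expand = FALSE) +
    ggplot2::theme_minimal()

  if (!is.null(elim) && elim@k > 0L) {
    gg <- gg +
      ggplot2::geom_point(
        data = elim@excluded,
        ggplot2::aes(x = .data$bg, y = .data$roc),
        shape = 4, size = 1.6, color = "grey25"
      ) +
      ggplot2::geom_path(
        data = .ellipsePath(elimCfg, elim@maxExcludedD),
        ggplot2::aes(x = .data$bg, y = .data$roc),
        color = "red", linewidth = 0.7
      )
  }
  if (!is.null(curve)) {
    gg <- gg + ggplot2::geom_path(
      data = curve, ggplot2::aes(x = .data$bg, y = .data$roc),
      color = "blue", linewidth = 0.8
    )
  }
  if (!showPanel) {
    return(gg)
  }

  rep <- distributionReport(pairs, cfg, req, includeFlagged = TRUE)
  lines <- c(
    sprintf("n = %d", rep@nTotal),
    "",
    vapply(dgrRegions(), function(r) {
      sprintf(
        "%-10s %5.1f%%%s", r, formatPercent(rep@fractions[[r]]),
        if (r %in% criticalRegions()) {
          sprintf(" (req ≥ %.1f%%)", 100 * req@minCriticalFraction)
        } else {
          sprintf(" (req ≤ %.0f%%)", 100 * req@maxNeutralFraction)
        }
      )
    }, character(1)),
    "",
    sprintf("MARoC = %.2f mg/(dL·min)", maroc(pairs))
  )
  panel <- ggplot2::ggplot() +
    ggplot2::annotate("text",
      x = 0, y = 1, label = paste(lines, collapse = "\n"),
      hjust = 0, vjust = 1, family = "mono", size = 3.2
    ) +
    ggplot2::xlim(0, 1) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_void()
  patchwork::wrap_plots(gg, panel, widths = c(3, 1.4))
}

#' Save a DGR plot to file
#'
#' @param plot object from [renderDGRPlot()].
#' @param path output file; format inferred from the extension (`.png`,
#'   `.pdf` or `.svg`).
#' @param width,height,dpi device settings.
#' @return The path, invisibly.
#' @export
saveDGRPlot <- function(plot, path, width = 9, height = 5, dpi = 150) {
  ggplot2::ggsave(path, plot, width = width, height = height, dpi = dpi)
  invisible(path)
}
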