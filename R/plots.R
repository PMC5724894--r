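#' @import ggplot2
#' @importFrom rlang .data
NULL

.cat_centers <- data.frame(category = 1:6, center = seq(30, 330, 60))

#' Polar scatter of pattern angles and magnitudes
#'
#' One point per gene at angle `theta` (0 degrees at the top, increasing
#' clockwise) and radial distance `r`, with the six 60-degree category
#' sectors delineated and labelled.
#'
#' @param x A [TriCompResult-class]; genes with undefined theta are
#'   dropped (an error if none remain).
#' @param rScale If `FALSE`, all points are drawn on the unit circle so
#'   only the pattern is shown.
#' @param shadeCategories Shade alternating category sectors.
#' @param pointSize,alpha Passed to `geom_point`.
#' @return A `ggplot` object; the plotted coordinates sit in `$data`
#'   (columns `theta`, `rplot`).
#' @export
plotPolar <- function(x, rScale = TRUE, shadeCategories = TRUE,
                      pointSize = 1, alpha = 0.7) {
  df <- data.frame(gene_id = x$gene_id, theta = x$theta, r = x$r)
  df <- df[!is.na(df$theta), , drop = FALSE]
  if (nrow(df) == 0) stop("no genes with defined theta to plot")
  df$rplot <- if (rScale) df$r else 1
  rmax <- max(df$rplot)
  gg <- ggplot(df, aes(x = .data$theta, y = .data$rplot))
  if (shadeCategories) {
    shade <- data.frame(xmin = seq(0, 300, 60)[c(1, 3, 5)],
                        xmax = seq(60, 360, 60)[c(1, 3, 5)])
    gg <- gg + geom_rect(data = shade,
                         aes(xmin = .data$xmin, xmax = .data$xmax,
                             ymin = 0, ymax = rmax * 1.05),
                         inherit.aes = FALSE, fill = "grey92")
  }
  gg +
    geom_vline(xintercept = seq(0, 300, 60), colour = "grey70",
               linewidth = 0.3) +
    geom_point(size = pointSize, alpha = alpha, colour = "steelblue4") +
    annotate("text", x = .cat_centers$center, y = rmax * 1.12,
             label = .cat_centers$category, fontface = "bold") +
    coord_polar(theta = "x", start = 0, direction = 1) +
    scale_x_continuous(limits = c(0, 360), breaks = seq(0, 300, 60)) +
    scale_y_continuous(limits = c(0, rmax * 1.15)) +
    labs(x = expression(theta ~ "(degrees)"),
         y = if (rScale) "r (log2 units)" else NULL) +
    theme_minimal()
}

#' Strip plot of theta distributions per group
#'
#' Jittered one-dimensional scatter of theta values for one or more
#' groups of genes on a common 0-360 degree axis, with category
#' boundaries at multiples of 60 degrees and an optional p-value
#' annotation per group.
#'
#' @param groups Named list of numeric theta vectors (or a single
#'   vector). Undefined values are an error.
#' @param pValues Optional named numeric vector of p values annotated
#'   after the group labels.
#' @param jitterHeight Vertical jitter (default 0.2).
#' @param seed Seed for the jitter so output files are reproducible.
#' @return A `ggplot` object (`$data` holds `theta` and `group`).
#' @export
plotThetaDistribution <- function(groups, pValues = NULL,
                                  jitterHeight = 0.2, seed = 1) {
  if (!is.list(groups)) groups <- list(all = groups)
  if (length(groups) == 0 || all(lengths(groups) == 0))
    stop("need at least one non-empty group")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  if (any(vapply(groups, anyNA, logical(1))))
    stop("undefined theta present; filter flat genes first")
  df <- data.frame(
    group = rep(names(groups), lengths(groups)),
    theta = unlist(groups, use.names = FALSE))
  labels <- names(groups)
  if (!is.null(pValues)) {
    shown <- pValues[labels]
    labels <- ifelse(is.na(shown), labels,
                     sprintf("%s (p = %.3g)", labels, shown))
    names(labels) <- names(groups)
    df$group <- labels[df$group]
  }
  df$group <- factor(df$group, levels = rev(unique(df$group)))
  .with_seed(seed,
    ggplot(df, aes(x = .data$theta, y = .data$group)) +
      geom_vline(xintercept = seq(0, 360, 60), colour = "grey80",
                 linewidth = 0.3) +
      geom_jitter(width = 0, height = jitterHeight, size = 1,
                  alpha = 0.7, colour = "steelblue4") +
      scale_x_continuous(limits = c(0, 360),
                         breaks = seq(0, 360, 60)) +
      labs(x = expression(theta ~ "(degrees)"), y = NULL) +
      theme_minimal())
}

#' Bar plot of gene counts per pattern category
#'
#' @param x A [TriCompResult-class] or an integer vector of category
#'   assignments (1-6; `NA` dropped) or six bin counts.
#' @return A `ggplot` object.
#' @export
plotCategoryBar <- function(x) {
  counts <- if (is(x, "TriCompResult"))
    binTheta(x$theta[!is.na(x$theta)])
  else if (length(x) == 6 && !is.null(names(x)) &&
           all(grepl("^cat", names(x)))) as.numeric(x)
  else stats::setNames(tabulate(x[!is.na(x)], 6L), paste0("cat", 1:6))
  df <- data.frame(category = factor(1:6), n = as.numeric(counts))
  ggplot(df, aes(x = .data$category, y = .data$n)) +
    geom_col(fill = "steelblue4") +
    labs(x = "pattern category", y = "genes") +
    theme_minimal()
}

#' Save a plot to a file by extension
#'
#' @param plot A `ggplot` object.
#' @param path Output path ending in `.png` or `.pdf`.
#' @param width,height,dpi Device settings in inches / dots per inch.
#' @return `path`, invisibly.
#' @export
savePlot <- function(plot, path, width = 7, height = 6, dpi = 150) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "pdf"))
    stop("unsupported plot format: .", ext)
  ggsave(path, plot, width = width, height = height, dpi = dpi)
  invisible(path)
}
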