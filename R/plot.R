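# Diversity tree plot: every clonotype is a spot whose area is
# proportional to its relative transcript frequency, positioned in a
# V x J grid (x: V usage, y: J usage; cell extents proportional to cell
# mass). Within-cell packing is deterministic concentric-ring placement
# ordered by descending frequency. Rendering is plain SVG text so that
# identical layouts give byte-identical files.

#' Diversity plot specification
#'
#' @param width,height canvas size in px.
#' @param color_seed seed for the per-plot color permutation (each plot
#'   has a distinct color code; colors are unique per clonotype).
#' @param min_radius minimum renderable spot radius in px; floored spots
#'   lose strict area proportionality and are flagged in the layout.
#' @param area_budget fraction of the canvas area shared by all spots.
#' @return object of class `plot_spec`.
#' @export
plot_spec <- function(width = 800, height = 800, color_seed = 1L,
                      min_radius = 0.2, area_budget = 0.3) {
  stopifnot(width > 0, height > 0, min_radius >= 0,
            area_budget > 0, area_budget <= 1)
  structure(list(width = width, height = height, color_seed = color_seed,
                 min_radius = min_radius, area_budget = area_budget),
            class = "plot_spec")
}

# injective 24-bit color per index (odd multiplier modulo 2^24)
spot_colors <- function(n, seed) {
  perm <- with_seed(seed, sample.int(n))
  val <- (perm * 2654435761) %% 16777216
  sprintf("#%06X", val)
}

#' Lay out a diversity plot
#'
#' @param rep a `repertoire`.
#' @param spec a [plot_spec()].
#' @param library optional `germline_library` fixing the V/J axis orders.
#' @return data frame: `junction_nt`, `v_call`, `j_call`, `frequency`,
#'   `x`, `y`, `radius` (post-floor), `radius_raw`, `floored` (minimum-
#'   radius floor engaged), `overflow` (spot larger than its cell, placed
#'   at the cell center; area proportionality is preserved but
#'   confinement is not), `color`.
#' @export
layout_diversity_plot <- function(rep, spec = plot_spec(), library = NULL) {
  cl <- rep$clonotypes
  if (!nrow(cl)) {
    return(data.frame(junction_nt = character(0), v_call = character(0),
                      j_call = character(0), frequency = numeric(0),
                      x = numeric(0), y = numeric(0), radius = numeric(0),
                      radius_raw = numeric(0), floored = logical(0),
                      overflow = logical(0), color = character(0),
                      stringsAsFactors = FALSE))
  }
  usage <- vj_usage(rep, library)
  v_labels <- rownames(usage); j_labels <- colnames(usage)
  v_mass <- rowSums(usage)
  # x partition by V usage; within a column, y partition by J-given-V mass
  x_edges <- unname(c(0, cumsum(v_mass / sum(v_mass)))) * spec$width
  area_total <- spec$area_budget * spec$width * spec$height
  cl$radius_raw <- sqrt(cl$frequency * area_total / pi)
  cl$radius <- pmax(cl$radius_raw, spec$min_radius)
  cl$floored <- cl$radius > cl$radius_raw
  cl$color <- spot_colors(nrow(cl), spec$color_seed)
  cl$x <- NA_real_; cl$y <- NA_real_
  cl$overflow <- FALSE

  for (vi in seq_along(v_labels)) {
    jv <- usage[vi, ]
    if (sum(jv) == 0) next
    y_edges <- unname(c(0, cumsum(jv / sum(jv)))) * spec$height
    for (ji in seq_along(j_labels)) {
      idx <- which(cl$v_call == v_labels[vi] & cl$j_call == j_labels[ji])
      if (!length(idx)) next
      idx <- idx[order(-cl$frequency[idx], cl$junction_nt[idx])]
      cell <- c(x0 = x_edges[vi], x1 = x_edges[vi + 1],
                y0 = y_edges[ji], y1 = y_edges[ji + 1])
      cx <- (cell["x0"] + cell["x1"]) / 2
      cy <- (cell["y0"] + cell["y1"]) / 2
      r1 <- cl$radius[idx[1]]
      ring <- 0; pos_on_ring <- 0; ring_cap <- 1
      ring_r <- 0
      for (k in seq_along(idx)) {
        r <- cl$radius[idx[k]]
        if (k == 1) {
          px <- cx; py <- cy
        } else {
          if (pos_on_ring >= ring_cap) {
            ring <- ring + 1
            ring_r <- ring * 2.2 * max(r1, 1e-9)
            ring_cap <- max(6 * ring, 1)
            pos_on_ring <- 0
          }
          theta <- 2 * pi * pos_on_ring / ring_cap
          px <- cx + ring_r * cos(theta)
          py <- cy + ring_r * sin(theta)
          pos_on_ring <- pos_on_ring + 1
        }
        # clamp inside the cell so no fitting spot crosses its boundary;
        # spots wider than the cell are centered and flagged
        if (cell["x1"] - cell["x0"] < 2 * r) {
          px <- cx; cl$overflow[idx[k]] <- TRUE
        } else px <- min(max(px, cell["x0"] + r), cell["x1"] - r)
        if (cell["y1"] - cell["y0"] < 2 * r) {
          py <- cy; cl$overflow[idx[k]] <- TRUE
        } else py <- min(max(py, cell["y0"] + r), cell["y1"] - r)
        cl$x[idx[k]] <- px; cl$y[idx[k]] <- py
      }
    }
  }
  out <- cl[, c("junction_nt", "v_call", "j_call", "frequency",
                "x", "y", "radius", "radius_raw", "floored", "overflow",
                "color")]
  rownames(out) <- NULL
  out
}

#' Render a diversity plot layout as SVG
#'
#' Deterministic: identical layouts produce byte-identical files.
#'
#' @param layout data frame from [layout_diversity_plot()].
#' @param path output `.svg` path.
#' @param spec the [plot_spec()] used for the layout.
#' @return invisibly, `path`.
#' @export
render_svg <- function(layout, path, spec = plot_spec()) {
  con <- try(file(path, "wb"), silent = TRUE)
  if (inherits(con, "try-error")) stop_input("cannot write to ", path)
  on.exit(close(con))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%g" height="%g" viewBox="0 0 %g %g">',
            spec$width, spec$height, spec$width, spec$height),
    sprintf('<rect width="%g" height="%g" fill="white"/>',
            spec$width, spec$height))
  if (nrow(layout)) {
    lines <- c(lines, sprintf(
      '<circle cx="%.3f" cy="%.3f" r="%.3f" fill="%s"/>',
      layout$x, layout$y, layout$radius, layout$color))
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Plot a repertoire diversity tree
#'
#' Base-graphics rendering of the same layout, for interactive use.
#'
#' @param x a `repertoire`.
#' @param spec a [plot_spec()].
#' @param library optional axis-order library.
#' @param ... passed to [graphics::symbols()].
#' @export
plot.repertoire <- function(x, spec = plot_spec(), library = NULL, ...) {
  lay <- layout_diversity_plot(x, spec, library)
  graphics::plot(NA, xlim = c(0, spec$width), ylim = c(spec$height, 0),
                 xlab = "V usage", ylab = "J usage", asp = 1,
                 main = sprintf("%s / %s (%d variants)", x$donor_id,
                                x$lineage, nrow(x$clonotypes)))
  if (nrow(lay))
    graphics::symbols(lay$x, lay$y, circles = lay$radius, inches = FALSE,
                      add = TRUE, bg = lay$color, fg = NA, ...)
  invisible(lay)
}
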