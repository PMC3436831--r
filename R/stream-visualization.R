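# Stream-style lineage visualization: each colony is a vertical band whose
# width tracks a feature (area by default, normalized so that the widths of a
# frame sum to that frame's covered-area fraction -- full plot width means
# confluency) and whose color encodes a second feature (circularity: red =
# round, blue = irregular). Time runs downward; merging and splitting
# colonies appear as converging and diverging bands.

#' Stream rendering style
#'
#' @param color_low,color_high Colors for the low/high end of the color
#'   feature (low circularity = irregular maps to blue, high = round to
#'   red).
#' @param gap Horizontal gap between adjacent streams, as a fraction of plot
#'   width (excluded from the width normalization).
#' @param samples_per_interval Interpolation samples between consecutive
#'   frames for smooth band boundaries.
#' @return A `stream_style` list.
#' @export
stream_style <- function(color_low = "#2166AC", color_high = "#B2182B",
                         gap = 0.01, samples_per_interval = 8L) {
  if (gap < 0) stopf("gap must be >= 0")
  structure(list(color_low = color_low, color_high = color_high,
                 gap = gap,
                 samples_per_interval = as.integer(samples_per_interval)),
            class = "stream_style")
}

#' Lay out colony streams
#'
#' Computes, per frame and colony, a horizontal interval whose width is
#' proportional to `width_feature` and a color value normalized from
#' `color_feature` over the whole sequence. With the default width feature
#' (`area_px`) widths are normalized by the frame pixel count, so the widths
#' of one frame sum to its covered-area fraction. Stream order is inherited
#' frame to frame (initially by centroid column); split children take their
#' parent's slot, so converging/diverging bands stay adjacent.
#'
#' @param graph A [track_graph()].
#' @param records Feature tibble from [measure_sequence()]; every graph node
#'   needs a record.
#' @param width_feature Feature column controlling band width.
#' @param color_feature Feature column controlling band color.
#' @param frame_px Total pixels per frame (for the area normalization);
#'   defaults to the `frame_px` attribute of `records`.
#' @param gap Gap between adjacent streams (fraction of plot width).
#' @return A `stream_layout` tibble with columns `frame`, `colony_id`,
#'   `left`, `right`, `width`, `color_value`, `color_norm`.
#' @export
layout_streams <- function(graph, records, width_feature = "area_px",
                           color_feature = "circularity",
                           frame_px = attr(records, "frame_px"),
                           gap = 0.01) {
  stopifnot(inherits(graph, "track_graph"))
  if (!width_feature %in% names(records)) stopf("unknown width feature '%s'", width_feature)
  if (!color_feature %in% names(records)) stopf("unknown color feature '%s'", color_feature)
  nodes <- graph$nodes
  if (nrow(nodes) == 0) {
    return(structure(tibble::tibble(
      frame = integer(), colony_id = integer(), left = numeric(),
      right = numeric(), width = numeric(), color_value = numeric(),
      color_norm = numeric()), class = c("stream_layout", "tbl_df", "tbl", "data.frame")))
  }
  key <- function(f, l) paste(f, l, sep = ":")
  rec_idx <- stats::setNames(seq_len(nrow(records)),
                             key(records$frame, records$colony_id))
  missing <- !key(nodes$frame, nodes$label) %in% names(rec_idx)
  if (any(missing)) {
    stopf("no feature record for node(s): %s",
          paste(utils::head(key(nodes$frame, nodes$label)[missing], 5), collapse = ", "))
  }
  if (is.null(frame_px)) {
    if (width_feature == "area_px") stopf("frame_px needed to normalize area widths")
    frame_px <- NA_real_
  }

  cvals <- records[[color_feature]]
  crange <- range(cvals, na.rm = TRUE)
  cspan <- if (diff(crange) < 1e-12) 1 else diff(crange)

  frames_all <- sort(unique(nodes$frame))
  # stream order: first frame by centroid column, inherited afterwards with
  # split children inserted at the parent's slot
  order_ids <- nodes$label[nodes$frame == frames_all[1]]
  ord0 <- order(nodes$centroid_col[nodes$frame == frames_all[1]], order_ids)
  order_ids <- order_ids[ord0]
  edges <- graph$edges

  rows <- list()
  for (f in frames_all) {
    labs <- nodes$label[nodes$frame == f]
    if (f != frames_all[1]) {
      # children inherit parent slots
      new_order <- integer(0)
      for (p in order_ids) {
        kids <- edges$child_label[!is.na(edges$parent_label) &
                                    edges$parent_frame == f - 1L &
                                    edges$parent_label == p &
                                    edges$child_frame == f]
        kids <- intersect(unique(kids), labs)
        kids <- setdiff(kids, new_order)
        if (p %in% labs && !(p %in% new_order)) kids <- union(kids, p)
        new_order <- c(new_order, sort(kids))
      }
      leftovers <- setdiff(labs, new_order)  # appearances etc.
      if (length(leftovers) > 0) {
        cen <- nodes$centroid_col[nodes$frame == f][match(leftovers, labs)]
        leftovers <- leftovers[order(cen, leftovers)]
      }
      order_ids <- c(new_order, leftovers)
    }
    wv <- vapply(order_ids, function(l) {
      records[[width_feature]][rec_idx[[key(f, l)]]]
    }, numeric(1))
    widths <- if (width_feature == "area_px") wv / frame_px else wv / sum(wv)
    cv <- vapply(order_ids, function(l) {
      records[[color_feature]][rec_idx[[key(f, l)]]]
    }, numeric(1))
    lefts <- cumsum(c(0, utils::head(widths, -1))) +
      gap * (seq_along(widths) - 1)
    rows[[length(rows) + 1]] <- tibble::tibble(
      frame = f, colony_id = order_ids,
      left = lefts, right = lefts + widths, width = widths,
      color_value = cv,
      color_norm = (cv - crange[1]) / cspan)
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("stream_layout", class(tibble::tibble())),
            frame_px = frame_px)
}

# piecewise-monotone cubic interpolation of band edges over frames
interp_edges <- function(frames, vals, n_samples) {
  if (length(frames) == 1) {
    return(list(t = frames, v = vals))
  }
  tt <- seq(min(frames), max(frames), length.out = (length(frames) - 1) * n_samples + 1)
  f <- stats::splinefun(frames, vals, method = "monoH.FC")
  list(t = tt, v = f(tt))
}

stream_color <- function(norm, style) {
  lo <- grDevices::col2rgb(style$color_low) / 255
  hi <- grDevices::col2rgb(style$color_high) / 255
  rgb <- lo + (hi - lo) * norm
  grDevices::rgb(rgb[1], rgb[2], rgb[3])
}

#' Render a stream layout to SVG
#'
#' Writes a deterministic standalone SVG: one `<path class="stream">` per
#' contiguous run of each colony's band (boundaries interpolated smoothly
#' between frames, colored segment-wise by the color feature), a downward
#' frame axis with ticks, and a color bar below the plot.
#'
#' @param layout A `stream_layout` from [layout_streams()].
#' @param style A [stream_style()].
#' @param path Output file (`.svg`).
#' @param width,height Canvas size in px.
#' @param color_feature_name Label for the color bar.
#' @return `path`, invisibly.
#' @export
render_streams <- function(layout, style = stream_style(), path,
                           width = 480, height = 640,
                           color_feature_name = "circularity") {
  mar <- c(top = 30, right = 30, bottom = 80, left = 50)
  pw <- width - mar[["left"]] - mar[["right"]]
  ph <- height - mar[["top"]] - mar[["bottom"]]
  frames_all <- sort(unique(layout$frame))
  nfr <- length(frames_all)
  fmin <- if (nfr > 0) min(frames_all) else 0
  fmax <- if (nfr > 0) max(frames_all) else 1
  fspan <- max(fmax - fmin, 1)
  xmax <- max(layout$right, 1e-9, na.rm = TRUE)
  sx <- function(x) mar[["left"]] + x / max(xmax, 1) * pw
  sy <- function(f) mar[["top"]] + (f - fmin) / fspan * ph

  out <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
    width, height, width, height),
    '<rect width="100%" height="100%" fill="white"/>')

  # bands: one path per colony per contiguous frame run
  if (nrow(layout) > 0) {
    for (id in unique(layout$colony_id)) {
      seg <- layout[layout$colony_id == id, ]
      seg <- seg[order(seg$frame), ]
      runs <- split(seq_len(nrow(seg)), cumsum(c(1, diff(seg$frame) != 1)))
      for (run in runs) {
        s <- seg[run, ]
        col <- stream_color(mean(s$color_norm), style)
        if (nrow(s) == 1) {
          y0 <- sy(s$frame) - 2; y1 <- sy(s$frame) + 2
          d <- sprintf("M %.2f %.2f L %.2f %.2f L %.2f %.2f L %.2f %.2f Z",
                       sx(s$left), y0, sx(s$right), y0,
                       sx(s$right), y1, sx(s$left), y1)
        } else {
          le <- interp_edges(s$frame, s$left, style$samples_per_interval)
          re <- interp_edges(s$frame, s$right, style$samples_per_interval)
          xs <- c(sx(le$v), rev(sx(re$v)))
          ys <- c(sy(le$t), rev(sy(re$t)))
          d <- paste0("M ", paste(sprintf("%.2f %.2f", xs, ys), collapse = " L "), " Z")
        }
        out <- c(out, sprintf(
          '<path class="stream" data-colony="%d" d="%s" fill="%s" stroke="none"/>',
          id, d, col))
      }
    }
  }

  # downward time axis with frame ticks
  out <- c(out, sprintf(
    '<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="black"/>',
    mar[["left"]] - 8, sy(fmin), mar[["left"]] - 8, sy(fmax)))
  tick_at <- if (nfr > 0) frames_all else integer(0)
  if (nfr > 12) tick_at <- pretty(frames_all)
  for (f in tick_at) {
    out <- c(out,
      sprintf('<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="black"/>',
              mar[["left"]] - 12, sy(f), mar[["left"]] - 8, sy(f)),
      sprintf('<text x="%.1f" y="%.1f" font-size="10" text-anchor="end">%d</text>',
              mar[["left"]] - 15, sy(f) + 3, as.integer(f)))
  }
  out <- c(out, sprintf(
    '<text x="12" y="%.1f" font-size="11" transform="rotate(-90 12 %.1f)" text-anchor="middle">frame</text>',
    mar[["top"]] + ph / 2, mar[["top"]] + ph / 2))

  # color bar
  bar_y <- height - 45
  nseg <- 64
  for (i in seq_len(nseg)) {
    out <- c(out, sprintf(
      '<rect class="colorbar" x="%.2f" y="%d" width="%.2f" height="10" fill="%s"/>',
      mar[["left"]] + (i - 1) / nseg * pw, bar_y, pw / nseg + 0.5,
      stream_color((i - 0.5) / nseg, style)))
  }
  out <- c(out,
    sprintf('<text x="%.1f" y="%d" font-size="10" text-anchor="start">irregular</text>',
            mar[["left"]], bar_y + 22),
    sprintf('<text x="%.1f" y="%d" font-size="10" text-anchor="end">round</text>',
            mar[["left"]] + pw, bar_y + 22),
    sprintf('<text x="%.1f" y="%d" font-size="11" text-anchor="middle">%s</text>',
            mar[["left"]] + pw / 2, bar_y + 35, color_feature_name),
    '</svg>')
  writeLines(out, path)
  invisible(path)
}

#' Plot a stream layout with ggplot2
#'
#' The ggplot2 view of [layout_streams()]: ribbons over (interpolated)
#' frames, time downward, color mapped to the color feature.
#'
#' @param object A `stream_layout`.
#' @param style A [stream_style()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stream_layout
#' @export
autoplot.stream_layout <- function(object, style = stream_style(), ...) {
  if (nrow(object) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::scale_y_reverse() +
             ggplot2::labs(x = NULL, y = "frame"))
  }
  smooth <- object |>
    dplyr::group_by(.data$colony_id) |>
    dplyr::group_modify(function(d, g) {
      d <- d[order(d$frame), ]
      runs <- split(seq_len(nrow(d)), cumsum(c(1, diff(d$frame) != 1)))
      dplyr::bind_rows(lapply(seq_along(runs), function(ri) {
        s <- d[runs[[ri]], ]
        if (nrow(s) < 2) {
          return(tibble::tibble(run = ri, t = s$frame, left = s$left,
                                right = s$right, color_norm = s$color_norm))
        }
        le <- interp_edges(s$frame, s$left, style$samples_per_interval)
        re <- interp_edges(s$frame, s$right, style$samples_per_interval)
        cn <- stats::approx(s$frame, s$color_norm, xout = le$t)$y
        tibble::tibble(run = ri, t = le$t, left = le$v, right = re$v,
                       color_norm = cn)
      }))
    }) |>
    dplyr::ungroup()
  ggplot2::ggplot(smooth, ggplot2::aes(y = .data$t, xmin = .data$left,
                                       xmax = .data$right,
                                       group = interaction(.data$colony_id, .data$run),
                                       fill = .data$color_norm)) +
    ggplot2::geom_ribbon(orientation = "y") +
    ggplot2::scale_fill_gradient(low = style$color_low, high = style$color_high,
                                 limits = c(0, 1), name = "feature\n(normalized)") +
    ggplot2::scale_y_reverse(breaks = scales_breaks_int) +
    ggplot2::labs(x = "covered fraction of the field of view", y = "frame") +
    ggplot2::theme_minimal()
}

scales_breaks_int <- function(lims) {
  b <- pretty(lims)
  b[b == floor(b)]
}
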