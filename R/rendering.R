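# Scale-adaptive static track rendering. The display is assembled as a flat
# list of drawing primitives (rects, lines, text), then emitted either as
# deterministic SVG text (the byte-exact reference output) or drawn onto a
# grDevices png device.

#' Choose detail vs histogram display mode
#'
#' Individual features are drawn only when they fit the display resolution:
#' detail mode iff there is at most one item per pixel, else a histogram
#' with one bin per pixel.
#'
#' @param item_count number of items in the view.
#' @param pixel_width display width in pixels (>= 1).
#' @return `"detail"` or `"histogram"`.
#' @export
mode_for_view <- function(item_count, pixel_width) {
  if (pixel_width < 1) stop("pixel_width must be >= 1")
  if (item_count <= pixel_width) "detail" else "histogram"
}

#' Affine genome-to-pixel coordinate map
#'
#' @param pos base-pair position(s).
#' @param view list with `start`, `end` (1-based inclusive bp).
#' @param pixel_width display width in pixels.
#' @return pixel x coordinate(s), rounded and clamped to [0, pixel_width].
#' @export
pixel_x <- function(pos, view, pixel_width) {
  view <- as.list(view)
  span <- as.numeric(view$end) - as.numeric(view$start) + 1
  px <- round((pos - as.numeric(view$start)) / span * pixel_width)
  pmin(pmax(px, 0), pixel_width)
}

#' Rendering configuration
#'
#' @param view list with `chrom`, `start`, `end`.
#' @param pixel_width image width in pixels (>= 16).
#' @param tracks list of track specs; each a list with `type` (one of
#'   "snp", "features", "mosaic", "ibd", "intervals", "het"), `data`, and
#'   optionally `strain_order`, `label`.
#' @param format "svg" or "png".
#' @return list of class `render_config`.
#' @export
render_config <- function(view, pixel_width = 800, tracks = list(),
                          format = c("svg", "png")) {
  if (pixel_width < 16) stop("pixel_width must be >= 16")
  structure(list(view = as.list(view), pixel_width = pixel_width,
                 tracks = tracks, format = match.arg(format)),
            class = "render_config")
}

prim_rect <- function(x, y, w, h, fill) {
  list(kind = "rect", x = x, y = y, w = w, h = h, fill = fill)
}
prim_line <- function(x1, y1, x2, y2, col = "#000000") {
  list(kind = "line", x1 = x1, y1 = y1, x2 = x2, y2 = y2, col = col)
}
prim_text <- function(x, y, s, size = 10, col = "#000000") {
  list(kind = "text", x = x, y = y, s = s, size = size, col = col)
}

ROW_H <- 14      # per-strain row height, px
HIST_H <- 40     # histogram track height, px
GAP <- 6

# ruler: axis line plus ~8 labeled ticks at round positions
ruler_prims <- function(view, width, y) {
  v0 <- as.numeric(view$start); v1 <- as.numeric(view$end)
  prims <- list(prim_line(0, y, width, y))
  step <- 10^floor(log10((v1 - v0 + 1) / 4))
  ticks <- seq(ceiling(v0 / step) * step, v1, by = step)
  if (length(ticks) > 12) ticks <- ticks[seq(1, length(ticks), by = 2)]
  for (tp in ticks) {
    x <- pixel_x(tp, view, width)
    prims <- c(prims, list(prim_line(x, y, x, y + 4),
                           prim_text(x, y + 14, format(tp, scientific = FALSE,
                                                       trim = TRUE), 8)))
  }
  prims
}

# one mosaic-style track (mosaic / ibd / het / subspecies segments):
# data = data.frame(strain, start, end, color) with hex colors
mosaic_prims <- function(df, strain_order, view, width, y0) {
  prims <- list()
  for (i in seq_along(strain_order)) {
    rows <- df[df$strain == strain_order[i], , drop = FALSE]
    y <- y0 + (i - 1) * ROW_H
    for (r in seq_len(nrow(rows))) {
      x1 <- pixel_x(rows$start[r], view, width)
      x2 <- pixel_x(rows$end[r], view, width)
      if (x2 > x1)
        prims <- c(prims, list(prim_rect(x1, y, x2 - x1, ROW_H - 2,
                                         rows$color[r])))
    }
    prims <- c(prims, list(prim_text(-4, y + ROW_H - 4, strain_order[i], 8)))
  }
  prims
}

# snp/feature track: detail ticks at <= 1 item/px, else a histogram whose
# bars are normalized to the tallest bin in view
point_track_prims <- function(starts, view, width, y0, col = "#3366AA") {
  inview <- starts[starts >= view$start & starts <= view$end]
  if (mode_for_view(length(inview), width) == "detail") {
    lapply(inview, function(p) {
      x <- pixel_x(p, view, width)
      prim_line(x, y0, x, y0 + HIST_H)
    })
  } else {
    counts <- interval_density_histogram(inview, view, width)
    mx <- max(counts)
    prims <- list()
    for (b in seq_len(width)) {
      if (counts[b] == 0) next
      h <- round(counts[b] / mx * HIST_H)
      prims <- c(prims, list(prim_rect(b - 1, y0 + HIST_H - h, 1, h, col)))
    }
    prims
  }
}

# compatible intervals on two alternating parity rows
interval_track_prims <- function(intervals, view, width, y0) {
  prims <- list()
  for (i in seq_len(nrow(intervals))) {
    if (intervals$end_pos[i] < view$start ||
        intervals$start_pos[i] > view$end) next
    x1 <- pixel_x(intervals$start_pos[i], view, width)
    x2 <- pixel_x(intervals$end_pos[i], view, width)
    y <- y0 + ifelse(intervals$parity[i] == "even", 0, ROW_H)
    prims <- c(prims, list(prim_rect(x1, y, max(x2 - x1, 1), ROW_H - 2,
                                     "#3366AA")))
  }
  prims
}

# allele overlay in detail mode: one letter per (strain, marker)
allele_overlay_prims <- function(gm, strain_order, view, width, y0) {
  keep <- which(gm$pos >= view$start & gm$pos <= view$end)
  if (mode_for_view(length(keep), width) != "detail") return(list())
  prims <- list()
  for (i in seq_along(strain_order)) {
    ri <- match(strain_order[i], gm$strains)
    y <- y0 + (i - 1) * ROW_H + ROW_H - 4
    for (j in keep) {
      code <- gm$calls[ri, j]
      ch <- switch(as.character(code), "0" = gm$alleles[j, 1],
                   "1" = gm$alleles[j, 2], "2" = "H", "-1" = "N")
      prims <- c(prims, list(prim_text(pixel_x(gm$pos[j], view, width),
                                       y, ch, 7, "#000000")))
    }
  }
  prims
}

track_height <- function(track) {
  switch(track$type,
         snp = , het = , features = HIST_H + GAP,
         intervals = 2 * ROW_H + GAP,
         mosaic = , ibd = length(track$strain_order) * ROW_H + GAP)
}

#' Render stacked genome tracks to SVG or PNG
#'
#' Deterministic layout: a coordinate ruler on top, then each configured
#' track. Mosaic-style tracks draw one colored rectangle per segment per
#' strain; compatible intervals occupy two parity rows; SNP-like tracks
#' switch between per-item ticks and a max-normalized histogram depending on
#' scale; an allele overlay is drawn on mosaic tracks only in detail mode.
#' Identical inputs produce byte-identical SVG.
#'
#' @param config a [render_config()].
#' @param path output file path.
#' @return invisibly, the primitive list.
#' @export
render_tracks <- function(config, path) {
  view <- config$view
  if (view$start > view$end) stop("empty view")
  width <- config$pixel_width
  y <- 24
  prims <- ruler_prims(view, width, 4)
  for (track in config$tracks) {
    prims <- c(prims, switch(
      track$type,
      snp = , features = , het =
        point_track_prims(track$data, view, width, y),
      intervals = interval_track_prims(track$data, view, width, y),
      mosaic = , ibd = {
        p <- mosaic_prims(track$data, track$strain_order, view, width, y)
        if (!is.null(track$overlay_gm))
          p <- c(p, allele_overlay_prims(track$overlay_gm,
                                         track$strain_order, view, width, y))
        p
      },
      stop("unknown track type: ", track$type)))
    y <- y + track_height(track)
  }
  if (config$format == "svg") write_svg(prims, width + 80, y + 10, path)
  else write_png(prims, width + 80, y + 10, path)
  invisible(prims)
}

fmt_num <- function(x) sub("\\.?0+$", "", sprintf("%.3f", x))

write_svg <- function(prims, width, height, path) {
  # left margin of 60 px for strain labels
  off <- 60
  lines <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
    width + 20, height))
  for (p in prims) {
    lines <- c(lines, switch(
      p$kind,
      rect = sprintf(
        '<rect x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
        fmt_num(p$x + off), fmt_num(p$y), fmt_num(p$w), fmt_num(p$h), p$fill),
      line = sprintf(
        '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="1"/>',
        fmt_num(p$x1 + off), fmt_num(p$y1), fmt_num(p$x2 + off),
        fmt_num(p$y2), p$col),
      text = sprintf(
        '<text x="%s" y="%s" font-size="%s" font-family="monospace" fill="%s" text-anchor="%s">%s</text>',
        fmt_num(p$x + off), fmt_num(p$y), fmt_num(p$size), p$col,
        if (p$x < 0) "end" else "middle", p$s)))
  }
  lines <- c(lines, "</svg>")
  con <- file(path, "wb")  # binary mode: fixed \n regardless of platform
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(NULL)
}

write_png <- function(prims, width, height, path) {
  off <- 60
  grDevices::png(path, width = width + 20, height = height)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, width + 20), ylim = c(height, 0),
                        xaxs = "i", yaxs = "i")
  for (p in prims) {
    if (p$kind == "rect")
      graphics::rect(p$x + off, p$y + p$h, p$x + off + p$w, p$y,
                     col = p$fill, border = NA)
    else if (p$kind == "line")
      graphics::segments(p$x1 + off, p$y1, p$x2 + off, p$y2, col = p$col)
    else
      graphics::text(p$x + off, p$y, p$s, cex = p$size / 12, col = p$col,
                     adj = if (p$x < 0) c(1, 0) else c(0.5, 0))
  }
  invisible(NULL)
}
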