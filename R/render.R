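#' Divergent colormap specification
#'
#' Blue-green-red divergent scheme: intense blue for strong
#' downregulation, green around zero, intense red for strong
#' upregulation. Values are clipped to [vmin, vmax] and interpolated
#' piecewise-linearly between the anchors. The default anchors are
#' vmin -> (0,0,255), 0 -> (0,255,0), vmax -> (255,0,0); alternative
#' divergent maps can be supplied as an anchor table.
#'
#' @param vmin,vmax Color range bounds (defaults -10, +10); vmin must be
#'   negative and vmax positive so the zero anchor exists.
#' @param anchors Optional data frame with columns value, r, g, b,
#'   strictly increasing in value, overriding the default three anchors.
#' @return A `gt_colormap` object.
#' @export
colormap_spec <- function(vmin = -10, vmax = 10, anchors = NULL) {
  if (vmin >= vmax) stop("vmin must be < vmax")
  if (!(vmin < 0 && vmax > 0)) stop("need vmin < 0 < vmax")
  if (is.null(anchors)) {
    anchors <- data.frame(value = c(vmin, 0, vmax),
                          r = c(0, 0, 255), g = c(0, 255, 0),
                          b = c(255, 0, 0))
  } else {
    if (!all(c("value", "r", "g", "b") %in% names(anchors)))
      stop("anchors need columns value, r, g, b")
    if (any(diff(anchors$value) <= 0))
      stop("anchor values must be strictly increasing")
  }
  structure(list(vmin = vmin, vmax = vmax, anchors = anchors),
            class = "gt_colormap")
}

#' Map values to RGB through a divergent colormap
#'
#' @param value Numeric vector of field values.
#' @param spec A [colormap_spec()].
#' @return Integer matrix, one row per value, columns r, g, b in
#'   [0, 255].
#' @export
map_color <- function(value, spec = colormap_spec()) {
  stopifnot(inherits(spec, "gt_colormap"))
  v <- pmin(pmax(value, spec$vmin), spec$vmax)
  a <- spec$anchors
  chan <- function(col)
    stats::approx(a$value, a[[col]], xout = v, rule = 2)$y
  out <- cbind(r = round(chan("r")), g = round(chan("g")),
               b = round(chan("b")))
  storage.mode(out) <- "integer"
  out
}

# Field grid (y-up) -> H x W x 3 RGB array in [0,1], row 1 = image top.
.field_rgb <- function(field, spec) {
  grid <- field$grid
  rgb <- map_color(as.vector(grid), spec) / 255
  h <- nrow(grid); w <- ncol(grid)
  arr <- array(0, c(h, w, 3))
  for (ch in 1:3) arr[, , ch] <- matrix(rgb[, ch], h, w)
  arr[h:1, , , drop = FALSE] # flip: stored y-up, image row 1 is top
}

#' Render one terrain field to PNG
#'
#' The PNG has one pixel per grid cell; the stored field is y-up, so the
#' top image row shows the top of the unit square. Output bytes are
#' deterministic for identical field and colormap.
#'
#' @param field A `gt_field`.
#' @param path Output PNG path.
#' @param spec A [colormap_spec()].
#' @return Invisibly, `path`.
#' @export
render_field <- function(field, path, spec = colormap_spec()) {
  stopifnot(inherits(field, "gt_field"))
  png::writePNG(.field_rgb(field, spec), path)
  invisible(path)
}

# --- 5x7 bitmap font (uppercase, digits, a few symbols) ---------------
# Bundled so montage labels render byte-identically everywhere.
.gt_font <- local({
  def <- list(
    "A" = c("01110","10001","10001","11111","10001","10001","10001"),
    "B" = c("11110","10001","10001","11110","10001","10001","11110"),
    "C" = c("01110","10001","10000","10000","10000","10001","01110"),
    "D" = c("11110","10001","10001","10001","10001","10001","11110"),
    "E" = c("11111","10000","10000","11110","10000","10000","11111"),
    "F" = c("11111","10000","10000","11110","10000","10000","10000"),
    "G" = c("01110","10001","10000","10111","10001","10001","01111"),
    "H" = c("10001","10001","10001","11111","10001","10001","10001"),
    "I" = c("01110","00100","00100","00100","00100","00100","01110"),
    "J" = c("00111","00010","00010","00010","00010","10010","01100"),
    "K" = c("10001","10010","10100","11000","10100","10010","10001"),
    "L" = c("10000","10000","10000","10000","10000","10000","11111"),
    "M" = c("10001","11011","10101","10101","10001","10001","10001"),
    "N" = c("10001","11001","10101","10011","10001","10001","10001"),
    "O" = c("01110","10001","10001","10001","10001","10001","01110"),
    "P" = c("11110","10001","10001","11110","10000","10000","10000"),
    "Q" = c("01110","10001","10001","10001","10101","10010","01101"),
    "R" = c("11110","10001","10001","11110","10100","10010","10001"),
    "S" = c("01111","10000","10000","01110","00001","00001","11110"),
    "T" = c("11111","00100","00100","00100","00100","00100","00100"),
    "U" = c("10001","10001","10001","10001","10001","10001","01110"),
    "V" = c("10001","10001","10001","10001","10001","01010","00100"),
    "W" = c("10001","10001","10001","10101","10101","11011","10001"),
    "X" = c("10001","01010","00100","00100","00100","01010","10001"),
    "Y" = c("10001","01010","00100","00100","00100","00100","00100"),
    "Z" = c("11111","00001","00010","00100","01000","10000","11111"),
    "0" = c("01110","10001","10011","10101","11001","10001","01110"),
    "1" = c("00100","01100","00100","00100","00100","00100","01110"),
    "2" = c("01110","10001","00001","00110","01000","10000","11111"),
    "3" = c("11110","00001","00001","01110","00001","00001","11110"),
    "4" = c("00010","00110","01010","10010","11111","00010","00010"),
    "5" = c("11111","10000","11110","00001","00001","10001","01110"),
    "6" = c("01110","10000","10000","11110","10001","10001","01110"),
    "7" = c("11111","00001","00010","00100","01000","01000","01000"),
    "8" = c("01110","10001","10001","01110","10001","10001","01110"),
    "9" = c("01110","10001","10001","01111","00001","00001","01110"),
    "-" = c("00000","00000","00000","11111","00000","00000","00000"),
    ">" = c("10000","01000","00100","00010","00100","01000","10000"),
    "." = c("00000","00000","00000","00000","00000","01100","01100"),
    "_" = c("00000","00000","00000","00000","00000","00000","11111"),
    " " = c("00000","00000","00000","00000","00000","00000","00000")
  )
  lapply(def, function(rows)
    do.call(rbind, lapply(strsplit(rows, ""), function(r) r == "1")))
})

# Paint `text` (top-left corner at row/col, 1-based) into a [0,1] RGB
# array, black pixels, integer scale.
.draw_text <- function(arr, row, col, text, scale = 1) {
  chars <- strsplit(toupper(text), "")[[1]]
  x <- col
  for (ch in chars) {
    glyph <- .gt_font[[ch]]
    if (is.null(glyph)) glyph <- .gt_font[["."]]
    for (i in 1:7) for (j in 1:5) if (glyph[i, j]) {
      rr <- row + (i - 1) * scale + seq_len(scale) - 1
      cc <- x + (j - 1) * scale + seq_len(scale) - 1
      rr <- rr[rr >= 1 & rr <= dim(arr)[1]]
      cc <- cc[cc >= 1 & cc <= dim(arr)[2]]
      if (length(rr) && length(cc)) arr[rr, cc, ] <- 0
    }
    x <- x + 6 * scale
  }
  arr
}

# Normalize one montage row input to a list of gt_field plus default
# column labels.
.montage_row <- function(x) {
  if (inherits(x, "gt_series"))
    return(list(fields = x$fields,
                labels = paste0(x$time_points, "H")))
  if (is.list(x) && length(x) > 0 && inherits(x[[1]], "gt_delta"))
    return(list(fields = lapply(x, `[[`, "field"),
                labels = vapply(x, function(d)
                  paste0(d$interval[1], ">", d$interval[2], "H"), "")))
  if (is.list(x) && length(x) > 0 && inherits(x[[1]], "gt_field"))
    return(list(fields = x, labels = rep("", length(x))))
  if (inherits(x, "gt_field"))
    return(list(fields = list(x), labels = ""))
  stop("montage rows must be gt_series, or lists of gt_delta/gt_field")
}

#' Render a condition x time (or interval) montage to PNG
#'
#' Tiles fields in a grid: one row per condition (control first, in the
#' given order), one column per time point or interval, with labels
#' drawn in white margins using a bundled bitmap font so output bytes
#' are deterministic. Each tile's pixels equal the individually rendered
#' field.
#'
#' @param rows Named list; each element is a `gt_series`, a list of
#'   `gt_delta` (delta-terrain row), or a list of `gt_field`. All tiles
#'   must share one grid shape.
#' @param path Output PNG path.
#' @param spec A [colormap_spec()].
#' @param col_labels Optional column labels overriding the defaults
#'   derived from time points / intervals.
#' @return Invisibly, `path`.
#' @export
render_montage <- function(rows, path, spec = colormap_spec(),
                           col_labels = NULL) {
  if (length(rows) == 0) stop("no rows to render")
  norm <- lapply(rows, .montage_row)
  ncols <- vapply(norm, function(r) length(r$fields), 1L)
  if (length(unique(ncols)) != 1)
    stop("all rows must have the same number of tiles")
  nc <- ncols[1]
  for (r in norm) for (f in r$fields)
    if (!identical(dim(f$grid), dim(norm[[1]]$fields[[1]]$grid)))
      stop("mismatched tile grid shapes")
  th <- nrow(norm[[1]]$fields[[1]]$grid)
  tw <- ncol(norm[[1]]$fields[[1]]$grid)
  if (is.null(col_labels)) col_labels <- norm[[1]]$labels
  row_labels <- if (!is.null(names(rows))) names(rows)
                else rep("", length(rows))
  scale <- max(1L, as.integer(round(tw / 128)))
  left <- (max(nchar(row_labels), 1) * 6 + 2) * scale
  top <- 10 * scale
  H <- top + length(norm) * th
  W <- left + nc * tw
  img <- array(1, c(H, W, 3))
  for (i in seq_along(norm)) {
    for (j in seq_len(nc)) {
      tile <- .field_rgb(norm[[i]]$fields[[j]], spec)
      img[top + (i - 1) * th + seq_len(th),
          left + (j - 1) * tw + seq_len(tw), ] <- tile
    }
    img <- .draw_text(img, top + (i - 1) * th + (th - 7 * scale) %/% 2,
                      2, row_labels[i], scale)
  }
  for (j in seq_len(nc))
    img <- .draw_text(img, 2, left + (j - 1) * tw + 2,
                      col_labels[j], scale)
  png::writePNG(img, path)
  invisible(path)
}
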