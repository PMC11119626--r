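# Rasterization of portraits, spatial maps and receptor-ligand maps.
#
# Images are plain RGB arrays (height x width x 3, values in [0, 1]) built
# pixel-by-pixel, so identical inputs give byte-identical output; writing
# to PNG goes through png::writePNG.

# One palette constant for the whole package. Conventions:
# red = overexpressed / blue = underexpressed in portraits; brown = high /
# blue = low in spatial maps; apricot / blue / green for receptor-ligand
# states.
spotsom_palette <- list(
  diverging_red_blue = c("#2166AC", "#F7F7F7", "#B2182B"),
  sequential_brown_blue = c("#2166AC", "#F5F5F5", "#8C510A"),
  rli = c(coexpressed = "#F59B5C", receptor_only = "#2166AC",
          ligand_only = "#1B7837")
)

#' Colour specification for rendering
#'
#' @param mode `"diverging_red_blue"` (portraits: red over, blue under),
#'   `"sequential_brown_blue"` (spatial maps: brown high, blue low),
#'   `"rli_triple"` or `"categorical"`.
#' @param normalization `"per_image"`, `"global"` (requires `limits`), or
#'   `"symmetric_about_zero"` (diverging mode only).
#' @param saturation_quantile quantile of `|values|` (symmetric) or values
#'   (otherwise) setting the colour-scale limit, in (0.5, 1]; default 0.99
#'   stabilizes the scale against single outlier units.
#' @param limits optional fixed `c(lo, hi)` for `normalization = "global"`.
#' @return a `color_spec` list.
#' @export
color_spec <- function(mode = c("diverging_red_blue", "sequential_brown_blue",
                                "rli_triple", "categorical"),
                       normalization = c("symmetric_about_zero", "per_image",
                                         "global"),
                       saturation_quantile = 0.99, limits = NULL) {
  mode <- match.arg(mode)
  normalization <- match.arg(normalization)
  if (normalization == "symmetric_about_zero" && mode != "diverging_red_blue")
    stop2("symmetric_about_zero is only meaningful with the diverging mode")
  if (saturation_quantile <= 0.5 || saturation_quantile > 1)
    stop2("saturation_quantile must lie in (0.5, 1]")
  structure(list(mode = mode, normalization = normalization,
                 saturation_quantile = saturation_quantile, limits = limits),
            class = "color_spec")
}

ramp_rgb <- function(colors) {
  f <- grDevices::colorRamp(colors, space = "rgb")
  function(x) f(pmin(1, pmax(0, x))) / 255
}

# Map values to [0,1] positions on the colour scale.
scale_positions <- function(values, spec) {
  if (spec$normalization == "global") {
    if (is.null(spec$limits)) stop2("normalization 'global' needs limits")
    lo <- spec$limits[[1]]; hi <- spec$limits[[2]]
  } else if (spec$normalization == "symmetric_about_zero") {
    m <- quantile(abs(values), spec$saturation_quantile, names = FALSE)
    if (m == 0) m <- 1
    lo <- -m; hi <- m
  } else {
    lo <- quantile(values, 1 - spec$saturation_quantile, names = FALSE)
    hi <- quantile(values, spec$saturation_quantile, names = FALSE)
    if (lo == hi) { lo <- lo - 0.5; hi <- hi + 0.5 }
  }
  pmin(1, pmax(0, (values - lo) / (hi - lo)))
}

#' Render an expression portrait
#'
#' @param portrait a `som_portrait`.
#' @param spec a [color_spec()] (diverging red-blue, symmetric about zero,
#'   by default).
#' @param cell_px square pixel size of each grid cell.
#' @param file optional path; when given the image is also written as PNG.
#' @return RGB array (rows x cols x 3, values in `[0, 1]`), invisibly when
#'   `file` is given.
#' @export
render_portrait <- function(portrait, spec = color_spec(), cell_px = 8L,
                            file = NULL) {
  v <- portrait$values
  if (any(!is.finite(v))) stop2("portrait contains non-finite values")
  ramp <- ramp_rgb(spotsom_palette[[if (spec$mode == "diverging_red_blue")
    "diverging_red_blue" else "sequential_brown_blue"]])
  pos <- scale_positions(as.vector(t(v)), spec)  # row-major
  rgb <- ramp(pos)
  img <- array(0, dim = c(nrow(v) * cell_px, ncol(v) * cell_px, 3))
  for (r in seq_len(nrow(v))) for (cc in seq_len(ncol(v))) {
    px <- rgb[(r - 1) * ncol(v) + cc, ]
    rows <- ((r - 1) * cell_px + 1):(r * cell_px)
    cols <- ((cc - 1) * cell_px + 1):(cc * cell_px)
    for (ch in 1:3) img[rows, cols, ch] <- px[[ch]]
  }
  finish_image(img, file)
}

finish_image <- function(img, file) {
  if (!is.null(file)) {
    png::writePNG(img, file)
    return(invisible(img))
  }
  img
}

# Common scaffolding for spot-disk images: returns pixel centres, radius
# and canvas dimensions for the in-tissue spots to draw.
spot_canvas <- function(layout, scale_factor, width) {
  lay <- layout[layout$in_tissue, , drop = FALSE]
  if (nrow(lay) == 0) stop2("layout has no in-tissue spots")
  x <- lay$pixel_x * scale_factor
  y <- lay$pixel_y * scale_factor
  # 55 um spot on a 100 um pitch: radius = 0.275 * min centre spacing
  if (nrow(lay) > 1) {
    d <- sqrt(outer(x, x, `-`)^2 + outer(y, y, `-`)^2)
    diag(d) <- Inf
    radius <- max(1.5, 0.55 * min(d) / 2)
  } else radius <- 5
  pad <- radius + 2
  list(barcode = lay$barcode,
       x = x - min(x) + pad, y = y - min(y) + pad, radius = radius,
       width = ceiling(max(x) - min(x) + 2 * pad),
       height = ceiling(max(y) - min(y) + 2 * pad))
}

draw_disks <- function(canvas, colors) {
  img <- array(1, dim = c(canvas$height, canvas$width, 3))  # white bg
  r2 <- canvas$radius^2
  for (i in seq_along(canvas$x)) {
    if (anyNA(colors[i, ])) next  # uncoloured spot (e.g. RLI state 'none')
    cx <- canvas$x[[i]]; cy <- canvas$y[[i]]
    rows <- max(1, floor(cy - canvas$radius)):min(canvas$height,
                                                  ceiling(cy + canvas$radius))
    cols <- max(1, floor(cx - canvas$radius)):min(canvas$width,
                                                  ceiling(cx + canvas$radius))
    for (py in rows) for (px in cols) {
      if ((px - cx)^2 + (py - cy)^2 <= r2) img[py, px, ] <- colors[i, ]
    }
  }
  img
}

#' Render a spatial map of per-spot values
#'
#' Draws one coloured disk per in-tissue spot at its (scaled) pixel
#' position; brown = high, blue = low by default. Spots outside the tissue
#' are omitted.
#'
#' @param values named numeric vector covering the in-tissue barcodes.
#' @param layout a [spatial_layout()].
#' @param spec a [color_spec()]; default sequential brown-blue, per-image
#'   normalization.
#' @param scale_factor multiplies the full-resolution pixel coordinates
#'   (e.g. a Space Ranger `tissue_lowres_scalef`); default 1.
#' @param file optional PNG output path.
#' @return RGB array (height x width x 3).
#' @export
render_spatial <- function(values, layout,
                           spec = color_spec("sequential_brown_blue",
                                             "per_image"),
                           scale_factor = 1, file = NULL) {
  canvas <- spot_canvas(layout, scale_factor, NULL)
  missing_bc <- setdiff(canvas$barcode, names(values))
  if (length(missing_bc) > 0)
    stop2("no value for in-tissue spot(s): %s",
          paste(utils::head(missing_bc, 5), collapse = ", "))
  v <- values[canvas$barcode]
  ramp <- ramp_rgb(spotsom_palette[[if (spec$mode == "diverging_red_blue")
    "diverging_red_blue" else "sequential_brown_blue"]])
  colors <- ramp(scale_positions(v, spec))
  finish_image(draw_disks(canvas, colors), file)
}

#' Render a receptor-ligand interaction map
#'
#' Apricot for co-expression of receptor and ligand, blue for receptor
#' only, green for ligand only, no disk for neither; colour saturation
#' scales with the call's `saturation` (1 = full hue, 0 = white).
#'
#' @param calls an `rli_calls` data frame ([classify_rli()] or
#'   [pathway_rli_map()]), covering the in-tissue spots.
#' @param layout a [spatial_layout()].
#' @param scale_factor pixel coordinate scale factor.
#' @param file optional PNG output path.
#' @return RGB array (height x width x 3).
#' @export
render_rli <- function(calls, layout, scale_factor = 1, file = NULL) {
  bad <- setdiff(unique(calls$state), rli_states)
  if (length(bad) > 0)
    stop2("unknown receptor-ligand state: %s", paste(bad, collapse = ", "))
  canvas <- spot_canvas(layout, scale_factor, NULL)
  idx <- match(canvas$barcode, calls$barcode)
  if (anyNA(idx))
    stop2("no call for in-tissue spot(s): %s",
          paste(utils::head(canvas$barcode[is.na(idx)], 5), collapse = ", "))
  state <- calls$state[idx]
  sat <- calls$saturation[idx]
  colors <- matrix(NA_real_, length(state), 3)
  for (s in names(spotsom_palette$rli)) {
    hue <- col2rgb(spotsom_palette$rli[[s]])[, 1] / 255
    pick <- state == s
    if (!any(pick)) next
    # saturation blends from white (0) to the full hue (1)
    colors[pick, ] <- t(vapply(sat[pick], function(a) 1 + a * (hue - 1),
                               numeric(3)))
  }
  finish_image(draw_disks(canvas, colors), file)
}
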