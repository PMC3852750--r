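#' Rendering similarity maps
#'
#' Normalized atom weights plus 2D depiction coordinates become a
#' topography-like map: an isotropic bivariate Gaussian is centered at
#' every atom position, its *peak* scaled by the atom's weight (the
#' variance is the same for all atoms), the summed field is colored on a
#' diverging scale — pink for negative, gray for no change, green for
#' positive — and the molecular skeleton plus contour lines are drawn on
#' top. The color scale is always symmetric about zero (limits are
#' plus/minus the maximum absolute weight, never data min/max), so gray
#' means exactly "no change" regardless of the weight distribution.
#'
#' Images are composed directly into a pixel raster and written with
#' \pkg{png} (no graphics device), so a PNG is byte-identical across runs
#' for fixed inputs and style.
#'
#' @name rendering
NULL

#' Style options for a similarity map
#'
#' @param sigma Gaussian width in depiction units; `NULL` (default) means
#'   0.3 x the median bond length of the rendered molecule, tying blob
#'   size to depiction scale
#' @param grid_resolution grid points per axis (also the image size in
#'   pixels), at least 50
#' @param n_contours number of evenly spaced contour levels
#' @param colors length-3 vector: negative, zero and positive endpoint
#'   colors of the diverging scale
#' @param padding extra margin as a fraction of the molecule bounding box
#' @param format `"png"` or `"svg"`
#' @export
map_style <- function(sigma = NULL, grid_resolution = 250L, n_contours = 10L,
                      colors = c(neg = "#E9A3C9", mid = "#F2F2F2",
                                 pos = "#A1D76A"),
                      padding = 0.1, format = c("png", "svg")) {
  format <- match.arg(format)
  if (!is.null(sigma) && sigma <= 0) {
    abort("sigma must be positive", "simmapr_value_error")
  }
  if (grid_resolution < 50) {
    abort("grid_resolution must be at least 50", "simmapr_value_error")
  }
  structure(list(sigma = sigma, grid_resolution = as.integer(grid_resolution),
                 n_contours = as.integer(n_contours),
                 colors = colors, padding = padding, format = format),
            class = "map_style")
}

#' @noRd
resolve_sigma <- function(style, mol) {
  if (!is.null(style$sigma)) {
    return(style$sigma)
  }
  if (!is.null(mol) && nrow(mol$bonds) > 0 && !is.null(mol$coords)) {
    b <- mol$bonds
    len <- sqrt(rowSums((mol$coords[b$a, , drop = FALSE] -
                         mol$coords[b$b, , drop = FALSE])^2))
    return(0.3 * stats::median(len))
  }
  0.45  # 0.3 x the standard depiction bond length
}

#' Gaussian weight field over a grid
#'
#' `field(x, y) = sum_i w_i * exp(-((x - x_i)^2 + (y - y_i)^2) / (2 sigma^2))`
#' — peak-scaled (amplitude = weight), equal isotropic sigma for every
#' atom, evaluated on a regular grid covering all atoms plus padding.
#'
#' @param coords n x 2 matrix of atom positions
#' @param weights length-n numeric weights (normally the normalized ones)
#' @param style a [map_style()]; `style$sigma` may be `NULL`, in which
#'   case the generic depiction default is used
#' @return a `scalar_field`: list with grid vectors `x`, `y` and value
#'   matrix `z` (dim `length(x)` x `length(y)`)
#' @export
weight_field <- function(coords, weights, style = map_style()) {
  coords <- as.matrix(coords)
  if (nrow(coords) != length(weights) || nrow(coords) < 1) {
    abort("coords and weights must have the same positive length",
          "simmapr_value_error")
  }
  sigma <- if (is.null(style$sigma)) 0.45 else style$sigma
  rng_x <- range(coords[, 1])
  rng_y <- range(coords[, 2])
  span <- max(diff(rng_x), diff(rng_y), 1e-6)
  pad <- style$padding * span + 2 * sigma
  # square extents centered on the bounding box keep the aspect ratio true
  cx <- mean(rng_x)
  cy <- mean(rng_y)
  half <- span / 2 + pad
  n <- style$grid_resolution
  x <- seq(cx - half, cx + half, length.out = n)
  y <- seq(cy - half, cy + half, length.out = n)
  z <- matrix(0, n, n)
  inv2s2 <- 1 / (2 * sigma^2)
  for (i in seq_along(weights)) {
    if (weights[i] == 0) next
    gx <- exp(-(x - coords[i, 1])^2 * inv2s2)
    gy <- exp(-(y - coords[i, 2])^2 * inv2s2)
    z <- z + weights[i] * outer(gx, gy)
  }
  structure(list(x = x, y = y, z = z, sigma = sigma),
            class = "scalar_field")
}

#' Map field values to diverging colors
#'
#' Values are clipped to `[-vmax, vmax]` and interpolated through the
#' style's negative/zero/positive colors; 0 always lands exactly on the
#' neutral midpoint color.
#'
#' @param values numeric vector (or matrix) of field values
#' @param style a [map_style()]
#' @param vmax symmetric scale limit; defaults to 1 (normalized weights)
#' @return character vector of hex colors, same length as `values`
#' @export
weight_colors <- function(values, style = map_style(), vmax = 1) {
  if (vmax <= 0) {
    vmax <- 1
  }
  v <- pmin(pmax(as.numeric(values), -vmax), vmax) / vmax
  ramp <- grDevices::colorRamp(style$colors, space = "Lab")
  rgb <- ramp((v + 1) / 2)
  grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255)
}

#' @noRd
field_raster <- function(field, style, vmax) {
  n <- length(field$x)
  cols <- weight_colors(field$z, style, vmax)
  rgb <- grDevices::col2rgb(cols) / 255
  img <- array(0, c(n, n, 3))
  # z[ix, iy] with y increasing; image rows run top-to-bottom
  for (ch in 1:3) {
    img[, , ch] <- t(matrix(rgb[ch, ], n, n))[n:1, ]
  }
  img
}

#' @noRd
px_of <- function(field, xy) {
  n <- length(field$x)
  px <- 1 + (xy[, 1] - field$x[1]) / (field$x[n] - field$x[1]) * (n - 1)
  py <- n - (xy[, 2] - field$y[1]) / (field$y[n] - field$y[1]) * (n - 1)
  cbind(px, py)
}

#' @noRd
draw_segment <- function(img, x0, y0, x1, y1, col, width = 1) {
  n <- dim(img)[1]
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  steps <- max(2L, ceiling(len * 2))
  ts <- seq(0, 1, length.out = steps)
  xs <- round(x0 + ts * (x1 - x0))
  ys <- round(y0 + ts * (y1 - y0))
  r <- floor(width / 2)
  for (k in seq_len(steps)) {
    for (dx in -r:r) {
      for (dy in -r:r) {
        xi <- xs[k] + dx
        yi <- ys[k] + dy
        if (xi >= 1 && xi <= n && yi >= 1 && yi <= n) {
          img[yi, xi, ] <- col
        }
      }
    }
  }
  img
}

#' @noRd
contour_levels <- function(vmax, n_contours) {
  lv <- seq(-vmax, vmax, length.out = n_contours + 2)
  lv[c(-1, -(n_contours + 2))]
}

#' Render a similarity map to an image file
#'
#' Composes the Gaussian weight field (diverging colors, symmetric about
#' zero), `n_contours` evenly spaced contour lines and the molecular
#' skeleton, and writes PNG (byte-deterministic) or SVG (vector bonds over
#' an embedded field layer).
#'
#' @param mol a `simmapr_mol`; 2D coordinates are computed if absent
#' @param weights an `atom_weights` object or a numeric vector of
#'   normalized weights
#' @param style a [map_style()]
#' @param out_path output file path (extension does not override
#'   `style$format`)
#' @return (invisibly) `out_path`
#' @export
render_map <- function(mol, weights, style = map_style(), out_path) {
  stopifnot(inherits(mol, "simmapr_mol"))
  w <- if (inherits(weights, "atom_weights")) weights$normalized
       else as.numeric(weights)
  if (length(w) != n_atoms(mol)) {
    abort("one weight per heavy atom is required", "simmapr_value_error")
  }
  mol <- ensure_2d_coords(mol)
  style$sigma <- resolve_sigma(style, mol)
  field <- weight_field(mol$coords, w, style)
  vmax <- max(abs(w), 0)
  img <- field_raster(field, style, if (vmax > 0) vmax else 1)

  bond_col <- rep(0.15, 3)
  contour_col <- rep(0.55, 3)
  if (vmax > 0 && style$n_contours > 0) {
    for (lv in contour_levels(vmax, style$n_contours)) {
      cl <- grDevices::contourLines(field$x, field$y, field$z, levels = lv)
      for (seg in cl) {
        p <- px_of(field, cbind(seg$x, seg$y))
        for (k in seq_len(nrow(p) - 1)) {
          img <- draw_segment(img, p[k, 1], p[k, 2], p[k + 1, 1], p[k + 1, 2],
                              contour_col, width = 1)
        }
      }
    }
  }
  apix <- px_of(field, mol$coords)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a[k]
      b <- mol$bonds$b[k]
      img <- draw_segment(img, apix[a, 1], apix[a, 2], apix[b, 1], apix[b, 2],
                          bond_col, width = 2)
    }
  } else {
    img <- draw_segment(img, apix[1, 1], apix[1, 2], apix[1, 1], apix[1, 2],
                        bond_col, width = 3)
  }

  ok <- tryCatch({
    if (style$format == "png") {
      png::writePNG(img, out_path)
    } else {
      write_svg_map(img, mol, apix, out_path)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    abort(paste0("failed to write image: ", conditionMessage(ok)),
          "simmapr_render_error")
  }
  invisible(out_path)
}

#' @noRd
write_svg_map <- function(img, mol, apix, out_path) {
  n <- dim(img)[1]
  png_tmp <- tempfile(fileext = ".png")
  on.exit(unlink(png_tmp), add = TRUE)
  png::writePNG(img, png_tmp)
  b64 <- jsonlite::base64_enc(readBin(png_tmp, "raw",
                                      file.info(png_tmp)$size))
  b64 <- gsub("[\r\n]", "", b64)
  lines <- c(
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                   'width="%d" height="%d" viewBox="0 0 %d %d">'),
            n, n, n, n),
    sprintf(paste0('<image x="0" y="0" width="%d" height="%d" ',
                   'href="data:image/png;base64,%s"/>'), n, n, b64),
    if (nrow(mol$bonds)) {
      vapply(seq_len(nrow(mol$bonds)), function(k) {
        a <- mol$bonds$a[k]
        b <- mol$bonds$b[k]
        sprintf(paste0('<line x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" ',
                       'stroke="#262626" stroke-width="2"/>'),
                apix[a, 1], apix[a, 2], apix[b, 1], apix[b, 2])
      }, character(1))
    },
    "</svg>"
  )
  writeLines(lines, out_path)
  invisible(out_path)
}
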