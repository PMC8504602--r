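#' Planar dose
#'
#' A 2D dose map on a regular in-plane grid. `origin_mm` is the center of the
#' first pixel; `plane_depth_mm` is the plane's depth below the detector
#' surface (NA for composite planes summed over several depths).
#'
#' @param origin_mm,spacing_mm Length-2 numeric vectors, mm.
#' @param values Matrix of doses, Gy, indexed `[ix, iy]`.
#' @param plane_depth_mm Depth below the detector surface, mm.
#' @return Object of class `planar_dose`.
#' @export
planar_dose <- function(origin_mm, spacing_mm, values,
                        plane_depth_mm = NA_real_) {
  stopifnot(length(origin_mm) == 2, length(spacing_mm) == 2,
            all(spacing_mm > 0), is.matrix(values))
  if (any(values < 0, na.rm = TRUE)) stop("planar dose must be >= 0")
  structure(list(origin_mm = as.numeric(origin_mm),
                 spacing_mm = as.numeric(spacing_mm),
                 dim = dim(values), values = values,
                 plane_depth_mm = plane_depth_mm),
            class = "planar_dose")
}

#' @export
print.planar_dose <- function(x, ...) {
  cat(sprintf(
    "<planar_dose> %d x %d pixels at %g x %g mm, depth %s mm, max %.4g Gy\n",
    x$dim[1], x$dim[2], x$spacing_mm[1], x$spacing_mm[2],
    format(x$plane_depth_mm), max(x$values, na.rm = TRUE)))
  invisible(x)
}

planar_axis <- function(p, axis) {
  p$origin_mm[axis] + (seq_len(p$dim[axis]) - 1) * p$spacing_mm[axis]
}

#' Chamber-grid measurement
#'
#' One dose value per populated chamber of a [chamber_layout()], aligned with
#' the rows of `layout$positions`.
#'
#' @param layout A [chamber_layout()].
#' @param values Numeric vector, Gy.
#' @return Object of class `chamber_grid`.
#' @export
chamber_grid <- function(layout, values) {
  stopifnot(inherits(layout, "chamber_layout"))
  if (length(values) != nrow(layout$positions))
    stop("need exactly one value per populated chamber")
  structure(list(layout = layout, values = as.numeric(values)),
            class = "chamber_grid")
}

#' @export
print.chamber_grid <- function(x, ...) {
  cat(sprintf("<chamber_grid> %d chambers, max %.4g Gy\n",
              length(x$values), max(x$values)))
  invisible(x)
}

#' Trilinear sampling of a 3D dose
#'
#' @param dose A `dose3d`.
#' @param points n x 3 matrix of world points, mm (must lie inside the grid).
#' @return Numeric vector of interpolated doses.
#' @export
trilinear_sample <- function(dose, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  n <- nrow(points)
  fi <- (points[, 1] - dose$origin_mm[1]) / dose$spacing_mm[1]
  fj <- (points[, 2] - dose$origin_mm[2]) / dose$spacing_mm[2]
  fk <- (points[, 3] - dose$origin_mm[3]) / dose$spacing_mm[3]
  if (any(fi < -1e-9 | fi > dose$dim[1] - 1 + 1e-9 |
            fj < -1e-9 | fj > dose$dim[2] - 1 + 1e-9 |
            fk < -1e-9 | fk > dose$dim[3] - 1 + 1e-9))
    stop("sampling point outside the dose grid")
  i0 <- pmin(pmax(floor(fi), 0), dose$dim[1] - 2); wi <- fi - i0
  j0 <- pmin(pmax(floor(fj), 0), dose$dim[2] - 2); wj <- fj - j0
  k0 <- pmin(pmax(floor(fk), 0), dose$dim[3] - 2); wk <- fk - k0
  at <- function(di, dj, dk)
    dose$dose[cbind(i0 + di + 1, j0 + dj + 1, k0 + dk + 1)]
  v <- numeric(n)
  for (dk in 0:1) for (dj in 0:1) for (di in 0:1) {
    w <- (if (di) wi else 1 - wi) * (if (dj) wj else 1 - wj) *
      (if (dk) wk else 1 - wk)
    v <- v + w * at(di, dj, dk)
  }
  v
}

#' Extract a planar dose at a stated depth
#'
#' Horizontal plane at `depth_mm` below the detector surface, sampled from
#' the 3D dose by trilinear interpolation (the in-plane sampling positions
#' coincide with the dose-grid pixels, so the interpolation is linear along
#' depth); a depth on a grid plane returns that slice exactly.
#'
#' @param dose A `dose3d` carrying `detector_surface_z_mm`.
#' @param depth_mm Depth below the detector surface, mm (must lie inside the
#'   grid's z extent).
#' @return A [planar_dose()].
#' @export
extract_planar <- function(dose, depth_mm) {
  z <- depth_mm + dose$detector_surface_z_mm
  zc <- dose$origin_mm[3] + (seq_len(dose$dim[3]) - 1) * dose$spacing_mm[3]
  if (z < zc[1] - 1e-9 || z > zc[length(zc)] + 1e-9)
    stop(sprintf("depth %.2f mm (world z %.2f) outside the dose grid z span [%.2f, %.2f] mm",
                 depth_mm, z, zc[1], zc[length(zc)]))
  fk <- (z - zc[1]) / dose$spacing_mm[3]
  k0 <- min(max(floor(fk), 0), dose$dim[3] - 2)
  w <- fk - k0
  vals <- (1 - w) * dose$dose[, , k0 + 1] + w * dose$dose[, , k0 + 2]
  planar_dose(dose$origin_mm[1:2], dose$spacing_mm[1:2], vals,
              plane_depth_mm = depth_mm)
}

#' Bilinear sampling of a planar dose
#'
#' @param planar A [planar_dose()].
#' @param x,y World coordinates, mm.
#' @param na_outside Return NA outside the extent instead of erroring.
#' @return Numeric vector of interpolated values.
#' @export
bilinear_sample <- function(planar, x, y, na_outside = FALSE) {
  fi <- (x - planar$origin_mm[1]) / planar$spacing_mm[1]
  fj <- (y - planar$origin_mm[2]) / planar$spacing_mm[2]
  out <- fi < -1e-9 | fi > planar$dim[1] - 1 + 1e-9 |
    fj < -1e-9 | fj > planar$dim[2] - 1 + 1e-9
  if (any(out) && !na_outside)
    stop("sampling point(s) outside the planar extent: ",
         paste(sprintf("(%.2f, %.2f)", x[out], y[out]), collapse = " "))
  i0 <- pmin(pmax(floor(fi), 0), planar$dim[1] - 2); wi <- fi - i0
  j0 <- pmin(pmax(floor(fj), 0), planar$dim[2] - 2); wj <- fj - j0
  v <- (1 - wi) * (1 - wj) * planar$values[cbind(i0 + 1, j0 + 1)] +
    wi * (1 - wj) * planar$values[cbind(i0 + 2, j0 + 1)] +
    (1 - wi) * wj * planar$values[cbind(i0 + 1, j0 + 2)] +
    wi * wj * planar$values[cbind(i0 + 2, j0 + 2)]
  v[out] <- NA_real_
  v
}

#' Sample a planar dose at the chamber centers
#'
#' Bilinear interpolation of the planar values at every populated chamber
#' position; chambers outside the planar extent are an error that lists the
#' offenders.
#'
#' @param planar A [planar_dose()].
#' @param layout A [chamber_layout()].
#' @return A [chamber_grid()].
#' @export
sample_at_chambers <- function(planar, layout) {
  p <- layout$positions
  chamber_grid(layout, bilinear_sample(planar, p$x_mm, p$y_mm))
}

#' Resample a chamber grid onto a fine planar grid
#'
#' Bilinear interpolation of the chamber lattice values onto a regular grid
#' (default 1 mm) covering the populated extent; no extrapolation beyond the
#' outer chambers, and pixels whose enclosing lattice cell touches an
#' unpopulated position are NA.
#'
#' @param meas A [chamber_grid()].
#' @param target_spacing_mm Output pixel size, mm (> 0).
#' @return A [planar_dose()] (NAs where the lattice is unpopulated).
#' @export
resample_chambers_to_grid <- function(meas, target_spacing_mm = 1.0) {
  stopifnot(inherits(meas, "chamber_grid"))
  if (target_spacing_mm <= 0) stop("target spacing must be > 0")
  p <- meas$layout$positions
  xs <- sort(unique(p$x_mm)); ys <- sort(unique(p$y_mm))
  if (length(xs) < 2 || length(ys) < 2)
    stop("need at least a 2 x 2 populated lattice to resample")
  lat <- matrix(NA_real_, length(xs), length(ys))
  lat[cbind(match(p$x_mm, xs), match(p$y_mm, ys))] <- meas$values
  gx <- seq(xs[1], xs[length(xs)], by = target_spacing_mm)
  gy <- seq(ys[1], ys[length(ys)], by = target_spacing_mm)
  ix <- findInterval(gx, xs, rightmost.closed = TRUE)
  iy <- findInterval(gy, ys, rightmost.closed = TRUE)
  ix <- pmin(ix, length(xs) - 1); iy <- pmin(iy, length(ys) - 1)
  wx <- (gx - xs[ix]) / (xs[ix + 1] - xs[ix])
  wy <- (gy - ys[iy]) / (ys[iy + 1] - ys[iy])
  v00 <- lat[ix, iy, drop = FALSE]; v10 <- lat[ix + 1, iy, drop = FALSE]
  v01 <- lat[ix, iy + 1, drop = FALSE]; v11 <- lat[ix + 1, iy + 1, drop = FALSE]
  WX <- matrix(wx, length(gx), length(gy))
  WY <- matrix(wy, length(gx), length(gy), byrow = TRUE)
  vals <- (1 - WX) * (1 - WY) * v00 + WX * (1 - WY) * v10 +
    (1 - WX) * WY * v01 + WX * WY * v11
  planar_dose(c(gx[1], gy[1]), rep(target_spacing_mm, 2), vals,
              plane_depth_mm = meas$layout$oemp_depth_mm)
}

#' Detector-response convolution
#'
#' Isotropic 2D Gaussian smoothing of a calculated planar dose, modelling the
#' volume-averaging response of the finite chamber cross-section. Separable
#' direct convolution with a kernel truncated at 4 sigma and edge-replicated
#' borders: a constant field is unchanged, total dose is conserved away from
#' the borders, and `sigma_mm = 0` is the identity.
#'
#' @param planar A [planar_dose()].
#' @param sigma_mm Gaussian sigma, mm (>= 0).
#' @return A [planar_dose()].
#' @export
convolve_response <- function(planar, sigma_mm) {
  stopifnot(inherits(planar, "planar_dose"), sigma_mm >= 0)
  if (sigma_mm == 0) return(planar)
  conv1 <- function(mat, h) {
    r <- as.integer(ceiling(4 * sigma_mm / h))
    k <- exp(-((-r:r) * h)^2 / (2 * sigma_mm^2))
    k <- k / sum(k)
    n <- nrow(mat)
    pad <- rbind(mat[rep(1, r), , drop = FALSE], mat,
                 mat[rep(n, r), , drop = FALSE])
    out <- matrix(0, n, ncol(mat))
    for (s in seq_along(k))
      out <- out + k[s] * pad[s:(s + n - 1), , drop = FALSE]
    out
  }
  v <- conv1(planar$values, planar$spacing_mm[1])
  v <- t(conv1(t(v), planar$spacing_mm[2]))
  planar_dose(planar$origin_mm, planar$spacing_mm, v, planar$plane_depth_mm)
}

#' Pixel-wise percent-error map
#'
#' `|ref - test| / max(ref) * 100` per pixel (global normalization), plus its
#' average, optionally restricted to the region at or above a percentage of
#' the reference maximum. Accepts two planar doses on the same grid or two
#' chamber grids on the same layout.
#'
#' @param ref,test Same-domain [planar_dose()]s or [chamber_grid()]s.
#' @param threshold_pct If non-NULL, average only where
#'   `ref >= threshold_pct/100 * max(ref)`.
#' @return List with `map`, `average_pct` and the logical `mask` used.
#' @export
percent_error_map <- function(ref, test, threshold_pct = NULL) {
  if (inherits(ref, "chamber_grid")) {
    stopifnot(inherits(test, "chamber_grid"),
              isTRUE(all.equal(ref$layout$positions[, c("x_mm", "y_mm")],
                               test$layout$positions[, c("x_mm", "y_mm")])))
    r <- ref$values; tv <- test$values
  } else {
    stopifnot(inherits(ref, "planar_dose"), inherits(test, "planar_dose"),
              all(ref$dim == test$dim),
              isTRUE(all.equal(ref$origin_mm, test$origin_mm)),
              isTRUE(all.equal(ref$spacing_mm, test$spacing_mm)))
    r <- ref$values; tv <- test$values
  }
  mx <- max(r, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0)
    stop("all-zero reference: percent error undefined")
  map <- abs(r - tv) / mx * 100
  mask <- if (is.null(threshold_pct)) !is.na(map)
  else !is.na(r) & r >= threshold_pct / 100 * mx & !is.na(map)
  list(map = map, average_pct = mean(map[mask]), mask = mask)
}

#' Extract a 1D dose profile
#'
#' Dose along a line parallel to the x or y axis, sampled at the planar
#' resolution; used for reports and penumbra/displacement diagnostics.
#'
#' @param planar A [planar_dose()].
#' @param axis `"x"` or `"y"`: direction along which the profile runs.
#' @param through_mm Coordinate of the fixed (other) axis, mm.
#' @return Data frame with `pos_mm` and `dose`.
#' @export
extract_profile <- function(planar, axis = c("x", "y"), through_mm = 0) {
  axis <- match.arg(axis)
  if (axis == "x") {
    pos <- planar_axis(planar, 1)
    dose <- bilinear_sample(planar, pos, rep(through_mm, length(pos)))
  } else {
    pos <- planar_axis(planar, 2)
    dose <- bilinear_sample(planar, rep(through_mm, length(pos)), pos)
  }
  data.frame(pos_mm = pos, dose = dose)
}

# ---- delimited-text I/O -----------------------------------------------------

# dialect: optional '#'-prefixed metadata lines, then a tab-separated table
# whose first row holds x coordinates (mm), first column y coordinates (mm),
# and cells dose in Gy at 6 significant digits; empty lattice sites are "NA".
.write_grid_tsv <- function(path, xs, ys, values_xy, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, format(meta[[nm]])), con)
  writeLines(paste(c("", format(signif(xs, 8), trim = TRUE)),
                   collapse = "\t"), con)
  for (j in seq_along(ys)) {
    row <- signif(values_xy[, j], 6)
    writeLines(paste(c(format(signif(ys[j], 8), trim = TRUE),
                       ifelse(is.na(row), "NA",
                              format(row, digits = 6, trim = TRUE))),
                     collapse = "\t"), con)
  }
  invisible(path)
}

.read_grid_tsv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub(":.*$", "", kv)
    meta[[trimws(key)]] <- trimws(sub("^[^:]*:", "", kv))
  }
  body <- lines[!grepl("^#", lines)]
  header <- strsplit(body[1], "\t")[[1]]
  xs <- as.numeric(header[-1])
  rows <- strsplit(body[-1], "\t")
  ys <- vapply(rows, function(r) as.numeric(r[1]), numeric(1))
  vals <- t(vapply(rows, function(r)
    suppressWarnings(as.numeric(r[-1])), numeric(length(xs))))
  list(xs = xs, ys = ys, values_xy = t(vals), meta = meta)
}

#' Read / write a chamber-grid file
#'
#' UTF-8 tab-separated text: first row x coordinates (mm), first column y
#' coordinates (mm), cells dose in Gy at 6 significant digits, unpopulated
#' lattice sites written as `NA`. Metadata lines prefixed with `#` precede
#' the table.
#'
#' @param path File path.
#' @return `read_chamber_grid` returns a [chamber_grid()] whose layout is
#'   reconstructed from the lattice; `write_chamber_grid` returns `path`
#'   invisibly.
#' @export
read_chamber_grid <- function(path) {
  g <- .read_grid_tsv(path)
  pop <- !is.na(g$values_xy)
  pitch <- stats::median(diff(g$xs))
  pos <- which(pop, arr.ind = TRUE)
  positions <- data.frame(row = pos[, 2], col = pos[, 1],
                          x_mm = g$xs[pos[, 1]], y_mm = g$ys[pos[, 2]])
  positions <- positions[order(positions$col, positions$row), ]
  rownames(positions) <- NULL
  lay <- chamber_layout(pitch_mm = pitch, n_rows = length(g$ys),
                        n_cols = length(g$xs), unpopulated = NULL)
  lay$positions <- positions
  oemp <- g$meta[["oemp_depth_mm"]]
  if (!is.null(oemp)) lay$oemp_depth_mm <- as.numeric(oemp)
  vals <- g$values_xy[cbind(match(positions$x_mm, g$xs),
                            match(positions$y_mm, g$ys))]
  chamber_grid(lay, vals)
}

#' @param meas A [chamber_grid()].
#' @rdname read_chamber_grid
#' @export
write_chamber_grid <- function(meas, path) {
  stopifnot(inherits(meas, "chamber_grid"))
  p <- meas$layout$positions
  xs <- sort(unique(p$x_mm)); ys <- sort(unique(p$y_mm))
  m <- matrix(NA_real_, length(xs), length(ys))
  m[cbind(match(p$x_mm, xs), match(p$y_mm, ys))] <- meas$values
  .write_grid_tsv(path, xs, ys, m,
                  meta = list(units = "Gy", pitch_mm = meas$layout$pitch_mm,
                              oemp_depth_mm = meas$layout$oemp_depth_mm))
}

#' Read / write a planar-dose file
#'
#' Same dialect as [write_chamber_grid()] at the planar grid's pitch, with
#' `spacing_mm` and `plane_depth_mm` carried as metadata.
#'
#' @param path File path.
#' @return `read_planar_dose` returns a [planar_dose()]; `write_planar_dose`
#'   returns `path` invisibly.
#' @export
read_planar_dose <- function(path) {
  g <- .read_grid_tsv(path)
  depth <- g$meta[["plane_depth_mm"]]
  planar_dose(c(g$xs[1], g$ys[1]),
              c(g$xs[2] - g$xs[1], g$ys[2] - g$ys[1]),
              g$values_xy,
              plane_depth_mm = if (is.null(depth)) NA_real_
              else as.numeric(depth))
}

#' @param planar A [planar_dose()].
#' @rdname read_planar_dose
#' @export
write_planar_dose <- function(planar, path) {
  stopifnot(inherits(planar, "planar_dose"))
  .write_grid_tsv(path, planar_axis(planar, 1), planar_axis(planar, 2),
                  planar$values,
                  meta = list(units = "Gy",
                              spacing_mm = paste(planar$spacing_mm,
                                                 collapse = " "),
                              plane_depth_mm = planar$plane_depth_mm))
}
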