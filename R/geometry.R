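#' Detector chamber layout
#'
#' Describes the lattice of pixel ionization chambers of a 2D array: a regular
#' `n_rows` by `n_cols` grid with the stated center-to-center pitch, centered
#' on the beam axis, minus a set of unpopulated grid positions. The default is
#' a 32 x 32 grid at 7.62 mm pitch with the four extreme corners unpopulated,
#' giving 1020 chambers over a 24.4 cm square, and an effective point of
#' measurement 3.5 mm below the detector surface.
#'
#' @param pitch_mm Center-to-center chamber distance in mm.
#' @param n_rows,n_cols Lattice dimensions.
#' @param unpopulated `"corners"` (default), `NULL` for a fully populated grid,
#'   or a two-column matrix/data.frame of (row, col) positions left empty.
#' @param oemp_depth_mm Depth of the effective point of measurement below the
#'   detector surface, mm.
#' @param chamber_diameter_mm,chamber_height_mm Single-chamber dimensions, mm.
#' @return An object of class `chamber_layout` with a `positions` data frame
#'   (columns `row`, `col`, `x_mm`, `y_mm`) holding one populated chamber
#'   center per row.
#' @export
chamber_layout <- function(pitch_mm = 7.62, n_rows = 32L, n_cols = 32L,
                           unpopulated = "corners", oemp_depth_mm = 3.5,
                           chamber_diameter_mm = 4.5,
                           chamber_height_mm = 5.0) {
  if (!is.numeric(pitch_mm) || pitch_mm <= 0)
    stop("invalid layout spec: pitch_mm must be > 0")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows <= 0L || n_cols <= 0L)
    stop("invalid layout spec: n_rows and n_cols must be positive")
  if (identical(unpopulated, "corners")) {
    unpopulated <- cbind(row = c(1L, 1L, n_rows, n_rows),
                         col = c(1L, n_cols, 1L, n_cols))
  } else if (is.null(unpopulated)) {
    unpopulated <- matrix(integer(0), ncol = 2,
                          dimnames = list(NULL, c("row", "col")))
  } else {
    unpopulated <- as.matrix(unpopulated)
    storage.mode(unpopulated) <- "integer"
    colnames(unpopulated) <- c("row", "col")
  }
  if (nrow(unpopulated) > n_rows * n_cols)
    stop("invalid layout spec: more unpopulated positions than grid cells")
  grid <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols))
  drop <- paste(unpopulated[, 1], unpopulated[, 2]) # nolint
  keep <- !(paste(grid$row, grid$col) %in% drop)
  pos <- grid[keep, , drop = FALSE]
  pos$x_mm <- (pos$col - (n_cols + 1) / 2) * pitch_mm
  pos$y_mm <- (pos$row - (n_rows + 1) / 2) * pitch_mm
  rownames(pos) <- NULL
  structure(list(
    pitch_mm = pitch_mm, n_rows = n_rows, n_cols = n_cols,
    active_side_mm = n_cols * pitch_mm,
    unpopulated = unpopulated, positions = pos,
    oemp_depth_mm = oemp_depth_mm,
    chamber_diameter_mm = chamber_diameter_mm,
    chamber_height_mm = chamber_height_mm
  ), class = "chamber_layout")
}

#' @export
print.chamber_layout <- function(x, ...) {
  cat(sprintf("<chamber_layout> %d x %d grid, pitch %.2f mm, %d chambers\n",
              x$n_rows, x$n_cols, x$pitch_mm, nrow(x$positions)))
  invisible(x)
}

#' Restrict a chamber layout to a rectangular region
#'
#' Keeps only chambers whose centers lie inside the given limits. Used for
#' desk-scale runs where the dose grid does not span the full detector.
#'
#' @param layout A [chamber_layout()].
#' @param xlim,ylim Length-2 numeric limits in mm (inclusive).
#' @return A `chamber_layout` whose `positions` are the retained subset.
#' @export
subset_chambers <- function(layout, xlim, ylim = xlim) {
  stopifnot(inherits(layout, "chamber_layout"))
  p <- layout$positions
  keep <- p$x_mm >= xlim[1] & p$x_mm <= xlim[2] &
    p$y_mm >= ylim[1] & p$y_mm <= ylim[2]
  if (!any(keep)) stop("no chambers inside the requested region")
  layout$positions <- p[keep, , drop = FALSE]
  rownames(layout$positions) <- NULL
  layout
}

#' Detector stack geometry
#'
#' Depth structure of the array, in mm below the detector surface: an absorber
#' slab, the air-chamber layer containing the effective point of measurement,
#' a thin anode layer whose effective density is the model parameter rho, and
#' internal backscatter material. All parts except the anode are modeled as
#' water-equivalent.
#'
#' @param absorber_thickness_mm Top absorber thickness.
#' @param chamber_layer_mm Depth span `c(top, bottom)` of the chamber layer.
#' @param anode_top_mm Depth of the anode layer's upper face.
#' @param anode_thickness_mm Anode layer thickness (0.75 mm).
#' @param backscatter_thickness_mm Internal backscatter below the anode.
#' @param body_density Density of the water-equivalent body, g/cm^3.
#' @param anode_density Placeholder anode density until calibrated, g/cm^3.
#' @return An object of class `detector_stack`.
#' @export
detector_stack <- function(absorber_thickness_mm = 3,
                           chamber_layer_mm = c(3, 8),
                           anode_top_mm = 8,
                           anode_thickness_mm = 0.75,
                           backscatter_thickness_mm = 35,
                           body_density = 1.0,
                           anode_density = 1.0) {
  stopifnot(absorber_thickness_mm > 0, anode_thickness_mm > 0,
            backscatter_thickness_mm > 0, body_density > 0,
            chamber_layer_mm[1] < chamber_layer_mm[2])
  total <- anode_top_mm + anode_thickness_mm + backscatter_thickness_mm
  if (total <= absorber_thickness_mm + backscatter_thickness_mm)
    stop("detector stack thinner than its absorber plus backscatter")
  structure(list(
    absorber_thickness_mm = absorber_thickness_mm,
    chamber_layer_mm = chamber_layer_mm,
    anode_top_mm = anode_top_mm,
    anode_thickness_mm = anode_thickness_mm,
    backscatter_thickness_mm = backscatter_thickness_mm,
    body_density = body_density,
    anode_density = anode_density,
    total_thickness_mm = total
  ), class = "detector_stack")
}

#' Single beam of a plan
#'
#' A divergent beam with IEC 61217 gantry convention: at 0 degrees the source
#' is vertically above the isocenter; the angle increases clockwise as seen
#' from the couch foot, and the rotation axis is the detector y axis. The
#' rectangular aperture is stated at the isocenter plane; its x side is the
#' MLC-motion direction.
#'
#' @param gantry_deg Gantry angle; normalized into `[0, 360)`.
#' @param aperture_mm Rectangle `c(x1, x2, y1, y2)` at the isocenter plane, mm.
#' @param mu Monitor units (beam weight), > 0.
#' @param sad_mm Source-to-axis distance (source to the reference measurement
#'   plane), mm.
#' @return An object of class `beam`.
#' @export
beam <- function(gantry_deg, aperture_mm, mu = 100, sad_mm = 1000) {
  a <- as.numeric(aperture_mm)
  if (length(a) != 4 || a[1] >= a[2] || a[3] >= a[4])
    stop("aperture must be c(x1, x2, y1, y2) with x1 < x2 and y1 < y2")
  if (!is.numeric(mu) || mu <= 0) stop("beam weight mu must be > 0")
  structure(list(gantry_deg = as.numeric(gantry_deg) %% 360,
                 aperture_mm = a, mu = as.numeric(mu),
                 sad_mm = as.numeric(sad_mm)),
            class = "beam")
}

#' Treatment/QA plan
#'
#' A non-empty list of weighted beams (IMRT segments are individual beams that
#' may share a gantry angle), an optional phantom reference and a label.
#'
#' @param beams List of [beam()] objects (a single beam is accepted).
#' @param label Plan label.
#' @param phantom Optional [density_volume].
#' @return An object of class `rt_plan`.
#' @export
rt_plan <- function(beams, label = "", phantom = NULL) {
  if (inherits(beams, "beam")) beams <- list(beams)
  if (!length(beams)) stop("a plan needs at least one beam")
  if (!all(vapply(beams, inherits, logical(1), "beam")))
    stop("all elements of beams must be beam objects")
  structure(list(beams = beams, label = label, phantom = phantom),
            class = "rt_plan")
}

#' @export
print.rt_plan <- function(x, ...) {
  ang <- vapply(x$beams, `[[`, numeric(1), "gantry_deg")
  cat(sprintf("<rt_plan> '%s': %d beam(s), gantry {%s} deg\n", x$label,
              length(x$beams), paste(unique(round(ang, 1)), collapse = ", ")))
  invisible(x)
}

#' Calibration plan suite
#'
#' One single-beam plan per gantry angle from 0 to 180 degrees in 10-degree
#' steps (19 plans), each with a static 4 cm x 10 cm jaw aperture (x = the
#' MLC-motion direction). The narrow 4 cm x side keeps the aperture penumbra
#' inside the sensitive area for near-horizontal beams, where the dose
#' gradient carries most of the calibration signal.
#'
#' @param phantom Optional [density_volume] attached to each plan.
#' @param angles_deg Gantry angles, degrees.
#' @param aperture_mm Aperture `c(x1, x2, y1, y2)`, mm.
#' @param mu Monitor units per plan.
#' @return List of [rt_plan()]s, one per angle.
#' @export
make_calibration_plans <- function(phantom = NULL,
                                   angles_deg = seq(0, 180, by = 10),
                                   aperture_mm = c(-20, 20, -50, 50),
                                   mu = 100) {
  lapply(angles_deg, function(th) {
    rt_plan(beam(th, aperture_mm, mu = mu),
            label = sprintf("cal-%03d", as.integer(round(th))),
            phantom = phantom)
  })
}

# ---- plan file I/O (YAML/JSON) ----------------------------------------------

plan_to_list <- function(plan) {
  list(label = plan$label,
       beams = lapply(plan$beams, function(b)
         list(gantry_deg = b$gantry_deg, aperture_mm = b$aperture_mm,
              mu = b$mu, sad_mm = b$sad_mm)))
}

plan_from_list <- function(x) {
  if (is.null(x$beams) || !length(x$beams))
    stop("plan file has no beams")
  beams <- lapply(x$beams, function(b) {
    beam(b$gantry_deg, unlist(b$aperture_mm), mu = b$mu,
         sad_mm = if (is.null(b$sad_mm)) 1000 else b$sad_mm)
  })
  rt_plan(beams, label = if (is.null(x$label)) "" else x$label)
}

#' Read / write a plan file
#'
#' Plans are stored as YAML or JSON (chosen by file extension) with keys
#' `label` and `beams: [{gantry_deg, aperture_mm, mu, sad_mm}]`.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_plan` returns an [rt_plan()]; `write_plan` returns `path`
#'   invisibly.
#' @export
read_plan <- function(path) {
  if (!file.exists(path)) stop("plan file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
              yaml = , yml = yaml::read_yaml(path),
              json = jsonlite::read_json(path, simplifyVector = FALSE),
              stop("unsupported plan file extension: .", ext))
  plan_from_list(x)
}

#' @param plan An [rt_plan()].
#' @rdname read_plan
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "rt_plan"))
  ext <- tolower(tools::file_ext(path))
  x <- plan_to_list(plan)
  switch(ext,
         yaml = , yml = yaml::write_yaml(x, path),
         json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17)),
         stop("unsupported plan file extension: .", ext))
  invisible(path)
}
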