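#' Build the hexagonal search-array geometry
#'
#' Constructs the 5x5 hexagonal grid of search elements used throughout the
#' package: 25 hexagonal cells with a flat-to-flat diameter equal to the
#' centre-to-centre spacing of adjacent cells (4.6 degrees of visual angle by
#' default), so the cells tile the array without gaps.  Cells are laid out in
#' `n_rows` rows of `n_cols` cells; odd rows (0-based, counting from the top)
#' are shifted right by half the spacing and the vertical row pitch is
#' `spacing * cos(pi/6)`, the pitch of a regular hexagonal tiling.  The middle
#' cell of the middle row sits exactly at the display centre `(0, 0)`.
#'
#' Coordinates are in degrees of visual angle relative to the display centre,
#' with x increasing rightward and y increasing downward.  Cells are indexed
#' 0-based, row-major from the top-left.
#'
#' @param spacing Centre-to-centre distance between adjacent hexagons, in
#'   degrees.  Also the flat-to-flat diameter of each hexagonal cell.
#' @param n_rows,n_cols Number of rows and columns; both must be odd so a
#'   middle cell exists.
#' @param jitter_max Maximum magnitude, in degrees, of the random horizontal
#'   and vertical shifts applied to the search element within its cell (see
#'   [jitter_elements()]).
#' @param screen_width_mm,screen_width_px Physical width and pixel width of
#'   the monitor, used for pixel/degree conversion.
#' @param viewing_distance_mm Eye-to-screen distance in millimetres.
#' @param screen_height_px Pixel height of the monitor (used only to express
#'   the vertical screen extent in degrees).
#' @param display_px Side length, in pixels, of the square stimulus area
#'   centred on the screen.
#'
#' @return An object of class `hex_grid`: a list with the grid parameters,
#'   the cell geometry (`apothem`, `circumradius`) and `centers`, a tibble
#'   with one row per cell (`hex_id`, `row`, `col`, `x_deg`, `y_deg`).
#' @examples
#' grid <- hex_grid()
#' hex_centers(grid)
#' @export
hex_grid <- function(spacing = 4.6, n_rows = 5, n_cols = 5,
                     jitter_max = 0.805,
                     screen_width_mm = 473, screen_width_px = 1680,
                     viewing_distance_mm = 650, screen_height_px = 1050,
                     display_px = 1040) {
  if (!is.numeric(spacing) || length(spacing) != 1 || !is.finite(spacing) ||
      spacing <= 0) {
    stop("invalid grid config: `spacing` must be a positive number",
         call. = FALSE)
  }
  if (n_rows %% 2 != 1 || n_cols %% 2 != 1 || n_rows < 1 || n_cols < 1) {
    stop("invalid grid config: `n_rows` and `n_cols` must be odd positive",
         call. = FALSE)
  }
  if (jitter_max < 0) {
    stop("invalid grid config: `jitter_max` must be non-negative",
         call. = FALSE)
  }
  if (screen_width_mm <= 0 || screen_width_px <= 0 ||
      viewing_distance_mm <= 0) {
    stop("invalid grid config: screen geometry must be positive",
         call. = FALSE)
  }

  pitch <- spacing * cos(pi / 6)
  row <- rep(seq_len(n_rows) - 1L, each = n_cols)
  col <- rep(seq_len(n_cols) - 1L, times = n_rows)
  centers <- tibble::tibble(
    hex_id = seq_len(n_rows * n_cols) - 1L,
    row = row,
    col = col,
    x_deg = (col - (n_cols - 1) / 2) * spacing +
      ifelse(row %% 2 == 1, spacing / 2, 0),
    y_deg = (row - (n_rows - 1) / 2) * pitch
  )

  structure(
    list(
      spacing = spacing,
      n_rows = as.integer(n_rows),
      n_cols = as.integer(n_cols),
      n_elements = as.integer(n_rows * n_cols),
      apothem = spacing / 2,
      circumradius = spacing / sqrt(3),
      jitter_max = jitter_max,
      screen_width_mm = screen_width_mm,
      screen_width_px = screen_width_px,
      screen_height_px = screen_height_px,
      viewing_distance_mm = viewing_distance_mm,
      display_px = display_px,
      centers = centers
    ),
    class = "hex_grid"
  )
}

#' @export
print.hex_grid <- function(x, ...) {
  cat(sprintf(
    "<hex_grid> %d x %d hexagonal array, %.3g deg spacing, %d cells\n",
    x$n_rows, x$n_cols, x$spacing, x$n_elements
  ))
  invisible(x)
}

#' Cell centres of a hexagonal grid
#'
#' @param grid A [hex_grid()] object.
#' @return A tibble with columns `hex_id`, `row`, `col`, `x_deg`, `y_deg`.
#' @export
hex_centers <- function(grid) {
  stopifnot(inherits(grid, "hex_grid"))
  grid$centers
}

#' Vertices of the hexagonal cells
#'
#' Returns the six corner points of every cell, useful for drawing the grid
#' and as an explicit polygon representation of each area of interest.  Cells
#' have two vertical edges (left and right); vertices are listed
#' counter-clockwise starting from the right-bottom vertex.
#'
#' @inheritParams hex_centers
#' @return A tibble with columns `hex_id`, `vertex` (1-6), `x_deg`, `y_deg`.
#' @export
hex_vertices <- function(grid) {
  stopifnot(inherits(grid, "hex_grid"))
  a <- grid$apothem
  r <- grid$circumradius
  vx <- c(a, a, 0, -a, -a, 0)
  vy <- c(-r / 2, r / 2, r, r / 2, -r / 2, -r)
  centers <- grid$centers
  tibble::tibble(
    hex_id = rep(centers$hex_id, each = 6L),
    vertex = rep(1:6, times = nrow(centers)),
    x_deg = rep(centers$x_deg, each = 6L) + rep(vx, times = nrow(centers)),
    y_deg = rep(centers$y_deg, each = 6L) + rep(vy, times = nrow(centers))
  )
}

#' Convert between pixels and degrees of visual angle
#'
#' `px_to_deg()` converts an on-screen length in pixels to degrees of visual
#' angle; `deg_to_px()` is its inverse.  The default `"radian"` method uses
#' the small-angle (arc-length) approximation
#' `deg = (px * mm_per_px / distance_mm) * 180 / pi`, which is the convention
#' under which the 1040-px stimulus square spans 25.8 degrees at 65 cm.  The
#' `"arctan"` method uses the exact `atan` of the subtended length.
#'
#' @param px,deg Lengths to convert (vectorised).
#' @param grid A [hex_grid()] carrying the screen geometry.
#' @param method `"radian"` (default) or `"arctan"`.
#' @return A numeric vector of converted lengths.
#' @examples
#' g <- hex_grid()
#' px_to_deg(1040, g) # ~25.8
#' @export
px_to_deg <- function(px, grid, method = c("radian", "arctan")) {
  stopifnot(inherits(grid, "hex_grid"))
  method <- match.arg(method)
  mm_per_px <- grid$screen_width_mm / grid$screen_width_px
  ratio <- px * mm_per_px / grid$viewing_distance_mm
  switch(method,
    radian = ratio * 180 / pi,
    arctan = atan(ratio) * 180 / pi
  )
}

#' @rdname px_to_deg
#' @export
deg_to_px <- function(deg, grid, method = c("radian", "arctan")) {
  stopifnot(inherits(grid, "hex_grid"))
  method <- match.arg(method)
  mm_per_px <- grid$screen_width_mm / grid$screen_width_px
  rad <- deg * pi / 180
  switch(method,
    radian = rad * grid$viewing_distance_mm / mm_per_px,
    arctan = tan(rad) * grid$viewing_distance_mm / mm_per_px
  )
}

#' Assign gaze positions to hexagonal cells
#'
#' Maps each point to the hexagonal cell whose interior contains it.  Points
#' outside every cell return `NA` (the "outside" sentinel).  Points exactly
#' on a shared border resolve to the cell with the nearest centre; exact
#' centre-distance ties resolve to the lower `hex_id`.
#'
#' @param x,y Numeric vectors of positions in degrees (display-centred).
#' @param grid A [hex_grid()] object.
#' @return An integer vector of cell ids (0-based) with `NA` for outside.
#' @examples
#' g <- hex_grid()
#' assign_hex(0, 0, g) # middle cell, 12
#' @export
assign_hex <- function(x, y, grid) {
  stopifnot(inherits(grid, "hex_grid"))
  if (length(x) != length(y)) stop("`x` and `y` must have equal length",
                                   call. = FALSE)
  if (length(x) == 0) return(integer(0))
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("invalid sample: non-finite gaze coordinates", call. = FALSE)
  }
  cx <- grid$centers$x_deg
  cy <- grid$centers$y_deg
  a <- grid$apothem
  r <- grid$circumradius
  # nearest centre (ties fall to the lower id via which.min), then an exact
  # point-in-hexagon test; cells are the Voronoi cells of their centres
  # within the tiling, so only the nearest cell can contain the point
  d2 <- outer(x, cx, "-")^2 + outer(y, cy, "-")^2
  nearest <- max.col(-d2, ties.method = "first")
  dx <- abs(x - cx[nearest])
  dy <- abs(y - cy[nearest])
  inside <- dx <= a & dy <= r - dx / sqrt(3)
  out <- grid$centers$hex_id[nearest]
  out[!inside] <- NA_integer_
  as.integer(out)
}

#' Random within-cell placement offsets for search elements
#'
#' Draws, for every cell, independent horizontal and vertical shifts of the
#' search element away from the cell centre.  Shift magnitudes are uniform on
#' `[0, jitter_max]` with random sign, matching a display in which element
#' positions are jittered anew for every trial while the area-of-interest
#' cells stay fixed.
#'
#' @param grid A [hex_grid()] object.
#' @param seed Integer seed; draws are deterministic given the seed.
#' @return A tibble with columns `hex_id`, `dx_deg`, `dy_deg`.
#' @export
jitter_elements <- function(grid, seed) {
  stopifnot(inherits(grid, "hex_grid"))
  if (missing(seed) || is.null(seed)) stop("`seed` must be given",
                                           call. = FALSE)
  n <- grid$n_elements
  withr::with_seed(as.integer(seed), {
    tibble::tibble(
      hex_id = grid$centers$hex_id,
      dx_deg = stats::runif(n, 0, grid$jitter_max) *
        sample(c(-1, 1), n, replace = TRUE),
      dy_deg = stats::runif(n, 0, grid$jitter_max) *
        sample(c(-1, 1), n, replace = TRUE)
    )
  })
}

#' Read a grid configuration file
#'
#' Reads a key-value (YAML) configuration file whose entries are the
#' arguments of [hex_grid()] and builds the grid.  Unknown keys are an error
#' so typos do not silently fall back to defaults.
#'
#' @param path Path to the configuration file.
#' @return A [hex_grid()] object.
#' @export
read_grid_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(hex_grid))
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0) {
    stop("invalid grid config: unknown keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(hex_grid, cfg)
}

#' Write grid cell centres to CSV
#'
#' @param grid A [hex_grid()] object.
#' @param path Output path.
#' @return The input grid, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  stopifnot(inherits(grid, "hex_grid"))
  readr::write_csv(
    grid$centers[, c("hex_id", "x_deg", "y_deg")],
    path
  )
  invisible(grid)
}
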