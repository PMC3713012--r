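#' Define a rectangular grid
#'
#' Grid points lie at `origin + spacing * (ix, iy, iz)` for
#' `0 <= ix < nx` etc.; field values are stored x-fastest, then y, then z,
#' with the origin at the minimum corner, so exported grids are comparable
#' across runs.
#'
#' @param origin minimum-corner coordinates (x, y, z) in Angstrom.
#' @param spacing grid spacing in Angstrom.
#' @param dims integer point counts (nx, ny, nz), each at least 2.
#' @return an object of class `GridSpec`.
#' @export
grid_spec <- function(origin, spacing, dims) {
  stopifnot(length(origin) == 3, length(dims) == 3, spacing > 0,
            all(dims >= 2))
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 dims = as.integer(dims)),
            class = "GridSpec")
}

#' @export
print.GridSpec <- function(x, ...) {
  cat(sprintf("<GridSpec %dx%dx%d, spacing %.3g A, origin (%.2f, %.2f, %.2f)>\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Number of points in a grid
#' @param grid a `GridSpec`.
#' @return integer point count nx*ny*nz.
#' @export
grid_size <- function(grid) prod(grid$dims)

same_grid <- function(a, b) {
  identical(a$dims, b$dims) &&
    abs(a$spacing - b$spacing) < 1e-9 &&
    max(abs(a$origin - b$origin)) < 1e-9
}

#' Build the shared molecule-centred grid
#'
#' One axis-aligned box covering every atom of every molecule with at
#' least `margin` Angstrom of padding on each face. The origin is snapped
#' down to the global `spacing` lattice so grids built with different
#' margins share their common points exactly. The same grid must be used
#' for all molecules of one analysis.
#'
#' @param mols list of `Molecule` objects (at least one atom overall).
#' @param margin minimum distance from any atom to a box face (default 6).
#' @param spacing grid spacing in Angstrom (default 0.5).
#' @return a `GridSpec`.
#' @export
build_common_grid <- function(mols, margin = 6, spacing = 0.5) {
  if (inherits(mols, "Molecule")) mols <- list(mols)
  xyz <- do.call(rbind, lapply(mols, coords))
  if (is.null(xyz) || nrow(xyz) == 0L) stop("no atoms to build a grid around")
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  origin <- floor(lo / spacing + 1e-9) * spacing
  dims <- pmax(2L, as.integer(ceiling((hi - origin) / spacing - 1e-9)) + 1L)
  grid_spec(origin, spacing, dims)
}

new_scalar_field <- function(grid, kind, values) {
  stopifnot(length(values) == grid_size(grid))
  structure(list(grid = grid, kind = kind, values = as.numeric(values)),
            class = "ScalarField")
}

#' @export
print.ScalarField <- function(x, ...) {
  cat(sprintf("<ScalarField '%s': %d values in [%.3g, %.3g]>\n",
              x$kind, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Binary shape field of a molecule
#'
#' Value 1 at grid points lying inside (closed sphere, boundary counts as
#' inside) the van der Waals sphere of at least one atom, else 0.
#'
#' @param mol a `Molecule` with assigned radii.
#' @param grid shared `GridSpec`.
#' @return a `ScalarField` of kind `"shape"`.
#' @export
shape_field <- function(mol, grid) {
  a <- mol$atoms
  if (nrow(a) == 0L) {
    return(new_scalar_field(grid, "shape", numeric(grid_size(grid))))
  }
  if (any(is.na(a$vdw_radius)) || any(a$vdw_radius <= 0)) {
    stop("molecule ", mol$id, " has atoms without a positive vdW radius")
  }
  v <- cpp_shape_field(coords(mol), a$vdw_radius, grid$origin,
                       grid$spacing, grid$dims)
  new_scalar_field(grid, "shape", v)
}

#' Electrostatic field of a molecule on a grid
#'
#' Coulomb energy of a unit positive probe under a distance-dependent
#' dielectric eps = 4r, i.e. `E = sum_i K q_i / (4 d_i^2)` (kcal/mol) with
#' `d_i` the probe-atom distance. Grid points inside the molecule's own
#' van der Waals surface are set to exactly 0, which also removes the
#' singularity at atom centres; finally values are truncated to
#' `[-clamp, +clamp]`. Pass `clamp = NA` to disable truncation (needed
#' for the in-range fraction statistic).
#'
#' @param mol a `Molecule` with radii and charges assigned.
#' @param grid shared `GridSpec`.
#' @param clamp truncation bound in kcal/mol (default 5; `NA` = none).
#' @param coulomb_k Coulomb constant in kcal A/(mol e^2); default
#'   332.0716.
#' @return a `ScalarField` of kind `"electrostatic"`.
#' @export
electrostatic_field <- function(mol, grid, clamp = 5,
                                coulomb_k = 332.0716) {
  a <- mol$atoms
  if (nrow(a) == 0L) {
    return(new_scalar_field(grid, "electrostatic", numeric(grid_size(grid))))
  }
  if (any(is.na(a$vdw_radius)) || any(is.na(a$partial_charge))) {
    stop("molecule ", mol$id, " needs radii and charges (see assign_parameters)")
  }
  v <- cpp_elec_field(coords(mol), a$partial_charge, a$vdw_radius,
                      grid$origin, grid$spacing, grid$dims,
                      coulomb_k, as.numeric(clamp))
  new_scalar_field(grid, "electrostatic", v)
}

#' Pooled distribution statistics of electrostatic fields
#'
#' Computed on unclamped fields (build them with `clamp = NA`): the
#' fraction of grid values with |E| <= `bound`, pooled over all supplied
#' molecules, plus min/max and a histogram.
#'
#' @param fields list of `ScalarField` objects.
#' @param bound range bound in kcal/mol (default 5).
#' @param breaks histogram breaks passed to [graphics::hist()] logic via
#'   [base::cut()]; default 20 equal bins over the clipped range.
#' @return list with `fraction_in_range`, `min`, `max`, `n`, `histogram`.
#' @export
field_stats <- function(fields, bound = 5, breaks = 20) {
  if (inherits(fields, "ScalarField")) fields <- list(fields)
  v <- unlist(lapply(fields, function(f) f$values))
  if (length(v) == 0L) stop("no field values")
  frac <- mean(abs(v) <= bound)
  clip <- pmin(pmax(v, -3 * bound), 3 * bound)
  h <- table(cut(clip, breaks = breaks))
  list(fraction_in_range = frac, min = min(v), max = max(v),
       n = length(v), histogram = h)
}

#' Export a scalar field as flat CSV
#'
#' Columns `ix, iy, iz, value` with 0-based indices, x fastest.
#'
#' @param field a `ScalarField`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, path) {
  d <- field$grid$dims
  idx <- expand.grid(ix = 0:(d[1] - 1), iy = 0:(d[2] - 1), iz = 0:(d[3] - 1))
  idx$value <- field$values
  utils::write.csv(idx, path, row.names = FALSE)
  invisible(path)
}

#' Export a scalar field in OpenDX scalar-grid format
#'
#' @param field a `ScalarField`.
#' @param path output .dx path.
#' @return `path`, invisibly.
#' @export
write_field_dx <- function(field, path) {
  g <- field$grid
  d <- g$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[3], d[2], d[1]),
    sprintf("origin %.6f %.6f %.6f", g$origin[1], g$origin[2], g$origin[3]),
    sprintf("delta %.6f 0 0", g$spacing),
    sprintf("delta 0 %.6f 0", g$spacing),
    sprintf("delta 0 0 %.6f", g$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[3], d[2], d[1]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            grid_size(g))), con)
  # DX wants z fastest; our storage is x fastest
  arr <- array(field$values, dim = d)
  vals <- as.vector(aperm(arr, c(3, 2, 1)))
  n <- length(vals)
  rows <- split(vals, ceiling(seq_len(n) / 3))
  writeLines(vapply(rows, function(r) paste(sprintf("%.6e", r), collapse = " "),
                    character(1)), con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}
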