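#' Default CoMFA probe atom
#'
#' The conventional sp3-carbon probe: 1.7 Angstrom radius, 0.107 kcal/mol
#' well depth, +1.0 e charge. Radii mix additively with atom radii and well
#' depths geometrically.
#'
#' @param radius,epsilon,charge Probe parameters.
#' @return A list with elements `radius`, `epsilon`, `charge`.
#' @export
comfa_probe <- function(radius = 1.7, epsilon = 0.107, charge = 1.0) {
  list(radius = radius, epsilon = epsilon, charge = charge)
}

#' Build a rectangular field lattice around aligned molecules
#'
#' The axis-aligned union bounding box of all atoms, expanded by `margin`
#' on every side and discretized at `spacing`. At least two planes per axis
#' are kept even for degenerate extents.
#'
#' @param molecules List of [aligned_molecule()] objects (or a single one).
#' @param spacing Lattice spacing in Angstrom (default 2.0).
#' @param margin Box expansion per side in Angstrom (default 4.0).
#' @return An object of class `grid_spec` with `origin`, `spacing`, `dims`.
#' @export
build_grid <- function(molecules, spacing = 2.0, margin = 4.0) {
  if (inherits(molecules, "aligned_molecule")) molecules <- list(molecules)
  if (length(molecules) == 0L) stop("need at least one molecule")
  stopifnot(spacing > 0, margin >= 0)
  xyz <- do.call(rbind, lapply(molecules, function(m) m$coords))
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  dims <- pmax(2L, as.integer(floor((hi - lo) / spacing)) + 1L)
  structure(list(origin = as.numeric(lo), spacing = spacing, dims = dims),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %dx%dx%d points, spacing %.2f A, origin (%s)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              paste(sprintf("%.2f", x$origin), collapse = ", ")))
  invisible(x)
}

#' Lattice point coordinates of a grid
#'
#' Points are enumerated with the x index varying fastest, then y, then z
#' (Fortran order), matching the column layout of field blocks and the
#' cube writer.
#'
#' @param grid A `grid_spec`.
#' @return Numeric matrix (n_points x 3).
#' @export
grid_points <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  ax <- lapply(1:3, function(k)
    grid$origin[k] + grid$spacing * (seq_len(grid$dims[k]) - 1L))
  pts <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                     KEEP.OUT.ATTRS = FALSE)
  as.matrix(pts)
}

# n_points x n_atoms distance matrix
point_atom_dist <- function(pts, coords) {
  d2 <- outer(rowSums(pts^2), rowSums(coords^2), "+") -
    2 * tcrossprod(pts, coords)
  sqrt(pmax(d2, 0))
}

#' CoMFA steric and electrostatic fields of one molecule
#'
#' Steric: Lennard-Jones 6-12 energy of the probe summed over atoms, with
#' additive radius mixing and geometric well-depth mixing. Electrostatic:
#' Coulomb energy with a distance-dependent dielectric of 1 and the
#' conversion constant 332.06 kcal A mol^-1 e^-2. Both fields are
#' truncated to `[-cap, +cap]`; the cap fires before any singularity, so a
#' probe on top of an atom yields `+cap`. Points whose steric value sits
#' at `+cap` are flagged sterically excluded; block assembly replaces
#' their electrostatic entries with the across-molecule column mean.
#'
#' @param molecule An [aligned_molecule()] with charges assigned.
#' @param grid A `grid_spec`.
#' @param probe Probe spec from [comfa_probe()].
#' @param cap Energy truncation in kcal/mol (default 30).
#' @return List with numeric vectors `steric`, `electrostatic` and logical
#'   `excluded`, one entry per lattice point.
#' @export
comfa_fields <- function(molecule, grid, probe = comfa_probe(), cap = 30) {
  stopifnot(inherits(molecule, "aligned_molecule"),
            inherits(grid, "grid_spec"), cap > 0)
  pts <- grid_points(grid)
  r <- point_atom_dist(pts, molecule$coords)
  rmix <- matrix(molecule$vdw_radius + probe$radius,
                 nrow(r), ncol(r), byrow = TRUE)
  emix <- matrix(sqrt(molecule$vdw_epsilon * probe$epsilon),
                 nrow(r), ncol(r), byrow = TRUE)
  ratio6 <- (rmix / pmax(r, 1e-12))^6
  steric <- rowSums(emix * (ratio6^2 - 2 * ratio6))
  steric <- pmin(pmax(steric, -cap), cap)
  qmat <- matrix(332.06 * probe$charge * molecule$charges,
                 nrow(r), ncol(r), byrow = TRUE)
  elec <- rowSums(qmat / pmax(r, 1e-12))
  elec <- pmin(pmax(elec, -cap), cap)
  list(steric = steric, electrostatic = elec, excluded = steric >= cap)
}

#' CoMSIA similarity fields of one molecule
#'
#' Gaussian-attenuated similarity indices for five property types: steric
#' (atom weight = vdW radius cubed), electrostatic (partial charge),
#' hydrophobic, hydrogen-bond donor and acceptor (rule-based weights from
#' [atom_properties()]). The value at lattice point j for property k is
#' `-sum_i w_probe_k * w_ik * exp(-alpha * r_ij^2)` with unit probe
#' weights; the Gaussian form is singularity-free everywhere.
#'
#' @param molecule An [aligned_molecule()].
#' @param grid A `grid_spec`.
#' @param alpha Attenuation factor in A^-2 (default 0.3).
#' @return List of five numeric vectors: `steric`, `electrostatic`,
#'   `hydrophobic`, `donor`, `acceptor`.
#' @export
comsia_fields <- function(molecule, grid, alpha = 0.3) {
  stopifnot(inherits(molecule, "aligned_molecule"),
            inherits(grid, "grid_spec"), alpha > 0)
  if (is.null(molecule$props) ||
      !all(c("hydrophobic", "donor", "acceptor") %in% names(molecule$props)))
    stop("molecule lacks a property table (hydrophobic/donor/acceptor)")
  pts <- grid_points(grid)
  r <- point_atom_dist(pts, molecule$coords)
  g <- exp(-alpha * r^2)
  weights <- list(steric = molecule$vdw_radius^3,
                  electrostatic = molecule$charges,
                  hydrophobic = molecule$props$hydrophobic,
                  donor = molecule$props$donor,
                  acceptor = molecule$props$acceptor)
  lapply(weights, function(w) -as.numeric(g %*% w))
}

#' Assemble a molecules-by-descriptors field block
#'
#' Runs the chosen field engine over every molecule on a shared lattice
#' and stacks the per-point values into the descriptor matrix of the QSTR
#' (one row per molecule, one column per lattice point and field type).
#' For CoMFA, electrostatic entries at sterically excluded points are
#' replaced by the mean of the non-excluded molecules at that point (the
#' column mean when every molecule is excluded).
#'
#' @param molecules List of [aligned_molecule()] objects.
#' @param grid Optional `grid_spec`; built from the molecules when `NULL`.
#' @param type `"comfa"` or `"comsia"`.
#' @param probe,cap CoMFA probe and truncation (see [comfa_fields()]).
#' @param alpha CoMSIA attenuation (see [comsia_fields()]).
#' @param spacing,margin Lattice parameters used when `grid` is `NULL`.
#' @return An object of class `field_block`: `matrix` (molecules x
#'   columns), `column_meta` (data frame `grid_index`, `field`),
#'   `dropped_columns` (empty until [column_filter()]), `grid`, `type`.
#' @export
field_block <- function(molecules, grid = NULL,
                        type = c("comfa", "comsia"),
                        probe = comfa_probe(), cap = 30, alpha = 0.3,
                        spacing = 2.0, margin = 4.0) {
  type <- match.arg(type)
  if (inherits(molecules, "aligned_molecule")) molecules <- list(molecules)
  if (length(molecules) == 0L) stop("need at least one molecule")
  if (is.null(grid)) grid <- build_grid(molecules, spacing, margin)
  per_mol <- lapply(molecules, function(m) {
    if (type == "comfa") comfa_fields(m, grid, probe, cap)
    else comsia_fields(m, grid, alpha)
  })
  fields <- if (type == "comfa") c("steric", "electrostatic")
            else c("steric", "electrostatic", "hydrophobic",
                   "donor", "acceptor")
  mats <- lapply(fields, function(f)
    do.call(rbind, lapply(per_mol, `[[`, f)))
  names(mats) <- fields
  if (type == "comfa") {
    excl <- do.call(rbind, lapply(per_mol, `[[`, "excluded"))
    e <- mats$electrostatic
    for (j in which(colSums(excl) > 0L)) {
      ok <- !excl[, j]
      e[!ok, j] <- if (any(ok)) mean(e[ok, j]) else mean(e[, j])
    }
    mats$electrostatic <- e
  }
  mat <- do.call(cbind, mats)
  n_pts <- prod(grid$dims)
  meta <- data.frame(grid_index = rep(seq_len(n_pts), length(fields)),
                     field = rep(fields, each = n_pts),
                     stringsAsFactors = FALSE)
  colnames(mat) <- paste(meta$field, meta$grid_index, sep = "_")
  rownames(mat) <- vapply(molecules, `[[`, character(1), "id")
  structure(list(matrix = mat, column_meta = meta,
                 dropped_columns = character(0), grid = grid, type = type),
            class = "field_block")
}

#' @export
print.field_block <- function(x, ...) {
  cat(sprintf("<field_block> %s: %d molecules x %d columns (%s), %d dropped\n",
              x$type, nrow(x$matrix), ncol(x$matrix),
              paste(unique(x$column_meta$field), collapse = "/"),
              length(x$dropped_columns)))
  invisible(x)
}

#' Minimum-standard-deviation column filtration
#'
#' Columns whose standard deviation across molecules falls strictly below
#' `threshold` (energy units for CoMFA) are moved to `dropped_columns`;
#' the order of the surviving columns is preserved. A threshold of 0
#' leaves the block unchanged.
#'
#' @param block A `field_block`.
#' @param threshold Minimum column standard deviation (default 2.0).
#' @return The filtered `field_block`.
#' @export
column_filter <- function(block, threshold = 2.0) {
  stopifnot(inherits(block, "field_block"), threshold >= 0)
  if (ncol(block$matrix) == 0L) stop("field block has no columns")
  sds <- apply(block$matrix, 2, stats::sd)
  drop <- sds < threshold
  if (all(drop))
    stop("column filtration removed every column; lower the threshold")
  block$dropped_columns <- c(block$dropped_columns,
                             colnames(block$matrix)[drop])
  block$matrix <- block$matrix[, !drop, drop = FALSE]
  block$column_meta <- block$column_meta[!drop, , drop = FALSE]
  block
}

#' Write one field as a Gaussian cube file
#'
#' Plain-text cube export of a per-lattice-point vector (e.g. a contour
#' grid) for downstream visualization tools. Coordinates are written in
#' Bohr as the format requires.
#'
#' @param grid A `grid_spec`.
#' @param values Numeric vector, one value per lattice point (x fastest).
#' @param path Output file.
#' @param title Header line.
#' @export
write_cube <- function(grid, values, path, title = "aconiqstr field") {
  stopifnot(inherits(grid, "grid_spec"),
            length(values) == prod(grid$dims))
  bohr <- 1 / 0.529177210903
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(title, "scalar field"), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", 1,
                     grid$origin[1] * bohr, grid$origin[2] * bohr,
                     grid$origin[3] * bohr), con)
  step <- grid$spacing * bohr
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", grid$dims[1], step, 0, 0), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", grid$dims[2], 0, step, 0), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", grid$dims[3], 0, 0, step), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f", 1, 0, 0, 0, 0), con)
  # cube body runs z fastest inside an x,y scan; our layout is x fastest
  arr <- array(values, dim = grid$dims)
  for (ix in seq_len(grid$dims[1]))
    for (iy in seq_len(grid$dims[2]))
      writeLines(paste(sprintf("%13.5e", arr[ix, iy, ]), collapse = " "), con)
  invisible(path)
}

#' Write a field block matrix to CSV
#'
#' @param block A `field_block`.
#' @param path Output CSV path (first column = molecule id).
#' @export
write_field_csv <- function(block, path) {
  stopifnot(inherits(block, "field_block"))
  df <- data.frame(id = rownames(block$matrix), block$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a field block matrix from CSV
#'
#' Reconstructs a `field_block` (without lattice geometry) from a CSV
#' written by [write_field_csv()]; column metadata is recovered from the
#' `field_index` column-name convention.
#'
#' @param path CSV path.
#' @return A `field_block` with `grid = NULL`.
#' @export
read_field_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  nm <- colnames(mat)
  meta <- data.frame(
    grid_index = as.integer(sub("^.*_", "", nm)),
    field = sub("_[0-9]+$", "", nm), stringsAsFactors = FALSE)
  structure(list(matrix = mat, column_meta = meta,
                 dropped_columns = character(0), grid = NULL, type = NA),
            class = "field_block")
}
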