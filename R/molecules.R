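#' Bundled nonbonded parameters for common elements
#'
#' Van der Waals radii (Angstrom) and Lennard-Jones well depths (kcal/mol)
#' used for the steric probe interaction, in the style of classic
#' molecular-mechanics force fields.
#'
#' @return A data frame with columns `element`, `radius`, `epsilon`.
#' @export
element_params <- function() {
  data.frame(
    element = c("H", "C", "N", "O", "S", "P", "F", "Cl", "Br", "I"),
    radius  = c(1.20, 1.70, 1.55, 1.52, 1.80, 1.80, 1.47, 1.75, 1.85, 1.98),
    epsilon = c(0.042, 0.107, 0.095, 0.116, 0.314, 0.314,
                0.109, 0.240, 0.320, 0.400),
    stringsAsFactors = FALSE
  )
}

#' Construct an aligned molecule
#'
#' A light container for one pre-aligned 3D structure: element symbols,
#' Cartesian coordinates, optional connectivity, partial charges and the
#' per-atom physicochemical property weights consumed by the similarity
#' fields. All molecules entering one field block must share a single
#' alignment frame; no re-fitting happens downstream.
#'
#' @param id Character identifier.
#' @param elements Character vector of element symbols.
#' @param coords Numeric matrix (n_atoms x 3) of coordinates in Angstrom.
#' @param bonds Optional data frame with columns `from`, `to`, `order`
#'   (1-based atom indices; order 1, 1.5, 2 or 3).
#' @param charges Optional numeric vector of partial charges (e). Defaults
#'   to zeros; see [assign_gasteiger_charges()].
#' @param props Optional data frame of per-atom property weights with
#'   columns `hydrophobic`, `donor`, `acceptor`. When missing it is derived
#'   from the elements and connectivity by [atom_properties()].
#' @param formal_charge Total formal charge of the molecule (e).
#'
#' @return An object of class `aligned_molecule`.
#' @examples
#' m <- aligned_molecule("water",
#'   elements = c("O", "H", "H"),
#'   coords = rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)),
#'   bonds = data.frame(from = c(1, 1), to = c(2, 3), order = 1))
#' @export
aligned_molecule <- function(id, elements, coords, bonds = NULL,
                             charges = NULL, props = NULL,
                             formal_charge = 0) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- length(elements)
  if (n < 3L) stop("a molecule needs at least 3 atoms")
  if (!is.matrix(coords) || nrow(coords) != n || ncol(coords) != 3L)
    stop("'coords' must be an n_atoms x 3 matrix")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  pars <- element_params()
  hit <- match(elements, pars$element)
  if (anyNA(hit)) {
    bad <- which(is.na(hit))[1L]
    stop(sprintf("atom %d: element '%s' has no nonbonded parameters",
                 bad, elements[bad]))
  }
  if (is.null(charges)) charges <- rep(0, n)
  if (length(charges) != n) stop("'charges' length mismatch")
  if (!is.null(bonds)) {
    bonds <- as.data.frame(bonds)
    stopifnot(all(c("from", "to") %in% names(bonds)))
    if (is.null(bonds$order)) bonds$order <- 1
    if (any(bonds$from < 1 | bonds$from > n | bonds$to < 1 | bonds$to > n))
      stop("bond indices out of range")
  }
  if (is.null(props)) props <- atom_properties(elements, bonds, charges)
  structure(
    list(id = as.character(id), elements = elements, coords = coords,
         bonds = bonds, charges = as.numeric(charges),
         vdw_radius = pars$radius[hit], vdw_epsilon = pars$epsilon[hit],
         props = props, formal_charge = formal_charge),
    class = "aligned_molecule")
}

#' @export
print.aligned_molecule <- function(x, ...) {
  cat(sprintf("<aligned_molecule> %s: %d atoms (%s), net charge %.3f e\n",
              x$id, length(x$elements),
              paste(unique(x$elements), collapse = ","),
              sum(x$charges)))
  invisible(x)
}

#' Derive per-atom similarity-field property weights
#'
#' A deliberately simple rule-based atom typing for the hydrophobic,
#' hydrogen-bond-donor and hydrogen-bond-acceptor similarity fields:
#' carbons are hydrophobic (+1), heteroatoms N/O hydrophilic (-1), halogens
#' mildly hydrophobic (+0.5); N and O atoms are acceptors (weight 1); N and
#' O atoms bearing at least one hydrogen are donors (weight 1). Without
#' connectivity every N/O is conservatively treated as both donor and
#' acceptor.
#'
#' @param elements Character vector of element symbols.
#' @param bonds Optional bond data frame (`from`, `to`, `order`).
#' @param charges Optional partial charges (unused by the default rules but
#'   kept in the signature for richer schemes).
#' @return Data frame with columns `hydrophobic`, `donor`, `acceptor`.
#' @export
atom_properties <- function(elements, bonds = NULL, charges = NULL) {
  n <- length(elements)
  hydro <- numeric(n)
  hydro[elements == "C"] <- 1
  hydro[elements %in% c("N", "O", "S", "P")] <- -1
  hydro[elements %in% c("F", "Cl", "Br", "I")] <- 0.5
  acc <- as.numeric(elements %in% c("N", "O"))
  if (is.null(bonds)) {
    don <- acc
  } else {
    has_h <- vapply(seq_len(n), function(i) {
      nb <- c(bonds$to[bonds$from == i], bonds$from[bonds$to == i])
      any(elements[nb] == "H")
    }, logical(1))
    don <- as.numeric(elements %in% c("N", "O") & has_h)
  }
  data.frame(hydrophobic = hydro, donor = don, acceptor = acc)
}

# Neighbor list (list of integer vectors) from a bond table.
neighbor_list <- function(n, bonds) {
  nb <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$from[k]; j <- bonds$to[k]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  nb
}

#' Read aligned molecules from an SDF file
#'
#' Thin wrapper over `ChemmineR::read.SDFset()` that converts each record
#' (3D coordinates plus bond block) into an [aligned_molecule()].
#'
#' @param path Path to an SDF/MOL file.
#' @return List of `aligned_molecule` objects.
#' @export
read_sdf <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("reading SDF files requires the ChemmineR package")
  sdfs <- ChemmineR::read.SDFset(path)
  ids <- ChemmineR::sdfid(sdfs)
  lapply(seq_along(sdfs), function(i) {
    sdf <- sdfs[[i]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    elements <- sub("_.*$", "", rownames(ab))
    bonds <- data.frame(from = as.integer(bb[, 1]),
                        to = as.integer(bb[, 2]),
                        order = as.numeric(bb[, 3]))
    aligned_molecule(ids[i], elements, ab[, 1:3, drop = FALSE],
                     bonds = bonds)
  })
}

#' Read aligned molecules from a TRIPOS MOL2 file
#'
#' Converts the file to SDF with OpenBabel (via ChemmineOB) and delegates
#' to [read_sdf()].
#'
#' @param path Path to a MOL2 file.
#' @return List of `aligned_molecule` objects.
#' @export
read_mol2 <- function(path) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("reading MOL2 files requires the ChemmineOB package")
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp))
  ChemmineOB::convertFormatFile("MOL2", "SDF", path, tmp)
  read_sdf(tmp)
}
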