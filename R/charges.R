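# Gasteiger-Marsili PEOE electronegativity polynomials chi(q) = a + b q + c q^2,
# indexed by element and hybridization (sp3/sp2/sp). Values from the original
# partial-equalization-of-orbital-electronegativity parameterization.
peoe_params <- function() {
  data.frame(
    key = c("H", "C.3", "C.2", "C.1", "N.3", "N.2", "N.1",
            "O.3", "O.2", "F", "Cl", "Br", "I", "S.3"),
    a = c(7.17, 7.98, 8.79, 10.39, 11.54, 12.87, 15.68,
          14.18, 17.07, 14.66, 11.00, 10.08, 9.90, 10.14),
    b = c(6.24, 9.18, 9.32, 9.45, 10.82, 11.15, 11.70,
          12.92, 13.79, 13.85, 9.69, 8.47, 7.96, 9.13),
    c = c(-0.56, 1.88, 1.51, 0.73, 1.36, 0.85, -0.27,
          1.39, 0.47, 2.31, 1.35, 1.16, 0.96, 1.38),
    stringsAsFactors = FALSE
  )
}

# sp assignment from the incident bond orders: any triple (or two doubles)
# -> sp; any double or aromatic -> sp2; else sp3.
peoe_key <- function(elements, bonds) {
  n <- length(elements)
  maxord <- rep(1, n)
  ndouble <- rep(0L, n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$from[k]; j <- bonds$to[k]; o <- bonds$order[k]
    maxord[i] <- max(maxord[i], o); maxord[j] <- max(maxord[j], o)
    if (o == 2) { ndouble[i] <- ndouble[i] + 1L; ndouble[j] <- ndouble[j] + 1L }
  }
  vapply(seq_len(n), function(i) {
    el <- elements[i]
    if (el %in% c("H", "F", "Cl", "Br", "I")) return(el)
    if (el == "S") return("S.3")
    hyb <- if (maxord[i] >= 3 || ndouble[i] >= 2) "1"
           else if (maxord[i] >= 1.5) "2" else "3"
    paste(el, hyb, sep = ".")
  }, character(1))
}

#' Assign Gasteiger (PEOE) partial charges
#'
#' Iterative partial equalization of orbital electronegativity: in round
#' `t` each bond transfers charge proportional to the electronegativity
#' difference of its atoms, damped by `damping^t`, with the donor's cation
#' electronegativity as the normalizer (hydrogen uses the conventional
#' 20.02). Six rounds with damping 0.5 reproduce the classic scheme. The
#' aromatic/pi Hueckel correction historically layered on top of PEOE is
#' not applied; for the saturated alkaloid scaffolds this package targets
#' the sigma framework dominates, and the omission is documented as a
#' limitation.
#'
#' @param molecule An [aligned_molecule()] with a bond table.
#' @param n_iter Number of damping rounds (default 6).
#' @param damping Per-round damping factor (default 0.5).
#' @return The molecule with `charges` populated; the total charge equals
#'   the molecule's formal charge to machine precision.
#' @examples
#' m <- aligned_molecule("methane", c("C", "H", "H", "H", "H"),
#'   coords = rbind(c(0, 0, 0), c(1.09, 0, 0), c(-0.36, 1.03, 0),
#'                  c(-0.36, -0.51, 0.89), c(-0.36, -0.51, -0.89)),
#'   bonds = data.frame(from = 1, to = 2:5, order = 1))
#' sum(assign_gasteiger_charges(m)$charges)  # 0
#' @export
assign_gasteiger_charges <- function(molecule, n_iter = 6, damping = 0.5) {
  stopifnot(inherits(molecule, "aligned_molecule"))
  if (is.null(molecule$bonds) || nrow(molecule$bonds) == 0L)
    stop("PEOE charge assignment needs connectivity (a bond table)")
  pars <- peoe_params()
  key <- peoe_key(molecule$elements, molecule$bonds)
  hit <- match(key, pars$key)
  if (anyNA(hit)) {
    bad <- which(is.na(hit))[1L]
    stop(sprintf("atom %d ('%s', type %s) is not PEOE-parameterized",
                 bad, molecule$elements[bad], key[bad]))
  }
  a <- pars$a[hit]; b <- pars$b[hit]; cc <- pars$c[hit]
  # cation electronegativity chi(+1); hydrogen fixed by convention
  chi_plus <- a + b + cc
  chi_plus[molecule$elements == "H"] <- 20.02
  n <- length(molecule$elements)
  # seed from the formal charge spread evenly (neutral molecules: zeros)
  q <- rep(molecule$formal_charge / n, n)
  bf <- molecule$bonds$from; bt <- molecule$bonds$to
  for (t in seq_len(n_iter)) {
    chi <- a + b * q + cc * q^2
    dq <- numeric(n)
    for (k in seq_along(bf)) {
      i <- bf[k]; j <- bt[k]
      if (chi[i] == chi[j]) next
      if (chi[i] < chi[j]) { lo <- i; hi <- j } else { lo <- j; hi <- i }
      tr <- (chi[hi] - chi[lo]) / chi_plus[lo] * damping^t
      dq[lo] <- dq[lo] + tr
      dq[hi] <- dq[hi] - tr
    }
    q <- q + dq
  }
  molecule$charges <- q
  molecule
}
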