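## Periodic-table subset used throughout: masses, covalent radii (Cordero),
## van der Waals radii (Bondi; non-Bondi entries are common fallbacks) and a
## small reference table of equilibrium bond lengths / ideal angles.
## All distances in Angstrom, masses in Da.

.ligdyn_elements <- local({
  el <- c("H", "C", "N", "O", "F", "NA", "MG", "P", "S", "CL",
          "K", "CA", "MN", "FE", "CO", "NI", "CU", "ZN", "BR", "I")
  data.frame(
    element = el,
    mass = c(1.008, 12.011, 14.007, 15.999, 18.998, 22.990, 24.305,
             30.974, 32.06, 35.45, 39.098, 40.078, 54.938, 55.845,
             58.933, 58.693, 63.546, 65.38, 79.904, 126.904),
    r_cov = c(0.31, 0.76, 0.71, 0.66, 0.57, 1.66, 1.41, 1.07, 1.05, 1.02,
              2.03, 1.76, 1.39, 1.32, 1.26, 1.24, 1.32, 1.22, 1.20, 1.39),
    r_vdw = c(1.20, 1.70, 1.55, 1.52, 1.47, 2.27, 1.73, 1.80, 1.80, 1.75,
              2.75, 2.31, 2.00, 2.00, 2.00, 1.63, 1.40, 1.39, 1.85, 1.98),
    max_bonds = c(1L, 4L, 4L, 3L, 1L, 1L, 2L, 5L, 6L, 1L,
                  1L, 2L, 6L, 6L, 6L, 6L, 6L, 4L, 1L, 1L),
    stringsAsFactors = FALSE
  )
})

## base (neutral) valence used by the valence audit
.ligdyn_valence <- c(H = 1, C = 4, N = 3, O = 2, F = 1, P = 5, S = 6,
                     CL = 1, BR = 1, I = 1)

## reference equilibrium bond lengths by element pair and bond order.
## CCCBDB-style experimental values for common organic bonds.
.ligdyn_ref_bonds <- local({
  tab <- rbind(
    c("C", "C", 1, 1.54), c("C", "C", 2, 1.34), c("C", "C", 3, 1.20),
    c("C", "N", 1, 1.47), c("C", "N", 2, 1.29), c("C", "N", 3, 1.16),
    c("C", "O", 1, 1.43), c("C", "O", 2, 1.22),
    c("C", "S", 1, 1.82), c("C", "S", 2, 1.60),
    c("C", "F", 1, 1.35), c("C", "CL", 1, 1.77),
    c("C", "BR", 1, 1.94), c("C", "I", 1, 2.14),
    c("N", "N", 1, 1.45), c("N", "N", 2, 1.25), c("N", "N", 3, 1.10),
    c("N", "O", 1, 1.40), c("N", "O", 2, 1.21),
    c("O", "O", 1, 1.48), c("O", "O", 2, 1.21),
    c("S", "O", 1, 1.57), c("S", "O", 2, 1.44),
    c("S", "S", 1, 2.05),
    c("P", "O", 1, 1.63), c("P", "O", 2, 1.48),
    c("C", "H", 1, 1.09), c("N", "H", 1, 1.01),
    c("O", "H", 1, 0.96), c("S", "H", 1, 1.34)
  )
  data.frame(a = tab[, 1], b = tab[, 2],
             order = as.numeric(tab[, 3]), length = as.numeric(tab[, 4]),
             stringsAsFactors = FALSE)
})

## ideal VSEPR angles (degrees) per central-atom hybridization
.ligdyn_ideal_angles <- c(sp3 = 109.47, sp2 = 120, sp = 180)

.norm_element <- function(element) {
  e <- toupper(trimws(element))
  e[e == "D"] <- "H"
  e
}

#' Look up element properties
#'
#' Returns masses, covalent radii or van der Waals radii for a vector of
#' element symbols from the package's periodic-table subset.
#'
#' @param element character vector of element symbols (case-insensitive).
#' @param what one of `"mass"`, `"r_cov"`, `"r_vdw"`, `"max_bonds"`.
#' @param strict if `TRUE` (default), an unknown element is an error;
#'   otherwise `NA` is returned for unknown symbols.
#' @return numeric vector aligned with `element`.
#' @export
element_property <- function(element, what = c("mass", "r_cov", "r_vdw", "max_bonds"),
                             strict = TRUE) {
  what <- match.arg(what)
  e <- .norm_element(element)
  idx <- match(e, .ligdyn_elements$element)
  if (strict && anyNA(idx)) {
    bad <- unique(e[is.na(idx)])
    stop_ligdyn("validation",
                sprintf("unsupported element(s): %s (supported: %s)",
                        paste(bad, collapse = ", "),
                        paste(.ligdyn_elements$element, collapse = ", ")))
  }
  .ligdyn_elements[[what]][idx]
}

## reference length for an element pair at a bond order; NA when unknown
.ref_bond_length <- function(ea, eb, order = 1) {
  ea <- .norm_element(ea); eb <- .norm_element(eb)
  lo <- pmin(ea, eb); hi <- pmax(ea, eb)
  tab <- .ligdyn_ref_bonds
  key_t <- paste(pmin(tab$a, tab$b), pmax(tab$a, tab$b), tab$order)
  unname(tab$length[match(paste(lo, hi, order), key_t)])
}
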