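#' @keywords internal
"_PACKAGE"

# Element-level property tables. Radii are the Bondi van der Waals set (A).
# Lennard-Jones well depths (kcal/mol) follow the Tripos-style sp3 values;
# the probe epsilon (0.107, sp3 carbon) pairs with these via Lorentz-Berthelot.
# Hydrophobicity values are coarse element-level atomic logP contributions
# (Crippen-style); adequate for field generation on pseudo-molecules where
# full atom typing is undefined.
.element_table <- data.frame(
  element        = c("H",   "C",   "N",    "O",    "F",   "P",   "S",   "Cl",  "Br",  "I"),
  vdw_radius     = c(1.20,  1.70,  1.55,   1.52,   1.47,  1.80,  1.80,  1.75,  1.85,  1.98),
  lj_epsilon     = c(0.042, 0.107, 0.095,  0.116,  0.109, 0.314, 0.314, 0.314, 0.434, 0.623),
  hydrophobicity = c(0.123, 0.272, -0.600, -0.170, 0.220, 0.000, 0.255, 0.320, 0.850, 0.890),
  stringsAsFactors = FALSE
)

.element_row <- function(element) {
  i <- match(element, .element_table$element)
  if (anyNA(i)) {
    stop("unknown element(s): ",
         paste(unique(element[is.na(i)]), collapse = ", "))
  }
  .element_table[i, , drop = FALSE]
}

#' Look up built-in per-element physicochemical parameters
#'
#' Returns the van der Waals radius (Bondi, in Angstrom), Lennard-Jones well
#' depth (kcal/mol) and element-level hydrophobicity contribution used when
#' assigning atom properties.
#'
#' @param element character vector of element symbols.
#' @return data.frame with one row per requested element.
#' @export
#' @examples
#' element_parameters(c("C", "O"))
element_parameters <- function(element) {
  out <- .element_row(element)
  rownames(out) <- NULL
  out
}
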