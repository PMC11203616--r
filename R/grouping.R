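#' Periodic-table element grouping
#'
#' Molecular graphs in this package carry a chemical-element symbol on every
#' node. To keep the number of node types (and the length of one-hot species
#' encodings) manageable, elements are collapsed into eight groups: the five
#' organochemical workhorses carbon, nitrogen, oxygen, phosphorus and sulfur
#' keep singleton groups, while the remaining elements fall into metals,
#' metalloids and halogens by their standard periodic-table classification.
#'
#' `element_grouping()` builds the grouping object. The default table covers
#' the elements found in common medicinal-chemistry datasets (heavy-atom
#' graphs; hydrogen is not listed and must be added explicitly by users whose
#' encodings keep explicit hydrogens). Both arguments can be overridden to
#' supply a custom table.
#'
#' @param group_names Ordered character vector of exactly 8 group names.
#' @param element_to_group Named integer vector mapping element symbols to a
#'   group index in `1:8`. Defaults to the shipped periodic-table table.
#' @return An object of class `element_grouping` with fields `group_names`
#'   and `element_to_group`.
#' @examples
#' grp <- element_grouping()
#' element_to_group("Cl", grp) # 3, a halogen
#' @export
element_grouping <- function(group_names = compgnn_group_names,
                             element_to_group = compgnn_element_table) {
  if (length(group_names) != 8L) {
    stop("an element grouping must have exactly 8 groups, got ",
         length(group_names), call. = FALSE)
  }
  if (is.null(names(element_to_group)) || any(!nzchar(names(element_to_group)))) {
    stop("'element_to_group' must be a named vector of group indices",
         call. = FALSE)
  }
  idx <- as.integer(element_to_group)
  if (anyNA(idx) || any(idx < 1L | idx > 8L)) {
    stop("group indices must all lie in 1..8", call. = FALSE)
  }
  if (anyDuplicated(names(element_to_group))) {
    stop("each element symbol may appear only once in the grouping table",
         call. = FALSE)
  }
  structure(
    list(group_names = as.character(group_names),
         element_to_group = stats::setNames(idx, names(element_to_group))),
    class = "element_grouping"
  )
}

#' @export
print.element_grouping <- function(x, ...) {
  cat("<element_grouping>: 8 groups,", length(x$element_to_group),
      "elements\n")
  for (i in seq_len(8L)) {
    el <- names(x$element_to_group)[x$element_to_group == i]
    cat(sprintf("  %d-%s: %s\n", i, x$group_names[i],
                paste(el, collapse = " ")))
  }
  invisible(x)
}

#' The canonical eight group names, in their fixed order
#' @export
compgnn_group_names <- c("Metals", "Metalloids", "Halogens", "Carbon",
                         "Nitrogen", "Oxygen", "Phosphorus", "Sulfur")

# The default element -> group table. Heavy-atom coverage for drug-like and
# screening chemistry: singletons for C/N/O/P/S; halogens F..At; metalloids
# B/Si/Ge/As/Sb/Te (+Se, often classed with them); everything metallic in
# group 1 (alkali, alkaline-earth, transition, post-transition, lanthanides,
# actinides).
.metals <- c(
  "Li", "Na", "K", "Rb", "Cs", "Fr",
  "Be", "Mg", "Ca", "Sr", "Ba", "Ra",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd",
  "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Al", "Ga", "In", "Tl", "Sn", "Pb", "Bi", "Po",
  "La", "Ce", "Pr", "Nd", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho",
  "Er", "Tm", "Yb", "Lu", "Ac", "Th", "Pa", "U", "Np", "Pu"
)
.metalloids <- c("B", "Si", "Ge", "As", "Sb", "Te", "Se")
.halogens <- c("F", "Cl", "Br", "I", "At")

#' The shipped element-to-group table (named integer vector)
#' @export
compgnn_element_table <- stats::setNames(
  c(rep(1L, length(.metals)), rep(2L, length(.metalloids)),
    rep(3L, length(.halogens)), 4L, 5L, 6L, 7L, 8L),
  c(.metals, .metalloids, .halogens, "C", "N", "O", "P", "S")
)

#' Map an element symbol to its group index
#'
#' @param symbol Character vector of element symbols.
#' @param grouping An [element_grouping()].
#' @return Integer vector of group indices in `1:8`.
#' @examples
#' element_to_group(c("C", "O", "Fe"), element_grouping())
#' @export
element_to_group <- function(symbol, grouping = element_grouping()) {
  stopifnot(inherits(grouping, "element_grouping"))
  idx <- grouping$element_to_group[symbol]
  if (anyNA(idx)) {
    bad <- unique(symbol[is.na(idx)])
    stop("unsupported element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(idx)
}
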