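#' Atom parameter table
#'
#' Loads the per-(residue, atom) parameter table used to assign radii,
#' partial charges, Lennard-Jones parameters and hydrogen-bond donor /
#' acceptor flags to structures.  Radii are a NACCESS-style united-atom
#' set keyed by element (C 1.87, N 1.65, O 1.40, S 1.85, H 1.00 A);
#' charges are simplified residue-level formal charges (Asp/Glu -0.5 on
#' each carboxylate oxygen, Lys +1 on NZ, Arg +0.5 on each terminal
#' nitrogen, His neutral).  LJ well depths (kcal/mol) and minimum-energy
#' distances Rmin (A) are a compact element-level set; pairwise values
#' use Lorentz-Berthelot combination.
#'
#' @param residue_file,element_file Optional paths overriding the tables
#'   shipped with the package.
#' @return An object of class `param_table`: a list with elements
#'   `residues` (data.frame: residue, atom, element, charge, donor,
#'   acceptor) and `elements` (data.frame: element, radius, eps, rmin).
#' @export
default_param_table <- function(residue_file = NULL, element_file = NULL) {
  if (is.null(residue_file))
    residue_file <- system.file("extdata", "residue_params.tsv",
                                package = "terndock", mustWork = TRUE)
  if (is.null(element_file))
    element_file <- system.file("extdata", "element_params.tsv",
                                package = "terndock", mustWork = TRUE)
  res <- utils::read.table(residue_file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  el <- utils::read.table(element_file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(el$eps >= 0), all(el$rmin > 0), all(el$radius > 0))
  pt <- list(residues = res, elements = el)
  class(pt) <- "param_table"
  pt
}

#' Side-chain atoms of a residue type beyond the beta carbon
#'
#' Heavy atoms of `residue` listed in the parameter table that are
#' removed by an alanine truncation (everything outside the backbone +
#' CB set).  Used by [mutate_to_alanine()] and by topology-count checks.
#'
#' @param param_table A [default_param_table()] object.
#' @param residue 3-letter residue name.
#' @return Character vector of atom names (may be empty).
#' @export
sidechain_beyond_cb <- function(param_table, residue) {
  rows <- param_table$residues[param_table$residues$residue == residue, ]
  keep <- c("N", "CA", "C", "O", "OXT", "CB")
  heavy <- rows$atom[rows$element != "H"]
  setdiff(heavy, keep)
}

# element lookup with fallback row "X"
.element_params <- function(param_table, element) {
  el <- param_table$elements
  i <- match(element, el$element)
  i[is.na(i)] <- match("X", el$element)
  el[i, , drop = FALSE]
}

# Assign radius/charge/eps/rmin/donor/acceptor columns to an atom table.
# Lookup is by (residue, atom name); atoms absent from the table fall
# back to element defaults with zero charge and no donor/acceptor flag.
.parameterize_atoms <- function(atoms, param_table) {
  key <- paste(atoms$resname, atoms$name)
  rkey <- paste(param_table$residues$residue, param_table$residues$atom)
  i <- match(key, rkey)
  elem <- atoms$element
  known <- !is.na(i)
  elem[known] <- param_table$residues$element[i[known]]
  ep <- .element_params(param_table, elem)
  atoms$element <- elem
  atoms$radius <- ep$radius
  atoms$eps <- ep$eps
  atoms$rmin <- ep$rmin
  atoms$charge <- ifelse(known, param_table$residues$charge[i], 0)
  atoms$donor <- ifelse(known, param_table$residues$donor[i] == 1, FALSE)
  atoms$acceptor <- ifelse(known, param_table$residues$acceptor[i] == 1, FALSE)
  atoms
}
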