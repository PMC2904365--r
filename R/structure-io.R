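#' Read a PDB file into a structure3d
#'
#' Parses ATOM/HETATM records (water HETATMs skipped by default) via
#' bio3d, keeping alternate location 'A' or blank only.  MODEL blocks
#' become frames; a file without MODEL records yields one frame.
#' Radii, charges, LJ parameters and donor/acceptor flags are assigned
#' from `param_table`.
#'
#' @param path PDB file path.
#' @param param_table A [default_param_table()] (default: the shipped one).
#' @param keep_water Keep water HETATM records (default FALSE).
#' @return A [new_structure()] object.
#' @export
load_structure <- function(path, param_table = default_param_table(),
                           keep_water = FALSE) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("PDB parse error in ", path, ": ",
                                           conditionMessage(e)))
  at <- pdb$atom
  keep <- at$alt %in% c("", "A") | is.na(at$alt)
  if (!keep_water) keep <- keep & !(at$resid %in% c("HOH", "WAT", "DOD"))
  if (!any(keep)) stop("empty structure: no atoms in ", path)
  sel <- which(keep)
  elem <- at$elesy[sel]
  elem[is.na(elem)] <- ""
  atoms <- data.frame(
    serial = at$eleno[sel],
    name = at$elety[sel],
    element = trimws(elem),
    resname = at$resid[sel],
    resno = at$resno[sel],
    chain = ifelse(is.na(at$chain[sel]), " ", at$chain[sel]),
    ins = ifelse(is.na(at$insert[sel]), "", at$insert[sel]),
    stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  frames <- lapply(seq_len(nrow(xyz)), function(i) {
    m <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    m[sel, , drop = FALSE]
  })
  new_structure(atoms, frames, param_table = param_table)
}

#' Write a structure3d to a PDB file
#'
#' Multi-frame structures are written as MODEL/ENDMDL blocks; chain ids
#' and residue numbers are preserved.  Coordinates are written at PDB
#' precision (0.001 A).
#'
#' @param structure A [new_structure()] object.
#' @param path Output file path.
#' @export
save_structure <- function(structure, path) {
  if (n_atoms(structure) == 0L) stop("empty structure")
  at <- structure$atoms
  xyz <- do.call(rbind, lapply(structure$coords, function(m) as.vector(t(m))))
  ok <- tryCatch({
    bio3d::write.pdb(file = path,
                     xyz = bio3d::as.xyz(xyz),
                     type = rep("ATOM", nrow(at)),
                     eleno = at$serial, elety = at$name,
                     resid = at$resname, chain = at$chain, resno = at$resno,
                     insert = at$ins,
                     elesy = at$element)
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ",
                              conditionMessage(e)))
  invisible(ok)
}
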