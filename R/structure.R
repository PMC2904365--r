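#' Molecular structure container
#'
#' A `structure3d` holds an ordered atom table plus one or more frames
#' (coordinate sets), e.g. the models of a multi-model PDB file used as
#' a trajectory carrier.  Atoms carry PDB identity (name, residue,
#' chain), element, and the parameterization columns (radius, charge,
#' LJ eps/rmin, donor/acceptor flags) assigned from a [default_param_table()].
#'
#' @param atoms data.frame with columns serial, name, element, resname,
#'   resno, chain (and optionally ins); further columns are kept.
#' @param coords a single n x 3 matrix or a list of congruent n x 3
#'   matrices (one per frame), coordinates in Angstrom.
#' @param param_table optional [default_param_table()]; when supplied,
#'   radii/charges/LJ/donor-acceptor columns are (re)assigned.
#' @return An object of class `structure3d`.
#' @export
new_structure <- function(atoms, coords, param_table = NULL) {
  if (is.matrix(coords)) coords <- list(coords)
  n <- nrow(atoms)
  if (n == 0L) stop("empty structure: no atoms")
  for (fr in coords) {
    if (!is.matrix(fr) || nrow(fr) != n || ncol(fr) != 3)
      stop("frame with mismatched atom count")
    if (!all(is.finite(fr))) stop("non-finite coordinates")
  }
  if (is.null(atoms$ins)) atoms$ins <- ""
  if (is.null(atoms$element) || any(!nzchar(atoms$element)))
    atoms$element <- .guess_element(atoms$name, atoms$element)
  key <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$name)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom name) triple: ",
         key[duplicated(key)][1])
  rownames(atoms) <- NULL
  if (!is.null(param_table)) atoms <- .parameterize_atoms(atoms, param_table)
  s <- list(atoms = atoms, coords = lapply(coords, unname))
  class(s) <- "structure3d"
  s
}

.guess_element <- function(name, element = NULL) {
  out <- if (is.null(element)) rep("", length(name)) else element
  miss <- !nzchar(out)
  nm <- toupper(sub("^[0-9]+", "", name[miss]))
  out[miss] <- ifelse(grepl("^H", nm), "H", substr(nm, 1, 1))
  out
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("<structure3d> %d atoms, %d frame(s), chains: %s\n",
              n_atoms(x), n_frames(x),
              paste(sort(unique(x$atoms$chain)), collapse = " ")))
  invisible(x)
}

#' @rdname new_structure
#' @param structure A `structure3d`.
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' @rdname new_structure
#' @export
n_frames <- function(structure) length(structure$coords)

#' Coordinates of one frame
#' @param structure A `structure3d`.
#' @param frame Frame index (default 1).
#' @return n x 3 matrix, Angstrom.
#' @export
frame_coords <- function(structure, frame = 1L) {
  if (frame < 1L || frame > n_frames(structure))
    stop("frame index out of range")
  structure$coords[[frame]]
}

#' Replace all frames with a single coordinate set
#' @keywords internal
set_coords <- function(structure, xyz) {
  structure$coords <- list(unname(xyz))
  structure
}

#' Subset a structure by atom indices (all frames)
#' @param structure A `structure3d`.
#' @param idx Integer or logical atom index.
#' @return A `structure3d` with the selected atoms.
#' @export
subset_structure <- function(structure, idx) {
  at <- structure$atoms[idx, , drop = FALSE]
  rownames(at) <- NULL
  s <- list(atoms = at, coords = lapply(structure$coords,
                                        function(m) m[idx, , drop = FALSE]))
  class(s) <- "structure3d"
  s
}

#' Concatenate two structures frame-wise
#'
#' Used e.g. to compute the ASA of a complex A+B.  Both structures must
#' have the same frame count; chains may not share (chain, resno, name)
#' triples.
#' @param a,b `structure3d` objects.
#' @return A combined `structure3d`.
#' @export
combine_structures <- function(a, b) {
  if (n_frames(a) != n_frames(b)) stop("frame count mismatch")
  atoms <- rbind(a$atoms, b$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  coords <- Map(rbind, a$coords, b$coords)
  new_structure(atoms, coords)
}

#' Atom indices of one residue
#' @param structure A `structure3d`.
#' @param chain Chain id.
#' @param resno Residue number.
#' @return Integer vector of atom row indices (may be empty).
#' @export
residue_atoms <- function(structure, chain, resno) {
  which(structure$atoms$chain == chain & structure$atoms$resno == resno)
}

#' Atom indices of one or more chains
#' @inheritParams residue_atoms
#' @param chains Character vector of chain ids.
#' @export
chain_atoms <- function(structure, chains) {
  which(structure$atoms$chain %in% chains)
}

# heavy-atom mask
.heavy <- function(structure) structure$atoms$element != "H"
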