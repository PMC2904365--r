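#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation (det +1) and translation minimizing the
#' RMSD of `mobile` onto `reference`.
#'
#' @param mobile,reference n x 3 coordinate matrices, equal n >= 3.
#' @return list(rotation = 3x3 matrix, translation = length-3 vector,
#'   rmsd = Angstrom); the aligned coordinates are
#'   `mobile %*% t(rotation) + translation` (row-vector convention).
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3 ||
      ncol(reference) != 3)
    stop("coordinate sets must be n x 3 with equal n")
  if (nrow(mobile) < 3) stop("need at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  x <- sweep(mobile, 2, cm); y <- sweep(reference, 2, cr)
  if (qr(x)$rank < 2) stop("degenerate (collinear) point set")
  h <- crossprod(x, y)                       # 3x3 covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)  # maps x rows: x %*% t(rot)
  trans <- as.numeric(cr - rot %*% cm)
  fitted <- mobile %*% t(rot) + rep(trans, each = nrow(mobile))
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  list(rotation = rot, translation = trans, rmsd = rmsd)
}

#' RMSD without fitting
#' @param a,b n x 3 matrices in the same frame.
#' @return Root-mean-square deviation in Angstrom.
#' @export
rmsd_raw <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("dimension mismatch")
  sqrt(mean(rowSums((a - b)^2)))
}

#' Per-frame RMSD of a multi-frame structure to a reference frame
#'
#' Each frame's selected atoms are best-fit superposed onto the
#' reference frame's selection before the RMSD is taken.
#'
#' @param structure A multi-frame [new_structure()] object.
#' @param reference_frame Frame index used as reference (default 1).
#' @param selection Integer/logical atom index (default: all atoms).
#' @param fit Superpose before measuring (default TRUE).
#' @return Numeric vector, one RMSD (Angstrom) per frame.
#' @export
frame_rmsd <- function(structure, reference_frame = 1L, selection = NULL,
                       fit = TRUE) {
  if (is.null(selection)) selection <- seq_len(n_atoms(structure))
  if (length(selection) == 0L ||
      (is.logical(selection) && !any(selection)))
    stop("empty selection")
  ref <- frame_coords(structure, reference_frame)[selection, , drop = FALSE]
  vapply(seq_len(n_frames(structure)), function(i) {
    m <- frame_coords(structure, i)[selection, , drop = FALSE]
    if (fit) superpose(m, ref)$rmsd else rmsd_raw(m, ref)
  }, numeric(1))
}

#' Per-atom RMSF over a trajectory
#'
#' Frames are superposed onto the reference frame over the selection;
#' the fluctuation is the per-atom RMS deviation from the mean fitted
#' structure.
#'
#' @inheritParams frame_rmsd
#' @return Numeric vector, one RMSF (Angstrom) per selected atom.
#' @export
frame_rmsf <- function(structure, selection = NULL, reference_frame = 1L) {
  if (is.null(selection)) selection <- seq_len(n_atoms(structure))
  if (length(selection) == 0L ||
      (is.logical(selection) && !any(selection)))
    stop("empty selection")
  ref <- frame_coords(structure, reference_frame)[selection, , drop = FALSE]
  fitted <- lapply(seq_len(n_frames(structure)), function(i) {
    m <- frame_coords(structure, i)[selection, , drop = FALSE]
    sp <- superpose(m, ref)
    m %*% t(sp$rotation) + rep(sp$translation, each = nrow(m))
  })
  mean_xyz <- Reduce(`+`, fitted) / length(fitted)
  dev2 <- lapply(fitted, function(m) rowSums((m - mean_xyz)^2))
  sqrt(Reduce(`+`, dev2) / length(dev2))
}
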