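#' Deterministic rotational sweep
#'
#' Rotations are generated as Rz(phi) Ry(theta) Rz(psi) with axis
#' directions (theta, phi) on a golden-section spiral whose mean
#' spacing equals `step_deg`, and twist angles psi swept in `step_deg`
#' increments.  The first rotation is the identity.
#'
#' @param step_deg Angular step in degrees.
#' @return list of 3x3 rotation matrices.
#' @export
rotation_set <- function(step_deg) {
  s <- step_deg * pi / 180
  n_dir <- max(1L, as.integer(ceiling(4 * pi / s^2 * 2 / sqrt(3))))
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n_dir)
  z <- if (n_dir == 1) 1 else 1 - 2 * (i - 1) / (n_dir - 1)
  z <- pmin(1, pmax(-1, z))
  theta <- acos(z)
  phi <- (i - 1) * golden
  psi <- seq(0, 2 * pi - s / 2, by = s)
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1),
                           3, 3)
  ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)),
                           3, 3)
  out <- vector("list", n_dir * length(psi))
  k <- 0L
  for (d in seq_len(n_dir)) {
    rd <- rz(phi[d]) %*% ry(theta[d])
    for (p in psi) {
      k <- k + 1L
      out[[k]] <- rd %*% rz(p)
    }
  }
  out
}

#' Rigid-body pose
#'
#' A pose places the mobile structure by rotating it about `center`
#' (its centroid at docking time) and translating:
#' `posed = (x - center) %*% t(rotation) + center + translation`.
#'
#' @param rotation 3x3 orthonormal matrix.
#' @param translation Length-3 vector (A), lattice-aligned when produced
#'   by [dock()].
#' @param center Rotation center (A).
#' @param shape_score Integer-valued grid correlation score.
#' @param elec_energy Coulombic screening energy, kcal/mol (NA before
#'   [electrostatic_screen()]).
#' @param rank Rank by shape score (1 = best).
#' @param id Stable pose identifier.
#' @return list of class `dock_pose`.
#' @export
new_pose <- function(rotation, translation, center,
                     shape_score = NA_real_, elec_energy = NA_real_,
                     rank = NA_integer_, id = NA_integer_) {
  p <- list(rotation = rotation, translation = as.numeric(translation),
            center = as.numeric(center), shape_score = shape_score,
            elec_energy = elec_energy, rank = as.integer(rank),
            id = as.integer(id))
  class(p) <- "dock_pose"
  p
}

#' Apply a pose to coordinates or to a structure
#' @param pose A [new_pose()].
#' @param x An n x 3 coordinate matrix or a `structure3d` (frame 1).
#' @return Posed coordinates (matrix) or posed structure.
#' @export
pose_apply <- function(pose, x) {
  if (inherits(x, "structure3d")) {
    xyz <- pose_apply(pose, frame_coords(x, 1L))
    return(set_coords(x, xyz))
  }
  sweep(x, 2, pose$center) %*% t(pose$rotation) +
    rep(pose$center + pose$translation, each = nrow(x))
}

#' Ligand RMSD between two poses of the same mobile structure
#' @param pose,reference [new_pose()] objects.
#' @param mobile The mobile `structure3d`.
#' @param selection Optional atom index (default: all atoms).
#' @return RMSD in Angstrom (no refitting; both poses share the static
#'   frame).
#' @export
pose_rmsd <- function(pose, reference, mobile, selection = NULL) {
  xyz <- frame_coords(mobile, 1L)
  if (!is.null(selection)) xyz <- xyz[selection, , drop = FALSE]
  a <- pose_apply(pose, xyz)
  b <- pose_apply(reference, xyz)
  rmsd_raw(a, b)
}

#' The identity pose of a mobile structure
#' @param mobile The mobile `structure3d`.
#' @return A [new_pose()] that leaves `mobile` where it is.
#' @export
identity_pose <- function(mobile) {
  new_pose(diag(3), c(0, 0, 0), colMeans(frame_coords(mobile, 1L)),
           id = 0L)
}

# top-k values of a numeric array; returns list(score, index) ordered
# by score descending, lexicographic 0-based index on ties
.top_k <- function(v, k) {
  k <- min(k, length(v))
  th <- -sort(-v, partial = k)[k]
  idx <- which(v >= th)
  idx <- idx[order(-v[idx], idx)][seq_len(k)]
  list(score = v[idx], index = idx)
}

#' FFT rigid-body docking
#'
#' For each rotation of a deterministic angular sweep the mobile
#' structure is digitized and cross-correlated with the static grid via
#' FFT; the `best_per_rotation` translations per rotation are pooled and
#' the top `n_poses_kept` by shape score are returned (positive scores
#' only).  Two rotations are evaluated per complex FFT by packing their
#' real grids into the real and imaginary parts.  Ties are broken by
#' lower rotation index, then lexicographic translation.
#'
#' @param static,mobile [new_structure()] objects; `static` should be
#'   the larger (roles are swapped with a warning otherwise).
#' @param params A [dock_params()] object.
#' @param seed Integer recorded for provenance; the sweep itself is
#'   deterministic.
#' @return list of class `pose_set`: poses (list of [new_pose()]),
#'   params, n_rotations.
#' @export
dock <- function(static, mobile, params = dock_params(), seed = 1L) {
  if (n_atoms(static) == 0L || n_atoms(mobile) == 0L)
    stop("empty structure")
  if (n_atoms(mobile) > n_atoms(static)) {
    warning("mobile is larger than static; swapping roles")
    tmp <- static; static <- mobile; mobile <- tmp
  }
  n <- params$grid_dim; res <- params$resolution
  ext <- function(s) {
    xyz <- frame_coords(s, 1L); r <- s$atoms$radius
    max(apply(xyz, 2, function(x) diff(range(x))) + 2 * max(r))
  }
  if (ext(static) + ext(mobile) > n * res)
    stop("grid overflow: combined extents exceed the zero-padded grid")
  sg <- discretize(static, params, "static")
  fs <- stats::fft(sg$values)
  n3 <- n^3
  cm <- colMeans(frame_coords(mobile, 1L))
  xyz0 <- sweep(frame_coords(mobile, 1L), 2, cm)
  radii <- mobile$atoms$radius
  om <- cm - res * (n - 1) / 2          # mobile grid origin (centroid-centred)
  rots <- rotation_set(params$rotation_step)
  nr <- length(rots)
  mob_grid <- function(rot) {
    xyz <- xyz0 %*% t(rot) + rep(cm, each = nrow(xyz0))
    og <- .occupancy_grid(xyz, radii, n, res, origin = om)
    g <- array(0, dim = c(n, n, n)); g[og$occ] <- 1
    g
  }
  kbest <- params$best_per_rotation
  recs <- vector("list", nr)
  harvest <- function(sc, ri) {
    tk <- .top_k(sc, kbest)
    cbind(rot = ri, score = tk$score, index = tk$index)
  }
  i <- 1L
  while (i <= nr) {
    if (i < nr) {
      packed <- mob_grid(rots[[i]]) + 1i * mob_grid(rots[[i + 1L]])
      cc <- stats::fft(fs * Conj(stats::fft(packed)), inverse = TRUE) / n3
      # conj(F[a + ib]) = conj(Fa) - i conj(Fb); both correlations real
      recs[[i]] <- harvest(round(Re(cc)), i)
      recs[[i + 1L]] <- harvest(round(-Im(cc)), i + 1L)
      i <- i + 2L
    } else {
      cc <- Re(stats::fft(fs * Conj(stats::fft(mob_grid(rots[[i]]))),
                          inverse = TRUE)) / n3
      recs[[i]] <- harvest(round(cc), i)
      i <- i + 1L
    }
  }
  pool <- do.call(rbind, recs)
  pool <- pool[pool[, "score"] > 0, , drop = FALSE]
  if (nrow(pool) == 0L) {
    warning("no positive-score pose")
    out <- list(poses = list(), params = params, n_rotations = nr,
                seed = seed)
    class(out) <- "pose_set"
    return(out)
  }
  ord <- order(-pool[, "score"], pool[, "rot"], pool[, "index"])
  pool <- pool[ord, , drop = FALSE]
  pool <- pool[seq_len(min(params$n_poses_kept, nrow(pool))), ,
               drop = FALSE]
  wrap <- function(d) ifelse(d > n / 2, d - n, d)
  poses <- lapply(seq_len(nrow(pool)), function(j) {
    idx <- pool[j, "index"] - 1
    d <- c(idx %% n, (idx %/% n) %% n, idx %/% (n * n))
    tau <- (sg$origin - om) + wrap(d) * res
    new_pose(rots[[pool[j, "rot"]]], tau, cm,
             shape_score = pool[j, "score"], rank = j, id = j)
  })
  out <- list(poses = poses, params = params, n_rotations = nr, seed = seed)
  class(out) <- "pose_set"
  out
}

#' @export
print.pose_set <- function(x, ...) {
  cat(sprintf("<pose_set> %d poses (%d rotations swept)\n",
              length(x$poses), x$n_rotations))
  invisible(x)
}

# Coulomb energy between two coordinate/charge sets with the
# distance-dependent dielectric eps(r) = 4r:  E = 332.0637 qi qj / (4 r^2)
.coulomb_dd <- function(xa, qa, xb, qb) {
  ia <- which(qa != 0); ib <- which(qb != 0)
  if (!length(ia) || !length(ib)) return(0)
  d2 <- outer(rowSums(xa[ia, , drop = FALSE]^2),
              rowSums(xb[ib, , drop = FALSE]^2), `+`) -
    2 * xa[ia, , drop = FALSE] %*% t(xb[ib, , drop = FALSE])
  d2[d2 < 1e-6] <- 1e-6
  sum(332.0637 * outer(qa[ia], qb[ib]) / (4 * d2))
}

#' Coulombic binary filter
#'
#' Computes, for each pose, the screened Coulomb energy between static
#' and posed mobile charges with a distance-dependent dielectric
#' eps(r) = 4r, and removes poses with repulsive (positive) energy.
#' Retained poses keep their order and are re-ranked.
#'
#' @param poses A `pose_set` or list of [new_pose()] objects.
#' @param static,mobile The docked structures.
#' @return Same type as `poses`, each retained pose carrying
#'   `elec_energy` (kcal/mol).
#' @export
electrostatic_screen <- function(poses, static, mobile) {
  plist <- if (inherits(poses, "pose_set")) poses$poses else poses
  xs <- frame_coords(static, 1L); qs <- static$atoms$charge
  xm <- frame_coords(mobile, 1L); qm <- mobile$atoms$charge
  kept <- list()
  for (p in plist) {
    e <- .coulomb_dd(xs, qs, pose_apply(p, xm), qm)
    if (e <= 0) {
      p$elec_energy <- e
      p$rank <- length(kept) + 1L
      kept[[length(kept) + 1L]] <- p
    }
  }
  if (inherits(poses, "pose_set")) {
    poses$poses <- kept
    poses
  } else kept
}

#' Pose list as a data.frame
#' @param poses A `pose_set` or list of poses.
#' @return data.frame: id, rank, shape_score, elec_energy, r11..r33
#'   (row-major rotation), t1..t3, c1..c3.
#' @export
poses_to_table <- function(poses) {
  plist <- if (inherits(poses, "pose_set")) poses$poses else poses
  if (!length(plist))
    return(data.frame(id = integer(), rank = integer(),
                      shape_score = numeric(), elec_energy = numeric()))
  do.call(rbind, lapply(plist, function(p) {
    r <- as.vector(t(p$rotation))
    d <- data.frame(id = p$id, rank = p$rank, shape_score = p$shape_score,
                    elec_energy = p$elec_energy)
    for (k in 1:9) d[[paste0("r", (k - 1) %/% 3 + 1, (k - 1) %% 3 + 1)]] <- r[k]
    for (k in 1:3) d[[paste0("t", k)]] <- p$translation[k]
    for (k in 1:3) d[[paste0("c", k)]] <- p$center[k]
    d
  }))
}

#' Materialize a pose list as a multi-frame structure
#'
#' Each pose becomes one frame holding the posed mobile coordinates, so
#' the whole candidate set can be written as a multi-model PDB via
#' [save_structure()].
#'
#' @param poses A `pose_set` or list of poses.
#' @param mobile The mobile `structure3d`.
#' @return A multi-frame `structure3d` (one frame per pose).
#' @export
poses_as_frames <- function(poses, mobile) {
  plist <- if (inherits(poses, "pose_set")) poses$poses else poses
  if (!length(plist)) stop("empty pose list")
  xyz <- frame_coords(mobile, 1L)
  s <- mobile
  s$coords <- lapply(plist, function(p) pose_apply(p, xyz))
  s
}

#' Rebuild a pose list from [poses_to_table()] output
#' @param tab data.frame as written by [poses_to_table()].
#' @return list of [new_pose()] objects.
#' @export
table_to_poses <- function(tab) {
  lapply(seq_len(nrow(tab)), function(i) {
    r <- matrix(as.numeric(tab[i, paste0("r", c(11, 12, 13, 21, 22, 23,
                                                31, 32, 33))]),
                3, 3, byrow = TRUE)
    new_pose(r, as.numeric(tab[i, c("t1", "t2", "t3")]),
             as.numeric(tab[i, c("c1", "c2", "c3")]),
             shape_score = tab$shape_score[i],
             elec_energy = tab$elec_energy[i],
             rank = tab$rank[i], id = tab$id[i])
  })
}
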