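#' Docking parameters
#'
#' @param grid_dim Grid points per axis N (grid is N^3).
#' @param resolution Grid spacing, Angstrom per cell.
#' @param surface_thickness Thickness of the static surface layer (A).
#' @param core_penalty Negative weight for static-core cells (rho).
#' @param rotation_step Angular step of the rotational sweep, degrees.
#' @param n_poses_kept Number of top-scoring poses returned.
#' @param best_per_rotation Translations pooled per rotation.
#' @param electrostatic_filter Apply the Coulombic binary filter.
#' @return list of class `dock_params`.
#' @export
dock_params <- function(grid_dim = 64L, resolution = 1.0,
                        surface_thickness = 1.3, core_penalty = -15,
                        rotation_step = 15, n_poses_kept = 10000L,
                        best_per_rotation = 3L,
                        electrostatic_filter = TRUE) {
  stopifnot(grid_dim > 0, resolution > 0, core_penalty < 0,
            n_poses_kept >= 1, surface_thickness >= 0, rotation_step > 0)
  p <- list(grid_dim = as.integer(grid_dim), resolution = resolution,
            surface_thickness = surface_thickness,
            core_penalty = core_penalty, rotation_step = rotation_step,
            n_poses_kept = as.integer(n_poses_kept),
            best_per_rotation = as.integer(best_per_rotation),
            electrostatic_filter = isTRUE(electrostatic_filter))
  class(p) <- "dock_params"
  p
}

# occupancy array for coordinates xyz with per-atom radii, centered grid.
# A cell is occupied iff its center lies within an atom's radius.
.occupancy_grid <- function(xyz, radii, n, res, origin = NULL) {
  if (is.null(origin)) {
    ctr <- colMeans(xyz)
    origin <- ctr - res * (n - 1) / 2
  }
  lo <- origin - res / 2
  hi <- origin + res * (n - 1) + res / 2
  if (any(xyz - radii < rep(lo, each = nrow(xyz))) ||
      any(xyz + radii > rep(hi, each = nrow(xyz))))
    stop("grid overflow: structure exceeds grid extent")
  occ <- array(FALSE, dim = c(n, n, n))
  # group atoms by radius so one integer-offset template serves each group
  for (r in unique(radii)) {
    sel <- which(radii == r)
    g <- sweep(xyz[sel, , drop = FALSE], 2, origin) / res  # 0-based float
    i0 <- round(g)
    frac <- g - i0
    m <- ceiling(r / res + 0.5 * sqrt(3))
    dd <- seq(-m, m)
    tpl <- as.matrix(expand.grid(dx = dd, dy = dd, dz = dd))
    tpl <- tpl[rowSums(tpl^2) <= (r / res + 0.5 * sqrt(3))^2 + 1e-9, ,
               drop = FALSE]
    nt <- nrow(tpl); na <- length(sel)
    # (nt x na) squared distance from cell center to atom, in cells
    d2 <- (outer(tpl[, 1], frac[, 1], `-`))^2 +
          (outer(tpl[, 2], frac[, 2], `-`))^2 +
          (outer(tpl[, 3], frac[, 3], `-`))^2
    hit <- which(d2 * res^2 <= r^2 + 1e-12)
    if (length(hit)) {
      ai <- (hit - 1L) %/% nt + 1L
      ti <- (hit - 1L) %% nt + 1L
      ci <- t(i0[ai, , drop = FALSE]) + t(tpl[ti, , drop = FALSE]) # 3 x k
      lin <- 1L + ci[1, ] + n * (ci[2, ] + n * ci[3, ])
      occ[lin] <- TRUE
    }
  }
  list(occ = occ, origin = origin)
}

# logical array shifted by integer offset, zero-filled at the boundary
.shift_array <- function(a, off) {
  n <- dim(a)
  out <- array(FALSE, dim = n)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    o <- off[k]
    if (o >= 0) { src[[k]] <- seq_len(n[k] - o); dst[[k]] <- src[[k]] + o }
    else { src[[k]] <- seq(1 - o, n[k]); dst[[k]] <- src[[k]] + o }
    if (length(src[[k]]) == 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Digitize a structure onto a docking grid
#'
#' A cell is occupied if its center lies within any atom's radius.
#' For the static role, occupied cells within `surface_thickness` of an
#' unoccupied cell form the surface layer (value 1) and the remainder
#' the core (value `core_penalty`); for the mobile role every occupied
#' cell has value 1.
#'
#' @param structure A [new_structure()] object (frame 1 is used).
#' @param params A [dock_params()] object.
#' @param role `"static"` or `"mobile"`.
#' @param frame Frame index to digitize.
#' @return list of class `dock_grid`: values (N^3 array), origin (A),
#'   resolution, role, occupied (logical array).
#' @export
discretize <- function(structure, params, role = c("static", "mobile"),
                       frame = 1L) {
  role <- match.arg(role)
  if (n_atoms(structure) == 0L) stop("empty structure")
  xyz <- frame_coords(structure, frame)
  og <- .occupancy_grid(xyz, structure$atoms$radius,
                        params$grid_dim, params$resolution)
  occ <- og$occ
  if (role == "mobile") {
    vals <- array(0, dim = dim(occ)); vals[occ] <- 1
  } else {
    # core: occupied cells all of whose neighbors within the surface
    # thickness are occupied
    m <- floor(params$surface_thickness / params$resolution)
    dd <- seq(-m, m)
    offs <- as.matrix(expand.grid(dd, dd, dd))
    offs <- offs[rowSums(offs^2) > 0 &
                 rowSums(offs^2) * params$resolution^2 <=
                   params$surface_thickness^2 + 1e-9, , drop = FALSE]
    core <- occ
    for (i in seq_len(nrow(offs))) core <- core & .shift_array(occ, offs[i, ])
    vals <- array(0, dim = dim(occ))
    vals[occ & !core] <- 1
    vals[core] <- params$core_penalty
  }
  g <- list(values = vals, origin = og$origin,
            resolution = params$resolution, role = role, occupied = occ)
  class(g) <- "dock_grid"
  g
}

#' FFT cross-correlation of two docking grids
#'
#' Computes `score(t) = sum_c static(c + t) * mobile(c)` for every
#' cyclic lattice translation t via forward/inverse FFT; real outputs
#' are rounded to the nearest integer.
#'
#' @param static,mobile [discretize()] grids sharing N and resolution.
#' @return N^3 numeric array; element `[i, j, k]` is the score of the
#'   cyclic shift `t = (i-1, j-1, k-1)` cells.
#' @export
correlate <- function(static, mobile) {
  if (!identical(dim(static$values), dim(mobile$values)) ||
      static$resolution != mobile$resolution)
    stop("incompatible grids: N or resolution mismatch")
  fs <- stats::fft(static$values)
  fm <- stats::fft(mobile$values)
  n3 <- prod(dim(static$values))
  sc <- Re(stats::fft(fs * Conj(fm), inverse = TRUE)) / n3
  round(sc)
}
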