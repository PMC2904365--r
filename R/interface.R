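# quasi-uniform unit sphere points (deterministic golden-section spiral)
.sphere_points <- function(n) {
  i <- seq_len(n)
  z <- (2 * i - 1) / n - 1
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom ASA by deterministic spherical sampling: each atom's area is
#' `4 pi (r + probe)^2` times the fraction of quasi-uniform surface
#' points not buried inside any neighbour's expanded sphere.  The point
#' set is a seed-free golden-section spiral, so results are reproducible
#' bit-for-bit at fixed `n_points`.
#'
#' @param structure A parameterized [new_structure()] (radii assigned).
#' @param probe_radius Solvent probe radius, A (default 1.4).
#' @param n_points Sampling points per atom (default 960, min 100).
#' @param frame Frame index.
#' @return Numeric vector of per-atom areas, A^2.
#' @export
asa <- function(structure, probe_radius = 1.4, n_points = 960L,
                frame = 1L) {
  if (n_points < 100L) stop("n_points must be >= 100")
  r <- structure$atoms$radius
  if (is.null(r) || any(is.na(r)) || any(r <= 0))
    stop("radii not assigned; load the structure with a parameter table")
  xyz <- frame_coords(structure, frame)
  n <- nrow(xyz)
  re <- r + probe_radius
  pts <- .sphere_points(n_points)
  # neighbour lists via squared-distance threshold
  out <- numeric(n)
  maxre <- max(re)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (re[i] + maxre)^2 & seq_len(n) != i)
    nb <- nb[d2[nb] < (re[i] + re[nb])^2]
    p <- pts * re[i] + rep(xyz[i, ], each = n_points)
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dj2 <- rowSums(sweep(p, 2, xyz[j, ])^2)
      free <- free & dj2 > re[j]^2
    }
    out[i] <- 4 * pi * re[i]^2 * sum(free) / n_points
  }
  out
}

#' Buried interface area between two parts
#'
#' Total buried solvent-accessible area on both sides:
#' `ASA(A) + ASA(B) - ASA(A+B)`.
#'
#' @param partA,partB Parameterized [new_structure()] objects.
#' @param probe_radius Probe radius, A.
#' @param n_points Sampling points per atom.
#' @return Buried area, A^2.
#' @export
interface_asa <- function(partA, partB, probe_radius = 1.4,
                          n_points = 960L) {
  aa <- sum(asa(partA, probe_radius, n_points))
  ab <- sum(asa(partB, probe_radius, n_points))
  both <- sum(asa(combine_structures(partA, partB), probe_radius, n_points))
  aa + ab - both
}

#' Energy model parameters
#'
#' @param cutoff Nonbonded cutoff, A.
#' @param dielectric_factor Distance-dependent dielectric eps(r) =
#'   `dielectric_factor * r`.
#' @return list of class `energy_params`.
#' @export
energy_params <- function(cutoff = 12, dielectric_factor = 4) {
  stopifnot(cutoff > 0, dielectric_factor > 0)
  p <- list(cutoff = cutoff, dielectric_factor = dielectric_factor)
  class(p) <- "energy_params"
  p
}

#' Pairwise interaction energy between two parts
#'
#' Sum over inter-part atom pairs within the cutoff of a 6-12
#' Lennard-Jones term (Lorentz-Berthelot combination of the per-atom
#' eps/Rmin from the parameter table) plus a Coulomb term with
#' distance-dependent dielectric.  Reported in kcal/mol; absolute
#' values are comparable only within this parameterization.
#'
#' @param partA,partB Parameterized [new_structure()] objects.
#' @param params An [energy_params()] object.
#' @return Energy, kcal/mol (negative = attractive).
#' @export
interaction_energy <- function(partA, partB, params = energy_params()) {
  for (s in list(partA, partB))
    if (is.null(s$atoms$eps) || any(is.na(s$atoms$eps)))
      stop("LJ parameters not assigned; use a parameter table")
  xa <- frame_coords(partA, 1L); xb <- frame_coords(partB, 1L)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb)
  d2[d2 < 1e-12] <- 1e-12
  within <- d2 <= params$cutoff^2
  if (!any(within)) return(0)
  r <- sqrt(d2[within])
  epsij <- sqrt(outer(partA$atoms$eps, partB$atoms$eps))[within]
  rminij <- outer(partA$atoms$rmin, partB$atoms$rmin, `+`)[within] / 2
  s6 <- (rminij / r)^6
  lj <- epsij * (s6^2 - 2 * s6)
  qq <- outer(partA$atoms$charge, partB$atoms$charge)[within]
  coul <- 332.0637 * qq / (params$dielectric_factor * r^2)
  sum(lj) + sum(coul)
}

#' Van der Waals contact table
#'
#' Residue pairs of the two parts with any inter-part heavy-atom
#' distance at or below the cutoff, with the minimum distance.
#'
#' @param partA,partB [new_structure()] objects.
#' @param cutoff Contact cutoff, A (default 4.0).
#' @return data.frame: chainA, resnoA, resnameA, chainB, resnoB,
#'   resnameB, min_dist; ordered by (chainA, resnoA).
#' @export
vdw_contacts <- function(partA, partB, cutoff = 4.0) {
  stopifnot(cutoff > 0)
  ia <- which(.heavy(partA)); ib <- which(.heavy(partB))
  xa <- frame_coords(partA, 1L)[ia, , drop = FALSE]
  xb <- frame_coords(partB, 1L)[ib, , drop = FALSE]
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb)
  hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
  empty <- data.frame(chainA = character(), resnoA = integer(),
                      resnameA = character(), chainB = character(),
                      resnoB = integer(), resnameB = character(),
                      min_dist = numeric(), stringsAsFactors = FALSE)
  if (!nrow(hit)) return(empty)
  aa <- partA$atoms[ia[hit[, 1]], ]; bb <- partB$atoms[ib[hit[, 2]], ]
  d <- sqrt(pmax(0, d2[hit]))
  key <- paste(aa$chain, aa$resno, bb$chain, bb$resno)
  agg <- tapply(d, key, min)
  first <- !duplicated(key)
  out <- data.frame(chainA = aa$chain[first], resnoA = aa$resno[first],
                    resnameA = aa$resname[first], chainB = bb$chain[first],
                    resnoB = bb$resno[first], resnameB = bb$resname[first],
                    min_dist = as.numeric(agg[key[first]]),
                    stringsAsFactors = FALSE)
  out[order(out$chainA, out$resnoA, out$chainB, out$resnoB), ,
      drop = FALSE]
}

#' Hydrogen-bond geometric criteria
#'
#' Defaults follow the trajectory-analysis convention: donor-acceptor
#' distance at most 0.35 nm and hydrogen-donor-acceptor angle at most
#' 30 degrees.
#'
#' @param max_da_nm Max donor-acceptor distance, nm.
#' @param max_angle_deg Max hydrogen-donor-acceptor angle, degrees.
#' @return list of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_da_nm = 0.35, max_angle_deg = 30) {
  stopifnot(max_da_nm > 0, max_angle_deg > 0)
  p <- list(max_da = max_da_nm * 10, max_angle = max_angle_deg)
  class(p) <- "hbond_criteria"
  p
}

# hydrogens covalently attached to donor atoms (same residue, < 1.25 A)
.donor_hydrogens <- function(structure, donors, xyz) {
  hyd <- which(structure$atoms$element == "H")
  out <- vector("list", length(donors))
  for (k in seq_along(donors)) {
    d <- donors[k]
    same <- hyd[structure$atoms$chain[hyd] == structure$atoms$chain[d] &
                structure$atoms$resno[hyd] == structure$atoms$resno[d]]
    if (length(same)) {
      dist <- sqrt(rowSums(sweep(xyz[same, , drop = FALSE], 2,
                                 xyz[d, ])^2))
      out[[k]] <- same[dist < 1.25]
    } else out[[k]] <- integer()
  }
  out
}

#' Inter-partition hydrogen bonds with per-frame occupancy
#'
#' Per frame, an H-bond between partition A and partition B exists iff
#' the donor-acceptor distance and the hydrogen-donor-acceptor angle
#' satisfy `criteria`.  Occupancy is the percentage of frames in which
#' the bond exists (reported to 0.01%).  When a donor carries no
#' hydrogen, a heavy-atom fallback is used (distance plus
#' antecedent-donor-acceptor angle >= 120 degrees) and the row is
#' marked `inferred`.
#'
#' @param structure A (possibly multi-frame) [new_structure()] with
#'   donor/acceptor flags assigned.
#' @param chains_a,chains_b Chain ids of the two partitions.
#' @param criteria An [hbond_criteria()] object.
#' @return data.frame: donor_chain, donor_resno, donor_resname,
#'   donor_atom, acceptor_chain, acceptor_resno, acceptor_resname,
#'   acceptor_atom, mean_dist, mean_angle, occupancy (percent),
#'   inferred (logical).
#' @export
hbonds <- function(structure, chains_a, chains_b,
                   criteria = hbond_criteria()) {
  if (n_frames(structure) < 1L) stop("no frames")
  at <- structure$atoms
  side <- function(chains, flag) which(at$chain %in% chains & flag)
  # donors on either side may bond acceptors on the other
  pairs <- rbind(
    expand.grid(d = side(chains_a, at$donor), a = side(chains_b, at$acceptor)),
    expand.grid(d = side(chains_b, at$donor), a = side(chains_a, at$acceptor)))
  if (!nrow(pairs)) return(.empty_hbond_table())
  nf <- n_frames(structure)
  present <- matrix(FALSE, nrow(pairs), nf)
  dsum <- numeric(nrow(pairs)); asum <- numeric(nrow(pairs))
  inferred <- logical(nrow(pairs))
  for (f in seq_len(nf)) {
    xyz <- frame_coords(structure, f)
    hyd <- .donor_hydrogens(structure, pairs$d, xyz)
    for (k in seq_len(nrow(pairs))) {
      d <- pairs$d[k]; a <- pairs$a[k]
      da <- sqrt(sum((xyz[a, ] - xyz[d, ])^2))
      if (da > criteria$max_da || da < 0.5) next
      hs <- hyd[[k]]
      if (length(hs)) {
        v_a <- xyz[a, ] - xyz[d, ]
        ok <- FALSE; best <- Inf
        for (h in hs) {
          v_h <- xyz[h, ] - xyz[d, ]
          ang <- .angle_deg(v_h, v_a)
          if (ang < best) best <- ang
        }
        if (best <= criteria$max_angle) {
          present[k, f] <- TRUE
          dsum[k] <- dsum[k] + da; asum[k] <- asum[k] + best
        }
      } else {
        # heavy-atom fallback: antecedent-donor-acceptor angle
        ante <- .donor_antecedent(structure, d, xyz)
        ang <- if (is.null(ante)) 180 else
          .angle_deg(xyz[ante, ] - xyz[d, ], xyz[a, ] - xyz[d, ])
        if (da <= criteria$max_da && ang >= 120) {
          present[k, f] <- TRUE
          inferred[k] <- TRUE
          dsum[k] <- dsum[k] + da; asum[k] <- asum[k] + ang
        }
      }
    }
  }
  cnt <- rowSums(present)
  keep <- cnt > 0
  if (!any(keep)) return(.empty_hbond_table())
  pairs <- pairs[keep, , drop = FALSE]
  cnt <- cnt[keep]
  out <- data.frame(
    donor_chain = at$chain[pairs$d], donor_resno = at$resno[pairs$d],
    donor_resname = at$resname[pairs$d], donor_atom = at$name[pairs$d],
    acceptor_chain = at$chain[pairs$a], acceptor_resno = at$resno[pairs$a],
    acceptor_resname = at$resname[pairs$a], acceptor_atom = at$name[pairs$a],
    mean_dist = dsum[keep] / cnt, mean_angle = asum[keep] / cnt,
    occupancy = round(100 * cnt / nf, 2),
    inferred = inferred[keep], stringsAsFactors = FALSE)
  out[order(-out$occupancy), , drop = FALSE]
}

.empty_hbond_table <- function() {
  data.frame(donor_chain = character(), donor_resno = integer(),
             donor_resname = character(), donor_atom = character(),
             acceptor_chain = character(), acceptor_resno = integer(),
             acceptor_resname = character(), acceptor_atom = character(),
             mean_dist = numeric(), mean_angle = numeric(),
             occupancy = numeric(), inferred = logical(),
             stringsAsFactors = FALSE)
}

.angle_deg <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# bonded heavy neighbour of a donor (nearest heavy atom < 1.8 A in the
# same residue), used by the hydrogen-free fallback
.donor_antecedent <- function(structure, d, xyz) {
  at <- structure$atoms
  cand <- which(at$chain == at$chain[d] & at$resno == at$resno[d] &
                at$element != "H" & seq_len(nrow(at)) != d)
  if (!length(cand)) return(NULL)
  dist <- sqrt(rowSums(sweep(xyz[cand, , drop = FALSE], 2, xyz[d, ])^2))
  if (min(dist) > 1.8) return(NULL)
  cand[which.min(dist)]
}

#' Full interface report for a two-part complex
#'
#' @param partA,partB Parameterized [new_structure()] objects (frame 1).
#' @param eparams An [energy_params()] object.
#' @param contact_cutoff vdW contact cutoff, A.
#' @param probe_radius,n_points ASA settings.
#' @return list of class `interface_report`: interface_asa,
#'   interaction_energy, contacts, hbonds.
#' @export
interface_report <- function(partA, partB, eparams = energy_params(),
                             contact_cutoff = 4.0, probe_radius = 1.4,
                             n_points = 960L) {
  combo <- combine_structures(partA, partB)
  rep <- list(
    interface_asa = interface_asa(partA, partB, probe_radius, n_points),
    interaction_energy = interaction_energy(partA, partB, eparams),
    contacts = vdw_contacts(partA, partB, contact_cutoff),
    hbonds = hbonds(combo, unique(partA$atoms$chain),
                    unique(partB$atoms$chain)))
  class(rep) <- "interface_report"
  rep
}
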