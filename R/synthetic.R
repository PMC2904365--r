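# ---- geometry helpers (toy secondary-structure builders) -------------

# ideal-ish alpha helix along +x, centred at `centre`; returns rows of
# (resno, name, pos) for N, CA, C, O, H and CB (non-GLY)
.helix_atoms <- function(resnos, resnames, centre, phase = 0) {
  n <- length(resnos)
  rows <- list()
  for (i in seq_len(n)) {
    a <- (i - 1) * 100 * pi / 180 + phase
    x <- (i - (n + 1) / 2) * 1.5
    rad <- function(r, ang) c(0, r * cos(ang), r * sin(ang))
    ca <- c(x, 0, 0) + rad(2.3, a)
    nn <- c(x - 0.9, 0, 0) + rad(1.5, a - 26 * pi / 180)
    cc <- c(x + 0.9, 0, 0) + rad(1.6, a + 26 * pi / 180)
    oo <- cc + 1.23 * .unit(0.3 * rad(1, a + 26 * pi / 180) + c(1, 0, 0))
    hh <- nn + rad(1.0, a - 26 * pi / 180)
    res <- list(N = nn, CA = ca, C = cc, O = oo, H = hh)
    if (resnames[i] != "GLY") res$CB <- ca + rad(1.53, a)
    for (nm in names(res))
      rows[[length(rows) + 1]] <- list(resno = resnos[i],
                                       resname = resnames[i], name = nm,
                                       pos = res[[nm]] + centre)
  }
  rows
}

# extended strand along +x with alternating pucker; `o_dir` = +1/-1
# flips the carbonyl direction (z)
.strand_atoms <- function(resnos, resnames, start, rise = 2.8,
                          o_dir = 1) {
  rows <- list()
  for (i in seq_along(resnos)) {
    s <- (-1)^i
    ca <- start + c((i - 1) * rise, 0.3 * s, 0)
    nn <- ca + c(-1.25, 0.5 * s, -0.4)
    cc <- ca + c(1.25, -0.5 * s, -0.3)
    oo <- cc + c(0.1, 0.25 * s, 1.18 * o_dir)
    hh <- nn + c(-0.2, -0.9 * s, -0.3)
    res <- list(N = nn, CA = ca, C = cc, O = oo, H = hh)
    if (resnames[i] != "GLY") res$CB <- ca + c(0.15, 1.0 * s, 1.1)
    for (nm in names(res))
      rows[[length(rows) + 1]] <- list(resno = resnos[i],
                                       resname = resnames[i], name = nm,
                                       pos = res[[nm]])
  }
  rows
}

.unit <- function(v) v / sqrt(sum(v^2))

# place a side chain from an anchor CA towards a fixed tip position:
# intermediate atoms evenly spaced along the line with a perpendicular
# zigzag sized to keep successive atoms ~`bond` apart
.chain_to_tip <- function(ca, tip, names) {
  n <- length(names)
  d <- tip - ca
  len <- sqrt(sum(d^2))
  u <- d / len
  perp <- .unit(if (abs(u[1]) < 0.9) pracma_cross(u, c(1, 0, 0)) else
                pracma_cross(u, c(0, 1, 0)))
  step <- len / n
  amp <- if (step >= 1.5) 0 else sqrt(1.5^2 - step^2) / 2
  out <- list()
  for (i in seq_len(n)) {
    zig <- if (i < n) amp * (-1)^i else 0   # tip lands exactly on target
    out[[names[i]]] <- ca + u * (step * i) + perp * zig
  }
  out
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.rows_to_structure <- function(rows, chain, param_table) {
  atoms <- data.frame(
    serial = seq_along(rows),
    name = vapply(rows, `[[`, character(1), "name"),
    element = "",
    resname = vapply(rows, `[[`, character(1), "resname"),
    resno = vapply(rows, function(r) as.integer(r$resno), integer(1)),
    chain = chain, stringsAsFactors = FALSE)
  xyz <- do.call(rbind, lapply(rows, `[[`, "pos"))
  list(atoms = atoms, xyz = xyz)
}

.bind_parts <- function(parts, param_table) {
  atoms <- do.call(rbind, lapply(parts, `[[`, "atoms"))
  atoms$serial <- seq_len(nrow(atoms))
  xyz <- do.call(rbind, lapply(parts, `[[`, "xyz"))
  new_structure(atoms, xyz, param_table = param_table)
}

# ---- benchmark ------------------------------------------------------

#' Deterministic synthetic docking benchmark with planted ground truth
#'
#' Builds, at toy scale, the geometry of a TCR-Vbeta domain docked onto
#' a peptide/MHC-II complex: the receptor (chains A and B: two
#' groove-flanking helices plus floor strands; chain P: an extended
#' 13-residue peptide with register labels P-2..P11, P1 at residue 263)
#' and a compact probe domain (chain D: three short helices and a
#' CDR3-like loop, residues 96-102, dipping into the groove).  Planted
#' features, recorded in the truth manifest: a Lys97(D)-Glu266(P) salt
#' bridge (the unique hotspot), a Ser100(D) OG -> Gln267(P) OE1
#' hydrogen bond with ideal geometry, CDR1/CDR2 contacts satisfying the
#' constraint set `"30D:A 50D:B (97-98)D:P"` at 4.5 A, and a native
#' pose (the identity: the probe is generated in its docked position).
#' Scaffold coordinates receive a tiny seeded jitter (0.02 A); planted
#' feature atoms are exact.
#'
#' @param seed Integer seed.
#' @param param_table A [default_param_table()].
#' @return list of class `dock_benchmark`: receptor, probe (both
#'   `structure3d`), native_pose, truth (manifest list).
#' @export
make_benchmark <- function(seed = 1L, param_table = default_param_table()) {
  set.seed(as.integer(seed))
  helA <- .helix_atoms(55:72, rep("ALA", 18), centre = c(0, -6.5, 2))
  helB <- .helix_atoms(64:81, rep("ALA", 18), centre = c(0, 6.5, 2),
                       phase = pi)
  # two-layer beta-sheet-like floor slab per chain (a thin floor would
  # let docking poses tunnel through it without core penalty)
  floA <- c(.strand_atoms(10:21, rep(c("ALA", "GLY"), 6),
                          start = c(-15.4, -4.4, -4.2), o_dir = -1),
            .strand_atoms(30:41, rep(c("GLY", "ALA"), 6),
                          start = c(-15.4, -1.5, -4.4), o_dir = -1),
            .strand_atoms(85:96, rep(c("ALA", "GLY"), 6),
                          start = c(-15.4, -3.0, -6.8), o_dir = -1))
  floB <- c(.strand_atoms(10:21, rep(c("GLY", "ALA"), 6),
                          start = c(-15.4, 4.4, -4.2), o_dir = -1),
            .strand_atoms(30:41, rep(c("ALA", "GLY"), 6),
                          start = c(-15.4, 1.5, -4.4), o_dir = -1),
            .strand_atoms(85:96, rep(c("GLY", "ALA"), 6),
                          start = c(-15.4, 3.0, -6.8), o_dir = -1))
  pep_names <- c("ALA", "GLY", "ALA", "ALA", "GLY", "GLU", "GLN",
                 "GLY", "ALA", "ALA", "GLY", "ALA", "ALA")
  pep <- .strand_atoms(261:273, pep_names, start = c(-16.8, 0, -1.5))
  # planted peptide side chains reaching out of the groove (+z)
  pep <- .plant_sidechains(pep)
  # probe scaffold; phases put residues 30/50 on the receptor-facing side
  h1 <- .helix_atoms(25:34, rep("ALA", 10), centre = c(0, -4.9, 12.4),
                     phase = 1.96)
  h2 <- .helix_atoms(45:54, rep("ALA", 10), centre = c(0, 4.9, 12.4),
                     phase = 2.58)
  h3 <- .helix_atoms(65:74, rep("ALA", 10), centre = c(0, 0, 16.2),
                     phase = pi / 2)
  loop <- .cdr3_loop()
  # jitter scaffold, then plant exact features
  jitter_rows <- function(rows) {
    lapply(rows, function(r) {
      r$pos <- r$pos + stats::rnorm(3, 0, 0.02)
      r
    })
  }
  helA <- jitter_rows(helA); helB <- jitter_rows(helB)
  floA <- jitter_rows(floA); floB <- jitter_rows(floB)
  h1 <- jitter_rows(h1); h2 <- jitter_rows(h2); h3 <- jitter_rows(h3)
  recA <- .rows_to_structure(c(helA, floA), "A", param_table)
  recB <- .rows_to_structure(c(helB, floB), "B", param_table)
  recP <- .rows_to_structure(pep, "P", param_table)
  receptor <- .bind_parts(list(recA, recB, recP), param_table)
  probe_rows <- c(h1, h2, h3, loop)
  # mold the probe's binding face onto the receptor: glycine filler
  # residues on the receptor's 3.5-A offset surface across the
  # interface window give the native pose its shape complementarity
  # (a TCR binding face is complementary to its pMHC surface; here the
  # complementarity is constructed explicitly)
  rec_xyz <- do.call(rbind, lapply(c(helA, helB, floA, floB, pep),
                                   `[[`, "pos"))
  probe_rows <- c(probe_rows, .mold_fillers(rec_xyz, probe_rows))
  probeS <- .rows_to_structure(probe_rows, "D", param_table)
  probe <- .bind_parts(list(probeS), param_table)
  # CDR1/CDR2 contact planting: CB of residues 30 (vs chain A) and 50
  # (vs chain B) placed 3.8 A from the nearest receptor atom, on the
  # line towards their CA
  probe <- .plant_cdr_contact(probe, receptor, 30, "A", 3.8)
  probe <- .plant_cdr_contact(probe, receptor, 50, "B", 3.8)
  truth <- list(
    constraints = "30D:A 50D:B (97-98)D:P",
    cutoff = 4.5,
    register_map = stats::setNames(
      c("P-2", "P-1", paste0("P", 1:11)), as.character(261:273)),
    allowed_positions = c("P5", "P6"),
    loop_residues = data.frame(chain = "D", resno = 97:101),
    peptide_chain = "P",
    hbond = list(donor = c(chain = "D", resno = "100", name = "OG"),
                 hydrogen = c(chain = "D", resno = "100", name = "HG"),
                 acceptor = c(chain = "P", resno = "267", name = "OE1")),
    hotspot = list(chain = "D", resno = 97L, resname = "LYS"),
    salt_bridge = list(probe = c("D", "97", "NZ"),
                       receptor = c("P", "266", "OE1")),
    seed = as.integer(seed))
  native <- identity_pose(probe)
  native$id <- 0L
  bench <- list(receptor = receptor, probe = probe, native_pose = native,
                truth = truth)
  class(bench) <- "dock_benchmark"
  .validate_benchmark(bench)
  bench
}

# peptide planted side chains: Glu266 and Gln267 extended towards +z
.plant_sidechains <- function(pep) {
  drop <- vapply(pep, function(r)
    r$resno %in% c(266, 267) && r$name == "CB", logical(1))
  pep <- pep[!drop]
  add <- function(resno, resname, name, pos)
    list(resno = resno, resname = resname, name = name, pos = pos)
  ca266 <- c(-16.8 + 5 * 2.8, 0.3, -1.5)
  sc266 <- .chain_to_tip(ca266, c(-2.8, -0.1, 2.9), c("CB", "CG", "CD"))
  ca267 <- c(-16.8 + 6 * 2.8, -0.3, -1.5)
  sc267 <- .chain_to_tip(ca267, c(0, 0, 3.1), c("CB", "CG", "CD"))
  pep <- c(pep, list(
    add(266, "GLU", "CB", sc266$CB), add(266, "GLU", "CG", sc266$CG),
    add(266, "GLU", "CD", sc266$CD),
    add(266, "GLU", "OE1", c(-2.8, -1.05, 3.7)),
    add(266, "GLU", "OE2", c(-2.8, 0.9, 3.6)),
    add(267, "GLN", "CB", sc267$CB), add(267, "GLN", "CG", sc267$CG),
    add(267, "GLN", "CD", sc267$CD),
    add(267, "GLN", "OE1", c(0, 0.9, 3.9)),
    add(267, "GLN", "NE2", c(0, -1.0, 3.8)),
    add(267, "GLN", "HE21", c(0, -1.8, 3.3)),
    add(267, "GLN", "HE22", c(0, -1.0, 4.8))))
  pep
}

# CDR3-like loop, chain D residues 96-102, arching over the peptide
# centre; Lys97 side chain extends to the planted salt bridge, Ser100
# carries the planted hydrogen-bond donor
.cdr3_loop <- function() {
  cas <- list(`96` = c(-6.2, 0, 10.6), `97` = c(-3.9, 0, 8.8),
              `98` = c(-1.3, 0, 7.6), `99` = c(1.1, 0, 7.3),
              `100` = c(3.4, 0, 7.8), `101` = c(5.7, 0, 8.9),
              `102` = c(7.3, 0, 10.5))
  resnames <- c(`96` = "ALA", `97` = "LYS", `98` = "ALA", `99` = "GLY",
                `100` = "SER", `101` = "ALA", `102` = "GLY")
  rows <- list()
  add <- function(resno, name, pos)
    rows[[length(rows) + 1]] <<- list(resno = resno,
                                      resname = resnames[[as.character(resno)]],
                                      name = name, pos = pos)
  prev_c <- NULL
  for (rn in names(cas)) {
    ca <- cas[[rn]]
    i <- as.integer(rn)
    nn <- ca + c(-1.0, 0.5, 0.8); cc <- ca + c(1.0, -0.5, 0.8)
    oo <- cc + c(0.2, -0.3, 1.16); hh <- nn + c(-0.3, 0.9, 0.2)
    add(i, "N", nn); add(i, "CA", ca); add(i, "C", cc); add(i, "O", oo)
    add(i, "H", hh)
    if (resnames[[rn]] == "ALA") add(i, "CB", ca + c(0.2, 0.9, -1.2))
  }
  # Lys97: NZ placed 3.0 A from Glu266 OE1 (-2.8, -1.05, 3.7)
  nz <- c(-2.3, -0.3, 6.6)
  k <- .chain_to_tip(cas$`97`, nz, c("CB", "CG", "CD", "CE", "NZ"))
  for (nm in names(k)) add(97, nm, k[[nm]])
  add(97, "HZ1", nz + c(0.9, 0.4, 0.2))
  add(97, "HZ2", nz + c(-0.6, 0.8, 0.3))
  add(97, "HZ3", nz + c(-0.2, -0.9, 0.5))
  # Ser100: OG 3.45 A from Gln267 OE1 (0, 0.9, 3.9), HG on the D->A line
  og <- c(1.85, 0.85, 6.81)
  add(100, "CB", c(2.6, 0.4, 7.6))
  add(100, "OG", og)
  add(100, "HG", og + 0.98 * .unit(c(0, 0.9, 3.9) - og))
  rows
}

# glycine filler residues molded onto the receptor's offset surface:
# for each (x, y) grid point the height at which an atom clears every
# receptor atom by `clear` is found by a rolling-ball style ray cast;
# fillers crowding the existing probe scaffold are skipped
.mold_fillers <- function(rec_xyz, probe_rows, clear = 3.5,
                          xs = seq(-8.4, 8.4, by = 2.8),
                          ys = seq(-7.5, 7.5, by = 2.5),
                          zmax = 9.2, resno0 = 200L) {
  scaffold <- do.call(rbind, lapply(probe_rows, `[[`, "pos"))
  out <- list()
  k <- 0L
  for (gx in xs) for (gy in ys) {
    l2 <- (rec_xyz[, 1] - gx)^2 + (rec_xyz[, 2] - gy)^2
    cand <- l2 < clear^2
    if (!any(cand)) next
    zsurf <- max(rec_xyz[cand, 3] + sqrt(clear^2 - l2[cand]))
    if (zsurf < 0 || zsurf > zmax) next
    ca <- c(gx, gy, zsurf)
    for (rep in 1:20) {     # lateral wall clearance: raise until clear
      d <- sqrt(min(rowSums(sweep(rec_xyz, 2, ca)^2)))
      if (d >= clear - 0.05) break
      ca[3] <- ca[3] + 0.2
    }
    if (ca[3] > zmax) next
    if (min(rowSums(sweep(scaffold, 2, ca)^2)) < 1.7^2) next
    atoms <- list(
      CA = ca,
      N = ca + c(-1.30, 0.30, 0.25),
      C = ca + c(1.30, -0.30, 0.25),
      O = ca + c(1.45, -0.50, 1.42),
      H = ca + c(-1.65, 0.55, 1.13))
    # every filler atom must respect the clearance
    ok <- all(vapply(atoms, function(p)
      min(rowSums(sweep(rec_xyz, 2, p)^2)) >= (clear - 0.4)^2,
      logical(1)))
    if (!ok) next
    k <- k + 1L
    for (nm in c("N", "CA", "C", "O", "H"))
      out[[length(out) + 1L]] <- list(resno = resno0 + k, resname = "GLY",
                                      name = nm, pos = atoms[[nm]])
    scaffold <- rbind(scaffold, do.call(rbind, atoms))
  }
  out
}

# place the CB of `resno` at exactly `dist` from the nearest atom of
# the target chain while staying ~1.5 A from its own CA (two-sphere
# intersection; falls back to the connecting line when out of reach)
.plant_cdr_contact <- function(probe, receptor, resno, target_chain,
                               dist, bond = 1.52) {
  ca_idx <- which(probe$atoms$resno == resno & probe$atoms$name == "CA")
  cb_idx <- which(probe$atoms$resno == resno & probe$atoms$name == "CB")
  ca <- frame_coords(probe, 1L)[ca_idx, ]
  tgt <- chain_atoms(receptor, target_chain)
  xs <- frame_coords(receptor, 1L)[tgt, , drop = FALSE]
  d <- sqrt(rowSums(sweep(xs, 2, ca)^2))
  a_star <- xs[which.min(d), ]
  dd <- sqrt(sum((ca - a_star)^2))
  u <- .unit(ca - a_star)
  xyz <- frame_coords(probe, 1L)
  if (dd > dist - bond && dd < dist + bond) {
    along <- (dd^2 + dist^2 - bond^2) / (2 * dd)
    h <- sqrt(max(0, dist^2 - along^2))
    perp <- .unit(pracma_cross(u, if (abs(u[1]) < 0.9) c(1, 0, 0)
                               else c(0, 0, 1)))
    xyz[cb_idx, ] <- a_star + along * u + h * perp
  } else {
    xyz[cb_idx, ] <- a_star + dist * u
  }
  set_coords(probe, xyz)
}

.validate_benchmark <- function(bench) {
  xs <- frame_coords(bench$receptor, 1L)
  xm <- pose_apply(bench$native_pose, frame_coords(bench$probe, 1L))
  if (.min_dist(xs, xm) < 1.5)
    stop("benchmark generation error: steric clash in native pose")
  cs <- parse_constraints(bench$truth$constraints, bench$truth$cutoff)
  ok <- apply_constraints(list(bench$native_pose), bench$receptor,
                          bench$probe, cs)
  if (length(ok) != 1L)
    stop("benchmark generation error: native violates its constraints")
  invisible(TRUE)
}

#' The native complex of a benchmark as one structure
#' @param bench A [make_benchmark()] object.
#' @return Receptor and natively-posed probe combined.
#' @export
native_complex <- function(bench) {
  combine_structures(bench$receptor, pose_apply(bench$native_pose,
                                                bench$probe))
}

#' Random clash-free decoy poses around the receptor
#'
#' Each decoy is a uniformly random rotation of the probe placed along
#' a random direction from the receptor centroid at a distance where
#' the parts touch (minimum inter-part distance in 1.8-3.6 A, never
#' below 1.5 A).  The manifest records, per decoy, whether it violates
#' the benchmark's distance constraints and register filter (computed
#' by direct distance loops).
#'
#' @param bench A [make_benchmark()] object.
#' @param n Number of decoys.
#' @param seed Integer seed.
#' @return list: poses (list of [new_pose()]), manifest (data.frame id,
#'   violates_constraints, violates_register).
#' @export
make_decoys <- function(bench, n, seed = 1L) {
  stopifnot(n >= 1)
  set.seed(as.integer(seed))
  xs <- frame_coords(bench$receptor, 1L)
  xm0 <- frame_coords(bench$probe, 1L)
  cm <- colMeans(xm0)
  ctr <- colMeans(xs)
  poses <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
      rot <- .quat_to_mat(q)
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      xr <- sweep(xm0, 2, cm) %*% t(rot)
      lo <- 0; hi <- 80
      mind <- function(t) .min_dist(xs, sweep(xr, 2, ctr + t * u, `+`))
      if (mind(hi) < 3.6) next
      for (k in 1:16) {
        mid <- (lo + hi) / 2
        if (mind(mid) < 1.8) lo <- mid else hi <- mid
      }
      d <- mind(hi)
      if (d >= 1.5 && d <= 3.6) {
        tau <- (ctr + hi * u) - cm
        poses[[i]] <- new_pose(rot, tau, cm, id = i)
        break
      }
    }
  }
  manifest <- .decoy_manifest(bench, poses)
  list(poses = poses, manifest = manifest)
}

.quat_to_mat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# direct distance-loop audit of the planted filters (manifest ground
# truth for decoy sets)
.decoy_manifest <- function(bench, poses) {
  cs <- parse_constraints(bench$truth$constraints, bench$truth$cutoff)$constraints
  cut <- bench$truth$cutoff
  xs <- frame_coords(bench$receptor, 1L)
  at_r <- bench$receptor$atoms
  xm0 <- frame_coords(bench$probe, 1L)
  at_m <- bench$probe$atoms
  reg <- bench$truth$register_map
  loop_idx <- unlist(lapply(bench$truth$loop_residues$resno, function(r)
    which(at_m$resno == r & at_m$element != "H")))
  pep_idx <- which(at_r$chain == bench$truth$peptide_chain &
                   at_r$element != "H")
  rows <- lapply(poses, function(p) {
    xm <- pose_apply(p, xm0)
    viol_c <- FALSE
    for (j in seq_len(nrow(cs))) {
      pi_ <- which(at_m$chain == cs$probe_chain[j] &
                   at_m$resno == cs$resno[j])
      ti <- which(at_r$chain %in% strsplit(cs$target[j], "")[[1]])
      if (.min_dist(xm[pi_, , drop = FALSE], xs[ti, , drop = FALSE]) >=
          cut) { viol_c <- TRUE; break }
    }
    ctr <- colMeans(xm[loop_idx, , drop = FALSE])
    d <- sqrt(rowSums(sweep(xs[pep_idx, , drop = FALSE], 2, ctr)^2))
    lab <- reg[as.character(at_r$resno[pep_idx][which.min(d)])]
    viol_r <- !(lab %in% bench$truth$allowed_positions)
    data.frame(id = p$id, violates_constraints = viol_c,
               violates_register = viol_r)
  })
  do.call(rbind, rows)
}

#' Synthetic trajectory with a planted hydrogen-bond occupancy
#'
#' Frames are the base coordinates plus Gaussian noise.  When `bond` is
#' given (donor/hydrogen/acceptor atom descriptors, as in a benchmark
#' truth manifest), the ideal bond geometry is kept exactly in
#' `round(n_frames * bond_occupancy)` randomly chosen frames and broken
#' (donor-acceptor distance > 4 A) in the rest by displacing the
#' acceptor.
#'
#' @param structure A single-frame [new_structure()].
#' @param n_frames Number of frames.
#' @param bond_occupancy Fraction of frames with the bond intact.
#' @param noise_sigma Gaussian noise, A (default 0.3: below the
#'   hydrogen-bond criteria margins).
#' @param seed Integer seed.
#' @param bond Optional list(donor, hydrogen, acceptor), each
#'   c(chain, resno, name).
#' @return Multi-frame `structure3d`.
#' @export
make_trajectory <- function(structure, n_frames, bond_occupancy = 1,
                            noise_sigma = 0.3, seed = 1L, bond = NULL) {
  stopifnot(bond_occupancy >= 0, bond_occupancy <= 1, n_frames >= 1)
  set.seed(as.integer(seed))
  base <- frame_coords(structure, 1L)
  fixed <- integer()
  acc <- NULL
  if (!is.null(bond)) {
    find <- function(b) {
      i <- which(structure$atoms$chain == b[["chain"]] &
                 structure$atoms$resno == as.integer(b[["resno"]]) &
                 structure$atoms$name == b[["name"]])
      if (length(i) != 1L) stop("bond atom not found")
      i
    }
    don <- find(bond$donor); acc <- find(bond$acceptor)
    hyd <- if (!is.null(bond$hydrogen)) find(bond$hydrogen) else integer()
    fixed <- c(don, acc, hyd)
  }
  k <- round(n_frames * bond_occupancy)
  on_frames <- if (!is.null(bond) && k > 0)
    sort(sample.int(n_frames, k)) else integer()
  frames <- lapply(seq_len(n_frames), function(f) {
    m <- base + matrix(stats::rnorm(length(base), 0, noise_sigma),
                       ncol = 3)
    if (length(fixed)) m[fixed, ] <- base[fixed, , drop = FALSE]
    if (!is.null(bond) && !(f %in% on_frames))
      m[acc, ] <- base[acc, ] + c(0, 0, -2.2)   # break: D-A > 4 A
    m
  })
  s <- structure
  s$coords <- frames
  s
}
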