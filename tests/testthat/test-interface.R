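test_that("isolated-atom ASA matches the analytic sphere", {
  s <- blob_structure(matrix(c(3, 4, 5), 1))
  s$atoms$radius <- 1.7
  a <- asa(s, probe_radius = 1.4, n_points = 960)
  expect_equal(a, 4 * pi * 3.1^2, tolerance = 0.005)
})

test_that("tangent spheres do not bury each other", {
  r <- 1.7; probe <- 1.4
  s <- blob_structure(matrix(c(0, 0, 0, 2 * (r + probe), 0, 0), 2,
                             byrow = TRUE))
  s$atoms$radius <- r
  a <- asa(s, probe, n_points = 960)
  expect_equal(a, rep(4 * pi * (r + probe)^2, 2), tolerance = 0.005)
})

test_that("overlapping equal spheres match the spherical-cap formula", {
  r <- 1.87; probe <- 1.4; re <- r + probe
  for (d in c(2.0, 3.5, 5.0)) {
    s <- blob_structure(matrix(c(0, 0, 0, d, 0, 0), 2, byrow = TRUE))
    s$atoms$radius <- r
    tot <- sum(asa(s, probe, n_points = 4000))
    # analytic: each sphere loses a cap of height h = re - d/2
    h <- re - d / 2
    analytic <- 2 * (4 * pi * re^2 - 2 * pi * re * h)
    expect_equal(tot, analytic, tolerance = 0.01)
  }
})

test_that("ASA converges with the sampling density", {
  s <- random_blob(50, extent = 12, seed = 51)
  a1 <- sum(asa(s, n_points = 4000))
  a2 <- sum(asa(s, n_points = 16000))
  expect_lt(abs(a1 - a2) / a2, 0.01)
})

test_that("missing radii and too-few points are rejected", {
  s <- random_blob(3, seed = 52)
  expect_error(asa(s, n_points = 50), "n_points")
  s$atoms$radius <- NULL
  expect_error(asa(s), "radii")
})

test_that("interface ASA vanishes for separated parts and is rigid-invariant", {
  a <- random_blob(25, extent = 9, seed = 53, chain = "A")
  b <- random_blob(25, extent = 9, seed = 54, chain = "B")
  far <- b
  far$coords[[1]] <- far$coords[[1]] + 100
  expect_lt(abs(interface_asa(a, far)), 0.1)
  # touching parts: positive burial, invariant under common rigid motion
  bt <- b
  bt$coords[[1]] <- bt$coords[[1]] + c(9, 0, 0)
  i0 <- interface_asa(a, bt)
  expect_gt(i0, 0)
  set.seed(55)
  r <- random_rotation(); tr <- c(5, -3, 8)
  rot <- function(s) {
    s$coords[[1]] <- s$coords[[1]] %*% t(r) + rep(tr, each = n_atoms(s))
    s
  }
  expect_equal(interface_asa(rot(a), rot(bt)), i0,
               tolerance = 0.005 * max(1, i0))
})

test_that("a planted interface agrees with a high-density reference run", {
  a <- random_blob(20, extent = 8, seed = 56, chain = "A")
  b <- random_blob(20, extent = 8, seed = 57, chain = "B")
  b$coords[[1]] <- b$coords[[1]] + c(8.5, 0, 0)
  ref <- interface_asa(a, b, n_points = 10000)
  expect_equal(interface_asa(a, b, n_points = 960), ref,
               tolerance = 0.02)
})

test_that("an LJ pair at Rmin scores exactly -eps and cutoffs zero out", {
  mk <- function(x) {
    s <- atom_structure(
      data.frame(name = "CB", resname = "ALA", resno = 1L, chain = "A"),
      matrix(c(x, 0, 0), 1))
    s
  }
  a <- mk(0); b <- mk(4.0)          # carbon Rmin(C,C) = 4.0
  e <- interaction_energy(a, b, energy_params(cutoff = 12))
  expect_equal(e, -a$atoms$eps[1], tolerance = 1e-12)
  expect_identical(interaction_energy(a, mk(30), energy_params(cutoff = 12)),
                   0)
})

test_that("interaction energy equals a direct double-loop oracle", {
  b <- get_bench()
  set.seed(58)
  pa <- subset_structure(b$probe, sample(n_atoms(b$probe), 20))
  pb <- subset_structure(b$receptor, sample(n_atoms(b$receptor), 20))
  ep <- energy_params(cutoff = 12, dielectric_factor = 4)
  oracle <- 0
  xa <- frame_coords(pa); xb <- frame_coords(pb)
  for (i in seq_len(20)) for (j in seq_len(20)) {
    r <- sqrt(sum((xa[i, ] - xb[j, ])^2))
    if (r > ep$cutoff) next
    epsij <- sqrt(pa$atoms$eps[i] * pb$atoms$eps[j])
    rmin <- (pa$atoms$rmin[i] + pb$atoms$rmin[j]) / 2
    oracle <- oracle + epsij * ((rmin / r)^12 - 2 * (rmin / r)^6) +
      332.0637 * pa$atoms$charge[i] * pb$atoms$charge[j] / (4 * r^2)
  }
  expect_equal(interaction_energy(pa, pb, ep), oracle, tolerance = 1e-8)
})

test_that("energy decays to zero as parts separate beyond the cutoff", {
  b <- get_bench()
  ep <- energy_params(cutoff = 12)
  shift <- function(dz) {
    m <- b$probe
    m$coords[[1]] <- m$coords[[1]] + rep(c(0, 0, dz), each = n_atoms(m))
    abs(interaction_energy(m, b$receptor, ep))
  }
  e <- vapply(c(0, 10, 20, 40), shift, numeric(1))
  expect_true(all(diff(e) <= 1e-9))
  expect_identical(e[4], 0)
})

test_that("vdW contacts respect the cutoff boundary", {
  mk <- function(x) atom_structure(
    data.frame(name = "CB", resname = "ALA", resno = 1L, chain = "A"),
    matrix(c(x, 0, 0), 1))
  expect_equal(nrow(vdw_contacts(mk(0), mk(3.9))), 1L)
  expect_equal(nrow(vdw_contacts(mk(0), mk(4.1))), 0L)
})

test_that("the contact table matches exhaustive enumeration on the benchmark", {
  b <- get_bench()
  ct <- vdw_contacts(b$probe, b$receptor, 4.0)
  # oracle: all heavy-atom pairs, grouped by residue
  xa <- frame_coords(b$probe); xb <- frame_coords(b$receptor)
  ha <- which(b$probe$atoms$element != "H")
  hb <- which(b$receptor$atoms$element != "H")
  seen <- list()
  for (i in ha) for (j in hb) {
    d <- sqrt(sum((xa[i, ] - xb[j, ])^2))
    if (d <= 4.0) {
      key <- paste(b$probe$atoms$chain[i], b$probe$atoms$resno[i],
                   b$receptor$atoms$chain[j], b$receptor$atoms$resno[j])
      seen[[key]] <- if (is.null(seen[[key]])) d else min(seen[[key]], d)
    }
  }
  got <- paste(ct$chainA, ct$resnoA, ct$chainB, ct$resnoB)
  expect_setequal(got, names(seen))
  expect_equal(ct$min_dist, unname(unlist(seen[got])), tolerance = 1e-10)
  expect_true(all(ct$min_dist <= 4.0))
})

test_that("hydrogen bonds obey the distance and angle criteria", {
  mk <- function(acc_pos, h_pos) {
    df <- data.frame(
      name = c("OG", "HG", "OE1"),
      resname = c("SER", "SER", "GLU"),
      resno = c(1L, 1L, 2L),
      chain = c("A", "A", "B"))
    atom_structure(df, rbind(c(0, 0, 0), h_pos, acc_pos))
  }
  crit <- hbond_criteria(0.35, 30)
  # ideal: D-A 3.0 A, angle ~5 deg
  ang <- 5 * pi / 180
  h <- c(cos(ang), sin(ang), 0) * 0.98
  hb <- hbonds(mk(c(3.0, 0, 0), h), "A", "B", crit)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$occupancy, 100)
  expect_false(hb$inferred)
  # distance fail at 3.6 A
  expect_equal(nrow(hbonds(mk(c(3.6, 0, 0), h), "A", "B", crit)), 0L)
  # angle fail at 40 deg
  ang2 <- 40 * pi / 180
  h2 <- c(cos(ang2), sin(ang2), 0) * 0.98
  expect_equal(nrow(hbonds(mk(c(3.0, 0, 0), h2), "A", "B", crit)), 0L)
})

test_that("occupancy counts planted frames exactly", {
  b <- get_bench()
  cx <- native_complex(b)
  tr <- make_trajectory(cx, 10, bond_occupancy = 0.6, seed = 61,
                        bond = b$truth$hbond)
  hb <- hbonds(tr, "D", c("A", "B", "P"))
  row <- hb[hb$donor_atom == "OG" & hb$acceptor_atom == "OE1" &
              hb$donor_resno == 100, ]
  expect_equal(row$occupancy, 60)
  # oracle: recount per frame with plain geometry
  don <- which(cx$atoms$chain == "D" & cx$atoms$resno == 100 &
                 cx$atoms$name == "OG")
  hyd <- which(cx$atoms$chain == "D" & cx$atoms$resno == 100 &
                 cx$atoms$name == "HG")
  acc <- which(cx$atoms$chain == "P" & cx$atoms$resno == 267 &
                 cx$atoms$name == "OE1")
  cnt <- 0
  for (f in seq_len(n_frames(tr))) {
    m <- frame_coords(tr, f)
    da <- sqrt(sum((m[acc, ] - m[don, ])^2))
    v1 <- m[hyd, ] - m[don, ]; v2 <- m[acc, ] - m[don, ]
    angle <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    if (da <= 3.5 && angle <= 30) cnt <- cnt + 1
  }
  expect_equal(row$occupancy, 100 * cnt / 10)
})

test_that("donor-free structures fall back to inferred heavy-atom bonds", {
  df <- data.frame(name = c("CB", "OG", "OE1"),
                   resname = c("SER", "SER", "GLU"),
                   resno = c(1L, 1L, 2L), chain = c("A", "A", "B"))
  s <- atom_structure(df, rbind(c(-1.4, 0, 0), c(0, 0, 0), c(3.0, 0, 0)))
  hb <- hbonds(s, "A", "B")
  expect_equal(nrow(hb), 1L)
  expect_true(hb$inferred)
})
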