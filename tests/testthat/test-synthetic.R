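test_that("benchmark generation is deterministic given the seed", {
  b1 <- make_benchmark(seed = 5)
  b2 <- make_benchmark(seed = 5)
  expect_identical(frame_coords(b1$receptor), frame_coords(b2$receptor))
  expect_identical(frame_coords(b1$probe), frame_coords(b2$probe))
  expect_identical(b1$truth, b2$truth)
})

test_that("the native pose satisfies the manifest constraints and geometry", {
  b <- get_bench()
  cs <- parse_constraints(b$truth$constraints, b$truth$cutoff)
  expect_length(apply_constraints(list(b$native_pose), b$receptor,
                                  b$probe, cs), 1L)
  # no steric clash between the parts
  d <- min_pair_dist(frame_coords(b$receptor),
                     pose_apply(b$native_pose, frame_coords(b$probe)))
  expect_gte(d, 1.5)
  # the planted hydrogen bond is detected at the standard criteria
  hb <- hbonds(native_complex(b), "D", c("A", "B", "P"))
  planted <- hb[hb$donor_resno == 100 & hb$donor_atom == "OG" &
                  hb$acceptor_resno == 267 & hb$acceptor_atom == "OE1", ]
  expect_equal(nrow(planted), 1L)
  expect_equal(planted$occupancy, 100)
  # the salt-bridge geometry is in range
  at <- native_complex(b)$atoms
  xyz <- frame_coords(native_complex(b))
  nz <- which(at$chain == "D" & at$resno == 97 & at$name == "NZ")
  oe <- which(at$chain == "P" & at$resno == 266 & at$name == "OE1")
  expect_lt(sqrt(sum((xyz[nz, ] - xyz[oe, ])^2)), 4.0)
})

test_that("generator output round-trips through PDB files losslessly", {
  b <- get_bench()
  for (s in list(b$receptor, b$probe)) {
    f <- tempfile(fileext = ".pdb")
    save_structure(s, f)
    s2 <- load_structure(f)
    expect_equal(n_atoms(s2), n_atoms(s))
    expect_identical(s2$atoms$name, s$atoms$name)
    expect_identical(s2$atoms$resname, s$atoms$resname)
    expect_lt(max(abs(frame_coords(s2) - frame_coords(s))), 0.001)
  }
})

test_that("decoys are clash-free, touching, and seed-sensitive", {
  b <- get_bench()
  dec <- get_decoys(30, 91)
  expect_length(dec$poses, 30L)
  xs <- frame_coords(b$receptor); xm <- frame_coords(b$probe)
  for (p in dec$poses[1:10]) {
    d <- min_pair_dist(xs, pose_apply(p, xm))
    expect_gte(d, 1.5)
    expect_lte(d, 3.6)
  }
  dec2 <- make_decoys(b, 30, seed = 92)
  t1 <- do.call(rbind, lapply(dec$poses, function(p) p$translation))
  t2 <- do.call(rbind, lapply(dec2$poses, function(p) p$translation))
  expect_false(isTRUE(all.equal(t1, t2)))
})

test_that("the decoy manifest agrees with the constraint filter", {
  b <- get_bench()
  dec <- get_decoys(50, 41)
  cs <- parse_constraints(b$truth$constraints, b$truth$cutoff)
  kept <- apply_constraints(dec$poses, b$receptor, b$probe, cs)
  expect_equal(length(dec$poses) - length(kept),
               sum(dec$manifest$violates_constraints))
  spec <- register_spec(b$truth$loop_residues, "P",
                        b$truth$allowed_positions, b$truth$register_map)
  keptr <- apply_register_filter(dec$poses, b$receptor, b$probe, spec)
  expect_equal(length(dec$poses) - length(keptr),
               sum(dec$manifest$violates_register))
})

test_that("trajectory occupancies are planted exactly", {
  b <- get_bench()
  cx <- native_complex(b)
  has_bond <- function(tr) {
    hb <- hbonds(tr, "D", c("A", "B", "P"))
    row <- hb[hb$donor_resno == 100 & hb$donor_atom == "OG" &
                hb$acceptor_resno == 267 & hb$acceptor_atom == "OE1", ]
    if (nrow(row) == 0L) 0 else row$occupancy
  }
  expect_equal(has_bond(make_trajectory(cx, 10, 1.0, seed = 93,
                                        bond = b$truth$hbond)), 100)
  expect_equal(has_bond(make_trajectory(cx, 10, 0.0, seed = 94,
                                        bond = b$truth$hbond)), 0)
  expect_equal(has_bond(make_trajectory(cx, 50, 0.6, seed = 95,
                                        bond = b$truth$hbond)), 60)
})

test_that("trajectory frames carry the configured noise level", {
  b <- get_bench()
  tr <- make_trajectory(b$receptor, 20, noise_sigma = 0.3, seed = 96)
  expect_equal(n_frames(tr), 20L)
  devs <- unlist(lapply(seq_len(20), function(f)
    frame_coords(tr, f) - frame_coords(b$receptor)))
  expect_equal(sd(devs), 0.3, tolerance = 0.05)
  r <- frame_rmsd(tr, fit = FALSE)   # frame 1 is the reference
  expect_true(all(r[-1] > 0.3 & r[-1] < 0.8))
})

test_that("the native docking score beats random placements", {
  # signal check: the planted native's grid score exceeds the median
  # score of random decoy placements
  b <- get_bench()
  p <- dock_params(grid_dim = 64, resolution = 1.0)
  sg <- discretize(b$receptor, p, "static")
  score_of <- function(pose) {
    posed <- pose_apply(pose, b$probe)
    mg <- discretize(posed, p, "mobile")
    sc <- correlate(sg, mg)
    d <- round(mg$origin - sg$origin) %% p$grid_dim
    best <- -Inf         # nearest lattice placements of this pose
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      i <- (d + c(dx, dy, dz)) %% p$grid_dim
      best <- max(best, sc[i[1] + 1, i[2] + 1, i[3] + 1])
    }
    best
  }
  nat <- score_of(b$native_pose)
  dec <- get_decoys(30, 97)
  rand <- vapply(dec$poses, score_of, numeric(1))
  expect_gt(nat, stats::median(rand))
})
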