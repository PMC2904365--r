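test_that("constraint tokens parse, including ranges and en-dashes", {
  cs <- parse_constraints("30D:A 30D:B 50D:A 50D:B (97–98)D:P", 4.5)
  expect_equal(nrow(cs$constraints), 6L)
  expect_equal(cs$constraints$resno, c(30, 30, 50, 50, 97, 98))
  expect_equal(cs$constraints$probe_chain, rep("D", 6))
  expect_equal(cs$constraints$target, c("A", "B", "A", "B", "P", "P"))
  cs2 <- parse_constraints("(100-101)D:P", 4.5)
  expect_equal(cs2$constraints$resno, c(100, 101))
  expect_equal(nrow(parse_constraints("", 4.5)$constraints), 0L)
  expect_error(parse_constraints("30D", 4.5), "malformed")
  expect_error(parse_constraints("(98-97)D:P", 4.5), "range")
  expect_error(parse_constraints("x30D:A", 4.5), "malformed")
})

# micro-fixture: one probe residue vs a two-atom target chain at an
# adjustable gap
micro_filter_case <- function(gap) {
  stat <- atom_structure(
    data.frame(name = c("CA", "CB"), resname = "ALA", resno = 1L,
               chain = "A"),
    matrix(c(0, 0, 0, 1.5, 0, 0), 2, byrow = TRUE))
  mob <- atom_structure(
    data.frame(name = "CA", resname = "GLY", resno = 30L, chain = "D"),
    matrix(c(-gap, 0, 0), 1))
  list(stat = stat, mob = mob, pose = identity_pose(mob))
}

test_that("the distance cutoff is strict at the boundary", {
  cs <- parse_constraints("30D:A", 4.5)
  inside <- micro_filter_case(4.4)
  expect_length(apply_constraints(list(inside$pose), inside$stat,
                                  inside$mob, cs), 1L)
  outside <- micro_filter_case(4.6)
  expect_length(apply_constraints(list(outside$pose), outside$stat,
                                  outside$mob, cs), 0L)
  at <- micro_filter_case(4.5)
  expect_length(apply_constraints(list(at$pose), at$stat, at$mob, cs),
                0L)    # strict <
})

test_that("missing chains or residues raise specification errors", {
  c1 <- micro_filter_case(3)
  expect_error(apply_constraints(list(c1$pose), c1$stat, c1$mob,
                                 parse_constraints("31D:A", 4.5)),
               "missing residue")
  expect_error(apply_constraints(list(c1$pose), c1$stat, c1$mob,
                                 parse_constraints("30D:Q", 4.5)),
               "missing chain")
})

test_that("survivors match a brute-force distance oracle on random poses", {
  b <- get_bench()
  dec <- get_decoys(50, 41)
  poses <- c(dec$poses, list(b$native_pose))
  cs <- parse_constraints(b$truth$constraints, b$truth$cutoff)
  kept <- apply_constraints(poses, b$receptor, b$probe, cs)
  kept_ids <- vapply(kept, function(p) p$id, integer(1))
  # oracle: explicit min-distance loops straight from the parsed table
  xs <- frame_coords(b$receptor); xm0 <- frame_coords(b$probe)
  at_s <- b$receptor$atoms; at_m <- b$probe$atoms
  ok <- vapply(poses, function(p) {
    xm <- pose_apply(p, xm0)
    all(vapply(seq_len(nrow(cs$constraints)), function(j) {
      pi_ <- which(at_m$chain == cs$constraints$probe_chain[j] &
                   at_m$resno == cs$constraints$resno[j])
      ti <- which(at_s$chain == cs$constraints$target[j])
      min_pair_dist(xm[pi_, , drop = FALSE], xs[ti, , drop = FALSE]) <
        cs$cutoff
    }, logical(1)))
  }, logical(1))
  expect_setequal(kept_ids, vapply(poses[ok], function(p) p$id, integer(1)))
  expect_true(0L %in% kept_ids)       # native survives by construction
})

test_that("surviving sets are monotone in the cutoff and order-independent", {
  b <- get_bench()
  dec <- get_decoys(50, 41)
  poses <- c(dec$poses, list(b$native_pose))
  ids <- function(k) sort(vapply(k, function(p) p$id, integer(1)))
  prev <- NULL
  for (cut in c(3.5, 4.5, 5.5)) {
    cs <- parse_constraints(b$truth$constraints, cut)
    cur <- ids(apply_constraints(poses, b$receptor, b$probe, cs))
    if (!is.null(prev)) expect_true(all(prev %in% cur))
    prev <- cur
  }
  # permuted constraint order gives the same survivors
  cs <- parse_constraints(b$truth$constraints, 4.5)
  csr <- cs; csr$constraints <- cs$constraints[rev(seq_len(nrow(cs$constraints))), ]
  expect_identical(ids(apply_constraints(poses, b$receptor, b$probe, cs)),
                   ids(apply_constraints(poses, b$receptor, b$probe, csr)))
})

test_that("staged filtering reports counts but keeps the same final set", {
  b <- get_bench()
  dec <- get_decoys(50, 41)
  poses <- c(dec$poses, list(b$native_pose))
  cs <- parse_constraints(b$truth$constraints, b$truth$cutoff)
  all_mode <- apply_constraints(poses, b$receptor, b$probe, cs, "all")
  staged <- apply_constraints(poses, b$receptor, b$probe, cs, "staged")
  ids <- function(k) sort(vapply(k, function(p) p$id, integer(1)))
  expect_identical(ids(all_mode), ids(staged))
  st <- attr(staged, "stages")
  expect_equal(st$stage, c("input", "mhc_facing", "peptide_facing"))
  expect_true(all(diff(st$survivors) <= 0))
  expect_equal(st$survivors[1], length(poses))
  expect_equal(st$survivors[3], length(staged))
})

test_that("the register filter keeps central-register poses only", {
  b <- get_bench()
  spec <- register_spec(b$truth$loop_residues, "P",
                        b$truth$allowed_positions, b$truth$register_map)
  # native: CDR3 centroid sits over P5
  expect_length(apply_register_filter(list(b$native_pose), b$receptor,
                                      b$probe, spec), 1L)
  # slide the probe towards the peptide N-terminus: nearest register P1
  shifted <- b$native_pose
  shifted$translation <- shifted$translation + c(-8.4, 0, 0)
  expect_length(apply_register_filter(list(shifted), b$receptor,
                                      b$probe, spec), 0L)
  expect_error(register_spec(b$truth$loop_residues, "P", "P99",
                             b$truth$register_map), "labels")
})

test_that("register survivors equal a nearest-residue oracle on random poses", {
  b <- get_bench()
  dec <- get_decoys(50, 43)
  spec <- register_spec(b$truth$loop_residues, "P",
                        b$truth$allowed_positions, b$truth$register_map)
  kept <- apply_register_filter(dec$poses, b$receptor, b$probe, spec)
  kept_ids <- vapply(kept, function(p) p$id, integer(1))
  at_s <- b$receptor$atoms; at_m <- b$probe$atoms
  xs <- frame_coords(b$receptor); xm0 <- frame_coords(b$probe)
  loop_idx <- which(at_m$resno %in% 97:101 & at_m$element != "H")
  pep_idx <- which(at_s$chain == "P" & at_s$element != "H")
  ok <- vapply(dec$poses, function(p) {
    ctr <- colMeans(pose_apply(p, xm0)[loop_idx, , drop = FALSE])
    d <- apply(xs[pep_idx, , drop = FALSE], 1,
               function(a) sqrt(sum((a - ctr)^2)))
    lab <- b$truth$register_map[as.character(at_s$resno[pep_idx][which.min(d)])]
    lab %in% c("P5", "P6")
  }, logical(1))
  expect_setequal(kept_ids,
                  vapply(dec$poses[ok], function(p) p$id, integer(1)))
})
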