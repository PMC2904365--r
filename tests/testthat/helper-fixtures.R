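# shared fixtures and independent oracles, built in code

.fixture_cache <- new.env(parent = emptyenv())

get_bench <- function(seed = 1L) {
  key <- paste0("bench", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- make_benchmark(seed = seed)
  .fixture_cache[[key]]
}

get_decoys <- function(n, seed) {
  key <- paste0("dec", n, "_", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- make_decoys(get_bench(), n, seed = seed)
  .fixture_cache[[key]]
}

# quick structure from bare coordinates: one GLY CA per residue
blob_structure <- function(xyz, chain = "X", resname = "GLY",
                           name = "CA") {
  n <- nrow(xyz)
  atoms <- data.frame(serial = seq_len(n), name = name, element = "",
                      resname = resname, resno = seq_len(n),
                      chain = chain, stringsAsFactors = FALSE)
  new_structure(atoms, xyz, param_table = default_param_table())
}

random_blob <- function(n, extent = 10, seed = 1, chain = "X") {
  set.seed(seed)
  blob_structure(matrix(runif(3 * n, 0, extent), ncol = 3), chain = chain)
}

# a structure with explicit atom rows (name/resname/chain/resno) for
# charge- and donor-bearing fixtures
atom_structure <- function(df, xyz) {
  df$serial <- seq_len(nrow(df))
  df$element <- ""
  new_structure(df, xyz, param_table = default_param_table())
}

# ---- independent oracles --------------------------------------------

# Horn's quaternion-based absolute orientation (closed form), used as
# the superposition oracle
horn_superpose <- function(mobile, reference) {
  cm <- colMeans(mobile); cr <- colMeans(reference)
  x <- sweep(mobile, 2, cm); y <- sweep(reference, 2, cr)
  s <- crossprod(x, y)
  nmat <- matrix(0, 4, 4)
  nmat[1, 1] <- s[1, 1] + s[2, 2] + s[3, 3]
  nmat[1, 2] <- nmat[2, 1] <- s[2, 3] - s[3, 2]
  nmat[1, 3] <- nmat[3, 1] <- s[3, 1] - s[1, 3]
  nmat[1, 4] <- nmat[4, 1] <- s[1, 2] - s[2, 1]
  nmat[2, 2] <- s[1, 1] - s[2, 2] - s[3, 3]
  nmat[2, 3] <- nmat[3, 2] <- s[1, 2] + s[2, 1]
  nmat[2, 4] <- nmat[4, 2] <- s[1, 3] + s[3, 1]
  nmat[3, 3] <- -s[1, 1] + s[2, 2] - s[3, 3]
  nmat[3, 4] <- nmat[4, 3] <- s[2, 3] + s[3, 2]
  nmat[4, 4] <- -s[1, 1] - s[2, 2] + s[3, 3]
  q <- eigen(nmat, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; xq <- q[2]; yq <- q[3]; zq <- q[4]
  rot <- matrix(c(
    1 - 2 * (yq^2 + zq^2), 2 * (xq * yq - w * zq), 2 * (xq * zq + w * yq),
    2 * (xq * yq + w * zq), 1 - 2 * (xq^2 + zq^2), 2 * (yq * zq - w * xq),
    2 * (xq * zq - w * yq), 2 * (yq * zq + w * xq), 1 - 2 * (xq^2 + yq^2)),
    3, 3, byrow = TRUE)
  fitted <- x %*% t(rot) + rep(cr, each = nrow(x))  # rows: (R x_i)^T
  list(rmsd = sqrt(mean(rowSums((fitted - reference)^2))))
}

# direct cyclic cross-correlation by cell enumeration (no FFT)
direct_correlation <- function(svals, mvals) {
  n <- dim(svals)[1]
  out <- array(0, dim = dim(svals))
  occ <- which(mvals != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(occ))) {
    i <- occ[r, ]
    v <- mvals[i[1], i[2], i[3]]
    idx1 <- ((i[1] - 1 + 0:(n - 1)) %% n) + 1
    idx2 <- ((i[2] - 1 + 0:(n - 1)) %% n) + 1
    idx3 <- ((i[3] - 1 + 0:(n - 1)) %% n) + 1
    out <- out + v * svals[idx1, idx2, idx3]
  }
  out
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# minimum inter-set distance, straightforward double loop
min_pair_dist <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    d <- sqrt(colSums((t(b) - a[i, ])^2))
    best <- min(best, min(d))
  }
  best
}
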