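#' Parse a residue-chain proximity constraint specification
#'
#' The notation is whitespace-separated tokens `R C:T` written `RC:T`
#' (e.g. `"30D:A"`: residue 30 of chain D within the cutoff of any atom
#' of chain A) or `(R1-R2)C:T` for an inclusive residue range (an
#' en-dash is accepted, as in `"(97`–`98)D:P"`).  The target `T`
#' may name several chains (e.g. `AB` = any atom of chain A or B).
#'
#' @param spec Constraint string, e.g.
#'   `"30D:A 30D:B 50D:A 50D:B (97-98)D:P"`.
#' @param cutoff Distance cutoff in Angstrom (strict `<` on
#'   application).
#' @return Object of class `constraint_set`: a data.frame with one row
#'   per (residue, probe_chain, target) requirement plus the cutoff.
#' @export
parse_constraints <- function(spec, cutoff = 4.5) {
  stopifnot(cutoff > 0)
  tokens <- strsplit(trimws(spec), "\\s+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  rows <- lapply(tokens, function(tk) {
    m <- regmatches(tk, regexec(
      "^\\((\\d+)[-–](\\d+)\\)([A-Za-z0-9]):([A-Za-z0-9]+)$", tk))[[1]]
    if (length(m)) {
      lo <- as.integer(m[2]); hi <- as.integer(m[3])
      if (lo > hi) stop("malformed token (range low > high): ", tk)
      return(data.frame(resno = seq(lo, hi), probe_chain = m[4],
                        target = m[5], stringsAsFactors = FALSE))
    }
    m <- regmatches(tk, regexec("^(\\d+)([A-Za-z0-9]):([A-Za-z0-9]+)$",
                                tk))[[1]]
    if (!length(m)) stop("malformed constraint token: ", tk)
    data.frame(resno = as.integer(m[2]), probe_chain = m[3], target = m[4],
               stringsAsFactors = FALSE)
  })
  cs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(resno = integer(), probe_chain = character(),
               target = character(), stringsAsFactors = FALSE)
  out <- list(constraints = cs, cutoff = cutoff)
  class(out) <- "constraint_set"
  out
}

#' @export
print.constraint_set <- function(x, ...) {
  cat(sprintf("<constraint_set> %d constraint(s), cutoff %.2f A\n",
              nrow(x$constraints), x$cutoff))
  invisible(x)
}

# min distance between two coordinate sets
.min_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}

# atoms of (chain, resno) taken from mobile if present there, else static
.constraint_probe <- function(static, mobile, chain, resno, heavy_only) {
  for (role in c("mobile", "static")) {
    s <- if (role == "mobile") mobile else static
    idx <- residue_atoms(s, chain, resno)
    if (heavy_only) idx <- idx[.heavy(s)[idx]]
    if (length(idx)) return(list(role = role, idx = idx))
  }
  stop("constraint references missing residue ", resno, " of chain ", chain)
}

.constraint_target <- function(static, mobile, target, heavy_only) {
  chains <- strsplit(target, "")[[1]]
  for (role in c("static", "mobile")) {
    s <- if (role == "static") static else mobile
    idx <- chain_atoms(s, chains)
    if (heavy_only) idx <- idx[.heavy(s)[idx]]
    if (length(idx)) return(list(role = role, idx = idx))
  }
  stop("constraint references missing chain(s): ", target)
}

#' Apply distance constraints to candidate poses
#'
#' A pose survives iff, for every constraint, the minimum any-atom
#' distance between the probe residue and the target chain(s) is
#' strictly below the cutoff.  In `staged` mode constraints whose
#' target is not the peptide chain are applied first (the MHC-facing
#' step of the two-step binding mechanism), then the peptide-facing
#' ones, and per-stage survivor counts are attached as attribute
#' `"stages"`.
#'
#' @param poses A `pose_set` or list of [new_pose()] objects.
#' @param static,mobile The docked structures (probe residues are looked
#'   up in `mobile` first).
#' @param constraints A [parse_constraints()] object.
#' @param mode `"all"` or `"staged"`.
#' @param peptide_chain Chain id treated as the peptide for staging
#'   (default `"P"`).
#' @param heavy_only Restrict distances to heavy atoms (default FALSE:
#'   hydrogens count when present).
#' @return Surviving poses (same container type), with attribute
#'   `"stages"` (data.frame stage/survivors) in staged mode.
#' @export
apply_constraints <- function(poses, static, mobile, constraints,
                              mode = c("all", "staged"),
                              peptide_chain = "P", heavy_only = FALSE) {
  mode <- match.arg(mode)
  plist <- if (inherits(poses, "pose_set")) poses$poses else poses
  cs <- constraints$constraints
  cut <- constraints$cutoff
  # resolve atom selections once; errors surface even for empty pose lists
  res <- lapply(seq_len(nrow(cs)), function(i) {
    p <- .constraint_probe(static, mobile, cs$probe_chain[i], cs$resno[i],
                           heavy_only)
    t <- .constraint_target(static, mobile, cs$target[i], heavy_only)
    list(probe = p, target = t,
         peptide_facing = cs$target[i] == peptide_chain)
  })
  xs <- frame_coords(static, 1L)
  xm <- frame_coords(mobile, 1L)
  satisfied <- function(pose, r) {
    pm <- pose_apply(pose, xm)
    pick <- function(side) {
      x <- if (side$role == "mobile") pm else xs
      x[side$idx, , drop = FALSE]
    }
    .min_dist(pick(r$probe), pick(r$target)) < cut
  }
  order_idx <- seq_along(res)
  stage_counts <- NULL
  if (mode == "staged" && length(res)) {
    pep <- vapply(res, `[[`, logical(1), "peptide_facing")
    keep1 <- vapply(plist, function(p)
      all(vapply(res[!pep], satisfied, logical(1), pose = p)), logical(1))
    stage1 <- plist[keep1]
    keep2 <- vapply(stage1, function(p)
      all(vapply(res[pep], satisfied, logical(1), pose = p)), logical(1))
    kept <- stage1[keep2]
    stage_counts <- data.frame(
      stage = c("input", "mhc_facing", "peptide_facing"),
      survivors = c(length(plist), length(stage1), length(kept)))
  } else {
    keep <- vapply(plist, function(p)
      all(vapply(res, satisfied, logical(1), pose = p)), logical(1))
    kept <- if (length(plist)) plist[keep] else plist
  }
  out <- if (inherits(poses, "pose_set")) { poses$poses <- kept; poses }
         else kept
  if (!is.null(stage_counts)) attr(out, "stages") <- stage_counts
  out
}

#' Peptide-register filter specification
#'
#' @param loop_residues data.frame (chain, resno) naming the CDR3 apex
#'   residues on the probe.
#' @param peptide_chain Chain id of the groove-bound peptide.
#' @param allowed_positions Character vector of register labels a pose
#'   may focus on (e.g. `c("P5", "P6")`).
#' @param register_map Named character vector mapping peptide residue
#'   numbers (names) to register labels (values), e.g.
#'   `c("263" = "P1", ...)`; caller-supplied, never inferred.
#' @return list of class `register_spec`.
#' @export
register_spec <- function(loop_residues, peptide_chain, allowed_positions,
                          register_map) {
  if (!all(allowed_positions %in% register_map))
    stop("allowed_positions must be labels of register_map")
  s <- list(loop_residues = loop_residues, peptide_chain = peptide_chain,
            allowed_positions = allowed_positions,
            register_map = register_map)
  class(s) <- "register_spec"
  s
}

#' Apply the CDR3 register (topology) filter
#'
#' Operationalizes the visual-inspection step: a pose survives iff the
#' peptide residue nearest (minimum heavy-atom distance) to the
#' centroid of the CDR3 loop residues carries a register label in
#' `allowed_positions` (e.g. the central P5-P6 positions).
#'
#' @inheritParams apply_constraints
#' @param spec A [register_spec()].
#' @return Surviving poses (same container type as `poses`).
#' @export
apply_register_filter <- function(poses, static, mobile, spec) {
  plist <- if (inherits(poses, "pose_set")) poses$poses else poses
  pep_idx <- chain_atoms(static, spec$peptide_chain)
  pep_idx <- pep_idx[.heavy(static)[pep_idx]]
  if (!length(pep_idx)) stop("empty peptide chain: ", spec$peptide_chain)
  pep_res <- static$atoms$resno[pep_idx]
  xs <- frame_coords(static, 1L)
  loop_idx <- unlist(lapply(seq_len(nrow(spec$loop_residues)), function(i) {
    idx <- residue_atoms(mobile, spec$loop_residues$chain[i],
                         spec$loop_residues$resno[i])
    idx[.heavy(mobile)[idx]]
  }))
  if (!length(loop_idx)) stop("loop residues not found in mobile structure")
  xm <- frame_coords(mobile, 1L)
  keep <- vapply(plist, function(p) {
    ctr <- colMeans(pose_apply(p, xm)[loop_idx, , drop = FALSE])
    d <- sqrt(rowSums(sweep(xs[pep_idx, , drop = FALSE], 2, ctr)^2))
    nearest <- pep_res[which.min(d)]
    lab <- spec$register_map[as.character(nearest)]
    !is.na(lab) && lab %in% spec$allowed_positions
  }, logical(1))
  if (inherits(poses, "pose_set")) {
    poses$poses <- if (length(plist)) plist[keep] else plist
    poses
  } else if (length(plist)) plist[keep] else plist
}
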