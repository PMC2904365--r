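#' Truncate a residue to alanine
#'
#' Removes all side-chain heavy atoms beyond the beta carbon together
#' with their hydrogens (names at Greek positions gamma and beyond),
#' renames the residue ALA and retypes CB with alanine parameters.
#' Backbone atoms, CB and its hydrogens are untouched.
#'
#' @param structure A parameterized [new_structure()] object.
#' @param chain Chain id of the residue.
#' @param resno Residue number.
#' @param param_table Parameter table used to retype the mutant.
#' @return The mutated `structure3d`.
#' @export
mutate_to_alanine <- function(structure, chain, resno,
                              param_table = default_param_table()) {
  idx <- residue_atoms(structure, chain, resno)
  if (!length(idx)) stop("residue ", resno, " of chain ", chain,
                         " not found")
  resname <- structure$atoms$resname[idx[1]]
  if (resname %in% c("GLY", "PRO"))
    stop("residue ", resname, " is not scannable (no mutable side chain)")
  keep_heavy <- c("N", "CA", "C", "O", "OXT", "CB")
  keep_h_prefix <- c("H", "HN", "HA", "HB")   # backbone + beta hydrogens
  nm <- structure$atoms$name[idx]
  el <- structure$atoms$element[idx]
  base <- toupper(sub("^[0-9]+", "", nm))      # strip leading digits
  is_h <- el == "H"
  keep <- (!is_h & nm %in% keep_heavy) |
    (is_h & (base %in% keep_h_prefix |
               substr(base, 1, 2) %in% c("HA", "HB") | base == "H"))
  drop <- idx[!keep]
  out <- if (length(drop)) subset_structure(structure,
                                            setdiff(seq_len(n_atoms(structure)),
                                                    drop))
         else structure
  ridx <- residue_atoms(out, chain, resno)
  out$atoms$resname[ridx] <- "ALA"
  out$atoms <- .parameterize_atoms(out$atoms, param_table)
  out
}

#' Simplified computational alanine scan of an interface
#'
#' For every interface residue of `partA` (a residue appearing in
#' [vdw_contacts()] at `contact_cutoff`), the residue is truncated to
#' alanine and the change in pairwise interaction energy is recorded:
#' `ddg_proxy = E(mutant) - E(wild type)`, oriented so destabilizing
#' mutations are positive.  Residues with `ddg_proxy >=
#' hotspot_threshold` are flagged hotspots.  Gly, Pro and Ala rows are
#' reported as not scannable.  This is a deterministic
#' energy-difference proxy (no repacking, no trained energy function);
#' per-residue values are comparable only within this parameterization.
#'
#' @param partA Structure whose residues are scanned (e.g. the TCR
#'   probe side).
#' @param partB The binding partner.
#' @param eparams An [energy_params()] object.
#' @param threshold Hotspot threshold, kcal/mol (default 1.0).
#' @param contact_cutoff Interface definition cutoff, A (default 4.0).
#' @param param_table Parameter table for mutant retyping.
#' @return data.frame of class `hotspot_report`: chain, resno, resname,
#'   ddg_proxy, is_hotspot, scannable; sorted by ddg_proxy descending.
#' @export
scan_interface <- function(partA, partB, eparams = energy_params(),
                           threshold = 1.0, contact_cutoff = 4.0,
                           param_table = default_param_table()) {
  stopifnot(threshold > 0)
  ct <- vdw_contacts(partA, partB, contact_cutoff)
  if (!nrow(ct)) {
    message("no interface residues at ", contact_cutoff, " A")
    out <- data.frame(chain = character(), resno = integer(),
                      resname = character(), ddg_proxy = numeric(),
                      is_hotspot = logical(), scannable = logical())
    class(out) <- c("hotspot_report", class(out))
    return(out)
  }
  resmask <- !duplicated(paste(ct$chainA, ct$resnoA))
  targets <- ct[resmask, c("chainA", "resnoA", "resnameA")]
  e_wt <- interaction_energy(partA, partB, eparams)
  rows <- lapply(seq_len(nrow(targets)), function(i) {
    ch <- targets$chainA[i]; rn <- targets$resnoA[i]
    nm <- targets$resnameA[i]
    if (nm %in% c("GLY", "PRO", "ALA"))
      return(data.frame(chain = ch, resno = rn, resname = nm,
                        ddg_proxy = if (nm == "ALA") 0 else NA_real_,
                        is_hotspot = FALSE, scannable = FALSE))
    mut <- mutate_to_alanine(partA, ch, rn, param_table)
    ddg <- interaction_energy(mut, partB, eparams) - e_wt
    data.frame(chain = ch, resno = rn, resname = nm, ddg_proxy = ddg,
               is_hotspot = ddg >= threshold, scannable = TRUE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-replace(out$ddg_proxy, is.na(out$ddg_proxy), -Inf)), ]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  class(out) <- c("hotspot_report", class(out))
  out
}
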