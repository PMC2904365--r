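#' Pipeline configuration
#'
#' Bundles everything needed for the end-to-end selection procedure:
#' dock (or take supplied poses), Coulombic screen, distance-constraint
#' filter, register filter, per-survivor interface scoring, ranking,
#' selection.
#'
#' @param static,mobile `structure3d` objects (receptor and probe).
#' @param dock_params A [dock_params()]; ignored when `poses` given.
#' @param constraints Constraint string (see [parse_constraints()]) or
#'   NULL to skip the constraint filter.
#' @param cutoff Constraint cutoff, A.
#' @param register A [register_spec()] or NULL to skip the register
#'   filter.
#' @param energy_params An [energy_params()].
#' @param ranking `"joint"`, `"energy"` or `"asa"`.
#' @param poses Optional pre-computed pose list (e.g. decoys); skips
#'   the docking stage.
#' @param seed Integer seed.
#' @param asa_points ASA sampling points per atom used in scoring.
#' @param max_scored Cap on the number of survivors scored with
#'   energy/ASA (top by shape score first).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(static, mobile, dock_params = NULL,
                            constraints = NULL, cutoff = 4.5,
                            register = NULL,
                            energy_params = NULL,
                            ranking = c("joint", "energy", "asa"),
                            poses = NULL, seed = 1L, asa_points = 480L,
                            max_scored = 25L) {
  ranking <- match.arg(ranking)
  cfg <- list(static = static, mobile = mobile,
              dock_params = if (is.null(dock_params)) dock_params()
                            else dock_params,
              constraints = constraints, cutoff = cutoff,
              register = register,
              energy_params = if (is.null(energy_params)) energy_params()
                              else energy_params,
              ranking = ranking, poses = poses, seed = as.integer(seed),
              asa_points = as.integer(asa_points),
              max_scored = as.integer(max_scored))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Rank scored survivors and select a model
#'
#' The `joint` rule selects the pose maximal in both binding-energy
#' magnitude (most negative `energy`) and interface ASA when such a
#' double maximizer exists; otherwise it falls back to the best
#' rank-sum over the two keys (noted in the rationale).  `energy` /
#' `asa` are single-key sorts.  Ties break towards the lower pose id.
#'
#' @param table data.frame with columns id, energy, asa.
#' @param rule `"joint"`, `"energy"` or `"asa"`.
#' @return list: table (ordered), selected (pose id), rationale.
#' @export
rank_survivors <- function(table, rule = c("joint", "energy", "asa")) {
  rule <- match.arg(rule)
  if (!nrow(table))
    return(list(table = table, selected = NA_integer_,
                rationale = "empty survivor table"))
  r_e <- rank(table$energy, ties.method = "min")          # low = best
  r_a <- rank(-table$asa, ties.method = "min")
  if (rule == "energy") {
    ord <- order(table$energy, table$id)
    sel <- table$id[ord[1]]
    rationale <- "largest binding-energy magnitude (most negative energy)"
  } else if (rule == "asa") {
    ord <- order(-table$asa, table$id)
    sel <- table$id[ord[1]]
    rationale <- "largest buried interface ASA"
  } else {
    both <- which(r_e == 1 & r_a == 1)
    if (length(both)) {
      sel <- min(table$id[both])
      rationale <- "dominates both keys: largest binding energy and interface ASA"
    } else {
      rs <- r_e + r_a
      cand <- which(rs == min(rs))
      sel <- min(table$id[cand])
      rationale <- "no double maximizer; best rank-sum of energy and ASA"
    }
    ord <- order(r_e + r_a, table$id)
  }
  list(table = table[ord, , drop = FALSE], selected = sel,
       rationale = rationale)
}

#' Run the full docking / filtering / ranking pipeline
#'
#' Stages: dock (or supplied poses) -> Coulombic screen -> distance
#' constraints -> register filter -> per-survivor interaction energy +
#' interface ASA -> ranking -> selection.  Deterministic given the
#' config and seed.  If a stage empties the pose list the report names
#' it and no selection is made (no error).
#'
#' @param config A [pipeline_config()].
#' @return list of class `selection_report`: stages (data.frame stage /
#'   survivors), table (scored survivors), selected (pose id or NA),
#'   rationale, poses (named by id, the scored survivors), emptied_at.
#' @export
run_pipeline <- function(config) {
  stages <- list()
  note <- function(nm, n) stages[[length(stages) + 1L]] <<-
    data.frame(stage = nm, survivors = n)
  if (is.null(config$poses)) {
    ps <- dock(config$static, config$mobile, config$dock_params,
               seed = config$seed)
    plist <- ps$poses
  } else {
    plist <- if (inherits(config$poses, "pose_set")) config$poses$poses
             else config$poses
  }
  note("poses", length(plist))
  emptied <- NA_character_
  if (length(plist) && config$dock_params$electrostatic_filter) {
    plist <- electrostatic_screen(plist, config$static, config$mobile)
  }
  note("electrostatic_screen", length(plist))
  if (!length(plist) && is.na(emptied)) emptied <- "electrostatic_screen"
  if (length(plist) && !is.null(config$constraints)) {
    cs <- parse_constraints(config$constraints, config$cutoff)
    plist <- apply_constraints(plist, config$static, config$mobile, cs)
    if (!length(plist) && is.na(emptied)) emptied <- "constraint_filter"
  }
  note("constraint_filter", length(plist))
  if (length(plist) && !is.null(config$register)) {
    plist <- apply_register_filter(plist, config$static, config$mobile,
                                   config$register)
    if (!length(plist) && is.na(emptied)) emptied <- "register_filter"
  }
  note("register_filter", length(plist))
  scored <- data.frame(id = integer(), shape_score = numeric(),
                       energy = numeric(), asa = numeric())
  if (length(plist)) {
    if (length(plist) > config$max_scored) {
      ss <- vapply(plist, function(p)
        if (is.na(p$shape_score)) -Inf else p$shape_score, numeric(1))
      plist <- plist[order(-ss)][seq_len(config$max_scored)]
    }
    rows <- lapply(plist, function(p) {
      posed <- pose_apply(p, config$mobile)
      data.frame(
        id = p$id, shape_score = p$shape_score,
        energy = interaction_energy(posed, config$static,
                                    config$energy_params),
        asa = interface_asa(posed, config$static,
                            n_points = config$asa_points))
    })
    scored <- do.call(rbind, rows)
  }
  note("scored", nrow(scored))
  rk <- rank_survivors(scored, config$ranking)
  rep <- list(stages = do.call(rbind, stages), table = rk$table,
              selected = rk$selected, rationale = rk$rationale,
              poses = stats::setNames(plist,
                                      vapply(plist, function(p)
                                        as.character(p$id), character(1))),
              emptied_at = emptied)
  class(rep) <- "selection_report"
  rep
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report>\n")
  print(x$stages, row.names = FALSE)
  if (!is.na(x$selected))
    cat(sprintf("selected pose: %s (%s)\n", x$selected, x$rationale))
  else cat(sprintf("no selection (emptied at: %s)\n", x$emptied_at))
  invisible(x)
}

#' Write a selection report to disk
#'
#' Writes `survivors_scored.tsv`, `selection.json`, and (when a
#' selection exists) `final_model.pdb` with the static structure and
#' the selected posed mobile structure.
#'
#' @param report A [run_pipeline()] report.
#' @param config The [pipeline_config()] used.
#' @param dir Output directory (created if needed).
#' @export
write_selection_report <- function(report, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$table, file.path(dir, "survivors_scored.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(stages = report$stages, selected = report$selected,
         rationale = report$rationale, emptied_at = report$emptied_at),
    file.path(dir, "selection.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  if (!is.na(report$selected)) {
    sel <- report$poses[[as.character(report$selected)]]
    model <- combine_structures(config$static,
                                pose_apply(sel, config$mobile))
    save_structure(model, file.path(dir, "final_model.pdb"))
  }
  invisible(dir)
}

#' Per-pose RMSD of posed mobile coordinates against a reference
#'
#' Computes, for each pose, the RMSD of the selected mobile atoms to
#' the reference coordinates in the static frame (the static part is
#' the alignment frame, as in redocking validation), and bins the
#' values (< 4.5, 4.5-8, > 8 A).
#'
#' @param poses A `pose_set` or list of poses.
#' @param mobile The mobile structure.
#' @param reference n x 3 reference coordinates for the selection (e.g.
#'   the native posed mobile), or a pose to derive them from.
#' @param selection Atom index into `mobile` (default: CA atoms).
#' @return list: rmsd (data.frame id, rmsd), bins (named counts).
#' @export
validate_against_reference <- function(poses, mobile, reference,
                                       selection = NULL) {
  plist <- if (inherits(poses, "pose_set")) poses$poses else poses
  if (is.null(selection))
    selection <- which(mobile$atoms$name == "CA")
  if (!length(selection)) stop("empty selection")
  xyz <- frame_coords(mobile, 1L)[selection, , drop = FALSE]
  if (inherits(reference, "dock_pose"))
    reference <- pose_apply(reference,
                            frame_coords(mobile, 1L))[selection, ,
                                                      drop = FALSE]
  if (!all(dim(reference) == dim(xyz)))
    stop("reference dimensions do not match the selection")
  r <- vapply(plist, function(p)
    rmsd_raw(pose_apply(p, frame_coords(mobile, 1L))[selection, ,
                                                     drop = FALSE],
             reference), numeric(1))
  ids <- vapply(plist, function(p) p$id, integer(1))
  bins <- c(`<4.5` = sum(r < 4.5), `4.5-8` = sum(r >= 4.5 & r < 8),
            `>8` = sum(r >= 8))
  list(rmsd = data.frame(id = ids, rmsd = r), bins = bins)
}
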