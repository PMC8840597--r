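# TM6-deflection activation-state analysis.
#
# The deflection metric is the Calpha-Calpha distance between the
# intracellular anchor residues 6.31 (bottom of TM6) and 4.40 (bottom of
# TM4). The TM6 outward movement that accompanies class-A GPCR activation
# increases this distance; frames are classified against reference
# distances measured on active- and inactive-state crystal structures.

#' Crystal-referenced activation-state thresholds
#'
#' Reference distances are user inputs, typically measured on the active
#' and inactive crystal structures of the receptor of interest; the package
#' never fetches structures itself.
#'
#' @param receptor_id identifier
#' @param residue_631,residue_440 residue specs (author number or BW label)
#'   of the TM6 and TM4 intracellular anchors
#' @param active_ref_dist,inactive_ref_dist reference deflections in
#'   Angstrom (must differ; normally active > inactive)
#' @param tolerance band half-width in Angstrom added around each reference
#'   (default 0: the open interval between the references is intermediate,
#'   boundary values belong to the end states)
#' @param use_carbonyl measure between backbone carbonyl carbons (`C`)
#'   instead of Calpha atoms
#' @export
state_reference <- function(receptor_id, residue_631 = "6.31",
                            residue_440 = "4.40",
                            active_ref_dist, inactive_ref_dist,
                            tolerance = 0, use_carbonyl = FALSE) {
  if (active_ref_dist == inactive_ref_dist) {
    stop("active and inactive reference distances must differ")
  }
  if (tolerance < 0) stop("tolerance must be >= 0")
  structure(
    list(receptor_id = receptor_id, residue_631 = residue_631,
         residue_440 = residue_440, active_ref_dist = active_ref_dist,
         inactive_ref_dist = inactive_ref_dist, tolerance = tolerance,
         use_carbonyl = use_carbonyl),
    class = "state_reference"
  )
}

#' Read a state reference from YAML
#' @param path YAML file with fields matching [state_reference()] arguments
#' @export
read_state_reference <- function(path) {
  y <- yaml::read_yaml(path)
  state_reference(
    receptor_id = y$receptor %||% y$receptor_id,
    residue_631 = y$residue_631 %||% "6.31",
    residue_440 = y$residue_440 %||% "4.40",
    active_ref_dist = y$active_ref_dist,
    inactive_ref_dist = y$inactive_ref_dist,
    tolerance = y$tolerance %||% 0,
    use_carbonyl = isTRUE(y$use_carbonyl)
  )
}

state_anchor_atoms <- function(system, reference) {
  nm <- if (isTRUE(reference$use_carbonyl)) "C" else "CA"
  a631 <- tryCatch(
    resolve_residue(system, reference$residue_631, names = nm),
    error = function(e) stop("TM6 anchor: ", conditionMessage(e))
  )
  a440 <- tryCatch(
    resolve_residue(system, reference$residue_440, names = nm),
    error = function(e) stop("TM4 anchor: ", conditionMessage(e))
  )
  c(a631[1], a440[1])
}

#' TM6 deflection of one frame (or all frames)
#'
#' @param system a `molecular_system` with BW labels assigned (or numeric
#'   residue specs in the reference)
#' @param frame 1-based frame index, or NULL for the whole trajectory
#' @param reference a [state_reference()]
#' @return distance(s) in Angstrom
#' @export
tm6_deflection <- function(system, frame = NULL, reference) {
  idx <- state_anchor_atoms(system, reference)
  d <- min_dist_series(system$frames, idx[1], idx[2])
  if (is.null(frame)) d else d[frame]
}

#' Classify frames by TM6 deflection
#'
#' `active_like` when `d >= active_ref_dist - tolerance`, `inactive_like`
#' when `d <= inactive_ref_dist + tolerance`, `intermediate` otherwise.
#' The classification is monotone in d. If the reference distances are
#' inverted (active < inactive) they are swapped with a warning.
#'
#' @param deflection numeric vector of deflections in Angstrom
#' @param reference a [state_reference()]
#' @return character vector of labels
#' @export
classify_frame <- function(deflection, reference) {
  if (any(!is.finite(deflection))) stop("non-finite deflection")
  act <- reference$active_ref_dist
  inact <- reference$inactive_ref_dist
  if (act < inact) {
    warning("active reference below inactive reference; swapping")
    tmp <- act; act <- inact; inact <- tmp
  }
  tol <- reference$tolerance
  ifelse(deflection >= act - tol, "active_like",
         ifelse(deflection <= inact + tol, "inactive_like", "intermediate"))
}

#' Activation-state fractions across replicates
#'
#' Classifies every frame of every replicate (frames pooled across
#' replicates) and reports the percentage of each state.
#'
#' @param replicates list of `molecular_system`s (or a single system)
#' @param reference a [state_reference()]
#' @return object of class `state_profile` with per-replicate label
#'   vectors, pooled `fractions` (%) and `n_frames`
#' @export
state_fractions <- function(replicates, reference) {
  if (inherits(replicates, "molecular_system")) replicates <- list(replicates)
  if (!length(replicates)) stop("at least one replicate is required")
  labels <- lapply(replicates, function(s) {
    classify_frame(tm6_deflection(s, NULL, reference), reference)
  })
  pooled <- unlist(labels)
  lv <- c("active_like", "intermediate", "inactive_like")
  frac <- 100 * vapply(lv, function(l) mean(pooled == l), numeric(1))
  structure(
    list(labels = labels, fractions = frac, n_frames = length(pooled),
         receptor_id = reference$receptor_id),
    class = "state_profile"
  )
}

#' @export
print.state_profile <- function(x, ...) {
  cat("<state_profile>",
      if (!is.null(x$receptor_id)) paste0(" ", x$receptor_id), "\n", sep = "")
  cat("  frames:", x$n_frames, "\n")
  print(round(x$fractions, 1))
  invisible(x)
}

#' Write a state profile as JSON (and optionally per-frame labels as CSV)
#' @param x a `state_profile`
#' @param json_path output JSON
#' @param csv_path optional CSV with columns replicate, frame, label
#' @export
write_state_profile <- function(x, json_path, csv_path = NULL) {
  jsonlite::write_json(
    list(receptor = x$receptor_id, n_frames = x$n_frames,
         fractions = as.list(x$fractions)),
    json_path, auto_unbox = TRUE, digits = NA
  )
  if (!is.null(csv_path)) {
    rows <- do.call(rbind, lapply(seq_along(x$labels), function(r) {
      data.frame(replicate = r, frame = seq_along(x$labels[[r]]),
                 label = x$labels[[r]])
    }))
    utils::write.csv(rows, csv_path, row.names = FALSE)
  }
  invisible(x)
}

#' Occupancy of the TM5-TM6 salt bridge
#'
#' Percentage of frames in which the K5.39 / E6.58 side chains form an
#' ionic contact; a persistent bridge tethers TM6 to TM5 and is expected to
#' hinder the activation-related TM6 outward movement.
#'
#' @param system a `molecular_system`
#' @param k539,e658 residue specs of the bridge partners
#' @param criteria an [interaction_criteria()]
#' @return occupancy in percent
#' @export
tm5_tm6_bridge_occupancy <- function(system, k539 = "5.39", e658 = "6.58",
                                     criteria = interaction_criteria()) {
  def <- interaction_definition("PI", res_a = k539, res_b = e658)
  pair_occupancy(system, def, criteria)
}
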