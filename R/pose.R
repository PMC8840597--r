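# Docking-pose rescoring against a reference interaction fingerprint.
#
# Externally generated poses are re-evaluated by (1) counting how many
# entries of a reference interaction pattern they reproduce, (2) enforcing
# a maximum distance between the ligand's protonated ring amine and the
# side-chain carboxylate carbon of D3.32, and (3) ranking by score with
# ties broken by that same amine-D3.32 distance.

#' Reference interaction fingerprint
#'
#' @param receptor_id identifier
#' @param entries data.frame with columns `itype` (one of `PI`, `HY`,
#'   `HBA`, `HBD`, `HBA/HBD`, `WATER_MEDIATED`) and `partner` (residue
#'   spec: author number or BW label, or `"HOH"` for a water-mediated
#'   entry). An optional `receptor_atom` column restricts the receptor-side
#'   atoms (e.g. backbone `"O"`).
#' @return object of class `reference_fingerprint`
#' @export
reference_fingerprint <- function(receptor_id, entries) {
  stopifnot(is.data.frame(entries), nrow(entries) >= 1,
            all(c("itype", "partner") %in% names(entries)))
  ok <- c("PI", "NI", "HY", "HBA", "HBD", "HBA/HBD", "WATER_MEDIATED")
  bad <- setdiff(entries$itype, ok)
  if (length(bad)) stop("unknown entry itype(s): ", paste(bad, collapse = ", "))
  if (!"receptor_atom" %in% names(entries)) entries$receptor_atom <- NA_character_
  structure(list(receptor_id = receptor_id, entries = entries),
            class = "reference_fingerprint")
}

#' Read a reference fingerprint from YAML
#'
#' Layout: `receptor`, `entries: [{itype, partner, receptor_atom?}, ...]`.
#' @param path YAML file
#' @export
read_reference_fingerprint <- function(path) {
  y <- yaml::read_yaml(path)
  entries <- do.call(rbind, lapply(y$entries, function(e) {
    data.frame(itype = e$itype, partner = as.character(e$partner),
               receptor_atom = e$receptor_atom %||% NA_character_,
               stringsAsFactors = FALSE)
  }))
  reference_fingerprint(y$receptor %||% y$receptor_id, entries)
}

#' Match one fingerprint entry against a pose
#' @noRd
match_entry <- function(pose, itype, partner, receptor_atom, criteria) {
  ratom <- if (!is.na(receptor_atom)) receptor_atom
  if (itype == "WATER_MEDIATED" || identical(as.character(partner), "HOH")) {
    return(match_water_entry(pose, criteria))
  }
  part <- resolve_residue(pose, partner, names = ratom)
  lig_all <- which(pose$atoms$kind == "ligand")
  if (itype == "PI") {
    cat_atoms <- charged_subset(pose, lig_all, +1)
    an_atoms <- charged_subset(pose, part, -1)
    if (!length(an_atoms)) return(FALSE)
    !is.null(detect_ionic(pose, 1, cat_atoms, an_atoms, criteria))
  } else if (itype == "NI") {
    an_atoms <- charged_subset(pose, lig_all, -1)
    cat_atoms <- charged_subset(pose, part, +1)
    if (!length(cat_atoms)) return(FALSE)
    !is.null(detect_ionic(pose, 1, cat_atoms, an_atoms, criteria, itype = "NI"))
  } else if (itype == "HY") {
    a <- apolar_subset(pose, lig_all)
    b <- apolar_subset(pose, part)
    if (!length(b)) return(FALSE)
    !is.null(suppressWarnings(detect_hydrophobic(pose, 1, a, b, criteria)))
  } else {
    # hydrogen bond in either direction, heavy-atom surrogate geometry
    lig_polar <- polar_subset(pose, lig_all)
    rec_polar <- polar_subset(pose, part)
    if (!length(lig_polar) || !length(rec_polar)) return(FALSE)
    any(vapply(lig_polar, function(la) {
      !is.null(detect_hbond(pose, 1, hbond_donor(la), rec_polar, criteria))
    }, logical(1)))
  }
}

#' Water-mediated entries match if any retained water bridges any polar
#' ligand atom to any polar protein atom (waters carry no stable identity
#' across poses).
#' @noRd
match_water_entry <- function(pose, criteria) {
  waters <- water_oxygens(pose)
  if (!length(waters)) return(FALSE)
  lig_polar <- polar_subset(pose, which(pose$atoms$kind == "ligand"))
  prot_polar <- which(pose$atoms$kind == "protein" &
                        pose$atoms$element %in% c("N", "O"))
  xyz <- frame_coords(pose, 1)
  for (w in waters) {
    dl <- cross_dist(xyz[w, , drop = FALSE],
                     xyz[lig_polar, , drop = FALSE])[1, ]
    if (min(dl) > criteria$hbond_max_dist) next
    dp <- cross_dist(xyz[w, , drop = FALSE],
                     xyz[prot_polar, , drop = FALSE])[1, ]
    if (min(dp) <= criteria$hbond_max_dist) return(TRUE)
  }
  FALSE
}

#' Amine-to-D3.32 constraint distance of a pose
#'
#' Distance between the ligand's protonated ring (morphinan) amine nitrogen
#' and the side-chain carboxylate carbon (gamma C) of D3.32.
#' @noRd
constraint_distance <- function(pose, criteria) {
  n_idx <- polar_subset(pose, ligand_group_atoms(pose, "morphinan_amine"))
  n_idx <- n_idx[pose$atoms$element[n_idx] == "N"]
  if (!length(n_idx)) stop("morphinan_amine group contains no nitrogen")
  d332 <- tryCatch(
    resolve_residue(pose, "3.32", names = "CG"),
    error = function(e) stop("D3.32 gamma carbon unresolvable: ",
                             conditionMessage(e))
  )
  xyz <- frame_coords(pose, 1)
  min(cross_dist(xyz[n_idx, , drop = FALSE], xyz[d332, , drop = FALSE]))
}

#' Evaluate a docking pose against a reference fingerprint
#'
#' @param pose single-frame `molecular_system` (receptor + ligand + waters)
#' @param reference a [reference_fingerprint()]
#' @param criteria an [interaction_criteria()]
#' @param max_constraint maximum allowed amine-D3.32 distance in Angstrom
#' @param pose_id identifier recorded in the result
#' @return one-row data.frame of class `pose_evaluation`: `pose_id`,
#'   `score` (number of matched reference entries), `constraint_distance`,
#'   `constraint_pass`, `matched` (semicolon-joined matched entries)
#' @export
evaluate_pose <- function(pose, reference, criteria = interaction_criteria(),
                          max_constraint = 5.5, pose_id = NA_character_) {
  stopifnot(inherits(reference, "reference_fingerprint"))
  if (n_frames(pose) != 1) stop("a pose must be a single-frame system")
  entries <- reference$entries
  hit <- vapply(seq_len(nrow(entries)), function(i) {
    match_entry(pose, entries$itype[i], entries$partner[i],
                entries$receptor_atom[i], criteria)
  }, logical(1))
  cdist <- constraint_distance(pose, criteria)
  out <- data.frame(
    pose_id = as.character(pose_id),
    score = sum(hit),
    constraint_distance = cdist,
    constraint_pass = cdist <= max_constraint,
    matched = paste(paste0(entries$itype[hit], ":", entries$partner[hit]),
                    collapse = ";"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("pose_evaluation", class(out))
  out
}

#' Evaluate a list of poses
#' @param poses named list of single-frame systems (names become pose ids)
#' @inheritParams evaluate_pose
#' @export
evaluate_poses <- function(poses, reference,
                           criteria = interaction_criteria(),
                           max_constraint = 5.5) {
  ids <- names(poses) %||% as.character(seq_along(poses))
  out <- do.call(rbind, lapply(seq_along(poses), function(i) {
    evaluate_pose(poses[[i]], reference, criteria, max_constraint, ids[i])
  }))
  out
}

#' Filter pose evaluations on the amine-D3.32 distance constraint
#'
#' Keeps poses with `constraint_distance <= max_constraint` (inclusive).
#' An empty input yields an empty output.
#'
#' @param evaluations data.frame of pose evaluations
#' @param max_constraint distance constraint in Angstrom
#' @export
filter_constraint <- function(evaluations, max_constraint = 5.5) {
  evaluations[evaluations$constraint_distance <= max_constraint, ,
              drop = FALSE]
}

#' Rank pose evaluations
#'
#' Descending score; ties broken by ascending amine-D3.32 distance (the
#' pose with the lowest distance among equally scored poses wins);
#' remaining ties by pose id (stable, total order).
#'
#' @param evaluations non-empty data.frame of pose evaluations
#' @return the same rows reordered, with a `rank` column added
#' @export
rank_poses <- function(evaluations) {
  if (is.null(evaluations) || nrow(evaluations) == 0) {
    stop("cannot rank an empty pose list")
  }
  ord <- order(-evaluations$score, evaluations$constraint_distance,
               evaluations$pose_id)
  out <- evaluations[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Built-in rescoring fingerprints for the opioid receptors
#'
#' Reference patterns for pose rescoring, expressed in BW labels: the
#' conserved D3.32 salt bridge, hydrophobic contacts of the morphinan
#' scaffold (3.36, 5.42, 6.55; additionally 6.51 and 7.35 at the MOR), a
#' hydrogen bond to Y3.33 at DOR/KOR, and a water-mediated bond. The
#' `"NOP_inactive"` pattern follows the antagonist-bound pocket: the D3.32
#' salt bridge plus hydrophobic contacts to 3.29, 3.31, 3.33, 3.36, 6.51
#' and 6.55.
#'
#' @param receptor one of `"MOR"`, `"DOR"`, `"KOR"`, `"NOP"`,
#'   `"NOP_inactive"`
#' @return a [reference_fingerprint()]
#' @export
builtin_reference_fingerprint <- function(receptor = c("MOR", "DOR", "KOR",
                                                       "NOP", "NOP_inactive")) {
  receptor <- match.arg(receptor)
  e <- function(itype, partner) data.frame(itype = itype, partner = partner,
                                           stringsAsFactors = FALSE)
  entries <- switch(receptor,
    MOR = rbind(e("PI", "3.32"), e("HY", "3.36"), e("HY", "5.42"),
                e("HY", "6.51"), e("HY", "6.55"), e("HY", "7.35"),
                e("WATER_MEDIATED", "HOH")),
    DOR = rbind(e("PI", "3.32"), e("HY", "3.36"), e("HY", "5.42"),
                e("HY", "6.55"), e("HBA/HBD", "3.33"),
                e("WATER_MEDIATED", "HOH")),
    KOR = rbind(e("PI", "3.32"), e("HY", "3.36"), e("HY", "5.42"),
                e("HY", "6.55"), e("HBA/HBD", "3.33"),
                e("WATER_MEDIATED", "HOH")),
    NOP = rbind(e("PI", "3.32"), e("HY", "3.36"), e("HY", "5.42"),
                e("HY", "6.55"), e("WATER_MEDIATED", "HOH")),
    NOP_inactive = rbind(e("PI", "3.32"), e("HY", "3.29"), e("HY", "3.31"),
                         e("HY", "3.33"), e("HY", "3.36"), e("HY", "6.51"),
                         e("HY", "6.55"))
  )
  reference_fingerprint(receptor, entries)
}

#' Write a pose report as CSV (and optionally JSON)
#' @param evaluations ranked pose evaluations
#' @param csv_path,json_path output files (either may be NULL)
#' @export
write_pose_report <- function(evaluations, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(evaluations), csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(as.data.frame(evaluations), json_path,
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(evaluations)
}
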