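# Dynamic-pharmacophore statistics: per-frame fingerprints, occurrence
# frequencies across replicates, single-pair occupancies, and
# interaction-distance profiles.

#' Define one monitored interaction
#'
#' A definition names the detector to run (via `itype`), the ligand feature
#' group, and the receptor partner. Receptor-receptor pairs (e.g. a TM5-TM6
#' salt bridge) are expressed with `res_a`/`res_b` instead of
#' `ligand_group`/`partner`.
#'
#' @param itype one of `"PI"`, `"NI"` (ionic), `"HBD"`, `"HBA"` (hydrogen
#'   bond), `"HY"` (hydrophobic), `"CATPI"`, `"WATER_MEDIATED"`
#' @param ligand_group ligand feature group name
#' @param partner receptor residue: author number, BW label (`"5.39"`), or
#'   `"HOH"`-anchored water spec for water-mediated rows
#' @param res_a,res_b residue specs for receptor-receptor definitions
#' @param receptor_atom optional atom-name filter on the receptor side
#'   (e.g. `"O"` for a backbone carbonyl in water-mediated bridges)
#' @export
interaction_definition <- function(itype, ligand_group = NULL, partner = NULL,
                                   res_a = NULL, res_b = NULL,
                                   receptor_atom = NULL) {
  itypes <- c("PI", "NI", "HBD", "HBA", "HY", "CATPI", "WATER_MEDIATED")
  if (!itype %in% itypes) {
    stop("unknown interaction type '", itype, "'; expected one of ",
         paste(itypes, collapse = ", "))
  }
  if (is.null(ligand_group) && (is.null(res_a) || is.null(res_b))) {
    stop("give ligand_group+partner or res_a+res_b")
  }
  structure(list(itype = itype, ligand_group = ligand_group,
                 partner = partner, res_a = res_a, res_b = res_b,
                 receptor_atom = receptor_atom),
            class = "interaction_definition")
}

#' Resolve a residue spec (author number or BW label) to atom indices
#' @noRd
resolve_residue <- function(system, spec, names = NULL) {
  if (is.numeric(spec)) {
    residue_atoms(system, res_number = spec, names = names)
  } else if (grepl("^[1-7]\\.[0-9]{1,2}$", spec)) {
    residue_atoms(system, bw = spec, names = names)
  } else if (grepl("^[0-9]+$", spec)) {
    residue_atoms(system, res_number = as.integer(spec), names = names)
  } else {
    stop("cannot resolve residue spec '", spec, "'")
  }
}

#' Atom sets for one definition on one system
#' @noRd
resolve_definition <- function(system, def) {
  itype <- def$itype
  if (!is.null(def$ligand_group)) {
    lig <- ligand_group_atoms(system, def$ligand_group)
    part <- resolve_residue(system, def$partner, names = def$receptor_atom)
    a <- switch(itype,
                PI = charged_subset(system, lig, +1),
                NI = charged_subset(system, lig, -1),
                HY = lig,
                CATPI = charged_subset(system, lig, +1),
                lig)
    b <- switch(itype,
                PI = charged_subset(system, part, -1),
                NI = charged_subset(system, part, +1),
                HY = part,
                part)
  } else {
    ra <- resolve_residue(system, def$res_a)
    rb <- resolve_residue(system, def$res_b, names = def$receptor_atom)
    a <- switch(itype,
                PI = , NI = charged_subset(system, ra),
                CATPI = charged_subset(system, ra, +1),
                ra)
    b <- switch(itype, PI = , NI = charged_subset(system, rb), rb)
    # orient ionic receptor pairs so the detector branch sees the charges it
    # expects: PI passes (a, b) as (cation, anion), NI as (anion, cation)
    if (itype %in% c("PI", "NI") && length(a) && length(b)) {
      a_cation <- any(system$atoms$charge[a] > 0)
      if (a_cation != (itype == "PI")) {
        tmp <- a; a <- b; b <- tmp
      }
    }
  }
  if (!length(a) || !length(b)) {
    stop("definition (", itype, ", ",
         def$ligand_group %||% def$res_a, ", ",
         def$partner %||% def$res_b, ") resolves to an empty atom group")
  }
  list(a = a, b = b)
}

definition_key <- function(def) {
  c(itype = def$itype,
    ligand_group = def$ligand_group %||% as.character(def$res_a),
    partner = as.character(def$partner %||% def$res_b))
}

#' Run one definition's detector on one frame
#' @noRd
run_definition <- function(system, frame, def, criteria) {
  sets <- resolve_definition(system, def)
  key <- definition_key(def)
  switch(def$itype,
    PI = detect_ionic(system, frame, sets$a, sets$b, criteria, itype = "PI",
                      ligand_group = key["ligand_group"], partner = key["partner"]),
    NI = detect_ionic(system, frame, sets$b, sets$a, criteria, itype = "NI",
                      ligand_group = key["ligand_group"], partner = key["partner"]),
    HY = detect_hydrophobic(system, frame, sets$a, sets$b, criteria,
                            ligand_group = key["ligand_group"],
                            partner = key["partner"]),
    HBD = detect_hbond(system, frame, hbond_donor(sets$a[1]), sets$b, criteria,
                       itype = "HBD", ligand_group = key["ligand_group"],
                       partner = key["partner"]),
    HBA = detect_hbond(system, frame, hbond_donor(sets$b[1]), sets$a, criteria,
                       itype = "HBA", ligand_group = key["ligand_group"],
                       partner = key["partner"]),
    CATPI = detect_cation_pi(system, frame, sets$a, sets$b, criteria,
                             ligand_group = key["ligand_group"],
                             partner = key["partner"]),
    WATER_MEDIATED = detect_water_mediated(
      system, frame, hbond_donor(sets$a[1]), sets$b[1], criteria,
      ligand_group = key["ligand_group"], partner = key["partner"])
  )
}

#' Interaction fingerprint of one frame
#'
#' Runs every configured detector on one frame, in the (deterministic)
#' order the definitions are listed.
#'
#' @param system a `molecular_system`
#' @param frame 1-based frame index
#' @param definitions list of [interaction_definition()]s
#' @param criteria an [interaction_criteria()]
#' @return event data.frame (zero or more rows)
#' @export
frame_fingerprint <- function(system, frame, definitions,
                              criteria = interaction_criteria()) {
  evs <- lapply(definitions, function(def) {
    run_definition(system, frame, def, criteria)
  })
  evs <- evs[!vapply(evs, is.null, logical(1))]
  if (!length(evs)) return(empty_events())
  do.call(rbind, evs)
}

#' Per-frame minimum distance series between two atom sets (vectorised)
#' @noRd
min_dist_series <- function(frames, a, b) {
  nf <- dim(frames)[3]
  dmin <- rep(Inf, nf)
  for (i in a) {
    xi <- frames[i, , , drop = FALSE]
    for (j in b) {
      dx <- xi[1, 1, ] - frames[j, 1, ]
      dy <- xi[1, 2, ] - frames[j, 2, ]
      dz <- xi[1, 3, ] - frames[j, 3, ]
      dmin <- pmin(dmin, sqrt(dx * dx + dy * dy + dz * dz))
    }
  }
  dmin
}

#' Logical positive-frame vector for one definition on one system
#' @noRd
positive_frames <- function(system, def, criteria) {
  sets <- resolve_definition(system, def)
  if (def$itype %in% c("PI", "NI")) {
    min_dist_series(system$frames, sets$a, sets$b) <= criteria$ionic_max_dist
  } else if (def$itype == "HY") {
    a <- apolar_subset(system, sets$a)
    b <- apolar_subset(system, sets$b)
    if (!length(a) || !length(b)) {
      warning("hydrophobic definition without apolar atoms")
      return(rep(FALSE, n_frames(system)))
    }
    min_dist_series(system$frames, a, b) <= criteria$hydrophobic_max_dist
  } else {
    vapply(seq_len(n_frames(system)), function(f) {
      !is.null(run_definition(system, f, def, criteria))
    }, logical(1))
  }
}

#' Occurrence frequencies across simulation replicates
#'
#' For every monitored interaction, the per-replicate frequency is the
#' percentage of frames in which at least one positive event of that row
#' occurs; the reported mean is the unweighted arithmetic mean over
#' replicates (with `pooled = TRUE`, frames of all replicates are pooled
#' into one percentage instead).
#'
#' @param replicates list of `molecular_system`s sharing one topology
#' @param definitions list of [interaction_definition()]s
#' @param criteria an [interaction_criteria()]
#' @param pooled pool frames across replicates instead of averaging
#'   per-replicate percentages
#' @return data.frame of class `occurrence_table` with one row per
#'   definition, per-replicate columns `rep_1`.. and `mean_frequency` (%)
#' @export
occurrence_frequencies <- function(replicates, definitions,
                                   criteria = interaction_criteria(),
                                   pooled = FALSE) {
  if (!length(replicates)) stop("at least one replicate is required")
  if (inherits(replicates, "molecular_system")) replicates <- list(replicates)
  for (r in replicates[-1]) {
    if (!same_topology(replicates[[1]], r)) {
      stop("replicates do not share a topology")
    }
  }
  rows <- lapply(definitions, function(def) {
    pos <- lapply(replicates, positive_frames, def = def, criteria = criteria)
    freqs <- vapply(pos, function(p) 100 * mean(p), numeric(1))
    m <- if (pooled) 100 * mean(unlist(pos)) else mean(freqs)
    key <- definition_key(def)
    out <- data.frame(itype = key[["itype"]],
                      ligand_group = key[["ligand_group"]],
                      partner = key[["partner"]],
                      stringsAsFactors = FALSE)
    for (i in seq_along(freqs)) out[[paste0("rep_", i)]] <- freqs[i]
    out$mean_frequency <- m
    out
  })
  tab <- do.call(rbind, rows)
  attr(tab, "n_replicates") <- length(replicates)
  attr(tab, "n_frames") <- vapply(replicates, n_frames, integer(1))
  attr(tab, "pooled") <- pooled
  class(tab) <- c("occurrence_table", class(tab))
  tab
}

#' Write an occurrence table as CSV (percentages to one decimal place)
#' @param tab an `occurrence_table`
#' @param path output file
#' @export
write_occurrence_csv <- function(tab, path) {
  out <- as.data.frame(tab)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, digits = 1)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Occupancy of a single interaction on one trajectory
#'
#' Same counting rule as [occurrence_frequencies()], for one system and one
#' pair; supports receptor-receptor pairs.
#'
#' @param system a `molecular_system`
#' @param definition an [interaction_definition()]
#' @param criteria an [interaction_criteria()]
#' @return occupancy in percent
#' @export
pair_occupancy <- function(system, definition,
                           criteria = interaction_criteria()) {
  100 * mean(positive_frames(system, definition, criteria))
}

#' Interaction-distance profile of an atom pair
#'
#' Euclidean distance per frame between two single atoms, with a five-number
#' summary (min, quartiles by linear interpolation, max) matching the
#' quantile markers of a violin plot.
#'
#' @param system a `molecular_system`
#' @param atom_a,atom_b atom indices, or lists `list(res =, name =)` /
#'   `list(bw =, name =)` naming a receptor atom, or
#'   `list(group =, name =)` naming a ligand atom
#' @return object of class `distance_series` with fields `pair`,
#'   `distances` (Angstrom) and `summary`
#' @export
distance_profile <- function(system, atom_a, atom_b) {
  ra <- resolve_atom(system, atom_a)
  rb <- resolve_atom(system, atom_b)
  d <- min_dist_series(system$frames, ra, rb)
  s <- stats::quantile(d, probs = c(0, 0.25, 0.5, 0.75, 1), type = 7,
                       names = FALSE)
  structure(
    list(pair = c(a = atom_label(system, ra), b = atom_label(system, rb)),
         distances = d,
         summary = c(min = s[1], q1 = s[2], median = s[3], q3 = s[4],
                     max = s[5])),
    class = "distance_series"
  )
}

resolve_atom <- function(system, spec) {
  if (is.numeric(spec) && length(spec) == 1) {
    if (spec < 1 || spec > n_atoms(system)) stop("unknown atom index ", spec)
    return(as.integer(spec))
  }
  if (is.list(spec)) {
    if (!is.null(spec$group)) {
      idx <- ligand_group_atoms(system, spec$group)
      if (!is.null(spec$name)) {
        idx <- idx[system$atoms$name[idx] == spec$name]
        if (!length(idx)) stop("no atom '", spec$name, "' in group ", spec$group)
      }
      return(idx[1])
    }
    idx <- residue_atoms(system, res_number = spec$res, bw = spec$bw,
                         names = spec$name)
    return(idx[1])
  }
  stop("cannot resolve atom spec")
}

atom_label <- function(system, idx) {
  paste0(system$atoms$res_name[idx], system$atoms$res_number[idx], ":",
         system$atoms$name[idx])
}

#' @export
print.distance_series <- function(x, ...) {
  cat("<distance_series> ", x$pair["a"], " <-> ", x$pair["b"], "\n", sep = "")
  cat("  n =", length(x$distances), "frames\n")
  print(round(x$summary, 3))
  invisible(x)
}

#' Write a distance series as CSV plus a JSON summary
#' @param x a `distance_series`
#' @param csv_path,json_path output files (either may be NULL)
#' @export
write_distance_series <- function(x, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(
      data.frame(frame = seq_along(x$distances), distance = x$distances),
      csv_path, row.names = FALSE
    )
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(pair = as.list(x$pair),
                              summary = as.list(x$summary)),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(x)
}
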