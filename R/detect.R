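# Per-frame geometric interaction detectors.
#
# All detectors work on heavy-atom coordinates of one frame and return
# either NULL (no interaction) or a one-row event data.frame; detect_clash
# returns one row per clashing atom pair. Distance boundaries are
# inclusive.

#' Geometric criteria for interaction detection
#'
#' Cutoffs follow common pharmacophore-toolkit conventions; every value is
#' a plain user-adjustable parameter.
#'
#' @param ionic_max_dist max heavy-atom distance between oppositely charged
#'   groups, Angstrom.
#' @param hbond_max_dist max donor-acceptor heavy-atom distance, Angstrom.
#' @param hbond_min_angle min angle in degrees at the donor (donor-H-acceptor
#'   when a hydrogen is given, otherwise root-donor-acceptor with the donor's
#'   bonded heavy-atom antecedent as surrogate).
#' @param hydrophobic_max_dist max apolar carbon/sulfur contact distance.
#' @param cationpi_max_dist max cation to ring-centroid distance.
#' @param cationpi_max_offset max angle (degrees) between the centroid-to-
#'   cation vector and the ring normal.
#' @param clash_overlap min van der Waals overlap (sum of radii minus
#'   distance) reported as a steric clash, Angstrom.
#' @param planarity_tol max RMS out-of-plane deviation for a valid aromatic
#'   ring, Angstrom.
#' @param hbond_strict error (instead of distance-only fallback) when no
#'   hydrogen and no donor root atom is available.
#' @param vdw_radii named per-element van der Waals radii, Angstrom.
#' @return object of class `interaction_criteria`
#' @export
interaction_criteria <- function(ionic_max_dist = 4.5,
                                 hbond_max_dist = 3.5,
                                 hbond_min_angle = 130,
                                 hydrophobic_max_dist = 4.5,
                                 cationpi_max_dist = 6.0,
                                 cationpi_max_offset = 30,
                                 clash_overlap = 0.4,
                                 planarity_tol = 0.25,
                                 hbond_strict = FALSE,
                                 vdw_radii = c(H = 1.2, C = 1.7, N = 1.55,
                                               O = 1.52, S = 1.8, P = 1.8)) {
  dists <- c(ionic_max_dist, hbond_max_dist, hydrophobic_max_dist,
             cationpi_max_dist)
  if (any(dists <= 0)) stop("all distance cutoffs must be > 0")
  if (hbond_min_angle <= 0 || hbond_min_angle > 180) {
    stop("hbond_min_angle must be in (0, 180]")
  }
  if (cationpi_max_offset <= 0 || cationpi_max_offset > 180) {
    stop("cationpi_max_offset must be in (0, 180]")
  }
  if (clash_overlap < 0) stop("clash_overlap must be >= 0")
  structure(
    list(ionic_max_dist = ionic_max_dist, hbond_max_dist = hbond_max_dist,
         hbond_min_angle = hbond_min_angle,
         hydrophobic_max_dist = hydrophobic_max_dist,
         cationpi_max_dist = cationpi_max_dist,
         cationpi_max_offset = cationpi_max_offset,
         clash_overlap = clash_overlap, planarity_tol = planarity_tol,
         hbond_strict = hbond_strict, vdw_radii = vdw_radii),
    class = "interaction_criteria"
  )
}

#' Read interaction criteria from a YAML `criteria:` block
#' @param path YAML file with a top-level `criteria` mapping (or the mapping
#'   itself at top level)
#' @export
read_criteria <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$criteria)) y <- y$criteria
  vr <- if (!is.null(y$vdw_radii)) unlist(y$vdw_radii)
  y$vdw_radii <- NULL
  args <- y[names(y) %in% names(formals(interaction_criteria))]
  if (!is.null(vr)) args$vdw_radii <- vr
  do.call(interaction_criteria, args)
}

event_row <- function(frame, itype, ligand_group, partner, distance,
                      angle = NA_real_, water_id = NA_character_) {
  data.frame(frame = frame, itype = itype,
             ligand_group = as.character(ligand_group),
             partner = as.character(partner),
             distance = distance, angle = angle, water_id = water_id,
             stringsAsFactors = FALSE)
}

empty_events <- function() {
  event_row(integer(0), character(0), character(0), character(0),
            numeric(0), numeric(0), character(0))
}

#' Detect an ionic interaction (salt bridge)
#'
#' Positive iff the minimum heavy-atom distance between the two charged
#' groups is at most `ionic_max_dist` (inclusive).
#'
#' @param system a `molecular_system`
#' @param frame 1-based frame index
#' @param cation_atoms,anion_atoms integer atom indices of the two charged
#'   groups
#' @param criteria an [interaction_criteria()] object
#' @param itype event label, `"PI"` (ligand positive ionizable, default) or
#'   `"NI"` (ligand negative ionizable)
#' @param ligand_group,partner identifiers stored on the event
#' @return one-row event data.frame, or NULL if no interaction
#' @export
detect_ionic <- function(system, frame, cation_atoms, anion_atoms,
                         criteria = interaction_criteria(), itype = "PI",
                         ligand_group = NA, partner = NA) {
  if (!length(cation_atoms) || !length(anion_atoms)) {
    stop("ionic detection requires non-empty charged groups")
  }
  qc <- system$atoms$charge[cation_atoms]
  qa <- system$atoms$charge[anion_atoms]
  if (all(qc <= 0) || all(qa >= 0)) {
    warning("ionic detection between groups without declared opposite charges")
  }
  xyz <- frame_coords(system, frame)
  d <- min(cross_dist(xyz[cation_atoms, , drop = FALSE],
                      xyz[anion_atoms, , drop = FALSE]))
  if (d <= criteria$ionic_max_dist) {
    event_row(frame, itype, ligand_group, partner, d)
  } else {
    NULL
  }
}

#' Hydrogen-bond donor specification
#'
#' @param heavy atom index of the donor heavy atom
#' @param hydrogen optional atom index of the donated hydrogen
#' @param root optional atom index of the donor's bonded heavy-atom
#'   antecedent, used as angle surrogate when no hydrogen is present
#' @export
hbond_donor <- function(heavy, hydrogen = NULL, root = NULL) {
  structure(list(heavy = as.integer(heavy),
                 hydrogen = if (!is.null(hydrogen)) as.integer(hydrogen),
                 root = if (!is.null(root)) as.integer(root)),
            class = "hbond_donor")
}

#' Detect a hydrogen bond
#'
#' Positive iff the donor-acceptor heavy-atom distance is at most
#' `hbond_max_dist` and the angle criterion holds. With an explicit
#' hydrogen the angle is donor-H-acceptor; otherwise the angle at the donor
#' heavy atom (root-donor-acceptor) is used as surrogate. When neither a
#' hydrogen nor a root atom is available the angle check is skipped
#' (distance-only), unless `criteria$hbond_strict` is set, in which case an
#' error is raised.
#'
#' @inheritParams detect_ionic
#' @param donor an [hbond_donor()], or a bare atom index (no angle atoms)
#' @param acceptor_atoms candidate acceptor atom indices; the closest is used
#' @param itype `"HBD"` (ligand donates, default) or `"HBA"`
#' @export
detect_hbond <- function(system, frame, donor, acceptor_atoms,
                         criteria = interaction_criteria(), itype = "HBD",
                         ligand_group = NA, partner = NA) {
  if (!inherits(donor, "hbond_donor")) donor <- hbond_donor(donor)
  if (!length(acceptor_atoms)) stop("no acceptor atoms given")
  xyz <- frame_coords(system, frame)
  dvec <- cross_dist(xyz[donor$heavy, , drop = FALSE],
                     xyz[acceptor_atoms, , drop = FALSE])[1, ]
  best <- which.min(dvec)
  d <- dvec[best]
  if (d > criteria$hbond_max_dist) return(NULL)
  acc <- acceptor_atoms[best]
  ang <- NA_real_
  if (!is.null(donor$hydrogen)) {
    ang <- vertex_angle(xyz[donor$heavy, ], xyz[donor$hydrogen, ], xyz[acc, ])
  } else if (!is.null(donor$root)) {
    ang <- vertex_angle(xyz[donor$root, ], xyz[donor$heavy, ], xyz[acc, ])
  } else if (criteria$hbond_strict) {
    stop("strict hydrogen-bond mode requires a hydrogen or a donor root atom")
  }
  if (!is.na(ang) && ang < criteria$hbond_min_angle) return(NULL)
  event_row(frame, itype, ligand_group, partner, d, angle = ang)
}

#' Detect a water-mediated hydrogen bond
#'
#' Positive iff a single water oxygen hydrogen-bonds to both the ligand
#' donor/acceptor group and the receptor atom within the same frame
#' (single-water bridges only). The first bridging water in index order is
#' reported.
#'
#' @inheritParams detect_hbond
#' @param ligand_donor an [hbond_donor()] (or atom index) on the ligand side
#' @param receptor_atom acceptor atom index on the receptor side
#' @param waters water oxygen atom indices (default: all waters in the
#'   system; an empty set yields no event)
#' @export
detect_water_mediated <- function(system, frame, ligand_donor, receptor_atom,
                                  criteria = interaction_criteria(),
                                  waters = NULL,
                                  ligand_group = NA, partner = NA) {
  if (is.null(waters)) waters <- water_oxygens(system)
  if (!length(waters)) return(NULL)
  for (w in waters) {
    leg1 <- detect_hbond(system, frame, ligand_donor, w, criteria)
    if (is.null(leg1)) next
    leg2 <- detect_hbond(system, frame, hbond_donor(w), receptor_atom, criteria)
    if (is.null(leg2)) next
    ev <- event_row(frame, "WATER_MEDIATED", ligand_group, partner,
                    leg1$distance, angle = leg1$angle,
                    water_id = water_label(system, w))
    return(ev)
  }
  NULL
}

water_label <- function(system, idx) {
  paste0("HOH", system$atoms$res_number[idx])
}

#' Detect a hydrophobic contact
#'
#' Positive iff the minimum distance between apolar (C/S) heavy atoms of
#' the two groups is at most `hydrophobic_max_dist`. Polar atoms in the
#' input are ignored; a group without apolar atoms yields no event, with a
#' warning.
#'
#' @inheritParams detect_ionic
#' @param a_atoms,b_atoms atom indices of the two groups
#' @export
detect_hydrophobic <- function(system, frame, a_atoms, b_atoms,
                               criteria = interaction_criteria(),
                               ligand_group = NA, partner = NA) {
  a <- apolar_subset(system, a_atoms)
  b <- apolar_subset(system, b_atoms)
  if (!length(a) || !length(b)) {
    warning("hydrophobic detection on a group without apolar (C/S) atoms")
    return(NULL)
  }
  xyz <- frame_coords(system, frame)
  d <- min(cross_dist(xyz[a, , drop = FALSE], xyz[b, , drop = FALSE]))
  if (d <= criteria$hydrophobic_max_dist) {
    event_row(frame, "HY", ligand_group, partner, d)
  } else {
    NULL
  }
}

#' Ring centroid, normal and planarity RMS
#' @noRd
ring_geometry <- function(coords) {
  centroid <- colMeans(coords)
  centred <- sweep(coords, 2, centroid)
  sv <- svd(centred)
  normal <- sv$v[, 3]
  rms <- sqrt(mean((centred %*% normal)^2))
  list(centroid = centroid, normal = normal, planarity_rms = rms)
}

#' Detect a cation-pi interaction
#'
#' Positive iff the cation lies within `cationpi_max_dist` of the aromatic
#' ring centroid and the angle between the centroid-to-cation vector and
#' the ring normal is at most `cationpi_max_offset` (the normal direction
#' is sign-free). The closest cation atom to the centroid is evaluated.
#'
#' @inheritParams detect_ionic
#' @param ring_atoms indices of >= 5 roughly coplanar ring atoms; a
#'   planarity RMS above `criteria$planarity_tol` is an error
#' @export
detect_cation_pi <- function(system, frame, cation_atoms, ring_atoms,
                             criteria = interaction_criteria(),
                             ligand_group = NA, partner = NA) {
  if (length(ring_atoms) < 5) stop("a ring needs at least 5 atoms")
  if (!length(cation_atoms)) stop("cation group is empty")
  xyz <- frame_coords(system, frame)
  geo <- ring_geometry(xyz[ring_atoms, , drop = FALSE])
  if (geo$planarity_rms > criteria$planarity_tol) {
    stop("ring atoms are not planar (RMS ",
         format(geo$planarity_rms, digits = 3), " A)")
  }
  dvec <- cross_dist(matrix(geo$centroid, ncol = 3),
                     xyz[cation_atoms, , drop = FALSE])[1, ]
  best <- which.min(dvec)
  d <- dvec[best]
  if (d > criteria$cationpi_max_dist) return(NULL)
  v <- xyz[cation_atoms[best], ] - geo$centroid
  ct <- abs(sum(v * geo$normal)) / vnorm(v)
  offset <- acos(min(1, ct)) * 180 / pi
  if (offset > criteria$cationpi_max_offset) return(NULL)
  event_row(frame, "CATPI", ligand_group, partner, d, angle = offset)
}

#' Detect steric clashes between two atom sets
#'
#' Reports one event per atom pair whose van der Waals overlap (sum of the
#' two radii minus the interatomic distance) is at least `clash_overlap`.
#'
#' @inheritParams detect_ionic
#' @param a_atoms,b_atoms atom indices of the two sets
#' @return event data.frame with zero or more `CLASH` rows; the `angle`
#'   column carries the overlap in Angstrom
#' @export
detect_clash <- function(system, frame, a_atoms, b_atoms,
                         criteria = interaction_criteria(),
                         ligand_group = NA, partner = NA) {
  ele <- unique(system$atoms$element[c(a_atoms, b_atoms)])
  unknown <- setdiff(ele, names(criteria$vdw_radii))
  if (length(unknown)) {
    stop("no van der Waals radius configured for element(s): ",
         paste(unknown, collapse = ", "))
  }
  xyz <- frame_coords(system, frame)
  d <- cross_dist(xyz[a_atoms, , drop = FALSE], xyz[b_atoms, , drop = FALSE])
  ra <- criteria$vdw_radii[system$atoms$element[a_atoms]]
  rb <- criteria$vdw_radii[system$atoms$element[b_atoms]]
  overlap <- outer(ra, rb, "+") - d
  hits <- which(overlap >= criteria$clash_overlap, arr.ind = TRUE)
  if (!nrow(hits)) return(empty_events())
  out <- lapply(seq_len(nrow(hits)), function(k) {
    i <- hits[k, 1]; j <- hits[k, 2]
    ev <- event_row(frame, "CLASH", ligand_group, partner, d[i, j],
                    angle = overlap[i, j])
    ev$atom_a <- a_atoms[i]
    ev$atom_b <- b_atoms[j]
    ev
  })
  do.call(rbind, out)
}
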