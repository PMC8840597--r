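# Synthetic receptor-ligand systems with known ground truth.
#
# The generator builds a toy 7-helix scaffold whose named key residues
# cover every symbol used downstream, plus a four-feature ligand and
# optional bridging waters, and renders trajectories in which every
# monitored contact follows a scheduled occupancy and every frame follows
# a scheduled activation state. Each scheduled pair is displaced along its
# own axis so occupancies are geometrically independent and exactly
# recoverable; there is no physical realism (no force field, membrane or
# solvent).

#' Specification of a synthetic trajectory set
#'
#' @param receptor `"MOR"`, `"DOR"`, `"KOR"` or `"NOP"`; selects the
#'   built-in anchor table, key residues and default schedules.
#' @param n_frames frames per replicate.
#' @param n_replicates number of replicates; replicate `r` is generated
#'   with seed `seed + r`.
#' @param seed base RNG seed.
#' @param interactions list of schedule rows; each row has `itype`
#'   (`"PI"`/`"NI"`), `ligand_group` + `partner` (author residue number) or
#'   `res_a` + `res_b` for receptor-receptor pairs, occupancy `p`, and
#'   optional per-row `mode`, `bound_dist`, `unbound_dist`. Defaults to
#'   [hs731_ionic_schedule()] for the receptor.
#' @param state_fractions named fractions `active`/`intermediate`/
#'   `inactive` summing to 1; defaults to [hs731_state_fractions()].
#' @param mode default occupancy mode, `"exact"` (exactly
#'   `round(p * n_frames)` positive frames, round half up, shuffled) or
#'   `"bernoulli"` (i.i.d.).
#' @param state_mode state-schedule mode, `"exact"` or `"bernoulli"`.
#' @param bound_dist,unbound_dist default contact distances in Angstrom for
#'   scheduled-on and scheduled-off frames.
#' @param noise_sd Gaussian noise (Angstrom) added to every scheduled
#'   distance placement; must keep `bound + 3*sd < cutoff < unbound - 3*sd`.
#' @param deflection_targets per-state TM6-deflection targets in Angstrom.
#' @param state_reference_dists toy active/inactive reference deflections
#'   against which rendered frames are meant to be classified.
#' @param include_waters include the phenol / K5.39-backbone bridging water
#'   (plus one distant water).
#' @param clash_fixture place the Y3.33 side chain inside the pocket so it
#'   overlaps the morphinan scaffold (deep-pocket tyrosine, NOP-like).
#' @param frame_interval ps between frames.
#' @param nop_tyr333 author number of the NOP 3.33 tyrosine (130 or 131).
#' @param criteria [interaction_criteria()] used for schedule validation.
#' @return validated object of class `synthetic_spec`
#' @export
synthetic_spec <- function(receptor = c("MOR", "DOR", "KOR", "NOP"),
                           n_frames = 1000, n_replicates = 5, seed = 42,
                           interactions = NULL, state_fractions = NULL,
                           mode = c("exact", "bernoulli"),
                           state_mode = c("exact", "bernoulli"),
                           bound_dist = 3.0, unbound_dist = 8.0,
                           noise_sd = 0.05,
                           deflection_targets = c(active = 12.6,
                                                  intermediate = 10.0,
                                                  inactive = 7.4),
                           state_reference_dists = c(active = 12.0,
                                                     inactive = 8.0),
                           include_waters = TRUE, clash_fixture = FALSE,
                           frame_interval = 100, nop_tyr333 = 131,
                           criteria = interaction_criteria()) {
  receptor <- match.arg(receptor)
  mode <- match.arg(mode)
  state_mode <- match.arg(state_mode)
  if (is.null(interactions)) interactions <- hs731_ionic_schedule(receptor)
  if (is.null(state_fractions)) state_fractions <- hs731_state_fractions(receptor)
  interactions <- lapply(interactions, function(row) {
    row$mode <- row$mode %||% mode
    row$bound_dist <- row$bound_dist %||% bound_dist
    row$unbound_dist <- row$unbound_dist %||% unbound_dist
    row
  })
  spec <- structure(
    list(receptor = receptor, n_frames = as.integer(n_frames),
         n_replicates = as.integer(n_replicates), seed = as.integer(seed),
         interactions = interactions,
         state_fractions = state_fractions, mode = mode,
         state_mode = state_mode, noise_sd = noise_sd,
         deflection_targets = deflection_targets,
         state_reference_dists = state_reference_dists,
         include_waters = include_waters, clash_fixture = clash_fixture,
         frame_interval = frame_interval, nop_tyr333 = nop_tyr333,
         criteria = criteria),
    class = "synthetic_spec"
  )
  violations <- validate_synthetic_spec(spec)
  if (length(violations)) {
    stop("invalid synthetic spec:\n  - ", paste(violations, collapse = "\n  - "))
  }
  spec
}

#' @noRd
validate_synthetic_spec <- function(spec) {
  v <- character(0)
  if (spec$n_frames < 1) v <- c(v, "n_frames must be >= 1")
  if (spec$n_replicates < 1) v <- c(v, "n_replicates must be >= 1")
  sf <- spec$state_fractions
  if (!all(c("active", "intermediate", "inactive") %in% names(sf))) {
    v <- c(v, "state_fractions must name active/intermediate/inactive")
  } else {
    if (abs(sum(sf) - 1) > 1e-9) {
      v <- c(v, sprintf("state fractions sum to %.3f, not 1", sum(sf)))
    }
    if (any(sf < 0)) v <- c(v, "state fractions must be non-negative")
  }
  sd3 <- 3 * spec$noise_sd
  cutoff <- spec$criteria$ionic_max_dist
  for (row in spec$interactions) {
    key <- paste(row$itype, row$ligand_group %||% row$res_a,
                 row$partner %||% row$res_b)
    if (is.null(row$p) || row$p < 0 || row$p > 1) {
      v <- c(v, paste0("occupancy p outside [0,1] for row ", key))
    }
    if (!(row$bound_dist + sd3 < cutoff)) {
      v <- c(v, paste0("bound_dist + 3*noise_sd must stay below the ionic ",
                       "cutoff for row ", key))
    }
    if (!(cutoff < row$unbound_dist - sd3)) {
      v <- c(v, paste0("unbound_dist - 3*noise_sd must stay above the ionic ",
                       "cutoff for row ", key))
    }
  }
  dt <- spec$deflection_targets
  sr <- spec$state_reference_dists
  if (!(dt[["active"]] - sd3 >= sr[["active"]])) {
    v <- c(v, "active deflection target must clear the active reference by 3*noise_sd")
  }
  if (!(dt[["inactive"]] + sd3 <= sr[["inactive"]])) {
    v <- c(v, "inactive deflection target must clear the inactive reference by 3*noise_sd")
  }
  if (!(dt[["intermediate"]] - sd3 > sr[["inactive"]] &&
          dt[["intermediate"]] + sd3 < sr[["active"]])) {
    v <- c(v, "intermediate deflection target must lie strictly between the references")
  }
  v
}

#' Read a synthetic spec from YAML
#' @param path YAML file whose keys mirror the [synthetic_spec()] arguments
#' @export
read_synthetic_spec <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[names(y) %in% setdiff(names(formals(synthetic_spec)), "criteria")]
  if (!is.null(args$state_fractions)) {
    args$state_fractions <- unlist(args$state_fractions)
  }
  if (!is.null(args$deflection_targets)) {
    args$deflection_targets <- unlist(args$deflection_targets)
  }
  if (!is.null(args$state_reference_dists)) {
    args$state_reference_dists <- unlist(args$state_reference_dists)
  }
  if (!is.null(y$criteria)) {
    args$criteria <- do.call(interaction_criteria, y$criteria)
  }
  do.call(synthetic_spec, args)
}

#' Schedule a boolean occupancy mask
#'
#' @param n_frames number of frames
#' @param p target occupancy in `[0, 1]`
#' @param mode `"exact"`: exactly `round(p * n_frames)` (round half up)
#'   positive frames at seeded-shuffled positions; `"bernoulli"`: i.i.d.
#'   with probability p
#' @param seed optional seed; when NULL the current RNG stream is used
#' @return logical vector of length `n_frames`
#' @export
schedule_occupancy <- function(n_frames, p, mode = c("exact", "bernoulli"),
                               seed = NULL) {
  mode <- match.arg(mode)
  if (p < 0 || p > 1) stop("occupancy p must be in [0, 1]")
  draw <- function() {
    if (mode == "exact") {
      k <- round_half_up(p * n_frames)
      mask <- rep(FALSE, n_frames)
      if (k > 0) mask[sample.int(n_frames, k)] <- TRUE
      mask
    } else {
      stats::runif(n_frames) < p
    }
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' @noRd
schedule_states <- function(n_frames, fractions, mode) {
  lv <- c("active", "intermediate", "inactive")
  if (mode == "exact") {
    k_int <- round_half_up(fractions[["intermediate"]] * n_frames)
    k_act <- round_half_up(fractions[["active"]] * n_frames)
    k_in <- n_frames - k_int - k_act
    if (k_in < 0) stop("rounded state counts exceed n_frames")
    labels <- rep(lv, times = c(k_act, k_int, k_in))
    labels[sample.int(n_frames)]
  } else {
    sample(lv, n_frames, replace = TRUE, prob = fractions[lv])
  }
}

# ---- template geometry ----------------------------------------------------

HELIX_RADIUS <- 12
RISE_PER_RES <- 1.5

helix_dir <- function(t, off = 0) {
  th <- 2 * pi * (t - 1) / 7 + off
  c(cos(th), sin(th), 0)
}

hexagon <- function(center, dir, radius = 1.4) {
  zhat <- c(0, 0, 1)
  t(vapply(0:5, function(k) {
    a <- k * pi / 3
    center + radius * (cos(a) * dir + sin(a) * zhat)
  }, numeric(3)))
}

#' Build the single-frame synthetic template
#'
#' Constructs the toy 7-helix receptor with all named key residues of the
#' chosen receptor, the four-feature ligand, and optional waters, placed
#' so that every scheduled contact sits at its bound geometry. The
#' returned system carries the schedule geometry needed by
#' [render_trajectory()] and already has Ballesteros-Weinstein labels.
#'
#' @param spec a [synthetic_spec()]
#' @return single-frame `molecular_system`
#' @export
generate_template <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  anchors <- builtin_anchor_table(spec$receptor)
  keyres <- receptor_key_residues(spec$receptor, spec$nop_tyr333)

  acc <- new.env()
  acc$rows <- list()
  add_atom <- function(name, element, pos, res_number, res_name, kind,
                       chain = "A", charge = 0) {
    acc$rows[[length(acc$rows) + 1]] <- list(
      name = name, element = element, chain = chain,
      res_number = res_number, res_name = res_name, kind = kind,
      charge = charge, x = pos[1], y = pos[2], z = pos[3])
    length(acc$rows)
  }

  # --- ligand ---
  lig <- list()
  lig$N17 <- add_atom("N17", "N", c(0, 0, 6.0), 900, "LIG", "ligand", "L", 1)
  lig$C9  <- add_atom("C9", "C", c(1.2, -0.6, 5.4), 900, "LIG", "ligand", "L")
  lig$C13 <- add_atom("C13", "C", c(0.4, 0.9, 4.6), 900, "LIG", "ligand", "L")
  lig$C14 <- add_atom("C14", "C", c(-0.9, 0.2, 4.9), 900, "LIG", "ligand", "L")
  lig$C15 <- add_atom("C15", "C", c(-0.3, -1.2, 4.3), 900, "LIG", "ligand", "L")
  lig$N2  <- add_atom("N2", "N", c(2.4, 0.8, 7.0), 900, "LIG", "ligand", "L", 1)
  lig$C20 <- add_atom("C20", "C", c(3.6, 1.7, 7.6), 900, "LIG", "ligand", "L")
  lig$O1  <- add_atom("O1", "O", c(4.5, 2.3, 7.6), 900, "LIG", "ligand", "L", -0.5)
  lig$O2  <- add_atom("O2", "O", c(4.5, 2.3, 5.8), 900, "LIG", "ligand", "L", -0.5)
  u5 <- helix_dir(5)
  o3 <- c(-1.8, -1.1, 5.6)
  lig$O3 <- add_atom("O3", "O", o3, 900, "LIG", "ligand", "L")
  phenol_ring <- hexagon(o3 - 2.7 * u5, u5)
  for (k in 1:6) {
    lig[[paste0("C2", k)]] <- add_atom(paste0("C2", k), "C", phenol_ring[k, ],
                                       900, "LIG", "ligand", "L")
  }
  p_n17 <- c(0, 0, 6.0); p_n2 <- c(2.4, 0.8, 7.0)
  p_o1 <- c(4.5, 2.3, 7.6); p_c14 <- c(-0.9, 0.2, 4.9)

  # --- receptor helix backbone ---
  resname_of <- function(r) {
    hit <- keyres$res_name[keyres$res_number == r]
    if (length(hit)) hit[1] else "ALA"
  }
  ca_index <- new.env()
  for (t in 1:7) {
    rng <- anchors$tm_ranges[t, ]
    a <- anchors$anchors[[as.character(t)]]
    ctr <- HELIX_RADIUS * helix_dir(t)
    for (r in seq(rng$first, rng$last)) {
      pos <- ctr + c(0, 0, (r - a) * RISE_PER_RES)
      assign(as.character(r), add_atom("CA", "C", pos, r, resname_of(r),
                                       "protein"), envir = ca_index)
    }
  }
  # loop residues outside the helix ranges
  loop_pos <- list(
    nterm_asp = c(6, 2, 16),
    ecl2_lys = HELIX_RADIUS * 0.5 * (helix_dir(4) + helix_dir(5)) + c(0, 0, 14),
    ecl2_glu = HELIX_RADIUS * 0.5 * (helix_dir(4) + helix_dir(5)) + c(1, 1, 15),
    ecl3_arg = HELIX_RADIUS * 0.5 * (helix_dir(6) + helix_dir(7)) + c(0, 0, 14)
  )
  for (role in intersect(keyres$role, names(loop_pos))) {
    r <- keyres$res_number[keyres$role == role]
    assign(as.character(r),
           add_atom("CA", "C", loop_pos[[role]], r, resname_of(r), "protein"),
           envir = ca_index)
  }

  key <- function(role) {
    hit <- keyres[keyres$role == role, ]
    if (nrow(hit)) hit else NULL
  }
  side <- list()  # role -> atom indices
  add_side <- function(role, names, elements, positions, charges = 0) {
    kr <- key(role)
    if (is.null(kr)) return(invisible(NULL))
    charges <- rep_len(charges, length(names))
    idx <- integer(length(names))
    for (i in seq_along(names)) {
      idx[i] <- add_atom(names[i], elements[i], positions[i, ],
                         kr$res_number, kr$res_name, "protein",
                         charge = charges[i])
    }
    side[[role]] <<- idx
    invisible(idx)
  }

  # D3.32: anchor OD1 placed bound to the morphinan amine
  u3 <- helix_dir(3)
  od1 <- p_n17 + 3.0 * u3
  add_side("d332", c("OD1", "OD2", "CG"), c("O", "O", "C"),
           rbind(od1, od1 + c(0, 0, 1.6), od1 + 0.65 * u3 + c(0, 0, 0.8)),
           charges = c(-0.5, -0.5, 0))

  # Y3.33: phenol side chain; default just outside vdW contact of the
  # scaffold, clash_fixture pushes the ring onto it
  uy <- helix_dir(3, 0.5)
  oh <- p_n17 + 3.0 * uy + c(0, 0, 1.5)
  yring <- hexagon(oh + 2.6 * uy, uy)
  if (spec$clash_fixture) {
    shift <- (p_c14 + 0.8 * u3) - (oh + 2.6 * uy)
    oh <- oh + shift
    yring <- sweep(yring, 2, shift, "+")
  }
  add_side("y333", c("OH", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
           c("O", rep("C", 6)), rbind(oh, yring))

  # hydrophobic pocket residues: first side-chain atom exactly at the
  # default contact distance from scaffold atom C14
  hydrophobic_side <- function(role, dir, names, elements, zoff) {
    first <- p_c14 + 4.0 * dir
    pos <- rbind(first,
                 t(vapply(seq_along(zoff), function(i) {
                   first + 0.8 * dir + c(0, 0, zoff[i])
                 }, numeric(3))))
    add_side(role, names, elements, pos)
  }
  hydrophobic_side("m336", helix_dir(3, 0.35), c("CB", "CG", "SD", "CE"),
                   c("C", "C", "S", "C"), c(0, 1.0, -1.0))
  hydrophobic_side("v542", helix_dir(5, 0.3), c("CB", "CG1", "CG2"),
                   c("C", "C", "C"), c(0, -1.0))
  hydrophobic_side("i651", helix_dir(6, 0.3), c("CB", "CG1", "CD1"),
                   c("C", "C", "C"), c(0, 1.0))
  hydrophobic_side("v651", helix_dir(6, 0.3), c("CB", "CG1", "CG2"),
                   c("C", "C", "C"), c(0, 1.0))
  hydrophobic_side("v655", helix_dir(6, -0.3), c("CB", "CG1", "CG2"),
                   c("C", "C", "C"), c(0, -1.0))
  hydrophobic_side("i329", helix_dir(3, -0.85), c("CB", "CG1", "CD1"),
                   c("C", "C", "C"), c(0, 1.0))
  hydrophobic_side("i331", helix_dir(3, 0.7), c("CB", "CG1", "CD1"),
                   c("C", "C", "C"), c(0, 1.0))
  if (!is.null(key("w735"))) {
    ring <- hexagon(p_c14 + 5.2 * helix_dir(7, 0.3), helix_dir(7, 0.3))
    add_side("w735", c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
             rep("C", 6), ring)
  }
  if (!is.null(key("x658_trp"))) {
    ring <- hexagon(p_c14 + 6.0 * helix_dir(6, 0.15), helix_dir(6, 0.15))
    add_side("x658_trp", c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
             rep("C", 6), ring)
  }
  if (!is.null(key("x658_gln"))) {
    ug <- helix_dir(6, 0.15)
    cd <- p_c14 + 5.0 * ug
    add_side("x658_gln", c("CD", "OE1", "NE2"), c("C", "O", "N"),
             rbind(cd, cd + 0.8 * ug, cd + 0.8 * ug + c(0, 0, 1.0)))
  }

  # K5.39: charged NZ (default bound to the ligand carboxylate) plus the
  # backbone carbonyl O that coordinates the bridging water near the phenol
  nz539 <- p_o1 + 3.0 * u5
  add_side("k539", c("NZ", "O"), c("N", "O"),
           rbind(nz539, o3 + 5.2 * u5), charges = c(1, 0))
  # MOR K6.58
  add_side("x658_lys", "NZ", "N", rbind(p_o1 + 3.0 * helix_dir(6)),
           charges = 1)
  # KOR E6.58: default bridged to K5.39
  u6 <- helix_dir(6)
  oe1 <- nz539 + 3.4 * u6
  add_side("x658_glu", c("OE1", "CD"), c("O", "C"),
           rbind(oe1, oe1 + 0.7 * u6), charges = c(-0.5, 0))
  # loop side chains
  un <- helix_dir(1, 0.45)
  odn <- p_n2 + 3.0 * un
  add_side("nterm_asp", c("OD1", "OD2"), c("O", "O"),
           rbind(odn, odn + c(0, 0, 1.6)), charges = c(-0.5, -0.5))
  ul <- helix_dir(4, 0.35)
  add_side("ecl2_lys", "NZ", "N", rbind(p_o1 + 3.0 * ul), charges = 1)
  ue <- helix_dir(4, 0.8)
  oee <- p_n2 + 3.0 * ue
  add_side("ecl2_glu", c("OE1", "CD"), c("O", "C"),
           rbind(oee, oee + 0.7 * ue), charges = c(-0.5, 0))
  ur <- helix_dir(7, -0.35)
  nh1 <- p_o1 + 3.0 * ur
  add_side("ecl3_arg", c("NH1", "NH2", "CZ"), c("N", "N", "C"),
           rbind(nh1, nh1 + c(0, 0, 1.7), nh1 + 0.7 * ur),
           charges = c(0.5, 0.5, 0))

  # --- waters ---
  if (spec$include_waters) {
    add_atom("O", "O", o3 + 2.6 * u5, 901, "HOH", "water", "W")
    add_atom("O", "O", c(14, 14, 14), 902, "HOH", "water", "W")
  }

  df <- do.call(rbind, lapply(acc$rows, function(r) {
    data.frame(name = r$name, element = r$element, chain = r$chain,
               res_number = r$res_number, res_name = r$res_name,
               kind = r$kind, charge = r$charge, x = r$x, y = r$y, z = r$z,
               stringsAsFactors = FALSE)
  }))
  xyz <- as.matrix(df[, c("x", "y", "z")])
  atoms <- df[, c("name", "element", "chain", "res_number", "res_name",
                  "kind", "charge")]

  lspec <- hs731_ligand_spec()
  groups <- lapply(lspec$groups, function(nms) {
    which(atoms$kind == "ligand" & atoms$name %in% nms)
  })
  sys <- molecular_system(atoms, xyz, groups,
                          frame_interval = spec$frame_interval,
                          receptor_id = spec$receptor)
  sys <- assign_bw_numbers(sys, anchors)

  attr(sys, "schedule_geometry") <- build_schedule_geometry(sys, spec, keyres)
  attr(sys, "deflection_geometry") <- build_deflection_geometry(sys, keyres)
  attr(sys, "synthetic_spec") <- spec
  sys
}

#' Mobile side-chain atoms of a scheduled partner residue: everything but
#' the backbone (CA and carbonyl O), so the water-coordinating K5.39
#' backbone O stays put when NZ is displaced.
#' @noRd
mobile_atoms_of <- function(system, res_number) {
  idx <- residue_atoms(system, res_number = res_number)
  idx[!system$atoms$name[idx] %in% c("CA", "O")]
}

ligand_anchor_atom <- function(system, group) {
  idx <- ligand_group_atoms(system, group)
  ch <- charged_subset(system, idx)
  if (length(ch)) ch[1] else idx[1]
}

#' @noRd
build_schedule_geometry <- function(system, spec, keyres) {
  xyz <- frame_coords(system, 1)
  lapply(spec$interactions, function(row) {
    if (!is.null(row$ligand_group)) {
      anchor_ref <- ligand_anchor_atom(system, row$ligand_group)
      anchor_static <- TRUE
      mobile <- mobile_atoms_of(system, row$partner)
    } else {
      anchor_ref <- charged_subset(
        system, mobile_atoms_of(system, row$res_a))[1]
      anchor_static <- FALSE
      mobile <- mobile_atoms_of(system, row$res_b)
    }
    manchor <- charged_subset(system, mobile)[1]
    axis <- unit_vector(xyz[manchor, ] - xyz[anchor_ref, ])
    offsets <- sweep(xyz[mobile, , drop = FALSE], 2, xyz[manchor, ])
    list(row = row, anchor_ref = anchor_ref, anchor_static = anchor_static,
         mobile = mobile, offsets = offsets, axis = axis)
  })
}

#' @noRd
build_deflection_geometry <- function(system, keyres) {
  r631 <- keyres$res_number[keyres$role == "r631"]
  r440 <- keyres$res_number[keyres$role == "r440"]
  i631 <- residue_atoms(system, res_number = r631, names = "CA")[1]
  i440 <- residue_atoms(system, res_number = r440, names = "CA")[1]
  xyz <- frame_coords(system, 1)
  list(i631 = i631, i440 = i440,
       axis = unit_vector(xyz[i631, ] - xyz[i440, ]),
       res_631 = r631, res_440 = r440)
}

#' Render scheduled trajectory replicates
#'
#' Per frame, every scheduled pair is placed at its bound distance (mask
#' true) or unbound distance (mask false) along its own axis, plus Gaussian
#' noise on the placed distance; the TM6 deflection is set per frame from
#' the state schedule. Replicate `r` uses seed `spec$seed + r`. With
#' `out_dir` set, the topology (PDB), per-replicate frame files (CSV
#' dialect `frame,atom_index,x,y,z` in Angstrom) and a ground-truth JSON
#' (masks, state labels, fractions, seed) are written alongside.
#'
#' @param template output of [generate_template()]
#' @param spec the corresponding [synthetic_spec()] (defaults to the one
#'   stored on the template)
#' @param out_dir optional output directory
#' @return list with `replicates` (list of `molecular_system`s),
#'   `ground_truth`, and `files`
#' @export
render_trajectory <- function(template, spec = attr(template, "synthetic_spec"),
                              out_dir = NULL) {
  sched <- attr(template, "schedule_geometry")
  defl <- attr(template, "deflection_geometry")
  if (is.null(sched) || is.null(defl)) {
    stop("template was not produced by generate_template()")
  }
  nf <- spec$n_frames
  tmpl_xyz <- frame_coords(template, 1)
  na <- nrow(tmpl_xyz)
  gt_rows <- lapply(sched, function(g) {
    list(itype = g$row$itype,
         ligand_group = g$row$ligand_group %||% as.character(g$row$res_a),
         partner = as.character(g$row$partner %||% g$row$res_b),
         p = g$row$p, mode = g$row$mode)
  })
  replicates <- vector("list", spec$n_replicates)
  gt_masks <- vector("list", spec$n_replicates)
  gt_states <- vector("list", spec$n_replicates)
  for (r in seq_len(spec$n_replicates)) {
    draws <- with_seed(spec$seed + r, {
      masks <- lapply(sched, function(g) {
        schedule_occupancy(nf, g$row$p, g$row$mode)
      })
      dist_noise <- lapply(sched, function(g) stats::rnorm(nf, 0, spec$noise_sd))
      states <- schedule_states(nf, spec$state_fractions, spec$state_mode)
      defl_noise <- stats::rnorm(nf, 0, spec$noise_sd)
      list(masks = masks, dist_noise = dist_noise, states = states,
           defl_noise = defl_noise)
    })
    arr <- array(tmpl_xyz, dim = c(na, 3, nf))
    for (k in seq_along(sched)) {
      g <- sched[[k]]
      d <- ifelse(draws$masks[[k]], g$row$bound_dist, g$row$unbound_dist) +
        draws$dist_noise[[k]]
      anchor <- if (g$anchor_static) {
        matrix(tmpl_xyz[g$anchor_ref, ], nrow = 3, ncol = nf)
      } else {
        arr[g$anchor_ref, , ]  # 3 x nf, may have been moved by earlier rows
      }
      for (m in seq_along(g$mobile)) {
        for (j in 1:3) {
          arr[g$mobile[m], j, ] <- anchor[j, ] + d * g$axis[j] +
            g$offsets[m, j]
        }
      }
    }
    dtarg <- spec$deflection_targets[draws$states] + draws$defl_noise
    p440 <- tmpl_xyz[defl$i440, ]
    for (j in 1:3) {
      arr[defl$i631, j, ] <- p440[j] + dtarg * defl$axis[j]
    }
    sys_r <- template
    sys_r$frames <- arr
    attr(sys_r, "schedule_geometry") <- NULL
    replicates[[r]] <- sys_r
    gt_masks[[r]] <- lapply(draws$masks, as.integer)
    gt_states[[r]] <- draws$states
  }
  ground_truth <- list(
    receptor = spec$receptor, seed = spec$seed, n_frames = nf,
    n_replicates = spec$n_replicates, noise_sd = spec$noise_sd,
    rows = gt_rows, masks = gt_masks, state_labels = gt_states,
    state_fractions = as.list(spec$state_fractions),
    deflection_targets = as.list(spec$deflection_targets),
    state_reference_dists = as.list(spec$state_reference_dists)
  )
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    topo <- file.path(out_dir, "topology.pdb")
    write_system_pdb(template, topo)
    files <- topo
    for (r in seq_len(spec$n_replicates)) {
      f <- file.path(out_dir, sprintf("replicate_%d.csv", r))
      write_frames_csv(replicates[[r]], f)
      files <- c(files, f)
    }
    gtf <- file.path(out_dir, "ground_truth.json")
    jsonlite::write_json(ground_truth, gtf, auto_unbox = TRUE, digits = NA)
    files <- c(files, gtf)
  }
  list(replicates = replicates, ground_truth = ground_truth, files = files)
}

#' Analysis definitions matching a synthetic schedule
#'
#' Translates the scheduled rows of a spec into the
#' [interaction_definition()]s that monitor them, so recovered occupancies
#' can be compared with the scheduled ground truth.
#'
#' @param spec a [synthetic_spec()]
#' @return list of [interaction_definition()]s
#' @export
schedule_definitions <- function(spec) {
  lapply(spec$interactions, function(row) {
    if (!is.null(row$ligand_group)) {
      interaction_definition(row$itype, ligand_group = row$ligand_group,
                             partner = row$partner)
    } else {
      interaction_definition(row$itype, res_a = row$res_a, res_b = row$res_b)
    }
  })
}

#' State reference matching a synthetic spec
#' @param spec a [synthetic_spec()]
#' @return a [state_reference()] using the spec's toy crystal distances
#' @export
schedule_state_reference <- function(spec) {
  state_reference(spec$receptor,
                  active_ref_dist = spec$state_reference_dists[["active"]],
                  inactive_ref_dist = spec$state_reference_dists[["inactive"]])
}
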