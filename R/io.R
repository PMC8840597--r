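# Structure and trajectory I/O.
#
# Topologies and reference structures are PDB (via bio3d); frames come
# from the PDB itself (single frame), a DCD binary trajectory, or the
# plain-text CSV dialect "frame,atom_index,x,y,z" (Angstrom) used for
# human-inspectable fixtures.

#' Load a receptor-ligand structure (and optional trajectory)
#'
#' @param path PDB file with the topology (protein + ligand + waters)
#' @param ligand_spec list with `resid` (ligand residue name), `groups`
#'   (named list of atom names per feature group) and optional `charges`
#'   (named group charges: positive groups charge their N atoms, negative
#'   ones their O atoms). See [hs731_ligand_spec()].
#' @param frames optional trajectory file (`.csv` dialect or `.dcd`);
#'   when NULL the PDB coordinates form a single frame
#' @param frame_interval ps between frames
#' @param anchors optional [anchor_table()]; when given,
#'   Ballesteros-Weinstein labels are assigned on load
#' @return a `molecular_system`
#' @export
load_structure <- function(path, ligand_spec = hs731_ligand_spec(),
                           frames = NULL, frame_interval = 100,
                           anchors = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  element <- at$elesy
  if (is.null(element) || all(is.na(element)) || all(element == "")) {
    element <- guess_element(at$elety)
  } else {
    blank <- is.na(element) | element == ""
    element[blank] <- guess_element(at$elety[blank])
  }
  kind <- ifelse(at$resid %in% c("HOH", "WAT", "TIP3", "TIP4"), "water",
                 ifelse(at$resid == ligand_spec$resid, "ligand", "protein"))
  atoms <- data.frame(
    name = at$elety, element = element, chain = at$chain,
    res_number = at$resno, res_name = at$resid, kind = kind,
    charge = 0, stringsAsFactors = FALSE
  )
  atoms$charge <- assign_charges(atoms, ligand_spec)
  groups <- lapply(ligand_spec$groups, function(nms) {
    which(atoms$kind == "ligand" & atoms$name %in% nms)
  })
  for (g in names(groups)) {
    if (!length(groups[[g]])) {
      stop("ligand feature group '", g, "' matches no atom in ", path)
    }
  }
  xyz <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  coords <- if (is.null(frames)) {
    array(xyz, dim = c(nrow(atoms), 3, 1))
  } else if (grepl("\\.csv$", frames, ignore.case = TRUE)) {
    read_frames_csv(frames, n_atoms = nrow(atoms))
  } else if (grepl("\\.dcd$", frames, ignore.case = TRUE)) {
    traj <- bio3d::read.dcd(frames, verbose = FALSE)
    if (ncol(traj) != 3 * nrow(atoms)) {
      stop("trajectory atom count (", ncol(traj) / 3,
           ") does not match topology (", nrow(atoms), ")")
    }
    aperm(array(t(traj), dim = c(3, nrow(atoms), nrow(traj))), c(2, 1, 3))
  } else {
    stop("unsupported trajectory format: ", frames)
  }
  sys <- molecular_system(atoms, coords, groups,
                          frame_interval = frame_interval)
  if (!is.null(anchors)) sys <- assign_bw_numbers(sys, anchors)
  sys
}

#' @noRd
guess_element <- function(elety) {
  first <- toupper(substr(gsub("^[0-9]+", "", elety), 1, 1))
  ifelse(first %in% c("C", "N", "O", "S", "H", "P"), first, "C")
}

#' Formal-charge heuristics for standard residues and the ligand groups
#' @noRd
assign_charges <- function(atoms, ligand_spec) {
  q <- rep(0, nrow(atoms))
  prot <- atoms$kind == "protein"
  q[prot & atoms$res_name == "ASP" & atoms$name %in% c("OD1", "OD2")] <- -0.5
  q[prot & atoms$res_name == "GLU" & atoms$name %in% c("OE1", "OE2")] <- -0.5
  q[prot & atoms$res_name == "LYS" & atoms$name == "NZ"] <- 1
  q[prot & atoms$res_name == "ARG" & atoms$name %in% c("NH1", "NH2")] <- 0.5
  charges <- ligand_spec$charges
  for (g in names(ligand_spec$groups)) {
    qg <- charges[[g]] %||% 0
    if (qg == 0) next
    sel <- atoms$kind == "ligand" & atoms$name %in% ligand_spec$groups[[g]]
    if (qg > 0) {
      sel <- sel & atoms$element == "N"
      q[sel] <- qg
    } else {
      sel <- sel & atoms$element == "O"
      q[sel] <- qg / max(1, sum(sel))
    }
  }
  q
}

#' Write a system's topology (one frame) as PDB
#' @param system a `molecular_system`
#' @param path output file
#' @param frame frame to write
#' @export
write_system_pdb <- function(system, path, frame = 1) {
  xyz <- frame_coords(system, frame)
  at <- system$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(xyz)),
    resno = at$res_number,
    resid = at$res_name,
    chain = at$chain,
    elety = at$name,
    elesy = at$element,
    eleno = seq_len(nrow(at)),
    o = rep(1, nrow(at)),
    b = rep(0, nrow(at))
  )
  invisible(path)
}

#' Write trajectory frames in the CSV dialect
#'
#' Columns `frame,atom_index,x,y,z`, 1-based indices, Angstrom, four
#' decimals.
#' @param system a `molecular_system`
#' @param path output file
#' @export
write_frames_csv <- function(system, path) {
  nf <- n_frames(system)
  na <- n_atoms(system)
  df <- data.frame(
    frame = rep(seq_len(nf), each = na),
    atom_index = rep(seq_len(na), nf),
    x = round(as.vector(system$frames[, 1, ]), 4),
    y = round(as.vector(system$frames[, 2, ]), 4),
    z = round(as.vector(system$frames[, 3, ]), 4)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read trajectory frames from the CSV dialect
#' @param path CSV file with header `frame,atom_index,x,y,z`
#' @param n_atoms expected atom count (checked against every frame)
#' @return an `n_atoms x 3 x n_frames` array
#' @export
read_frames_csv <- function(path, n_atoms = NULL) {
  df <- utils::read.csv(path)
  need <- c("frame", "atom_index", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("frame CSV must have columns ", paste(need, collapse = ","))
  }
  counts <- table(df$frame)
  if (length(unique(counts)) != 1) {
    stop("atom-count mismatch between frames in ", path)
  }
  na <- as.integer(counts[1])
  if (!is.null(n_atoms) && na != n_atoms) {
    stop("frame atom count (", na, ") does not match topology (", n_atoms, ")")
  }
  df <- df[order(df$frame, df$atom_index), ]
  nf <- length(counts)
  arr <- array(NA_real_, dim = c(na, 3, nf))
  arr[, 1, ] <- df$x
  arr[, 2, ] <- df$y
  arr[, 3, ] <- df$z
  if (!all(is.finite(arr))) stop("non-finite coordinates in ", path)
  arr
}
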