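# MolecularSystem: topology plus per-frame coordinates.

#' Construct a molecular system
#'
#' A `molecular_system` couples a static topology (protein residues, ligand
#' feature groups, water sites) with per-frame Cartesian coordinates in
#' Angstrom. It is the common container consumed by all interaction
#' detectors and trajectory statistics in this package.
#'
#' @param atoms data.frame with one row per atom and columns `name`
#'   (PDB-style atom name), `element` (element symbol), `chain`,
#'   `res_number` (author numbering, 1-based), `res_name` (3-letter code),
#'   `kind` (`"protein"`, `"ligand"` or `"water"`) and `charge` (signed
#'   formal/partial charge used by the ionic detector; 0 for neutral atoms).
#'   An optional `bw_label` column holds Ballesteros-Weinstein labels.
#' @param frames numeric array `n_atoms x 3 x n_frames` of coordinates in
#'   Angstrom, or an `n_atoms x 3` matrix for a single frame.
#' @param ligand_groups named list mapping the four ligand pharmacophoric
#'   feature groups (`morphinan_amine`, `secondary_amine`, `carboxylate`,
#'   `phenol`) to integer atom indices. Each group must resolve to at least
#'   one atom.
#' @param frame_interval time between stored frames in picoseconds.
#' @param receptor_id optional identifier (e.g. `"MOR"`).
#'
#' @return An object of class `molecular_system`.
#' @export
molecular_system <- function(atoms, frames, ligand_groups,
                             frame_interval = 100, receptor_id = NA_character_) {
  stopifnot(is.data.frame(atoms))
  req <- c("name", "element", "chain", "res_number", "res_name", "kind", "charge")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  if (!"bw_label" %in% names(atoms)) atoms$bw_label <- NA_character_
  if (is.matrix(frames)) frames <- array(frames, dim = c(nrow(frames), 3, 1))
  if (length(dim(frames)) != 3 || dim(frames)[2] != 3) {
    stop("frames must be an n_atoms x 3 x n_frames array")
  }
  if (dim(frames)[1] != nrow(atoms)) {
    stop("frame atom count (", dim(frames)[1], ") does not match topology (",
         nrow(atoms), ")")
  }
  if (!all(is.finite(frames))) stop("coordinates must be finite")
  if (!(frame_interval > 0)) stop("frame_interval must be > 0")
  if (anyDuplicated(atoms[atoms$kind == "protein", c("chain", "res_number", "name")])) {
    stop("duplicate (chain, res_number, atom name) in protein topology")
  }
  stopifnot(is.list(ligand_groups), !is.null(names(ligand_groups)))
  for (g in names(ligand_groups)) {
    idx <- ligand_groups[[g]]
    if (length(idx) < 1 || any(idx < 1 | idx > nrow(atoms))) {
      stop("ligand feature group '", g, "' does not resolve to any atom")
    }
  }
  structure(
    list(
      atoms = atoms,
      frames = frames,
      ligand_groups = lapply(ligand_groups, as.integer),
      frame_interval = frame_interval,
      receptor_id = receptor_id
    ),
    class = "molecular_system"
  )
}

#' @export
print.molecular_system <- function(x, ...) {
  cat("<molecular_system>",
      if (!is.na(x$receptor_id)) paste0(" ", x$receptor_id), "\n", sep = "")
  cat("  atoms:  ", nrow(x$atoms),
      " (protein ", sum(x$atoms$kind == "protein"),
      ", ligand ", sum(x$atoms$kind == "ligand"),
      ", water ", sum(x$atoms$kind == "water"), ")\n", sep = "")
  cat("  frames: ", n_frames(x), " @ ", x$frame_interval, " ps\n", sep = "")
  cat("  ligand groups: ", paste(names(x$ligand_groups), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Number of frames / atoms in a system
#' @param system a `molecular_system`
#' @export
n_frames <- function(system) dim(system$frames)[3]

#' @rdname n_frames
#' @export
n_atoms <- function(system) dim(system$frames)[1]

#' Coordinates of one frame
#' @param system a `molecular_system`
#' @param frame 1-based frame index
#' @return an `n_atoms x 3` matrix (Angstrom)
#' @export
frame_coords <- function(system, frame) {
  if (frame < 1 || frame > n_frames(system)) {
    stop("frame index ", frame, " out of range 1..", n_frames(system))
  }
  system$frames[, , frame, drop = TRUE]
}

#' Atom indices of a ligand feature group
#' @param system a `molecular_system`
#' @param group group name (e.g. `"carboxylate"`)
#' @export
ligand_group_atoms <- function(system, group) {
  idx <- system$ligand_groups[[group]]
  if (is.null(idx)) {
    stop("unknown ligand feature group '", group, "' (available: ",
         paste(names(system$ligand_groups), collapse = ", "), ")")
  }
  idx
}

#' Atom indices of a receptor residue
#'
#' The residue may be addressed by author number or by its
#' Ballesteros-Weinstein label (after [assign_bw_numbers()]).
#'
#' @param system a `molecular_system`
#' @param res_number author residue number
#' @param bw Ballesteros-Weinstein label such as `"3.32"`
#' @param names optional atom-name filter
#' @export
residue_atoms <- function(system, res_number = NULL, bw = NULL, names = NULL) {
  at <- system$atoms
  if (!is.null(bw)) {
    res_number <- bw_residue(system, bw)
  }
  if (is.null(res_number)) stop("give res_number or bw")
  sel <- which(at$kind == "protein" & at$res_number == res_number)
  if (!length(sel)) stop("no atoms for residue ", res_number)
  if (!is.null(names)) {
    sel <- sel[at$name[sel] %in% names]
    if (!length(sel)) {
      stop("residue ", res_number, " has no atom named ",
           paste(names, collapse = "/"))
    }
  }
  sel
}

#' Reverse lookup of a Ballesteros-Weinstein label
#' @param system a `molecular_system` with assigned labels
#' @param bw label such as `"5.39"` (also accepts `"5.9"` for position 9)
#' @return the author residue number
#' @export
bw_residue <- function(system, bw) {
  lab <- normalize_bw(bw)
  hit <- unique(system$atoms$res_number[!is.na(system$atoms$bw_label) &
                                          system$atoms$bw_label == lab &
                                          system$atoms$kind == "protein"])
  if (length(hit) != 1) {
    stop("Ballesteros-Weinstein label '", bw, "' resolves to ", length(hit),
         " residues (labels assigned? see assign_bw_numbers)")
  }
  hit
}

#' Oxygen atom indices of all water sites
#' @param system a `molecular_system`
#' @export
water_oxygens <- function(system) {
  which(system$atoms$kind == "water" & system$atoms$element == "O")
}

#' Charged atoms within a set of atom indices
#' @noRd
charged_subset <- function(system, idx, sign = NULL) {
  q <- system$atoms$charge[idx]
  if (is.null(sign)) idx[q != 0] else if (sign > 0) idx[q > 0] else idx[q < 0]
}

#' Apolar (C/S) atoms within a set of atom indices
#' @noRd
apolar_subset <- function(system, idx) {
  idx[system$atoms$element[idx] %in% c("C", "S")]
}

#' Polar (N/O) atoms within a set of atom indices
#' @noRd
polar_subset <- function(system, idx) {
  idx[system$atoms$element[idx] %in% c("N", "O")]
}

#' Check two systems share a topology (atom count, names, residue numbering)
#' @noRd
same_topology <- function(a, b) {
  nrow(a$atoms) == nrow(b$atoms) &&
    all(a$atoms$name == b$atoms$name) &&
    all(a$atoms$res_number == b$atoms$res_number) &&
    all(a$atoms$kind == b$atoms$kind)
}
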