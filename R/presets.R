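# Built-in receptor presets for the four opioid receptors.
#
# Anchor tables use the author numbering of the study systems (human MOR /
# DOR / KOR, NOP homology model). The x.50 anchor positions are chosen so
# that the published residue labels are reproduced (e.g. MOR K235 -> 5.39,
# KOR E297 -> 6.58); helix spans are generous but non-overlapping.

#' Built-in Ballesteros-Weinstein anchor tables
#'
#' @param receptor `"MOR"`, `"DOR"`, `"KOR"` or `"NOP"`
#' @return an [anchor_table()]
#' @export
builtin_anchor_table <- function(receptor = c("MOR", "DOR", "KOR", "NOP")) {
  receptor <- match.arg(receptor)
  tm <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(tm = 1:7, first = m[, 1], last = m[, 2])
  }
  rg <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(first = as.integer(m[, 1]), last = as.integer(m[, 2]),
               tag = m[, 3], stringsAsFactors = FALSE)
  }
  switch(receptor,
    MOR = anchor_table("MOR",
      anchors = c(95, 130, 167, 194, 246, 297, 335),
      tm_ranges = tm(85, 100, 120, 135, 142, 172, 180, 199,
                     225, 250, 270, 307, 315, 345),
      regions = rg(1, 84, "N-term", 101, 119, "ICL1", 136, 141, "ECL1",
                   173, 179, "ICL2", 200, 224, "ECL2", 251, 269, "ICL3",
                   308, 314, "ECL3", 346, 400, "C-term")),
    DOR = anchor_table("DOR",
      anchors = c(75, 110, 146, 173, 225, 276, 300),
      tm_ranges = tm(65, 80, 100, 115, 121, 151, 158, 178,
                     204, 229, 250, 286, 293, 305),
      regions = rg(1, 64, "N-term", 81, 99, "ICL1", 116, 120, "ECL1",
                   152, 157, "ICL2", 179, 203, "ECL2", 230, 249, "ICL3",
                   287, 292, "ECL3", 306, 372, "C-term")),
    KOR = anchor_table("KOR",
      anchors = c(85, 120, 156, 183, 238, 289, 312),
      tm_ranges = tm(75, 90, 110, 125, 131, 161, 168, 188,
                     217, 242, 263, 299, 305, 320),
      regions = rg(1, 74, "N-term", 91, 109, "ICL1", 126, 130, "ECL1",
                   162, 167, "ICL2", 189, 216, "ECL2", 243, 262, "ICL3",
                   300, 304, "ECL3", 321, 380, "C-term")),
    NOP = anchor_table("NOP",
      anchors = c(80, 115, 148, 180, 227, 278, 300),
      tm_ranges = tm(70, 85, 105, 120, 123, 153, 166, 186,
                     206, 231, 252, 288, 293, 308),
      regions = rg(1, 69, "N-term", 86, 104, "ICL1", 121, 122, "ECL1",
                   154, 165, "ICL2", 187, 205, "ECL2", 232, 251, "ICL3",
                   289, 292, "ECL3", 309, 370, "C-term"))
  )
}

#' Key pocket and anchor residues per receptor
#'
#' Internal role table used by the synthetic template builder: the
#' conserved D3.32 / Y3.33 / 5.39 motif, the non-conserved residue 6.58
#' (MOR: K, DOR: W, KOR: E), the intracellular deflection anchors 6.31 and
#' 4.40, loop residues contributing auxiliary ionic contacts, and the
#' hydrophobic pocket residues of the rescoring fingerprints.
#'
#' @param receptor receptor id
#' @param nop_tyr333 author number of the NOP 3.33 tyrosine (130 or 131;
#'   the pocket aspartate is placed at the preceding position)
#' @return data.frame with columns `role`, `res_number`, `res_name`
#' @export
receptor_key_residues <- function(receptor = c("MOR", "DOR", "KOR", "NOP"),
                                  nop_tyr333 = 131) {
  receptor <- match.arg(receptor)
  r <- function(role, num, name) data.frame(role = role, res_number = num,
                                            res_name = name,
                                            stringsAsFactors = FALSE)
  switch(receptor,
    MOR = rbind(
      r("d332", 149, "ASP"), r("y333", 150, "TYR"), r("m336", 153, "MET"),
      r("r440", 184, "ARG"), r("k539", 235, "LYS"), r("v542", 238, "VAL"),
      r("r631", 278, "ARG"), r("i651", 298, "ILE"), r("v655", 302, "VAL"),
      r("x658_lys", 305, "LYS"), r("w735", 320, "TRP"),
      r("nterm_asp", 56, "ASP")),
    DOR = rbind(
      r("d332", 128, "ASP"), r("y333", 129, "TYR"), r("m336", 132, "MET"),
      r("r440", 163, "ALA"), r("k539", 214, "LYS"), r("v542", 217, "VAL"),
      r("r631", 257, "ARG"), r("v655", 281, "VAL"),
      r("x658_trp", 284, "TRP"), r("ecl3_arg", 291, "ARG")),
    KOR = rbind(
      r("d332", 138, "ASP"), r("y333", 139, "TYR"), r("m336", 142, "MET"),
      r("r440", 173, "LEU"), r("k539", 227, "LYS"), r("v542", 230, "VAL"),
      r("r631", 270, "ARG"), r("v655", 294, "ILE"),
      r("x658_glu", 297, "GLU"), r("ecl2_lys", 200, "LYS"),
      r("ecl2_glu", 209, "GLU")),
    NOP = {
      if (!nop_tyr333 %in% c(130L, 131L)) {
        stop("nop_tyr333 must be 130 or 131")
      }
      rbind(
        r("d332", nop_tyr333 - 1L, "ASP"), r("y333", nop_tyr333, "TYR"),
        r("i329", 127, "ILE"), r("i331", if (nop_tyr333 == 131) 129 else 128,
          "ILE"),
        r("m336", 134, "MET"), r("r440", 170, "ALA"), r("k539", 216, "LYS"),
        r("v542", 219, "ILE"), r("r631", 259, "ARG"), r("v651", 279, "VAL"),
        r("v655", 283, "VAL"), r("x658_gln", 286, "GLN"))
    }
  )
}

#' Ionic-contact occupancy schedule of the HS-731 study systems
#'
#' The per-receptor ionic interaction rows with their mean trajectory
#' occurrence (fraction of frames), used as ground-truth occupancies by
#' the synthetic generator: the conserved morphinan-amine / D3.32 salt
#' bridge in every frame, the carboxylate contacts to 5.39 and to the
#' receptor-specific 6.58 / loop partners, the secondary-amine contacts to
#' the MOR N-terminal aspartate and the KOR ECL2 glutamate, and (KOR only)
#' the intramolecular K5.39-E6.58 TM5-TM6 bridge.
#'
#' @param receptor receptor id
#' @return list of schedule rows (fields `itype`, `ligand_group`/`res_a`,
#'   `partner`/`res_b`, `p`)
#' @export
hs731_ionic_schedule <- function(receptor = c("MOR", "DOR", "KOR", "NOP")) {
  receptor <- match.arg(receptor)
  lig <- function(itype, group, partner, p) {
    list(itype = itype, ligand_group = group, partner = partner, p = p)
  }
  pair <- function(res_a, res_b, p) {
    list(itype = "PI", res_a = res_a, res_b = res_b, p = p)
  }
  switch(receptor,
    MOR = list(
      lig("PI", "morphinan_amine", 149, 1.000),
      lig("PI", "secondary_amine", 56, 0.737),
      lig("NI", "carboxylate", 235, 0.813),
      lig("NI", "carboxylate", 305, 0.750)),
    DOR = list(
      lig("PI", "morphinan_amine", 128, 1.000),
      lig("NI", "carboxylate", 214, 0.650),
      lig("NI", "carboxylate", 291, 0.092)),
    KOR = list(
      lig("PI", "morphinan_amine", 138, 1.000),
      lig("PI", "secondary_amine", 209, 0.125),
      lig("NI", "carboxylate", 227, 0.633),
      lig("NI", "carboxylate", 200, 0.157),
      pair(227, 297, 0.456)),
    NOP = list(
      lig("PI", "morphinan_amine", 130, 1.000))
  )
}

#' Activation-state fraction schedule of the HS-731 study systems
#'
#' Intermediate-state fractions per receptor as observed over the pooled
#' study trajectories; the split of the remaining mass between active-like
#' and inactive-like frames is a generator choice (agonist-bound systems
#' spend most non-intermediate time active-like).
#'
#' @param receptor receptor id
#' @return named fractions `c(active =, intermediate =, inactive =)`
#'   summing to 1
#' @export
hs731_state_fractions <- function(receptor = c("MOR", "DOR", "KOR", "NOP")) {
  receptor <- match.arg(receptor)
  switch(receptor,
    MOR = c(active = 0.500, intermediate = 0.446, inactive = 0.054),
    DOR = c(active = 0.900, intermediate = 0.053, inactive = 0.047),
    KOR = c(active = 0.400, intermediate = 0.519, inactive = 0.081),
    NOP = c(active = 0.600, intermediate = 0.300, inactive = 0.100)
  )
}

#' Ligand feature-group specification matching the synthetic templates
#'
#' The four pharmacophoric groups of a 6beta-glycine-substituted morphinan:
#' protonated ring amine, protonated secondary amine of the glycine arm,
#' its carboxylate, and the 3-phenol.
#'
#' @return list with `resid`, `groups` (atom names) and `charges`
#' @export
hs731_ligand_spec <- function() {
  list(
    resid = "LIG",
    groups = list(
      morphinan_amine = "N17",
      secondary_amine = "N2",
      carboxylate = c("C20", "O1", "O2"),
      phenol = c("O3", "C21", "C22", "C23", "C24", "C25", "C26")
    ),
    charges = list(morphinan_amine = 1, secondary_amine = 1,
                   carboxylate = -1, phenol = 0)
  )
}
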