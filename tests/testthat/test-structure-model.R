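# Topology model, BW numbering, file round-trips, sequence comparison.

test_that("BW assignment follows the constant-offset rule", {
  anchors <- anchor_table(
    "toy", anchors = c(10, 30, 100, 130, 160, 190, 220),
    tm_ranges = data.frame(tm = 1:7,
                           first = c(5, 25, 80, 125, 155, 185, 215),
                           last = c(15, 35, 110, 135, 165, 195, 225))
  )
  coords <- matrix(0, 3, 3)
  sys <- point_system(c("CA", "CA", "CA"), rep("C", 3), rep(0, 3), coords,
                      res_numbers = c(82, 100, 130))
  sys <- assign_bw_numbers(sys, anchors)
  expect_equal(sys$atoms$bw_label, c("3.32", "3.50", "4.50"))
})

test_that("built-in MOR anchors map K235 to 5.39 and friends", {
  spec <- synthetic_spec("MOR", n_frames = 2, n_replicates = 1)
  tm <- generate_template(spec)
  lab <- function(r) unique(tm$atoms$bw_label[tm$atoms$res_number == r &
                                                tm$atoms$kind == "protein"])
  expect_equal(lab(235), "5.39")
  expect_equal(lab(149), "3.32")
  expect_equal(lab(305), "6.58")
  expect_equal(lab(278), "6.31")
  expect_equal(lab(184), "4.40")
  expect_equal(lab(56), "N-term")
})

test_that("BW assignment is invertible within a helix", {
  for (rec in c("MOR", "DOR", "KOR", "NOP")) {
    spec <- synthetic_spec(rec, n_frames = 2, n_replicates = 1)
    tm <- generate_template(spec)
    at <- tm$atoms[tm$atoms$kind == "protein", ]
    tmres <- unique(at$res_number[grepl("^[1-7]\\.", at$bw_label)])
    for (r in sample(tmres, 20)) {
      bw <- unique(at$bw_label[at$res_number == r])
      expect_equal(bw_residue(tm, bw), r)
    }
  }
})

test_that("residues outside helices and regions warn and get 'unassigned'", {
  anchors <- anchor_table(
    "toy", anchors = c(10, 30, 50, 70, 90, 110, 130),
    tm_ranges = data.frame(tm = 1:7, first = seq(5, 125, 20),
                           last = seq(15, 135, 20))
  )
  sys <- point_system(c("CA", "CA"), c("C", "C"), c(0, 0), matrix(0, 2, 3),
                      res_numbers = c(10, 17))
  expect_warning(sys <- assign_bw_numbers(sys, anchors), "17")
  expect_equal(sys$atoms$bw_label, c("1.50", "unassigned"))
})

test_that("anchor tables validate their invariants", {
  expect_error(anchor_table("x", anchors = 1:6,
                            tm_ranges = data.frame(tm = 1:7, first = 1:7,
                                                   last = 1:7)),
               "7 anchors")
  expect_error(anchor_table("x", anchors = c(3, 10, 20, 30, 40, 50, 60),
                            tm_ranges = data.frame(tm = 1:7,
                                                   first = seq(5, 65, 10),
                                                   last = seq(8, 68, 10))),
               "outside its range")
})

test_that("anchor tables round-trip through YAML", {
  anchors <- builtin_anchor_table("KOR")
  f <- tempfile(fileext = ".yaml")
  write_anchor_table(anchors, f)
  back <- read_anchor_table(f)
  expect_equal(back$anchors, anchors$anchors)
  expect_equal(back$tm_ranges$first, anchors$tm_ranges$first)
  expect_equal(back$regions$tag, anchors$regions$tag)
})

test_that("rendered fixtures round-trip through PDB + CSV within precision", {
  fx <- small_render("KOR", n_frames = 6, n_replicates = 1, seed = 3)
  d <- withr::local_tempdir()
  res <- render_trajectory(fx$template, fx$spec, out_dir = d)
  sys <- load_structure(file.path(d, "topology.pdb"),
                        frames = file.path(d, "replicate_1.csv"),
                        anchors = builtin_anchor_table("KOR"))
  expect_equal(n_frames(sys), 6)
  expect_equal(n_atoms(sys), n_atoms(fx$template))
  expect_lt(max(abs(sys$frames - res$replicates[[1]]$frames)), 1e-3)
  expect_identical(sys$atoms$bw_label, res$replicates[[1]]$atoms$bw_label)
  # loading twice is deterministic
  sys2 <- load_structure(file.path(d, "topology.pdb"),
                         frames = file.path(d, "replicate_1.csv"))
  expect_identical(sys$frames, sys2$frames)
})

test_that("an unresolvable ligand feature group is named in the error", {
  fx <- small_render("MOR", n_frames = 2, n_replicates = 1)
  d <- withr::local_tempdir()
  write_system_pdb(fx$template, file.path(d, "t.pdb"))
  bad_spec <- hs731_ligand_spec()
  bad_spec$groups$carboxylate <- c("XX9")
  expect_error(load_structure(file.path(d, "t.pdb"), bad_spec), "carboxylate")
})

test_that("frame CSVs with inconsistent atom counts are rejected", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("frame,atom_index,x,y,z",
               "1,1,0,0,0", "1,2,1,0,0", "2,1,0,0,0"), f)
  expect_error(read_frames_csv(f), "mismatch")
})

test_that("pairwise identity handles the simple cases", {
  expect_equal(unname(pairwise_identity("ACDEG", "ACDEG")), c(100, 100))
  expect_equal(unname(pairwise_identity("ACDE", "ACDF")[1]), 75)
  a <- "MKTAYIAKQR"
  expect_equal(pairwise_identity(a, a)[["identity"]], 100)
  expect_equal(pairwise_identity(a, "MKTAYIAKQW")[["identity"]],
               pairwise_identity("MKTAYIAKQW", a)[["identity"]])
  expect_error(pairwise_identity("", "ACD"), "non-empty")
})

test_that("pairwise identity agrees with an independent DP oracle", {
  pairs <- list(
    c("ACDEFGHIKLMN", "ACDEFGAIKLMN"),  # one substitution
    c("ACDEFGHIKLMN", "ACDEFGIKLMN"),   # one deletion
    c("WYKRHACDEFGS", "WYKRHACDEFGS")   # identical
  )
  for (p in pairs) {
    got <- pairwise_identity(p[1], p[2])
    aln <- gotoh_align(p[1], p[2], blosum62)
    want <- count_identity(aln$a, aln$b, blosum62)
    expect_equal(got[["identity"]], want[["identity"]], tolerance = 1e-9)
    expect_equal(got[["similarity"]], want[["similarity"]], tolerance = 1e-9)
  }
})
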