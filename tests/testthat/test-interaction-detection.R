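# Geometric detectors: boundary rules, angle criteria, oracle agreement.

crit <- interaction_criteria()

ionic_fixture <- function(d) {
  point_system(c("NZ", "OD1"), c("N", "O"), c(1, -0.5),
               rbind(c(0, 0, 0), c(0, 0, d)))
}

test_that("ionic detection uses an inclusive distance boundary", {
  ev <- detect_ionic(ionic_fixture(3.0), 1, 1, 2, crit)
  expect_equal(ev$distance, 3.0)
  expect_equal(ev$itype, "PI")
  ev45 <- detect_ionic(ionic_fixture(4.5), 1, 1, 2, crit)
  expect_equal(ev45$distance, 4.5)  # boundary is positive
  expect_null(detect_ionic(ionic_fixture(10.0), 1, 1, 2, crit))
  expect_error(detect_ionic(ionic_fixture(3), 1, integer(0), 2, crit),
               "non-empty")
})

test_that("hydrogen bonds need both distance and angle", {
  mk <- function(acc_pos) {
    point_system(c("C1", "O1", "O2"), c("C", "O", "O"), c(0, 0, 0),
                 rbind(c(-1.4, 0, 0), c(0, 0, 0), acc_pos))
  }
  don <- hbond_donor(2, root = 1)
  ev <- detect_hbond(mk(c(2.9, 0, 0)), 1, don, 3, crit)  # angle 180
  expect_equal(ev$distance, 2.9)
  expect_null(detect_hbond(mk(c(0, 2.9, 0)), 1, don, 3, crit))  # angle 90
  expect_null(detect_hbond(mk(c(4.5, 0, 0)), 1, don, 3, crit))  # too far
  # distance-only fallback without angle atoms; strict mode errors
  expect_equal(detect_hbond(mk(c(0, 2.9, 0)), 1, hbond_donor(2), 3,
                            crit)$distance, 2.9)
  strict <- interaction_criteria(hbond_strict = TRUE)
  expect_error(detect_hbond(mk(c(2.9, 0, 0)), 1, hbond_donor(2), 3, strict),
               "strict")
})

test_that("water-mediated bonds require one water bridging both legs", {
  mk <- function(water_x, with_water = TRUE) {
    nm <- c("C1", "O3", "O")
    el <- c("C", "O", "O")
    kd <- c("ligand", "ligand", "protein")
    pos <- rbind(c(-1.4, 0, 0), c(0, 0, 0), c(5.2, 0, 0))
    if (with_water) {
      nm <- c(nm, "O"); el <- c(el, "O"); kd <- c(kd, "water")
      pos <- rbind(pos, c(water_x, 0, 0))
    }
    point_system(nm, el, rep(0, length(nm)), pos, kinds = kd,
                 groups = list(phenol = 1:2))
  }
  don <- hbond_donor(2, root = 1)
  ev <- detect_water_mediated(mk(2.6), 1, don, 3, crit)
  expect_equal(ev$itype, "WATER_MEDIATED")
  expect_match(ev$water_id, "HOH")
  expect_null(detect_water_mediated(mk(2.6, with_water = FALSE), 1, don, 3,
                                    crit))
  # one leg too long (water 5 A from the phenol oxygen)
  expect_null(detect_water_mediated(mk(-5.0), 1, don, 3, crit))
})

test_that("hydrophobic contacts ignore polar atoms", {
  mk <- function(d, el_b = "C") {
    point_system(c("C1", "X1"), c("C", el_b), c(0, 0),
                 rbind(c(0, 0, 0), c(d, 0, 0)))
  }
  expect_equal(detect_hydrophobic(mk(4.0), 1, 1, 2, crit)$distance, 4.0)
  expect_null(detect_hydrophobic(mk(6.0), 1, 1, 2, crit))
  expect_warning(out <- detect_hydrophobic(mk(3.0, el_b = "O"), 1, 1, 2, crit),
                 "apolar")
  expect_null(out)
})

cation_pi_fixture <- function(cation_pos, wobble = 0) {
  ring <- t(vapply(0:5, function(k) {
    a <- k * pi / 3
    c(1.4 * cos(a), 1.4 * sin(a), wobble * (-1)^k)
  }, numeric(3)))
  point_system(c(paste0("C", 1:6), "NZ"), c(rep("C", 6), "N"),
               c(rep(0, 6), 1), rbind(ring, cation_pos))
}

test_that("cation-pi needs the cation near the ring axis", {
  ev <- detect_cation_pi(cation_pi_fixture(c(0, 0, 4)), 1, 7, 1:6, crit)
  expect_equal(ev$distance, 4.0)
  expect_lt(ev$angle, 1e-6)
  # in-plane cation at the same distance fails the offset criterion
  expect_null(detect_cation_pi(cation_pi_fixture(c(4, 0, 0)), 1, 7, 1:6, crit))
  expect_null(detect_cation_pi(cation_pi_fixture(c(0, 0, 10)), 1, 7, 1:6,
                               crit))
  expect_error(detect_cation_pi(cation_pi_fixture(c(0, 0, 4), wobble = 0.8),
                                1, 7, 1:6, crit), "planar")
})

test_that("steric clashes follow the vdW-overlap rule", {
  mk <- function(d) point_system(c("C1", "C2"), c("C", "C"), c(0, 0),
                                 rbind(c(0, 0, 0), c(d, 0, 0)))
  cl <- detect_clash(mk(1.0), 1, 1, 2, crit)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$angle, 3.4 - 1.0)  # overlap column
  expect_equal(nrow(detect_clash(mk(3.5), 1, 1, 2, crit)), 0)
  bad <- mk(1.0); bad$atoms$element[1] <- "ZZ"
  expect_error(detect_clash(bad, 1, 1, 2, crit), "ZZ")
})

test_that("detectors are symmetric under partner swap", {
  sys <- ionic_fixture(3.7)
  a <- detect_ionic(sys, 1, 1, 2, crit)
  b <- detect_ionic(sys, 1, 1, 2, crit, itype = "NI")
  expect_equal(a$distance, b$distance)
  hy <- point_system(c("C1", "C2"), c("C", "C"), c(0, 0),
                     rbind(c(0, 0, 0), c(4.2, 0, 0)))
  expect_equal(detect_hydrophobic(hy, 1, 1, 2, crit)$distance,
               detect_hydrophobic(hy, 1, 2, 1, crit)$distance)
})

test_that("shrinking cutoffs never creates new positive events", {
  set.seed(91)
  for (k in 1:25) {
    d <- runif(1, 1, 8)
    sys <- ionic_fixture(d)
    wide <- !is.null(detect_ionic(sys, 1, 1, 2,
                                  interaction_criteria(ionic_max_dist = 5.5)))
    narrow <- !is.null(detect_ionic(sys, 1, 1, 2,
                                    interaction_criteria(ionic_max_dist = 3.5)))
    expect_true(wide >= narrow)
  }
})

test_that("detectors agree with brute-force oracles on random frames", {
  set.seed(417)
  nf <- 60
  coords <- array(runif(10 * 3 * nf, 0, 9), dim = c(10, 3, nf))
  sys <- point_system(
    c("NZ", "NH1", "OD1", "OE1", "C1", "C2", "C3", "C4", "O5", "N6"),
    c("N", "N", "O", "O", "C", "C", "C", "C", "O", "N"),
    c(1, 0.5, -0.5, -0.5, 0, 0, 0, 0, 0, 0), coords)
  cat_idx <- 1:2; an_idx <- 3:4; hy_a <- 5:6; hy_b <- 7:8
  for (f in seq_len(nf)) {
    xyz <- frame_coords(sys, f)
    # ionic
    got <- detect_ionic(sys, f, cat_idx, an_idx, crit)
    want <- brute_min_dist(xyz, cat_idx, an_idx)
    if (want <= crit$ionic_max_dist) {
      expect_equal(got$distance, want)
    } else {
      expect_null(got)
    }
    # hydrophobic
    goth <- detect_hydrophobic(sys, f, hy_a, hy_b, crit)
    wanth <- brute_min_dist(xyz, hy_a, hy_b)
    if (wanth <= crit$hydrophobic_max_dist) {
      expect_equal(goth$distance, wanth)
    } else {
      expect_null(goth)
    }
    # hydrogen bond with surrogate angle at the donor heavy atom
    gotb <- detect_hbond(sys, f, hbond_donor(9, root = 5), 10, crit)
    db <- sqrt(sum((xyz[9, ] - xyz[10, ])^2))
    ab <- brute_angle(xyz[5, ], xyz[9, ], xyz[10, ])
    if (db <= crit$hbond_max_dist && ab >= crit$hbond_min_angle) {
      expect_equal(gotb$distance, db)
    } else {
      expect_null(gotb)
    }
    # clash: every overlapping pair is reported
    cl <- detect_clash(sys, f, hy_a, hy_b, crit)
    nover <- 0
    for (i in hy_a) for (j in hy_b) {
      if (3.4 - sqrt(sum((xyz[i, ] - xyz[j, ])^2)) >= crit$clash_overlap) {
        nover <- nover + 1
      }
    }
    expect_equal(nrow(cl), nover)
  }
})

test_that("cation-pi agrees with a direct geometric oracle", {
  set.seed(418)
  for (k in 1:40) {
    pos <- runif(3, -7, 7)
    sys <- cation_pi_fixture(pos)
    got <- detect_cation_pi(sys, 1, 7, 1:6, crit)
    d <- sqrt(sum(pos^2))  # ring centroid is the origin
    off <- brute_angle(c(0, 0, 1e6), c(0, 0, 0), pos)
    off <- min(off, 180 - off)
    if (d <= crit$cationpi_max_dist && off <= crit$cationpi_max_offset) {
      expect_equal(got$distance, d, tolerance = 1e-8)
    } else {
      expect_null(got)
    }
  }
})
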