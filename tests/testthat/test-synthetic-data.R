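# Synthetic generator: template validity, scheduling, rendering, ground truth.

test_that("templates resolve every named key residue", {
  for (rec in c("MOR", "DOR", "KOR", "NOP")) {
    spec <- synthetic_spec(rec, n_frames = 2, n_replicates = 1)
    tm <- generate_template(spec)
    for (bw in c("3.32", "3.33", "5.39", "6.58", "6.31", "4.40")) {
      expect_silent(residue_atoms(tm, bw = bw))
    }
    for (g in c("morphinan_amine", "secondary_amine", "carboxylate",
                "phenol")) {
      expect_gte(length(ligand_group_atoms(tm, g)), 1)
    }
  }
  # loop residues of the ionic schedules
  tm_mor <- generate_template(synthetic_spec("MOR", n_frames = 2,
                                             n_replicates = 1))
  expect_silent(residue_atoms(tm_mor, res_number = 56))
  tm_kor <- generate_template(synthetic_spec("KOR", n_frames = 2,
                                             n_replicates = 1))
  expect_silent(residue_atoms(tm_kor, res_number = 200))
  expect_silent(residue_atoms(tm_kor, res_number = 209))
})

test_that("a spec without waters yields an empty water list", {
  tm <- generate_template(synthetic_spec("MOR", n_frames = 2,
                                         n_replicates = 1,
                                         include_waters = FALSE))
  expect_length(water_oxygens(tm), 0)
})

test_that("invalid specs are rejected with the violations listed", {
  expect_error(synthetic_spec("MOR", state_fractions = c(active = 0.6,
                                                         intermediate = 0.4,
                                                         inactive = 0.2)),
               "sum")
  expect_error(synthetic_spec("MOR", interactions = list(
    list(itype = "PI", ligand_group = "morphinan_amine", partner = 149,
         p = 1.4))), "occupancy")
  expect_error(synthetic_spec("MOR", noise_sd = 0.6), "noise_sd")
})

test_that("exact occupancy masks have the rounded count, shuffled", {
  expect_true(all(schedule_occupancy(50, 1, "exact", seed = 1)))
  expect_false(any(schedule_occupancy(50, 0, "exact", seed = 1)))
  m <- schedule_occupancy(1000, 0.813, "exact", seed = 42)
  expect_equal(sum(m), 813)
  # round half up: 0.5 * 10 -> 5, 0.45 * 10 -> 5 (4.5 rounds up)
  expect_equal(sum(schedule_occupancy(10, 0.45, "exact", seed = 1)), 5)
  expect_identical(schedule_occupancy(1000, 0.3, "exact", seed = 7),
                   schedule_occupancy(1000, 0.3, "exact", seed = 7))
  expect_error(schedule_occupancy(10, 1.2, "exact"), "\\[0, 1\\]")
})

test_that("zero-noise rendering places bound pairs exactly", {
  spec <- synthetic_spec("MOR", n_frames = 30, n_replicates = 1, seed = 12,
                         noise_sd = 0)
  res <- render_trajectory(generate_template(spec), spec)
  sys <- res$replicates[[1]]
  masks <- res$ground_truth$masks[[1]]
  for (k in seq_along(spec$interactions)) {
    row <- spec$interactions[[k]]
    def <- schedule_definitions(spec)[[k]]
    mask <- as.logical(masks[[k]])
    for (f in c(which(mask)[1], which(!mask)[1])) {
      if (is.na(f)) next
      ev <- frame_fingerprint(sys, f, list(def))
      if (mask[f]) {
        expect_equal(ev$distance, row$bound_dist, tolerance = 1e-9)
      } else {
        expect_equal(nrow(ev), 0)
      }
    }
  }
})

test_that("rendering is deterministic and reproducible from the seed", {
  spec <- synthetic_spec("KOR", n_frames = 25, n_replicates = 2, seed = 99)
  a <- render_trajectory(generate_template(spec), spec)
  b <- render_trajectory(generate_template(spec), spec)
  expect_identical(a$replicates[[1]]$frames, b$replicates[[1]]$frames)
  expect_identical(a$ground_truth$masks, b$ground_truth$masks)
  expect_identical(a$ground_truth$state_labels, b$ground_truth$state_labels)
  # replicates differ from each other (seed + r)
  expect_false(identical(a$replicates[[1]]$frames, a$replicates[[2]]$frames))
})

test_that("ground truth masks recount to the recovered occupancies", {
  fx <- small_render("MOR", n_frames = 120, n_replicates = 2, seed = 41)
  defs <- schedule_definitions(fx$spec)
  tab <- occurrence_frequencies(fx$render$replicates, defs)
  for (r in 1:2) {
    for (k in seq_along(defs)) {
      expect_equal(tab[[paste0("rep_", r)]][k],
                   100 * mean(as.logical(fx$render$ground_truth$masks[[r]][[k]])))
    }
  }
  # scheduled state labels recount to the rendered state fractions
  ref <- schedule_state_reference(fx$spec)
  prof <- state_fractions(fx$render$replicates, ref)
  lab <- unlist(fx$render$ground_truth$state_labels)
  expect_equal(unname(prof$fractions["intermediate"]),
               100 * mean(lab == "intermediate"))
})

test_that("bernoulli occupancies converge within three binomial SEs", {
  n <- 600
  for (p in c(0.1, 0.5, 0.9)) {
    se <- sqrt(p * (1 - p) / n)
    for (seed in 1:3) {
      m <- schedule_occupancy(n, p, "bernoulli", seed = seed)
      expect_lt(abs(mean(m) - p), 3 * se + 1e-12)
    }
  }
})

test_that("specs round-trip through YAML", {
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(receptor = "KOR", n_frames = 40, n_replicates = 2,
                        seed = 5, noise_sd = 0.02,
                        state_fractions = list(active = 0.5,
                                               intermediate = 0.4,
                                               inactive = 0.1)), f)
  spec <- read_synthetic_spec(f)
  expect_s3_class(spec, "synthetic_spec")
  expect_equal(spec$n_frames, 40L)
  expect_equal(spec$state_fractions[["intermediate"]], 0.4)
  expect_length(spec$interactions, length(hs731_ionic_schedule("KOR")))
})
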