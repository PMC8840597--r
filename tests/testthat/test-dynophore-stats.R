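# Occurrence frequencies, occupancies and distance profiles.

definition_key_str <- function(def) {
  paste(def$itype, def$ligand_group %||% as.character(def$res_a),
        def$partner %||% def$res_b, sep = "|")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("frame fingerprints report scheduled contacts deterministically", {
  fx <- small_render("MOR", n_frames = 30, n_replicates = 1, seed = 5)
  sys <- fx$render$replicates[[1]]
  defs <- schedule_definitions(fx$spec)
  mask_539 <- as.logical(fx$render$ground_truth$masks[[1]][[3]])
  f_on <- which(mask_539)[1]
  f_off <- which(!mask_539)[1]
  ev_on <- frame_fingerprint(sys, f_on, defs)
  expect_true(any(ev_on$itype == "NI" & ev_on$partner == "235"))
  expect_true(any(ev_on$itype == "PI" & ev_on$partner == "149"))
  ev_off <- frame_fingerprint(sys, f_off, defs)
  expect_false(any(ev_off$partner == "235"))
  expect_identical(frame_fingerprint(sys, f_on, defs), ev_on)
  bad <- interaction_definition("PI", ligand_group = "morphinan_amine",
                                partner = 9999)
  expect_error(frame_fingerprint(sys, 1, list(bad)), "9999")
})

test_that("mean frequency is the arithmetic mean over replicates", {
  fx <- small_render("MOR", n_frames = 20, n_replicates = 1, seed = 2)
  def <- interaction_definition("NI", ligand_group = "carboxylate",
                                partner = 235)
  # two hand-scheduled replicates at 60% and 80%
  spec60 <- synthetic_spec("MOR", n_frames = 20, n_replicates = 1, seed = 2,
                           interactions = list(list(
                             itype = "NI", ligand_group = "carboxylate",
                             partner = 235, p = 0.6)))
  spec80 <- synthetic_spec("MOR", n_frames = 20, n_replicates = 1, seed = 3,
                           interactions = list(list(
                             itype = "NI", ligand_group = "carboxylate",
                             partner = 235, p = 0.8)))
  r60 <- render_trajectory(generate_template(spec60), spec60)$replicates[[1]]
  r80 <- render_trajectory(generate_template(spec80), spec80)$replicates[[1]]
  tab <- occurrence_frequencies(list(r60, r80), list(def))
  expect_equal(tab$rep_1, 60)
  expect_equal(tab$rep_2, 80)
  expect_equal(tab$mean_frequency, 70)
  pooled <- occurrence_frequencies(list(r60, r80), list(def), pooled = TRUE)
  expect_equal(pooled$mean_frequency, 70)  # equal n -> same value
})

test_that("exact schedules are recovered exactly and sum with complements", {
  fx <- small_render("KOR", n_frames = 1000, n_replicates = 1, seed = 8)
  sys <- fx$render$replicates[[1]]
  defs <- schedule_definitions(fx$spec)
  tab <- occurrence_frequencies(list(sys), defs)
  scheduled <- vapply(fx$spec$interactions, function(r) 100 * r$p, numeric(1))
  expect_equal(tab$mean_frequency, scheduled)
  # frequency of event + complement = 100 per replicate
  for (def in defs) {
    occ <- pair_occupancy(sys, def)
    expect_equal(occ + (100 - occ), 100)
    expect_equal(occ, tab$mean_frequency[match(
      definition_key_str(def), apply(tab[, 1:3], 1, paste, collapse = "|"))])
  }
})

test_that("frequencies are invariant under frame reordering", {
  fx <- small_render("MOR", n_frames = 50, n_replicates = 1, seed = 21)
  sys <- fx$render$replicates[[1]]
  def <- schedule_definitions(fx$spec)[[3]]
  before <- pair_occupancy(sys, def)
  perm <- sample(n_frames(sys))
  sys$frames <- sys$frames[, , perm]
  expect_equal(pair_occupancy(sys, def), before)
})

test_that("vectorised counting matches the per-frame detector route", {
  fx <- small_render("KOR", n_frames = 40, n_replicates = 1, seed = 13)
  sys <- fx$render$replicates[[1]]
  defs <- schedule_definitions(fx$spec)
  tab <- occurrence_frequencies(list(sys), defs)
  slow <- vapply(defs, function(def) {
    hits <- vapply(seq_len(n_frames(sys)), function(f) {
      nrow(frame_fingerprint(sys, f, list(def))) > 0
    }, logical(1))
    100 * mean(hits)
  }, numeric(1))
  expect_equal(tab$mean_frequency, slow)
})

test_that("bernoulli occupancies match a recount of the persisted mask", {
  spec <- synthetic_spec("MOR", n_frames = 200, n_replicates = 1, seed = 77,
                         mode = "bernoulli",
                         interactions = list(list(
                           itype = "NI", ligand_group = "carboxylate",
                           partner = 235, p = 0.5)))
  res <- render_trajectory(generate_template(spec), spec)
  def <- schedule_definitions(spec)[[1]]
  occ <- pair_occupancy(res$replicates[[1]], def)
  mask <- as.logical(res$ground_truth$masks[[1]][[1]])
  expect_equal(occ, 100 * mean(mask))
})

test_that("distance profiles match a sort-based quantile oracle", {
  mk_series <- function(d) {
    coords <- array(0, dim = c(2, 3, length(d)))
    coords[2, 3, ] <- d
    point_system(c("C1", "C2"), c("C", "C"), c(0, 0), coords)
  }
  const <- distance_profile(mk_series(rep(3, 10)), 1, 2)
  expect_equal(unname(const$summary), rep(3, 5))
  four <- distance_profile(mk_series(c(1, 2, 3, 4)), 1, 2)
  expect_equal(four$summary[["median"]], 2.5)
  set.seed(31)
  d <- runif(101, 2, 9)
  prof <- distance_profile(mk_series(d), 1, 2)
  expect_equal(prof$distances, d, tolerance = 1e-12)
  # independent oracle: sorted linear interpolation (type-7 definition)
  s <- sort(d)
  q7 <- function(p) {
    h <- (length(s) - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
  }
  expect_equal(unname(prof$summary),
               c(q7(0), q7(0.25), q7(0.5), q7(0.75), q7(1)))
  expect_true(all(diff(prof$summary) >= 0))
  expect_error(distance_profile(mk_series(1), 1, 99), "atom")
})

test_that("replicates with different topologies are rejected", {
  fx1 <- small_render("MOR", n_frames = 5, n_replicates = 1)
  fx2 <- small_render("KOR", n_frames = 5, n_replicates = 1)
  def <- interaction_definition("PI", ligand_group = "morphinan_amine",
                                partner = 149)
  expect_error(
    occurrence_frequencies(list(fx1$render$replicates[[1]],
                                fx2$render$replicates[[1]]), list(def)),
    "topology")
})
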