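# Synthetic trajectory generator: determinism, noise model, event
# kinematics and script validation.

test_that("a silent script reproduces the starting frame exactly", {
  sheet <- wt_sheet(4, termini = "neutral")
  traj <- generate_trajectory(sheet, scenario_script(n_frames = 6,
                                                     noise_sigma = 0, seed = 9))
  for (k in 1:6) expect_identical(traj$coords[[k]], sheet$xyz)
})

test_that("seed and script fully determine the output", {
  sheet <- wt_sheet(5, termini = "neutral")
  sc <- scenario_script(n_frames = 12, noise_sigma = 0.02, seed = 17,
                        events = list(scheduled_event("dissociation", "E",
                                                      4, 8)))
  t1 <- generate_trajectory(sheet, sc)
  t2 <- generate_trajectory(sheet, sc)
  expect_identical(t1$coords, t2$coords)
  sc2 <- scenario_script(n_frames = 12, noise_sigma = 0.02, seed = 18,
                         events = list(scheduled_event("dissociation", "E",
                                                       4, 8)))
  expect_false(identical(generate_trajectory(sheet, sc2)$coords, t1$coords))
  # generation does not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(generate_trajectory(sheet, sc)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("scripted dissociation moves the peptide by the stated distance", {
  sheet <- wt_sheet(6, termini = "neutral")
  sc <- scenario_script(n_frames = 60, noise_sigma = 0, seed = 1,
                        events = list(scheduled_event("dissociation", "F",
                                                      10, 50, distance = 2.0)))
  traj <- generate_trajectory(sheet, sc)
  comdist <- function(fr) {
    m <- crossbeta:::.atom_masses(fr)
    a <- fr$atoms$peptide == "F"
    cf <- colSums(fr$xyz[a, ] * m[a]) / sum(m[a])
    cr <- colSums(fr$xyz[!a, ] * m[!a]) / sum(m[!a])
    sqrt(sum((cf - cr)^2))
  }
  d0 <- comdist(frame_at(traj, 1))
  d1 <- comdist(frame_at(traj, 51))
  expect_equal(d1 - d0, 2.0, tolerance = 0.01)
})

test_that("rigid-filtered noise leaves peptide centres of mass in place", {
  sheet <- wt_sheet(4, termini = "neutral")
  traj <- generate_trajectory(sheet, scenario_script(n_frames = 20,
                                                     noise_sigma = 0.02, seed = 5))
  m <- crossbeta:::.atom_masses(frame_at(traj, 1))
  for (k in c(2, 10, 20)) for (p in c("A", "C")) {
    sel <- traj$atoms$peptide == p
    com0 <- colSums(sheet$xyz[sel, ] * m[sel]) / sum(m[sel])
    comk <- colSums(traj$coords[[k]][sel, ] * m[sel]) / sum(m[sel])
    # well inside the 3 sigma / sqrt(n_atoms) law-of-large-numbers bound
    expect_lt(sqrt(sum((comk - com0)^2)),
              3 * 0.02 / sqrt(sum(sel)))
  }
})

test_that("contradictory or ill-formed scripts are rejected", {
  expect_error(scenario_script(n_frames = 10, events = list(
    scheduled_event("dissociation", "A", 12))), "outside")
  expect_error(scheduled_event("dissociation", c("A", "B"), 5),
               "exactly one")
  expect_error(scheduled_event("rearrangement", "A", 5), "pair")
  expect_error(scheduled_event("teleport", "A", 5), "unknown event type")
  expect_error(scheduled_event("disintegration", start_frame = 5,
                               blocks = list(c("A", "B"))), ">= 2")
  expect_error(scenario_script(n_frames = 50, events = list(
    scheduled_event("dissociation", "A", 10, 30),
    scheduled_event("collapse", c("A", "B"), 20, 40))),
    "script conflict")
  # non-displacement overlaps are allowed
  expect_silent(scenario_script(n_frames = 50, noise_sigma = 0, events = list(
    scheduled_event("progressive_twist", c("A", "B"), 10, 30),
    scheduled_event("end_fray", c("A", "B"), 20, 40))))
  sheet <- wt_sheet(3)
  expect_error(generate_trajectory(sheet, scenario_script(
    n_frames = 10, noise_sigma = 0,
    events = list(scheduled_event("dissociation", "Z", 2)))),
    "unknown peptide")
})

test_that("presets cover the event taxonomy with declared expectations", {
  ps <- preset_scenarios(6)
  expect_gte(length(ps), 6)
  expect_true(all(c("stable_twisted", "end_fraying", "edge_dissociation",
                    "antiparallel_rearrangement", "disintegration_4_2",
                    "collapse_amorphous") %in% names(ps)))
  for (sc in ps) {
    e <- attr(sc, "expected")
    expect_true(e$verdict %in% c("stable", "unstable"))
  }
  # the scripted split leaves an ordered 5-mer after an edge dissociation
  sheet <- wt_sheet(6, termini = "neutral")
  traj <- generate_trajectory(sheet, preset_scenarios(6, noise_sigma = 0)$edge_dissociation)
  last <- frame_at(traj, n_frames(traj))
  cl <- cluster_peptides(last)
  expect_equal(sort(vapply(cl, length, integer(1))), c(1L, 5L))
})
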