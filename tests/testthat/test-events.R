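# Event layer: clustering, orientation classes, event detection, verdicts
# and the oligomer census.

test_that("connectivity clustering partitions every frame", {
  sh <- wt_sheet(6)
  cl <- cluster_peptides(sh)
  expect_length(cl, 1)
  expect_setequal(cl[[1]], LETTERS[1:6])
  # partition property over a noisy dissociation trajectory
  traj <- simulate_system(mutant = "N2S", n_peptides = 5,
                          scenario = "edge_dissociation",
                          n_frames = 30, noise_sigma = 0.01, seed = 2)
  for (k in c(1, 15, 30)) {
    part <- cluster_peptides(frame_at(traj, k))
    members <- unlist(part)
    expect_setequal(members, LETTERS[1:5])
    expect_equal(anyDuplicated(members), 0)
  }
  # final frame of the scripted split: a 4-mer and a singleton
  last <- cluster_peptides(frame_at(traj, 30))
  expect_equal(sort(vapply(last, length, integer(1))), c(1L, 4L))
})

test_that("orientation classes split at the configured twist bounds", {
  sh <- wt_sheet(3)
  expect_equal(pair_orientation(sh, "A", "B"), "parallel")
  rot <- function(deg) apply_rigid_transform(sh, "A",
                                             R = crossbeta:::.rotmat(c(0, 0, 1), deg))
  expect_equal(pair_orientation(rot(90), "A", "B"), "crossed")
  expect_equal(pair_orientation(rot(135), "A", "B"), "antiparallel")
  expect_equal(pair_orientation(rot(180), "A", "B"), "antiparallel")
})

test_that("event records carry types, onsets and participants", {
  stable <- simulate_system(mutant = "N2S", n_peptides = 6,
                            scenario = "stable_twisted", noise_sigma = 0, seed = 1)
  expect_equal(nrow(detect_events(stable)), 0)

  diss <- simulate_system(mutant = "N2S", n_peptides = 6,
                          scenario = "edge_dissociation", noise_sigma = 0, seed = 1)
  ev <- detect_events(diss)
  expect_equal(ev$type, "dissociation")
  expect_equal(ev$peptides, "F")
  expect_gte(ev$onset_frame, 40)   # scripted onset, persistence window 5
  expect_lte(ev$onset_frame, 45)

  re <- simulate_system(mutant = "N2S", n_peptides = 6,
                        scenario = "antiparallel_rearrangement",
                        noise_sigma = 0, seed = 1)
  ev <- detect_events(re)
  expect_equal(ev$type, "rearrangement")
  expect_equal(ev$peptides, "A,B")

  # label determinism
  expect_identical(detect_events(diss), detect_events(diss))
})

test_that("the stability verdict combines Rg drift, events and detachment", {
  sheet <- wt_sheet(5, termini = "neutral")
  const <- generate_trajectory(sheet, scenario_script(n_frames = 20,
                                                      noise_sigma = 0, seed = 1))
  v <- stability_verdict(const)
  expect_equal(v$verdict, "stable")
  expect_equal(v$key_event, "none")
  expect_equal(v$delta_rg, 0)

  for (case in list(c("edge_dissociation", "dissociation"),
                    c("collapse_amorphous", "collapse"),
                    c("disintegration_4_2", "disintegration"))) {
    traj <- simulate_system(mutant = "N2S", n_peptides = 6,
                            scenario = case[1], noise_sigma = 0, seed = 1)
    v <- stability_verdict(traj)
    expect_equal(v$verdict, "unstable")
    expect_equal(v$key_event, case[2])
  }
  # every key event stays inside the reference vocabulary
  vocab <- c("none", "disorder", "dissociation", "disintegration",
             "rearrangement", "collapse")
  for (sc in names(preset_scenarios())) {
    v <- stability_verdict(simulate_system(mutant = "N2S", n_peptides = 6,
                                           scenario = sc, noise_sigma = 0,
                                           seed = 2))
    expect_true(v$key_event %in% vocab)
  }
})

test_that("disintegration splits increase the cluster count at onset", {
  traj <- simulate_system(mutant = "N2S", n_peptides = 6,
                          scenario = "disintegration_4_2",
                          noise_sigma = 0, seed = 1)
  an <- analyze_trajectory(traj)
  ev <- detect_events(traj, analysis = an)
  t <- ev$onset_frame[ev$type == "disintegration"][1] + 1
  expect_gt(length(an$partitions[[t]]), length(an$partitions[[t - 1]]))
})

test_that("the census tracks oligomer membership, birth and lifetime", {
  # stable 7-mer: one record spanning the run
  traj <- simulate_system(mutant = "N2S", n_peptides = 7,
                          scenario = "stable_twisted", noise_sigma = 0, seed = 1)
  cen <- oligomer_census(traj)
  expect_equal(nrow(cen), 1)
  expect_equal(cen$size, 7)
  expect_equal(cen$lifetime_ns, 50)
  expect_true(cen$ordered)

  # scripted 4+2 split at frame 50 of 100 at 0.5 ns/frame
  traj <- simulate_system(mutant = "N2S", n_peptides = 6,
                          scenario = "disintegration_4_2",
                          noise_sigma = 0, seed = 1)
  cen <- oligomer_census(traj)
  expect_setequal(cen$size, c(6, 4, 2))
  expect_equal(cen$lifetime_ns[cen$size == 6], 25)
  expect_equal(cen$lifetime_ns[cen$size == 4], 25)
  expect_equal(cen$birth_frame[cen$size == 4], 50)

  # two sequential dissociations from a 5-mer: sizes 5, 4, 3 in order
  sheet <- wt_sheet(5, termini = "neutral")
  sc <- scenario_script(n_frames = 100, noise_sigma = 0, seed = 1, events = list(
    scheduled_event("dissociation", "E", 30, direction = c(0, 1, 0)),
    scheduled_event("dissociation", "D", 60, direction = c(0, 0, 1))))
  traj <- generate_trajectory(sheet, sc)
  cen <- oligomer_census(traj)
  big <- cen[order(cen$birth_frame), ]
  expect_equal(big$size[1:3], c(5L, 4L, 3L))
  ev <- detect_events(traj)
  expect_equal(ev$type, c("dissociation", "dissociation"))
  expect_equal(ev$peptides, c("E", "D"))
})
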