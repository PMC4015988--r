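# Builder: sequences, strand geometry, sheet stacking, rigid transforms.

test_that("point mutations apply at the stated position", {
  expect_equal(mutate_sequence("GNNQQNY", "N2D"), "GDNQQNY")
  expect_equal(mutate_sequence("GNNQQNY", "N2S"), "GSNQQNY")
  expect_equal(mutate_sequence("GNNQQNY", "N6D"), "GNNQQDY")
  expect_equal(mutate_sequence("GNNQQNY", "N2N"), "GNNQQNY")
  expect_error(mutate_sequence("GNNQQNY", "Q2D"), "inconsistent")
  expect_error(peptide_spec("GXNQQNY"), "template")
})

test_that("ideal strands have beta-strand Ca spacing and termini chemistry", {
  s <- build_strand(peptide_spec("GNNQQNY"))
  ca <- s$xyz[s$atoms$atom == "CA", ]
  d <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(d - 0.38) < 0.01))
  # charged termini: OXT acceptor only, N-terminal N donates
  a <- s$atoms
  expect_true(a$acceptor[a$atom == "OXT"])
  expect_false(a$donor[a$atom == "OXT"])
  expect_true(a$donor[a$atom == "N" & a$resid == 1])
  # neutral termini: carboxylic acid exposes one donor and one acceptor
  sn <- build_strand(peptide_spec("GNNQQNY", termini = "neutral"))
  an <- sn$atoms
  expect_true(an$donor[an$atom == "OXT"])
  expect_true(an$acceptor[an$atom == "O" & an$resid == 7])
  # serine hydroxyl is both donor and acceptor
  ser <- build_strand(peptide_spec(mutant = "N2S", termini = "neutral"))
  og <- ser$atoms[ser$atoms$atom == "OG", ]
  expect_true(og$donor && og$acceptor)
})

test_that("sheets stack in register at the requested spacing and twist", {
  ps <- peptide_spec("GNNQQNY")
  sh <- build_sheet(ps, aggregate_spec(5))
  expect_equal(peptide_ids(sh), LETTERS[1:5])
  for (k in 1:4) {
    reg <- registry_distances(sh, LETTERS[k], LETTERS[k + 1])
    expect_true(all(abs(reg - 0.48) < 1e-9))
    expect_lt(pair_twist(sh, LETTERS[k], LETTERS[k + 1]), 1e-6)
  }
  sh15 <- build_sheet(ps, aggregate_spec(6, per_pair_twist = 15))
  for (k in 1:5)
    expect_lt(abs(pair_twist(sh15, LETTERS[k], LETTERS[k + 1]) - 15), 1e-6)
  expect_lt(abs(pair_twist(sh15, "A", "C") - 30), 1e-6)
  # determinism
  expect_identical(build_sheet(ps, aggregate_spec(6))$xyz,
                   build_sheet(ps, aggregate_spec(6))$xyz)
  # register offset pushes equivalent residues beyond the spacing,
  # monotonically with the shift (wider spacing: a one-residue shift
  # interdigitates the fixed rotamers at the default spacing)
  sho1 <- build_sheet(ps, aggregate_spec(3, spacing = 0.55, register_offset = 1))
  sho2 <- build_sheet(ps, aggregate_spec(3, spacing = 0.55, register_offset = 2))
  expect_true(all(registry_distances(sho1, "A", "B") > 0.55))
  expect_gt(mean(registry_distances(sho2, "A", "B")),
            mean(registry_distances(sho1, "A", "B")))
})

test_that("sterically impossible builds are rejected with the offending pair", {
  expect_error(build_sheet(peptide_spec("GNNQQNY"),
                           aggregate_spec(2, orientation = "antiparallel")),
               "steric clash.*A and B")
  # the same arrangement builds cleanly at a wider spacing
  ap <- build_sheet(peptide_spec("GNNQQNY"),
                    aggregate_spec(2, spacing = 0.55,
                                   orientation = "antiparallel"))
  expect_gt(pair_twist(ap, "A", "B"), 130)
})

test_that("rigid transforms move one peptide and preserve its geometry", {
  sh <- wt_sheet(4)
  expect_identical(apply_rigid_transform(sh, "B"), sh)   # identity, bitwise
  # pure translation: per-peptide Rg unchanged, others untouched
  tr <- apply_rigid_transform(sh, "B", t = c(0.3, -0.1, 0.2))
  expect_equal(radius_of_gyration(tr, "B"), radius_of_gyration(sh, "B"),
               tolerance = 1e-12)
  selA <- crossbeta:::.sel_atoms(sh, peptide = "A")
  expect_identical(tr$xyz[selA, ], sh$xyz[selA, ])
  # internal distances preserved under rotation to ~1e-9 nm
  R <- crossbeta:::.rotmat(c(0.3, 1, 0.2), 37)
  rot <- apply_rigid_transform(sh, "C", R = R)
  selC <- crossbeta:::.sel_atoms(sh, peptide = "C")
  d0 <- dist(sh$xyz[selC, ])
  d1 <- dist(rot$xyz[selC, ])
  expect_lt(max(abs(d0 - d1)), 1e-9)
  # 180-degree flip about the sheet-plane normal turns a pair antiparallel
  flip <- apply_rigid_transform(sh, "A", R = crossbeta:::.rotmat(c(0, 0, 1), 180))
  expect_equal(pair_orientation(flip, "A", "B"), "antiparallel")
  expect_error(apply_rigid_transform(sh, "Z"), "unknown peptide")
})

test_that("every interior peptide of a built sheet bonds both neighbors", {
  for (term in c("charged", "neutral")) {
    sh <- wt_sheet(5, termini = term)
    hb <- detect_hbonds(sh)
    adj <- crossbeta:::.bb_adjacency(sh, hb, cb_config())
    for (k in 2:4) {
      expect_gte(adj[LETTERS[k], LETTERS[k - 1]], 4)
      expect_gte(adj[LETTERS[k], LETTERS[k + 1]], 4)
    }
  }
})
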