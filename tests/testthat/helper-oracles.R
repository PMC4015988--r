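# Independent oracles and small fixture builders used across the suite.

# Direct-sum mass-weighted radius of gyration (plain loop, no matrix ops).
rg_oracle <- function(frame, idx = seq_len(nrow(frame$atoms))) {
  masses <- c(C = 12.011, N = 14.007, O = 15.999)
  m <- masses[frame$atoms$element[idx]]
  com <- c(0, 0, 0)
  for (k in seq_along(idx)) com <- com + m[k] * frame$xyz[idx[k], ]
  com <- com / sum(m)
  s <- 0
  for (k in seq_along(idx)) s <- s + m[k] * sum((frame$xyz[idx[k], ] - com)^2)
  unname(sqrt(s / sum(m)))
}

# Brute-force hydrogen-bond census: nested loop over every donor/acceptor
# atom pair, re-deriving the geometric criterion from scratch.
hbond_oracle <- function(frame, dist_cut = 0.35, angle_min = 90) {
  a <- frame$atoms
  out <- character()
  for (d in seq_len(nrow(a))) {
    if (!a$donor[d]) next
    for (c in seq_len(nrow(a))) {
      if (!a$acceptor[c]) next
      if (a$peptide[d] == a$peptide[c] && a$resid[d] == a$resid[c]) next
      if (a$atom[d] == "N" && a$atom[c] == "O" &&
          a$peptide[d] == a$peptide[c] && a$resid[c] == a$resid[d] - 1) next
      r <- sqrt(sum((frame$xyz[d, ] - frame$xyz[c, ])^2))
      if (r > dist_cut) next
      u <- frame$xyz[a$ante[d], ] - frame$xyz[d, ]
      v <- frame$xyz[c, ] - frame$xyz[d, ]
      ang <- acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
      if (ang >= angle_min) out <- c(out, paste(d, c))
    }
  }
  sort(out)
}

# Minimal frame with bare-bones annotation (all atoms one peptide unless
# peptide ids given).
mini_frame <- function(xyz, element = "C", peptide = "A") {
  n <- nrow(xyz)
  atoms <- data.frame(
    peptide = rep_len(peptide, n), resid = 1L, resname = "GLY",
    atom = "CA", element = rep_len(element, n), backbone = TRUE,
    donor = FALSE, acceptor = FALSE, ante = NA_integer_)
  crossbeta:::cb_frame(atoms, xyz)
}

# Two tyrosine-like six-membered rings (plus a CA each), ring planes
# parallel to xy, centroids separated by `dz` along z.
ring_pair_frame <- function(dz) {
  hexagon <- function(center) {
    th <- (0:5) * pi / 3
    cbind(center[1] + 0.14 * cos(th), center[2] + 0.14 * sin(th),
          rep(center[3], 6))
  }
  xyz <- rbind(hexagon(c(0, 0, 0)), c(0.5, 0, 0),
               hexagon(c(0, 0, dz)), c(0.5, 0, dz))
  ring_names <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  atoms <- data.frame(
    peptide = rep(c("A", "B"), each = 7),
    resid = 7L, resname = "TYR",
    atom = rep(c(ring_names, "CA"), 2),
    element = "C", backbone = rep(c(rep(FALSE, 6), TRUE), 2),
    donor = FALSE, acceptor = FALSE, ante = NA_integer_)
  crossbeta:::cb_frame(atoms, xyz)
}

# Trajectory whose only feature is an exact Rg step: two equal-mass atoms
# at +-r1/2 then +-r2/2 (Rg = r/2), one frame each.
rg_step_traj <- function(rg1, rg2) {
  f <- function(rg) mini_frame(rbind(c(-rg, 0, 0), c(rg, 0, 0)))
  crossbeta::cb_trajectory(list(f(rg1), f(rg2)), frame_dt = 0.5)
}

wt_sheet <- function(n = 6, termini = "charged", ...) {
  build_sheet(peptide_spec("GNNQQNY", termini = termini),
              aggregate_spec(n, ...))
}
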