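# Geometric observables: Rg, twist, registry, stacking, hydrogen bonds,
# sheet assignment, residue profiles, edge classification.

#' Mass-weighted radius of gyration
#'
#' @param frame a `cb_frame`.
#' @param selection atoms to include: `NULL` for all, a character vector of
#'   peptide ids, or an integer vector of atom indices.
#' @return Rg in nm.
#' @examples
#' radius_of_gyration(build_strand(peptide_spec()))
#' @export
radius_of_gyration <- function(frame, selection = NULL) {
  idx <- if (is.null(selection)) seq_len(nrow(frame$atoms))
         else if (is.character(selection)) .sel_atoms(frame, peptide = selection)
         else as.integer(selection)
  if (!length(idx)) stop("empty selection")
  m <- .atom_masses(frame)[idx]
  x <- frame$xyz[idx, , drop = FALSE]
  com <- colSums(x * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(x, 2, com)^2)) / sum(m))
}

#' Rg time series over a trajectory
#' @inheritParams radius_of_gyration
#' @param traj a `cb_traj`.
#' @return Numeric vector, one Rg (nm) per frame.
#' @export
rg_series <- function(traj, selection = NULL) {
  vapply(seq_len(n_frames(traj)),
         function(k) radius_of_gyration(frame_at(traj, k), selection),
         numeric(1))
}

#' Radius-of-gyration drift over a trajectory
#'
#' `Rg(final) - Rg(initial)`, each side averaged over a terminal window of
#' `window_frac` of the frames (at least one frame); `mode = "endpoints"`
#' uses the single first and last frames.
#'
#' @param traj a `cb_traj`.
#' @param window_frac fraction of frames per window.
#' @param mode `"window"` (default) or `"endpoints"`.
#' @return Drift in nm (signed).
#' @export
delta_rg <- function(traj, window_frac = 0.05, mode = c("window", "endpoints")) {
  mode <- match.arg(mode)
  nf <- n_frames(traj)
  if (nf < 2) stop("delta_rg needs at least 2 frames")
  rg <- rg_series(traj)
  w <- if (mode == "endpoints") 1L else max(1L, floor(nf * window_frac))
  mean(rg[(nf - w + 1):nf]) - mean(rg[1:w])
}

#' Inter-peptide twist angle
#'
#' The unsigned angle, in `[0, 180]` degrees, between the Ca(2)->Ca(6)
#' vectors of two peptides.
#'
#' @param frame a `cb_frame`.
#' @param i,j peptide ids (chain letters).
#' @return Angle in degrees.
#' @export
pair_twist <- function(frame, i, j) {
  v <- function(p) {
    i2 <- .sel_atoms(frame, peptide = p, resid = 2, atom = "CA")
    i6 <- .sel_atoms(frame, peptide = p, resid = 6, atom = "CA")
    if (length(i2) != 1 || length(i6) != 1)
      stop("peptide ", p, ": missing CA at residue 2 or 6")
    frame$xyz[i6, ] - frame$xyz[i2, ]
  }
  .vec_angle(v(i), v(j))
}

#' Registry distances between equivalent residues
#'
#' Ca-Ca distance between residue r of peptide `i` and residue r of
#' peptide `j`, for r = 1..7.
#'
#' @inheritParams pair_twist
#' @return Numeric vector of 7 distances (nm).
#' @export
registry_distances <- function(frame, i, j) {
  ca <- function(p) {
    idx <- .sel_atoms(frame, peptide = p, atom = "CA")
    if (length(idx) != 7) stop("peptide ", p, ": expected 7 CA atoms")
    frame$xyz[idx[order(frame$atoms$resid[idx])], , drop = FALSE]
  }
  sqrt(rowSums((ca(i) - ca(j))^2))
}

#' Distance between tyrosine ring planes
#'
#' Default construction: the symmetrized centroid-to-plane projection, the
#' mean of |(c_j - c_i) . n_i| and |(c_i - c_j) . n_j| where c is the ring
#' centroid and n the best-fit ring-plane normal.  `method = "centroid"`
#' gives the plain centroid-centroid distance.  Two rings count as stacked
#' when the distance is strictly below the stacking cutoff (0.5 nm).
#'
#' @inheritParams pair_twist
#' @param method `"plane"` or `"centroid"`.
#' @return Distance in nm.
#' @export
tyr_ring_distance <- function(frame, i, j, method = c("plane", "centroid")) {
  method <- match.arg(method)
  ring <- function(p) {
    idx <- .sel_atoms(frame, peptide = p, atom = .cb_ring_atoms)
    idx <- idx[frame$atoms$resname[idx] == "TYR"]
    if (length(idx) != 6) stop("peptide ", p, ": tyrosine ring atoms missing")
    frame$xyz[idx, , drop = FALSE]
  }
  ri <- ring(i); rj <- ring(j)
  ci <- colMeans(ri); cj <- colMeans(rj)
  if (method == "centroid") return(sqrt(sum((cj - ci)^2)))
  normal <- function(r, cen) svd(sweep(r, 2, cen))$v[, 3]
  (abs(sum((cj - ci) * normal(ri, ci))) +
   abs(sum((ci - cj) * normal(rj, cj)))) / 2
}

# ---- hydrogen bonds -------------------------------------------------------

#' Detect hydrogen bonds in a frame
#'
#' Geometric criterion on heavy atoms: donor-acceptor distance below the
#' cutoff (default 0.35 nm) and antecedent-donor-acceptor angle of at
#' least `hbond_angle` (default 90 degrees).  Donor/acceptor roles come
#' from the residue chemistry tables and the termini protonation state.
#' Pairs within one residue, and a backbone amide with the carbonyl oxygen
#' it is covalently adjacent to, are excluded.
#'
#' @param frame a `cb_frame` (with donor/acceptor annotations, as produced
#'   by the builder or trajectory reader).
#' @param config a [cb_config()].
#' @return A data.frame, one row per bond: atom indices (`donor`, `ante`,
#'   `acceptor`), donor/acceptor peptide, residue and atom name, `dist`
#'   (nm), `class` (`"bb-bb"`, `"sc-sc"`, `"mixed"`) and `span`
#'   (`"intra"`, `"inter"`).
#' @export
detect_hbonds <- function(frame, config = cb_config()) {
  a <- frame$atoms
  don <- which(a$donor)
  acc <- which(a$acceptor)
  empty <- data.frame(donor = integer(), ante = integer(), acceptor = integer(),
                      don_peptide = character(), don_resid = integer(),
                      don_atom = character(), acc_peptide = character(),
                      acc_resid = integer(), acc_atom = character(),
                      dist = numeric(), class = character(), span = character())
  if (!length(don) || !length(acc)) return(empty)
  d2 <- .dist2(frame$xyz[don, , drop = FALSE], frame$xyz[acc, , drop = FALSE])
  ok <- d2 <= config$hbond_dist^2
  # exclusions: same residue; backbone N with the preceding residue's O
  same_res <- outer(paste(a$peptide[don], a$resid[don]),
                    paste(a$peptide[acc], a$resid[acc]), "==")
  adj <- outer(seq_along(don), seq_along(acc), function(x, y) {
    dn <- don[x]; ac <- acc[y]
    a$atom[dn] == "N" & a$atom[ac] == "O" &
      a$peptide[dn] == a$peptide[ac] & a$resid[ac] == a$resid[dn] - 1L
  })
  ok <- ok & !same_res & !adj
  hits <- which(ok, arr.ind = TRUE)
  if (!nrow(hits)) return(empty)
  dn <- don[hits[, 1]]; ac <- acc[hits[, 2]]
  an <- a$ante[dn]
  u <- frame$xyz[an, , drop = FALSE] - frame$xyz[dn, , drop = FALSE]
  v <- frame$xyz[ac, , drop = FALSE] - frame$xyz[dn, , drop = FALSE]
  co <- rowSums(u * v) / sqrt(rowSums(u^2) * rowSums(v^2))
  keep <- co <= cos(.deg2rad(config$hbond_angle))
  if (!any(keep)) return(empty)
  dn <- dn[keep]; ac <- ac[keep]; an <- an[keep]
  out <- data.frame(
    donor = dn, ante = an, acceptor = ac,
    don_peptide = a$peptide[dn], don_resid = a$resid[dn],
    don_atom = a$atom[dn], acc_peptide = a$peptide[ac],
    acc_resid = a$resid[ac], acc_atom = a$atom[ac],
    dist = sqrt(d2[hits[keep, , drop = FALSE]]),
    class = ifelse(a$backbone[dn] & a$backbone[ac], "bb-bb",
                   ifelse(!a$backbone[dn] & !a$backbone[ac], "sc-sc", "mixed")),
    span = ifelse(a$peptide[dn] == a$peptide[ac], "intra", "inter"))
  rownames(out) <- NULL
  out
}

# ---- sheet assignment -----------------------------------------------------

#' Assign per-residue sheet state
#'
#' A residue is marked when it either participates directly in an
#' inter-peptide backbone-backbone hydrogen bond (amide donated or
#' carbonyl accepted) or sits on a parallel beta-bridge: residue `i` of
#' peptide `p` bridges residue `i` of peptide `q` when `N(q,i)` bonds
#' `O(p,i-1)` and `N(p,i+1)` bonds `O(q,i)` (either assignment of the
#' roles).  Marked residues in runs of at least two consecutive positions
#' are labelled `E`, the rest `C`.  This is the sheet-ladder test used
#' for sheet content and end fraying, not a full 8-state
#' secondary-structure assignment.
#'
#' @param frame a `cb_frame`.
#' @param hbonds optional precomputed [detect_hbonds()] table.
#' @param config a [cb_config()].
#' @param strict use the coordinated beta-bridge test alone, without the
#'   direct-participation marks.  Incidental backbone contacts in densely
#'   packed (amorphous) geometries satisfy the single-bond criterion but
#'   not the two-bond bridge pattern, so the strict form is the one used
#'   by the event triggers.
#' @return A data.frame with columns `peptide`, `resid`, `ss`.
#' @export
assign_sheet <- function(frame, hbonds = NULL, config = cb_config(),
                         strict = FALSE) {
  if (is.null(hbonds)) hbonds <- detect_hbonds(frame, config)
  hb <- hbonds[hbonds$class == "bb-bb" & hbonds$span == "inter", , drop = FALSE]
  peps <- peptide_ids(frame)
  bridged <- matrix(FALSE, length(peps), 7, dimnames = list(peps, NULL))
  if (nrow(hb)) {
    if (!strict) {
      # direct participation
      bridged[cbind(match(hb$don_peptide, peps), hb$don_resid)] <- TRUE
      bridged[cbind(match(hb$acc_peptide, peps), hb$acc_resid)] <- TRUE
    }
    # parallel beta-bridges: N(q,i)>O(p,i-1) and N(p,i+1)>O(q,i)
    bondset <- paste0(hb$don_peptide, hb$don_resid, ">",
                      hb$acc_peptide, hb$acc_resid)
    prs <- unique(rbind(cbind(hb$don_peptide, hb$acc_peptide),
                        cbind(hb$acc_peptide, hb$don_peptide)))
    for (h in seq_len(nrow(prs))) {
      p <- prs[h, 1]; q <- prs[h, 2]
      i <- 2:6
      hit <- i[paste0(q, i, ">", p, i - 1) %in% bondset &
               paste0(p, i + 1, ">", q, i) %in% bondset]
      if (length(hit)) {
        bridged[cbind(match(p, peps), hit)] <- TRUE
        bridged[cbind(match(q, peps), hit)] <- TRUE
      }
    }
  }
  ss <- matrix("C", length(peps), 7, dimnames = list(peps, NULL))
  for (p in peps) {
    r <- rle(bridged[p, ])
    ends <- cumsum(r$lengths)
    for (k in seq_along(r$values))
      if (r$values[k] && r$lengths[k] >= 2)
        ss[p, (ends[k] - r$lengths[k] + 1):ends[k]] <- "E"
  }
  data.frame(peptide = rep(peps, each = 7), resid = rep(1:7, length(peps)),
             ss = as.vector(t(ss)))
}

# number of sheet residues per peptide (named vector)
.sheet_content <- function(frame, hbonds = NULL, config = cb_config(),
                           strict = FALSE) {
  ss <- assign_sheet(frame, hbonds, config, strict)
  tapply(ss$ss == "E", ss$peptide, sum)[peptide_ids(frame)]
}

# ---- neighbor / edge machinery -------------------------------------------

# count inter-peptide backbone-backbone H-bonds per peptide pair;
# returns a named matrix indexed by peptide id
.bb_adjacency <- function(frame, hbonds, config) {
  peps <- peptide_ids(frame)
  m <- matrix(0L, length(peps), length(peps), dimnames = list(peps, peps))
  hb <- hbonds[hbonds$class == "bb-bb" & hbonds$span == "inter", , drop = FALSE]
  if (nrow(hb)) for (h in seq_len(nrow(hb))) {
    m[hb$don_peptide[h], hb$acc_peptide[h]] <-
      m[hb$don_peptide[h], hb$acc_peptide[h]] + 1L
    m[hb$acc_peptide[h], hb$don_peptide[h]] <-
      m[hb$acc_peptide[h], hb$don_peptide[h]] + 1L
  }
  m
}

# minimum heavy-atom distance between every peptide pair
.min_dist_matrix <- function(frame) {
  peps <- peptide_ids(frame)
  sel <- lapply(peps, function(p) .sel_atoms(frame, peptide = p))
  m <- matrix(Inf, length(peps), length(peps), dimnames = list(peps, peps))
  for (i in seq_along(peps)) for (j in seq_along(peps)) if (i < j) {
    d <- sqrt(min(.dist2(frame$xyz[sel[[i]], , drop = FALSE],
                         frame$xyz[sel[[j]], , drop = FALSE])))
    m[i, j] <- m[j, i] <- d
  }
  m
}

# connectivity: bonded (>= min_bb_hbonds bb-bb bonds) OR in contact
.connected_matrix <- function(frame, hbonds, config) {
  adj <- .bb_adjacency(frame, hbonds, config)
  mind <- .min_dist_matrix(frame)
  conn <- adj >= config$min_bb_hbonds | mind <= config$contact_cutoff
  diag(conn) <- FALSE
  conn
}

#' Classify a peptide as interior, edge or detached
#'
#' A peptide with two connected neighbors is `interior`; with none it is
#' `detached`.  For an edge peptide the two sheet edges are told apart by
#' which alternating face of side chains is left without an in-sheet
#' hydrogen-bond partner: when none of the residues 2, 4, 6 donate an
#' inter-peptide side-chain hydrogen bond while at least one of residues
#' 1, 3, 5, 7 does, the peptide is the `N-edge` (its 2/4/6 face hydrogen
#' bonds with solvent); otherwise it is the `C-edge`.
#'
#' @param frame a `cb_frame`.
#' @param peptide chain letter.
#' @param hbonds optional precomputed [detect_hbonds()] table.
#' @param config a [cb_config()].
#' @return One of `"interior"`, `"N-edge"`, `"C-edge"`, `"detached"`.
#' @export
classify_edge <- function(frame, peptide, hbonds = NULL, config = cb_config()) {
  if (!peptide %in% peptide_ids(frame)) stop("unknown peptide '", peptide, "'")
  if (is.null(hbonds)) hbonds <- detect_hbonds(frame, config)
  conn <- .connected_matrix(frame, hbonds, config)
  nn <- sum(conn[peptide, ])
  if (nn == 0) return("detached")
  if (nn >= 2) return("interior")
  donated <- hbonds$span == "inter" & hbonds$don_peptide == peptide &
    !hbonds$donor %in% which(frame$atoms$backbone)
  dres <- hbonds$don_resid[donated]
  even <- sum(dres %in% c(2, 4, 6))
  odd <- sum(dres %in% c(1, 3, 5, 7))
  if (even == 0 && odd > 0) "N-edge" else "C-edge"
}

# ---- aggregated observables ----------------------------------------------

#' Observables for one peptide pair
#'
#' @inheritParams pair_twist
#' @param hbonds optional precomputed [detect_hbonds()] table.
#' @param config a [cb_config()].
#' @return A list: `twist_deg`, `com_distance`, `registry` (7 distances),
#'   `bb_hbonds`, `sc_hbonds`, `tyr_plane_distance`, `stacked`,
#'   `orientation`.
#' @export
pair_observables <- function(frame, i, j, hbonds = NULL, config = cb_config()) {
  if (is.null(hbonds)) hbonds <- detect_hbonds(frame, config)
  inter <- hbonds[hbonds$span == "inter" &
                  ((hbonds$don_peptide == i & hbonds$acc_peptide == j) |
                   (hbonds$don_peptide == j & hbonds$acc_peptide == i)), ,
                  drop = FALSE]
  com <- function(p) {
    sel <- .sel_atoms(frame, peptide = p)
    m <- .atom_masses(frame)[sel]
    colSums(frame$xyz[sel, , drop = FALSE] * m) / sum(m)
  }
  twist <- pair_twist(frame, i, j)
  tyr <- tryCatch(tyr_ring_distance(frame, i, j, config$ring_method),
                  error = function(e) NA_real_)
  list(i = i, j = j,
       twist_deg = twist,
       com_distance = sqrt(sum((com(j) - com(i))^2)),
       registry = registry_distances(frame, i, j),
       bb_hbonds = sum(inter$class == "bb-bb"),
       sc_hbonds = sum(inter$class == "sc-sc"),
       tyr_plane_distance = tyr,
       stacked = !is.na(tyr) && tyr < config$stack_cutoff,
       orientation = pair_orientation(frame, i, j, config, twist = twist))
}

#' Tidy per-frame pair observables over a trajectory
#'
#' @param traj a `cb_traj`.
#' @param pairs `"adjacent"` (consecutive chain letters) or `"all"`.
#' @param config a [cb_config()].
#' @return A data.frame, one row per frame x pair, with twist, centre-of-
#'   mass distance, mean registry distance, hydrogen-bond counts, ring
#'   distance, stacking flag and orientation class.
#' @export
trajectory_observables <- function(traj, pairs = c("adjacent", "all"),
                                   config = cb_config()) {
  pairs <- match.arg(pairs)
  peps <- unique(traj$atoms$peptide)
  pr <- if (pairs == "adjacent") {
    if (length(peps) < 2) stop("need at least two peptides")
    cbind(peps[-length(peps)], peps[-1])
  } else t(utils::combn(peps, 2))
  out <- list()
  for (k in seq_len(n_frames(traj))) {
    fr <- frame_at(traj, k)
    hb <- detect_hbonds(fr, config)
    for (q in seq_len(nrow(pr))) {
      po <- pair_observables(fr, pr[q, 1], pr[q, 2], hb, config)
      out[[length(out) + 1L]] <- data.frame(
        frame = k - 1L, time = traj$times[k], i = po$i, j = po$j,
        twist_deg = po$twist_deg, com_distance = po$com_distance,
        mean_registry = mean(po$registry), bb_hbonds = po$bb_hbonds,
        sc_hbonds = po$sc_hbonds, tyr_plane_distance = po$tyr_plane_distance,
        stacked = po$stacked, orientation = po$orientation)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Time-averaged per-residue profiles
#'
#' Mean inter-peptide backbone-backbone and side-chain-side-chain
#' hydrogen-bond counts and sheet frequency per residue position,
#' averaged over frames and peptides.  With `exclude_edges = TRUE`
#' (default), peptides with fewer than two connected neighbors in a frame
#' are excluded from that frame's average, mirroring the convention of
#' reporting interior peptides only.
#'
#' @param traj a `cb_traj`.
#' @param exclude_edges drop edge/detached peptides from the averages.
#' @param config a [cb_config()].
#' @return A data.frame with columns `resid`, `bb_hbonds`, `sc_hbonds`,
#'   `sheet_freq`.  If no interior peptides exist the counts are `NaN` and
#'   the attribute `empty_interior` is set.
#' @export
residue_profiles <- function(traj, exclude_edges = TRUE, config = cb_config()) {
  peps <- unique(traj$atoms$peptide)
  bb <- sc <- ee <- matrix(0, 0, 7)
  for (k in seq_len(n_frames(traj))) {
    fr <- frame_at(traj, k)
    hb <- detect_hbonds(fr, config)
    use <- peps
    if (exclude_edges) {
      conn <- .connected_matrix(fr, hb, config)
      use <- peps[rowSums(conn) >= 2]
    }
    if (!length(use)) next
    ss <- assign_sheet(fr, hb, config)
    inter <- hb[hb$span == "inter", , drop = FALSE]
    cnt <- function(cls) {
      h <- inter[inter$class == cls, , drop = FALSE]
      t(vapply(use, function(p) vapply(1:7, function(r)
        sum((h$don_peptide == p & h$don_resid == r) |
            (h$acc_peptide == p & h$acc_resid == r)), numeric(1)),
        numeric(7)))
    }
    bb <- rbind(bb, cnt("bb-bb"))
    sc <- rbind(sc, cnt("sc-sc"))
    ee <- rbind(ee, t(vapply(use, function(p)
      as.numeric(ss$ss[ss$peptide == p] == "E"), numeric(7))))
  }
  out <- data.frame(resid = 1:7,
                    bb_hbonds = colMeans(bb), sc_hbonds = colMeans(sc),
                    sheet_freq = colMeans(ee))
  if (nrow(bb) == 0) {
    warning("no interior peptides; profiles undefined")
    attr(out, "empty_interior") <- TRUE
  }
  out
}
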