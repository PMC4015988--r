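# Synthetic trajectory generation: thermal positional noise plus scripted
# molecular events, so every downstream analysis stage is testable without
# running molecular dynamics.

.cb_event_types <- c("progressive_twist", "end_fray", "disorder",
                     "dissociation", "rearrangement", "disintegration",
                     "collapse")
.cb_displacement_types <- c("disorder", "dissociation", "rearrangement",
                            "disintegration", "collapse")

#' Schedule one scripted event
#'
#' @param type one of `"progressive_twist"`, `"end_fray"`, `"disorder"`,
#'   `"dissociation"`, `"rearrangement"`, `"disintegration"`,
#'   `"collapse"`.
#' @param peptides peptide ids the event acts on (`NULL` = all; a
#'   dissociation names exactly one peptide, a rearrangement exactly two).
#' @param start_frame,end_frame 0-based window over which the event's
#'   kinematic parameter is interpolated linearly (equal start and end
#'   give a step).
#' @param ... kinematic parameters: `twist_deg` (per-pair target for
#'   progressive twist), `residues`/`angle_deg` (end fray), `sigma_deg`
#'   (disorder backbone jitter), `distance`/`direction` (dissociation),
#'   `angle_deg`/`rotate` (rearrangement), `blocks`/`distance`
#'   (disintegration partition), `factor`/`max_rot_deg` (collapse).
#' @return A list of class `cb_event`.
#' @export
scheduled_event <- function(type, peptides = NULL, start_frame, end_frame = start_frame,
                            ...) {
  if (!type %in% .cb_event_types) stop("unknown event type '", type, "'")
  stopifnot(start_frame >= 0, end_frame >= start_frame)
  par <- list(...)
  if (type == "dissociation" && length(peptides) != 1)
    stop("dissociation names exactly one peptide")
  if (type == "rearrangement" && length(peptides) != 2)
    stop("rearrangement names exactly one pair of peptides")
  if (type == "disintegration") {
    if (is.null(par$blocks) || length(par$blocks) < 2 ||
        any(vapply(par$blocks, length, integer(1)) < 1))
      stop("disintegration needs a partition into >= 2 non-empty blocks")
    peptides <- unlist(par$blocks)
  }
  structure(list(type = type, peptides = peptides,
                 start_frame = as.integer(start_frame),
                 end_frame = as.integer(end_frame), par = par),
            class = "cb_event")
}

#' Assemble a scenario script
#'
#' @param n_frames number of frames.
#' @param frame_dt time between frames (ns).
#' @param noise_sigma per-atom thermal noise: the rms total displacement in
#'   nm (isotropic Gaussian about the scripted geometry, per-axis sd
#'   `noise_sigma / sqrt(3)`; each peptide's best-fit rigid component is
#'   removed so the scripted pose is the mean).
#' @param seed RNG seed; together with the script it fully determines the
#'   trajectory.
#' @param events list of [scheduled_event()]s.  Events are sorted by start
#'   frame; two displacement-type events that overlap in time on a shared
#'   peptide are rejected as contradictory.
#' @return A list of class `cb_script`.
#' @export
scenario_script <- function(n_frames = 100, frame_dt = 0.5,
                            noise_sigma = 0.01, seed = 1,
                            events = list()) {
  stopifnot(n_frames >= 1, frame_dt > 0, noise_sigma >= 0)
  for (ev in events) {
    stopifnot(inherits(ev, "cb_event"))
    if (ev$start_frame >= n_frames || ev$end_frame >= n_frames)
      stop("event window outside [0, n_frames)")
  }
  if (length(events) > 1) {
    ord <- order(vapply(events, function(e) e$start_frame, integer(1)))
    events <- events[ord]
    for (i in seq_along(events)) for (j in seq_along(events)) if (i < j) {
      a <- events[[i]]; b <- events[[j]]
      if (a$type %in% .cb_displacement_types &&
          b$type %in% .cb_displacement_types &&
          b$start_frame <= a$end_frame &&
          length(intersect(a$peptides, b$peptides)))
        stop("script conflict: overlapping '", a$type, "' and '", b$type,
             "' events on peptide(s) ",
             paste(intersect(a$peptides, b$peptides), collapse = ","))
    }
  }
  structure(list(n_frames = as.integer(n_frames), frame_dt = frame_dt,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 events = events),
            class = "cb_script")
}

#' @export
print.cb_script <- function(x, ...) {
  cat(sprintf("cb_script: %d frames x %g ns, noise %g nm, seed %d\n",
              x$n_frames, x$frame_dt, x$noise_sigma, x$seed))
  for (ev in x$events)
    cat(sprintf("  [%d,%d] %s (%s)\n", ev$start_frame, ev$end_frame,
                ev$type, paste(ev$peptides, collapse = ",")))
  invisible(x)
}

# ---- event kinematics -----------------------------------------------------

.pep_com <- function(xyz, atoms, masses, peptide) {
  sel <- atoms$peptide %in% peptide
  colSums(xyz[sel, , drop = FALSE] * masses[sel]) / sum(masses[sel])
}

# precompute per-event geometric constants and random draws from frame0
.prepare_events <- function(frame0, script) {
  atoms <- frame0$atoms
  masses <- .atom_masses(frame0)
  peps <- unique(atoms$peptide)
  coms <- t(vapply(peps, function(p) .pep_com(frame0$xyz, atoms, masses, p),
                   numeric(3)))
  agg_com <- colSums(frame0$xyz * masses) / sum(masses)
  # stacking axis: principal axis of the peptide COM spread
  if (length(peps) > 1) {
    sv <- svd(sweep(coms, 2, colMeans(coms)))
    stack_axis <- sv$v[, 1]
    if (sum(stack_axis * (coms[nrow(coms), ] - coms[1, ])) < 0)
      stack_axis <- -stack_axis
  } else stack_axis <- c(0, 1, 0)

  lapply(script$events, function(ev) {
    pre <- list(ev = ev)
    ids <- if (is.null(ev$peptides)) peps else ev$peptides
    if (!all(ids %in% peps))
      stop("event names unknown peptide(s): ",
           paste(setdiff(ids, peps), collapse = ","))
    pre$ids <- ids
    if (ev$type == "progressive_twist") {
      pre$axis <- stack_axis; pre$center <- colMeans(coms)
      pre$twist <- if (is.null(ev$par$twist_deg)) 15 else ev$par$twist_deg
    } else if (ev$type == "end_fray") {
      pre$residues <- if (is.null(ev$par$residues)) 1L else sort(ev$par$residues)
      pre$angle <- if (is.null(ev$par$angle_deg)) 45 else ev$par$angle_deg
      if (!(all(diff(pre$residues) == 1) &&
            (pre$residues[1] == 1 || pre$residues[length(pre$residues)] == 7)))
        stop("end_fray residues must be a terminal run")
    } else if (ev$type == "disorder") {
      sg <- if (is.null(ev$par$sigma_deg)) 25 else ev$par$sigma_deg
      pre$jitter <- lapply(ids, function(p) matrix(stats::rnorm(14, 0, sg), 7, 2))
      names(pre$jitter) <- ids
      pre$com0 <- lapply(ids, function(p) .pep_com(frame0$xyz, atoms, masses, p))
      names(pre$com0) <- ids
    } else if (ev$type == "dissociation") {
      pre$distance <- if (is.null(ev$par$distance)) 2.0 else ev$par$distance
      if (!is.null(ev$par$direction)) pre$dir <- .unit(ev$par$direction)
      else {
        rest <- setdiff(peps, ids)
        v <- coms[match(ids, peps), ] -
          (if (length(rest)) colMeans(coms[match(rest, peps), , drop = FALSE])
           else agg_com)
        pre$dir <- if (sqrt(sum(v^2)) > 1e-9) .unit(v) else c(0, 1, 0)
      }
    } else if (ev$type == "rearrangement") {
      rot <- if (is.null(ev$par$rotate)) ids[1] else ev$par$rotate
      pre$rotate <- rot
      pre$angle <- if (is.null(ev$par$angle_deg)) 180 else ev$par$angle_deg
      i2 <- which(atoms$peptide == rot & atoms$resid == 2 & atoms$atom == "CA")
      i6 <- which(atoms$peptide == rot & atoms$resid == 6 & atoms$atom == "CA")
      strand_axis <- .unit(frame0$xyz[i6, ] - frame0$xyz[i2, ])
      # flip about the sheet-plane normal so the strand direction reverses
      nrm <- .cross3(strand_axis, stack_axis)
      pre$axis <- if (sqrt(sum(nrm^2)) > 1e-6) .unit(nrm) else c(0, 0, 1)
      pre$center <- .pep_com(frame0$xyz, atoms, masses, rot)
    } else if (ev$type == "disintegration") {
      pre$blocks <- ev$par$blocks
      pre$distance <- if (is.null(ev$par$distance)) 2.0 else ev$par$distance
      pre$dirs <- lapply(seq_along(pre$blocks), function(b) {
        if (b == 1) return(c(0, 0, 0))
        rest <- setdiff(peps, pre$blocks[[b]])
        v <- .pep_com(frame0$xyz, atoms, masses, pre$blocks[[b]]) -
          .pep_com(frame0$xyz, atoms, masses, rest)
        if (sqrt(sum(v^2)) > 1e-9) .unit(v) else c(0, 1, 0) * (b - 1)
      })
    } else if (ev$type == "collapse") {
      pre$factor <- if (is.null(ev$par$factor)) 0.7 else ev$par$factor
      maxrot <- if (is.null(ev$par$max_rot_deg)) 90 else ev$par$max_rot_deg
      pre$center <- agg_com
      pre$rots <- lapply(ids, function(p) {
        ax <- stats::rnorm(3); ax <- .unit(ax)
        list(axis = ax, angle = stats::runif(1, 0.5, 1) * maxrot)
      })
      names(pre$rots) <- ids
    }
    pre
  })
}

# apply one prepared event at progress alpha in [0, 1]
.apply_event <- function(xyz, atoms, masses, pre, alpha) {
  ev <- pre$ev
  if (alpha <= 0) return(xyz)
  if (ev$type == "progressive_twist") {
    for (k in seq_along(pre$ids)) {
      if (k == 1) next
      sel <- atoms$peptide == pre$ids[k]
      R <- .rotmat(pre$axis, (k - 1) * pre$twist * alpha)
      xyz[sel, ] <- .transform_xyz(xyz[sel, , drop = FALSE], R,
                                   center = pre$center)
    }
  } else if (ev$type == "end_fray") {
    nterm <- pre$residues[1] == 1
    hinge_res <- if (nterm) max(pre$residues) + 1L else min(pre$residues) - 1L
    for (p in pre$ids) {
      h <- which(atoms$peptide == p & atoms$resid == hinge_res &
                   atoms$atom == "CA")
      sel <- atoms$peptide == p & atoms$resid %in% pre$residues
      R <- .rotmat(c(0, 0, 1), pre$angle * alpha * (if (nterm) 1 else -1))
      xyz[sel, ] <- .transform_xyz(xyz[sel, , drop = FALSE], R,
                                   center = xyz[h, ])
    }
  } else if (ev$type == "disorder") {
    for (p in pre$ids)
      xyz <- .apply_disorder(xyz, atoms, masses, p, pre$jitter[[p]],
                             pre$com0[[p]], alpha)
  } else if (ev$type == "dissociation") {
    sel <- atoms$peptide %in% pre$ids
    xyz[sel, ] <- sweep(xyz[sel, , drop = FALSE], 2,
                        pre$dir * pre$distance * alpha, "+")
  } else if (ev$type == "rearrangement") {
    sel <- atoms$peptide == pre$rotate
    R <- .rotmat(pre$axis, pre$angle * alpha)
    xyz[sel, ] <- .transform_xyz(xyz[sel, , drop = FALSE], R,
                                 center = pre$center)
  } else if (ev$type == "disintegration") {
    for (b in seq_along(pre$blocks)) {
      if (b == 1) next
      sel <- atoms$peptide %in% pre$blocks[[b]]
      xyz[sel, ] <- sweep(xyz[sel, , drop = FALSE], 2,
                          pre$dirs[[b]] * pre$distance * alpha, "+")
    }
  } else if (ev$type == "collapse") {
    s <- 1 + alpha * (pre$factor - 1)
    for (p in pre$ids) {
      sel <- atoms$peptide == p
      com <- .pep_com(xyz, atoms, masses, p)
      newcom <- pre$center + s * (com - pre$center)
      R <- .rotmat(pre$rots[[p]]$axis, pre$rots[[p]]$angle * alpha)
      xyz[sel, ] <- .transform_xyz(xyz[sel, , drop = FALSE], R,
                                   t = newcom - com, center = com)
    }
  }
  xyz
}

# backbone dihedral jitter of one peptide: phi/psi rotations scaled by
# alpha, centre of mass pinned to com0
.apply_disorder <- function(xyz, atoms, masses, p, jitter, com0, alpha) {
  psel <- which(atoms$peptide == p)
  a <- atoms[psel, ]
  x <- xyz[psel, , drop = FALSE]
  idx <- function(r, nm) which(a$resid == r & a$atom == nm)
  for (r in 2:7) {       # phi: rotate C-ward atoms about N(r)->CA(r)
    ang <- jitter[r, 1] * alpha
    if (abs(ang) < 1e-9) next
    n <- x[idx(r, "N"), ]; ca <- x[idx(r, "CA"), ]
    mv <- a$resid > r | (a$resid == r & a$atom %in% c("C", "O", "OXT"))
    x[mv, ] <- .transform_xyz(x[mv, , drop = FALSE], .rotmat(ca - n, ang),
                              center = ca)
  }
  for (r in 1:6) {       # psi: rotate about CA(r)->C(r)
    ang <- jitter[r, 2] * alpha
    if (abs(ang) < 1e-9) next
    ca <- x[idx(r, "CA"), ]; cc <- x[idx(r, "C"), ]
    mv <- a$resid > r | (a$resid == r & a$atom %in% c("O", "OXT"))
    x[mv, ] <- .transform_xyz(x[mv, , drop = FALSE], .rotmat(cc - ca, ang),
                              center = cc)
  }
  m <- masses[psel]
  com <- colSums(x * m) / sum(m)
  x <- sweep(x, 2, com0 - com, "+")
  xyz[psel, ] <- x
  xyz
}

# remove each peptide's best-fit rigid (translation + infinitesimal
# rotation) component from a noise displacement field
.rigid_filter <- function(noise, xyz, atoms, peps) {
  for (p in peps) {
    sel <- atoms$peptide == p
    d <- noise[sel, , drop = FALSE]
    d <- sweep(d, 2, colMeans(d))
    r <- sweep(xyz[sel, , drop = FALSE], 2, colMeans(xyz[sel, , drop = FALSE]))
    A <- sum(rowSums(r^2)) * diag(3) - crossprod(r)
    b <- colSums(cbind(r[, 2] * d[, 3] - r[, 3] * d[, 2],
                       r[, 3] * d[, 1] - r[, 1] * d[, 3],
                       r[, 1] * d[, 2] - r[, 2] * d[, 1]))
    om <- tryCatch(solve(A, b), error = function(e) c(0, 0, 0))
    d <- d - cbind(om[2] * r[, 3] - om[3] * r[, 2],
                   om[3] * r[, 1] - om[1] * r[, 3],
                   om[1] * r[, 2] - om[2] * r[, 1])
    noise[sel, ] <- d
  }
  noise
}

#' Generate a synthetic trajectory
#'
#' Frame `t` is the starting frame with every scheduled event applied at
#' linear progress `(t - start) / (end - start)` (clamped to `[0, 1]`),
#' plus isotropic Gaussian positional noise about the scripted geometry.
#' The noise is rigid-body-filtered per peptide, so the scripted pose is
#' the per-frame mean and centres of mass never drift.  Output is fully
#' determined by `(frame0, script)` including the script's seed.
#'
#' @param frame0 starting `cb_frame` (e.g. from [build_sheet()]).
#' @param script a [scenario_script()].
#' @return A `cb_traj` of `n_frames` frames at `frame_dt` spacing.
#' @examples
#' sheet <- build_sheet(peptide_spec(mutant = "N2S", termini = "neutral"),
#'                      aggregate_spec(5))
#' sc <- scenario_script(n_frames = 10, noise_sigma = 0, seed = 1)
#' traj <- generate_trajectory(sheet, sc)
#' @export
generate_trajectory <- function(frame0, script) {
  stopifnot(inherits(frame0, "cb_frame"), inherits(script, "cb_script"))
  atoms <- frame0$atoms
  masses <- .atom_masses(frame0)
  peps <- unique(atoms$peptide)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(script$seed)

  prepared <- .prepare_events(frame0, script)
  sd_axis <- script$noise_sigma / sqrt(3)
  frames <- vector("list", script$n_frames)
  for (t in seq_len(script$n_frames) - 1L) {
    xyz <- frame0$xyz
    for (pre in prepared) {
      ev <- pre$ev
      if (t < ev$start_frame) next
      alpha <- if (ev$end_frame == ev$start_frame) 1
               else min(1, (t - ev$start_frame) / (ev$end_frame - ev$start_frame))
      xyz <- .apply_event(xyz, atoms, masses, pre, alpha)
    }
    if (script$noise_sigma > 0) {
      noise <- matrix(stats::rnorm(length(xyz), 0, sd_axis), ncol = 3)
      noise <- .rigid_filter(noise, xyz, atoms, peps)
      xyz <- xyz + noise
    }
    frames[[t + 1L]] <- cb_frame(atoms, xyz, time = t * script$frame_dt,
                                 termini = frame0$termini)
  }
  cb_trajectory(frames, frame_dt = script$frame_dt,
                provenance = list(seed = script$seed,
                                  n_frames = script$n_frames,
                                  noise_sigma = script$noise_sigma,
                                  events = vapply(script$events,
                                                  function(e) e$type,
                                                  character(1))))
}

#' Named preset scenarios
#'
#' Ready-made scripts that exhibit the event taxonomy on a built sheet:
#'
#' * `stable_twisted` — the sheet develops a 15 degree-per-pair twist and
#'   stays intact;
#' * `end_fraying` — the N-terminal glycine of every strand frays while
#'   the core stays in sheet;
#' * `edge_dissociation` — the last strand leaves the sheet (2 nm);
#' * `antiparallel_rearrangement` — the first strand flips 180 degrees
#'   about its own axis, turning the first pair antiparallel;
#' * `disintegration_4_2` — the sheet splits abruptly into an (n-2)-mer
#'   and a 2-mer;
#' * `collapse_amorphous` — strand centres contract towards the aggregate
#'   centre (factor 0.7) with randomized orientations;
#' * `edge_disorder` — the last strand loses its backbone conformation
#'   (25 degree phi/psi jitter) without leaving the aggregate.
#'
#' Each script carries an `expected` attribute with the verdict and key
#' event it is constructed to produce.
#'
#' @param n_peptides sheet size the scripts address (chain letters A..).
#' @param n_frames,frame_dt,noise_sigma,seed passed to [scenario_script()].
#' @return Named list of `cb_script` objects.
#' @export
preset_scenarios <- function(n_peptides = 6, n_frames = 100, frame_dt = 0.5,
                             noise_sigma = 0, seed = 1) {
  ids <- LETTERS[seq_len(n_peptides)]
  last <- ids[n_peptides]
  mk <- function(events, verdict, key_event) {
    sc <- scenario_script(n_frames = n_frames, frame_dt = frame_dt,
                          noise_sigma = noise_sigma, seed = seed,
                          events = events)
    attr(sc, "expected") <- list(verdict = verdict, key_event = key_event)
    sc
  }
  at <- function(f) as.integer(round(f * n_frames))  # scale windows
  list(
    stable_twisted = mk(list(
      scheduled_event("progressive_twist", ids, at(0.1), at(0.6),
                      twist_deg = 15)), "stable", "none"),
    end_fraying = mk(list(
      scheduled_event("end_fray", ids, at(0.2), at(0.8),
                      residues = 1L, angle_deg = 45)), "stable", "none"),
    edge_dissociation = mk(list(
      scheduled_event("dissociation", last, at(0.4), at(0.6),
                      distance = 2.0)), "unstable", "dissociation"),
    antiparallel_rearrangement = mk(list(
      scheduled_event("rearrangement", c("A", "B"), at(0.3), at(0.5),
                      rotate = "A", angle_deg = 180)),
      "unstable", "rearrangement"),
    disintegration_4_2 = mk(list(
      scheduled_event("disintegration", start_frame = at(0.5),
                      blocks = list(ids[seq_len(n_peptides - 2)],
                                    ids[c(n_peptides - 1, n_peptides)]),
                      distance = 2.0)), "unstable", "disintegration"),
    collapse_amorphous = mk(list(
      scheduled_event("collapse", ids, at(0.3), at(0.7),
                      factor = 0.7, max_rot_deg = 90)),
      "unstable", "collapse"),
    edge_disorder = mk(list(
      scheduled_event("disorder", last, at(0.3), at(0.6),
                      sigma_deg = 50)), "unstable", "disorder")
  )
}
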