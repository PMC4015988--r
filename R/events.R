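# Event layer: connectivity clusters, orientation classes, event
# detection, stability verdict and the ordered-oligomer census.

#' Orientation class of a peptide pair
#'
#' Classed from the pair twist: parallel below
#' `orient_parallel_max` (50 degrees), antiparallel above
#' `orient_antiparallel_min` (130 degrees), crossed in between.
#'
#' @inheritParams pair_twist
#' @param config a [cb_config()].
#' @param twist optional precomputed twist (degrees).
#' @return `"parallel"`, `"crossed"` or `"antiparallel"`.
#' @export
pair_orientation <- function(frame, i, j, config = cb_config(), twist = NULL) {
  if (is.null(twist)) twist <- pair_twist(frame, i, j)
  if (twist < config$orient_parallel_max) "parallel"
  else if (twist > config$orient_antiparallel_min) "antiparallel"
  else "crossed"
}

#' Partition peptides into connectivity clusters
#'
#' Two peptides are connected when they share at least `min_bb_hbonds`
#' inter-peptide backbone-backbone hydrogen bonds or their minimum
#' heavy-atom distance is at most `contact_cutoff`.  The partition is the
#' connected components of that graph.
#'
#' @param frame a `cb_frame`.
#' @param hbonds optional precomputed [detect_hbonds()] table.
#' @param config a [cb_config()].
#' @return A list of character vectors (sorted member ids); clusters
#'   ordered by decreasing size, ties by first member.
#' @export
cluster_peptides <- function(frame, hbonds = NULL, config = cb_config()) {
  if (is.null(hbonds)) hbonds <- detect_hbonds(frame, config)
  conn <- .connected_matrix(frame, hbonds, config)
  .components(conn)
}

# connected components of a logical adjacency matrix (union-find)
.components <- function(conn) {
  peps <- rownames(conn)
  parent <- seq_along(peps)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(peps)) for (j in seq_along(peps))
    if (i < j && conn[i, j]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  roots <- vapply(seq_along(peps), find, integer(1))
  comp <- unname(split(peps, roots))
  comp <- lapply(comp, sort)
  comp[order(-vapply(comp, length, integer(1)),
             vapply(comp, function(x) x[1], character(1)))]
}

# registry offset between peptides: the shift (in residues) minimizing the
# mean Ca-Ca distance over the overlapping positions
.registry_offset <- function(frame, i, j, shifts = -3:3) {
  ca <- function(p) {
    idx <- .sel_atoms(frame, peptide = p, atom = "CA")
    frame$xyz[idx[order(frame$atoms$resid[idx])], , drop = FALSE]
  }
  ci <- ca(i); cj <- ca(j)
  best_s <- 0L; best_d <- Inf
  for (s in shifts) {
    r <- which(1:7 + s >= 1 & 1:7 + s <= 7)
    if (length(r) < 4) next
    d <- mean(sqrt(rowSums((ci[r, , drop = FALSE] -
                            cj[r + s, , drop = FALSE])^2)))
    if (d < best_d) { best_d <- d; best_s <- as.integer(s) }
  }
  best_s
}

#' Precompute the per-frame quantities used by the event layer
#'
#' Runs hydrogen-bond detection, clustering, sheet assignment, Rg and the
#' orientation/registry state of initially adjacent pairs over every
#' frame.  [detect_events()], [stability_verdict()] and
#' [oligomer_census()] accept the result to avoid recomputation.
#'
#' @param traj a `cb_traj`.
#' @param config a [cb_config()].
#' @return A list of class `cb_analysis`.
#' @export
analyze_trajectory <- function(traj, config = cb_config()) {
  nf <- n_frames(traj)
  peps <- unique(traj$atoms$peptide)
  partitions <- vector("list", nf)
  sheet <- matrix(0L, length(peps), nf, dimnames = list(peps, NULL))
  rg <- numeric(nf)
  fr1 <- frame_at(traj, 1)
  hb1 <- detect_hbonds(fr1, config)
  adj1 <- .bb_adjacency(fr1, hb1, config) >= config$min_bb_hbonds
  init_pairs <- which(adj1 & upper.tri(adj1), arr.ind = TRUE)
  pair_ids <- cbind(peps[init_pairs[, 1]], peps[init_pairs[, 2]])
  np <- nrow(pair_ids)
  orient <- matrix(NA_character_, np, nf)
  regoff <- matrix(NA_integer_, np, nf)
  extended <- matrix(TRUE, length(peps), nf, dimnames = list(peps, NULL))
  for (k in seq_len(nf)) {
    fr <- frame_at(traj, k)
    hb <- detect_hbonds(fr, config)
    partitions[[k]] <- cluster_peptides(fr, hb, config)
    sheet[, k] <- .sheet_content(fr, hb, config, strict = TRUE)
    rg[k] <- radius_of_gyration(fr)
    for (p in peps) {
      i1 <- .sel_atoms(fr, peptide = p, resid = 1, atom = "CA")
      i7 <- .sel_atoms(fr, peptide = p, resid = 7, atom = "CA")
      # peptides without a full backbone cannot be assessed; treat as intact
      extended[p, k] <- length(i1) != 1 || length(i7) != 1 ||
        sqrt(sum((fr$xyz[i7, ] - fr$xyz[i1, ])^2)) >= config$extended_min
    }
    for (q in seq_len(np)) {
      orient[q, k] <- pair_orientation(fr, pair_ids[q, 1], pair_ids[q, 2], config)
      regoff[q, k] <- .registry_offset(fr, pair_ids[q, 1], pair_ids[q, 2])
    }
  }
  structure(list(peptides = peps, partitions = partitions, sheet = sheet,
                 extended = extended, rg = rg, pair_ids = pair_ids,
                 orient = orient, regoff = regoff, times = traj$times,
                 dt = .traj_dt(traj)),
            class = "cb_analysis")
}

# cluster (within a partition) containing peptide p, or NULL
.cluster_of <- function(partition, p) {
  for (cl in partition) if (p %in% cl) return(cl)
  NULL
}

# main-cluster series: largest cluster at frame 1, then max member overlap
# (ties: smallest lexicographic member set)
.main_series <- function(partitions) {
  pick <- function(cands, ref) {
    ov <- vapply(cands, function(cl) length(intersect(cl, ref)), integer(1))
    best <- which(ov == max(ov))
    if (length(best) > 1) {
      keys <- vapply(cands[best], function(cl) paste(cl, collapse = ""),
                     character(1))
      best <- best[order(keys)][1]
    }
    cands[[best[1]]]
  }
  main <- vector("list", length(partitions))
  sizes <- vapply(partitions[[1]], length, integer(1))
  main[[1]] <- pick(partitions[[1]][sizes == max(sizes)], partitions[[1]][[1]])
  for (t in seq_along(partitions)[-1])
    main[[t]] <- pick(partitions[[t]], main[[t - 1]])
  main
}

#' Detect molecular events in a trajectory
#'
#' Scans the per-frame cluster, sheet and orientation state for the five
#' event types, each required to persist for `persistence` consecutive
#' frames:
#'
#' * **dissociation** — a single peptide leaves the main cluster;
#' * **disintegration** — the main cluster splits into two or more blocks
#'   of at least two peptides;
#' * **rearrangement** — an initially adjacent pair of still-extended
#'   strands changes orientation class or shifts register by one or more
#'   residues while staying in one cluster (orientation changes of
#'   conformationally disordered peptides are scored as disorder, not
#'   rearrangement);
#' * **disorder** — an in-cluster peptide crumples: its sheet content
#'   drops below two residues and it loses its extended-strand geometry,
#'   while the rest of the cluster stays ordered (mean sheet content at
#'   least half its initial value).  A disorder record vetoes
#'   rearrangement records involving the same peptide;
#' * **collapse** — the aggregate Rg falls at least `delta_rg_cutoff`
#'   below its initial value while mean sheet content drops below half its
#'   initial value.  A collapse subsumes rearrangement/disorder records
#'   with onsets from `2 * persistence` frames before its own onset.
#'
#' @param traj a `cb_traj`.
#' @param config a [cb_config()].
#' @param analysis optional [analyze_trajectory()] result.
#' @return A data.frame, one row per event: `type`, `onset_frame`
#'   (0-based), `onset_ns`, `peptides` (comma-separated), `evidence`;
#'   ordered by onset (ties broken from aggregate-level to
#'   peptide-level: collapse, disintegration, dissociation,
#'   rearrangement, disorder).
#' @export
detect_events <- function(traj, config = cb_config(), analysis = NULL) {
  if (is.null(analysis)) analysis <- analyze_trajectory(traj, config)
  an <- analysis
  nf <- length(an$partitions)
  w <- config$persistence
  main <- .main_series(an$partitions)
  recs <- list()
  add <- function(type, onset, peptides, evidence)
    recs[[length(recs) + 1L]] <<- data.frame(
      type = type, onset_frame = onset - 1L,
      onset_ns = an$times[onset], peptides = paste(peptides, collapse = ","),
      evidence = evidence)

  # --- splits of the main cluster (dissociation / disintegration)
  reported <- character()
  for (t in seq_len(nf)[-1]) {
    departed <- setdiff(main[[t - 1]], main[[t]])
    departed <- setdiff(departed, reported)
    if (!length(departed)) next
    horizon <- t:min(t + w - 1L, nf)
    sustained <- all(vapply(horizon, function(tt)
      !any(departed %in% main[[tt]]), logical(1))) &&
      length(horizon) == w
    if (!sustained) next
    blocks <- Filter(length, lapply(an$partitions[[t]], intersect,
                                    y = main[[t - 1]]))
    big <- vapply(blocks, length, integer(1)) >= 2
    if (sum(big) >= 2) {
      add("disintegration", t, main[[t - 1]],
          paste0("split ", paste(vapply(blocks, length, integer(1)),
                                 collapse = "+")))
      reported <- union(reported, departed)
    } else {
      for (p in departed) {
        cl <- .cluster_of(an$partitions[[t]], p)
        if (length(cl) == 1) {
          add("dissociation", t, p, "singleton left main cluster")
          reported <- union(reported, p)
        }
      }
    }
  }

  # --- rearrangement of initially adjacent pairs
  if (nrow(an$pair_ids)) for (q in seq_len(nrow(an$pair_ids))) {
    i <- an$pair_ids[q, 1]; j <- an$pair_ids[q, 2]
    cond <- vapply(seq_len(nf), function(t) {
      cl <- .cluster_of(an$partitions[[t]], i)
      (an$orient[q, t] != an$orient[q, 1] ||
         abs(an$regoff[q, t] - an$regoff[q, 1]) >= 1) &&
        an$extended[i, t] && an$extended[j, t] &&   # intact strands only
        !is.null(cl) && j %in% cl
    }, logical(1))
    onset <- .first_sustained(cond, w)
    if (!is.na(onset))
      add("rearrangement", onset, c(i, j),
          paste0(an$orient[q, 1], "->", an$orient[q, onset],
                 "; register ", an$regoff[q, 1], "->", an$regoff[q, onset]))
  }

  # --- disorder: a peptide crumples (loses extension and sheet) while the
  #     rest of the cluster stays ordered
  sheet0 <- mean(an$sheet[main[[1]], 1])
  disordered_peps <- character()
  for (p in an$peptides) {
    cond <- vapply(seq_len(nf), function(t) {
      if (!p %in% main[[t]]) return(FALSE)
      others <- setdiff(main[[t]], p)
      an$sheet[p, t] < 2 && !an$extended[p, t] && length(others) > 0 &&
        mean(an$sheet[others, t]) >= 0.5 * sheet0
    }, logical(1))
    onset <- .first_sustained(cond, w)
    if (!is.na(onset)) {
      add("disorder", onset, p,
          sprintf("sheet content %d residues", an$sheet[p, onset]))
      disordered_peps <- union(disordered_peps, p)
    }
  }

  # --- collapse (aggregate contraction with global sheet loss)
  wlen <- max(1L, floor(nf * config$window_frac))
  rg0 <- mean(an$rg[seq_len(wlen)])
  msheet0 <- mean(an$sheet[, 1])
  cond <- (an$rg - rg0 <= -config$delta_rg_cutoff) &
    (colMeans(an$sheet) < 0.5 * msheet0)
  onset <- .first_sustained(cond, w)
  if (!is.na(onset))
    add("collapse", onset, an$peptides,
        sprintf("Rg drift %.3f nm, mean sheet %.1f of %.1f residues",
                an$rg[onset] - rg0, mean(an$sheet[, onset]), msheet0))

  if (!length(recs))
    return(data.frame(type = character(), onset_frame = integer(),
                      onset_ns = numeric(), peptides = character(),
                      evidence = character()))
  ev <- do.call(rbind, recs)
  # a crumpling peptide transits a bent-but-extended phase that can read as
  # an orientation change; its disorder record explains and vetoes
  # rearrangement records it is part of
  if (length(disordered_peps)) {
    in_pair <- vapply(strsplit(ev$peptides, ","), function(pp)
      any(pp %in% disordered_peps), logical(1))
    ev <- ev[!(ev$type == "rearrangement" & in_pair), , drop = FALSE]
  }
  # collapse subsumes peptide-level records from the onset of the global
  # contraction that culminated in it
  if (any(ev$type == "collapse")) {
    tc <- min(ev$onset_frame[ev$type == "collapse"])
    decline <- which(an$rg - rg0 <= -0.25 * config$delta_rg_cutoff)
    t0 <- if (length(decline)) decline[1] - 1L else tc
    drop <- ev$type %in% c("rearrangement", "disorder") &
      ev$onset_frame >= min(t0, tc) - 2L * w
    ev <- ev[!drop, , drop = FALSE]
  }
  sev <- c(collapse = 1, disintegration = 2, dissociation = 3,
           rearrangement = 4, disorder = 5)
  ev <- ev[order(ev$onset_frame, sev[ev$type]), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

# first index at which cond holds for w consecutive elements (NA if never)
.first_sustained <- function(cond, w) {
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  k <- which(r$values & r$lengths >= w)
  if (!length(k)) return(NA_integer_)
  ends[k[1]] - r$lengths[k[1]] + 1L
}

#' Stability verdict for a trajectory
#'
#' An aggregate is stable when it retains its initial organization to the
#' end: the Rg drift stays strictly below `delta_rg_cutoff` in magnitude,
#' no sustained molecular event of any type is detected, and no peptide
#' ends detached from the aggregate.  Otherwise the verdict is unstable
#' and the key event is the first detected event.
#'
#' @param traj a `cb_traj`.
#' @param config a [cb_config()].
#' @param events optional precomputed [detect_events()] table.
#' @param analysis optional [analyze_trajectory()] result.
#' @return A list of class `cb_verdict`: `verdict`, `key_event`,
#'   `delta_rg`, `detached`, `events`.
#' @export
stability_verdict <- function(traj, config = cb_config(), events = NULL,
                              analysis = NULL) {
  if (is.null(analysis)) analysis <- analyze_trajectory(traj, config)
  if (is.null(events)) events <- detect_events(traj, config, analysis)
  nf <- length(analysis$partitions)
  wlen <- max(1L, floor(nf * config$window_frac))
  rg <- analysis$rg
  drg <- mean(rg[(nf - wlen + 1):nf]) - mean(rg[seq_len(wlen)])
  detached <- length(analysis$partitions[[nf]]) > 1
  stable <- abs(drg) < config$delta_rg_cutoff && nrow(events) == 0 && !detached
  out <- list(verdict = if (stable) "stable" else "unstable",
              key_event = if (stable || nrow(events) == 0) "none"
                          else events$type[1],
              delta_rg = drg, detached = detached, events = events)
  class(out) <- "cb_verdict"
  out
}

#' @export
print.cb_verdict <- function(x, ...) {
  cat(sprintf("verdict: %s (dRg = %+.3f nm%s)\n", x$verdict, x$delta_rg,
              if (x$detached) ", peptide(s) detached" else ""))
  if (nrow(x$events)) {
    cat("key event:", x$key_event, "\n")
    print(x$events[, c("type", "onset_frame", "onset_ns", "peptides")])
  }
  invisible(x)
}

#' Census of ordered sub-oligomers
#'
#' Tracks every cluster of two or more peptides whose membership persists
#' over frames; a cluster's record survives interruptions shorter than the
#' persistence window.  Lifetime is `(death - birth) x frame_dt`, with
#' `death = n_frames` for clusters alive at the last frame.  At the
#' record's mid-life frame the internal pair orientations and mean sheet
#' content are summarised; a cluster is `ordered` when its members keep at
#' least half their residues in sheet conformation.
#'
#' @param traj a `cb_traj`.
#' @param config a [cb_config()].
#' @param analysis optional [analyze_trajectory()] result.
#' @return A data.frame, one row per tracked oligomer: `members`, `size`,
#'   `birth_frame`, `death_frame` (0-based), `lifetime_ns`,
#'   `mean_sheet_frac`, `ordered`, `arrangement`.
#' @export
oligomer_census <- function(traj, config = cb_config(), analysis = NULL) {
  if (is.null(analysis)) analysis <- analyze_trajectory(traj, config)
  nf <- length(analysis$partitions)
  w <- config$persistence
  keyof <- function(cl) paste(cl, collapse = ",")
  active <- list()   # key -> list(members, birth, absent_since)
  closed <- list()
  for (t in seq_len(nf)) {
    keys <- vapply(Filter(function(cl) length(cl) >= 2,
                          analysis$partitions[[t]]), keyof, character(1))
    for (key in keys) {
      if (!is.null(active[[key]])) {
        active[[key]]$absent_since <- NA_integer_
      } else {
        active[[key]] <- list(members = strsplit(key, ",")[[1]],
                              birth = t - 1L, absent_since = NA_integer_)
      }
    }
    for (key in names(active)) {
      if (key %in% keys) next
      if (is.na(active[[key]]$absent_since)) {
        active[[key]]$absent_since <- t - 1L
      } else if (t - 1L - active[[key]]$absent_since + 1L >= w) {
        rec <- active[[key]]
        closed[[length(closed) + 1L]] <-
          list(members = rec$members, birth = rec$birth,
               death = rec$absent_since)
        active[[key]] <- NULL
      }
    }
  }
  for (key in names(active)) {
    rec <- active[[key]]
    closed[[length(closed) + 1L]] <-
      list(members = rec$members, birth = rec$birth,
           death = if (is.na(rec$absent_since)) nf else rec$absent_since)
  }
  if (!length(closed))
    return(data.frame(members = character(), size = integer(),
                      birth_frame = integer(), death_frame = integer(),
                      lifetime_ns = numeric(), mean_sheet_frac = numeric(),
                      ordered = logical(), arrangement = character()))
  dt <- analysis$dt
  rows <- lapply(closed, function(rec) {
    mid <- min(nf, max(1L, floor((rec$birth + rec$death) / 2) + 1L))
    fr <- frame_at(traj, mid)
    hb <- detect_hbonds(fr, config)
    conn <- .connected_matrix(fr, hb, config)
    mem <- rec$members
    ors <- character()
    if (length(mem) > 1) {
      cmb <- utils::combn(mem, 2)
      for (q in seq_len(ncol(cmb)))
        if (conn[cmb[1, q], cmb[2, q]])
          ors <- c(ors, pair_orientation(fr, cmb[1, q], cmb[2, q], config))
    }
    msf <- mean(.sheet_content(fr, hb, config, strict = TRUE)[mem]) / 5
    data.frame(members = keyof(mem), size = length(mem),
               birth_frame = rec$birth, death_frame = rec$death,
               lifetime_ns = (rec$death - rec$birth) * dt,
               mean_sheet_frac = msf, ordered = msf >= 0.5,
               arrangement = if (length(ors))
                 paste(names(table(ors)), table(ors), sep = ":", collapse = ",")
                 else "")
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$birth_frame, -out$size), , drop = FALSE]
  rownames(out) <- NULL
  out
}
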