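# Multi-model PDB trajectory I/O and the one-call analysis pipeline.
#
# PDB dialect: standard ATOM records, coordinates in Angstrom (package
# units are nm; conversion at the boundary), chain = peptide letter,
# 1-based residue numbers, element column populated.  Frame spacing and
# termini protonation travel in REMARK 250 lines.

.cb_pdb_atom_fmt <- "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"

.pdb_atom_name <- function(nm) {
  # element-aligned atom-name field (cols 13-16)
  if (nchar(nm) < 4) paste0(" ", nm) else nm
}

#' Write a trajectory (or single frame) as multi-model PDB
#'
#' @param traj a `cb_traj` or a single `cb_frame`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  if (inherits(traj, "cb_frame"))
    traj <- cb_trajectory(list(traj), times = traj$time)
  stopifnot(inherits(traj, "cb_traj"))
  a <- traj$atoms
  con <- file(path, "w")
  on.exit(close(con))
  nf <- n_frames(traj)
  writeLines(c(
    sprintf("REMARK 250 FRAME_DT %g", .traj_dt(traj)),
    sprintf("REMARK 250 TERMINI %s", toupper(traj$termini))), con)
  for (k in seq_len(nf)) {
    if (nf > 1) writeLines(sprintf("MODEL %8d", k), con)
    xyz <- traj$coords[[k]] * 10   # nm -> Angstrom
    lines <- vapply(seq_len(nrow(a)), function(i)
      sprintf(.cb_pdb_atom_fmt, i, .pdb_atom_name(a$atom[i]), a$resname[i],
              a$peptide[i], a$resid[i], xyz[i, 1], xyz[i, 2], xyz[i, 3],
              1, 0, a$element[i]), character(1))
    writeLines(lines, con)
    if (nf > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB trajectory
#'
#' MODEL records map to frames; a file without MODEL records is a
#' one-frame trajectory.  The atom roster (chain, residue, atom name
#' sequence) must be identical in every model.  Frame spacing and termini
#' protonation are taken from `REMARK 250` lines when present.
#'
#' @param path PDB file.
#' @param frame_dt frame spacing override (ns).
#' @param termini termini protonation override (`"charged"`/`"neutral"`).
#' @return A `cb_traj`.
#' @export
read_trajectory <- function(path, frame_dt = NULL, termini = NULL) {
  lines <- readLines(path)
  rem_dt <- grep("^REMARK 250 FRAME_DT ", lines, value = TRUE)
  rem_tm <- grep("^REMARK 250 TERMINI ", lines, value = TRUE)
  if (is.null(frame_dt))
    frame_dt <- if (length(rem_dt)) as.numeric(sub(".*FRAME_DT ", "", rem_dt[1])) else 0.5
  if (is.null(termini))
    termini <- if (length(rem_tm)) tolower(sub(".*TERMINI ", "", rem_tm[1])) else "charged"
  stopifnot(termini %in% c("charged", "neutral"))

  is_atom <- startsWith(lines, "ATOM")
  model_starts <- which(startsWith(lines, "MODEL"))
  if (!length(model_starts)) {
    groups <- list(which(is_atom))
  } else {
    model_ends <- which(startsWith(lines, "ENDMDL"))
    if (length(model_ends) != length(model_starts))
      stop("PDB format error: unbalanced MODEL/ENDMDL")
    groups <- lapply(seq_along(model_starts), function(k) {
      idx <- seq(model_starts[k] + 1, model_ends[k] - 1)
      idx[is_atom[idx]]
    })
  }
  parse_block <- function(idx) {
    ln <- lines[idx]
    data.frame(
      atom = trimws(substr(ln, 13, 16)),
      resname = trimws(substr(ln, 18, 20)),
      peptide = trimws(substr(ln, 22, 22)),
      resid = as.integer(substr(ln, 23, 26)),
      x = as.numeric(substr(ln, 31, 38)) / 10,
      y = as.numeric(substr(ln, 39, 46)) / 10,
      z = as.numeric(substr(ln, 47, 54)) / 10,
      stringsAsFactors = FALSE)
  }
  blocks <- lapply(groups, parse_block)
  ref <- blocks[[1]][, c("atom", "resname", "peptide", "resid")]
  for (k in seq_along(blocks))
    if (!identical(blocks[[k]][, c("atom", "resname", "peptide", "resid")], ref))
      stop("PDB format error: atom roster of model ", k,
           " differs from model 1")
  bad <- setdiff(unique(ref$resname), names(.cb_aa1))
  if (length(bad)) stop("unknown residue(s): ", paste(bad, collapse = ", "))

  atoms <- data.frame(peptide = ref$peptide, resid = ref$resid,
                      resname = ref$resname, atom = ref$atom,
                      stringsAsFactors = FALSE)
  firstchain <- atoms[atoms$peptide == atoms$peptide[1], ]
  residues <- unname(.cb_aa1[firstchain$resname[match(1:7, firstchain$resid)]])
  if (anyNA(residues)) stop("PDB format error: chain ",
                            atoms$peptide[1], " lacks residues 1-7")
  atoms <- .annotate_atoms(atoms, residues, termini)
  frames <- lapply(seq_along(blocks), function(k)
    cb_frame(atoms, as.matrix(blocks[[k]][, c("x", "y", "z")]),
             time = (k - 1) * frame_dt, termini = termini))
  cb_trajectory(frames, frame_dt = frame_dt,
                provenance = list(source = path))
}

#' Build and simulate one system with a preset scenario
#'
#' Convenience wrapper: builds the mutant sheet and runs one of the
#' [preset_scenarios()] on it.
#'
#' @param mutant mutation label (`"N2D"`, `"N2S"`, `"N6D"`) or `NULL` for
#'   the wild type.
#' @param n_peptides sheet size.
#' @param termini `"charged"` or `"neutral"`.
#' @param scenario preset name, see [preset_scenarios()].
#' @param n_frames,frame_dt,noise_sigma,seed scenario parameters.
#' @param spacing inter-strand spacing (nm).
#' @return A `cb_traj` with scenario provenance.
#' @export
simulate_system <- function(mutant = NULL, n_peptides = 6,
                            termini = c("neutral", "charged"),
                            scenario = "stable_twisted",
                            n_frames = 100, frame_dt = 0.5,
                            noise_sigma = 0.01, seed = 1, spacing = 0.48) {
  termini <- match.arg(termini)
  presets <- preset_scenarios(n_peptides, n_frames, frame_dt, noise_sigma, seed)
  if (!scenario %in% names(presets))
    stop("unknown scenario '", scenario, "'; available: ",
         paste(names(presets), collapse = ", "))
  sheet <- build_sheet(peptide_spec(mutant = mutant, termini = termini),
                       aggregate_spec(n_peptides, spacing = spacing))
  traj <- generate_trajectory(sheet, presets[[scenario]])
  traj$provenance$scenario <- scenario
  traj$provenance$mutant <- mutant
  traj$provenance$expected <- attr(presets[[scenario]], "expected")
  traj
}

#' Run the full analysis pipeline on a trajectory
#'
#' Computes pair observables, events, the oligomer census and the
#' stability verdict; optionally writes a report bundle (observables CSV,
#' events/verdict JSON, census CSV, config JSON with hash and seed) and
#' compares the verdict against the packaged reference outcome.
#'
#' @param input a `cb_traj` or a path to a multi-model PDB file.
#' @param config a [cb_config()].
#' @param out_dir directory for the report bundle (`NULL` = don't write).
#' @param name,temperature optional system name (e.g. `"6N2D*"`) and
#'   temperature for comparison against [load_reference_outcomes()].
#' @return A list: `verdict`, `events`, `census`, `observables`,
#'   `analysis`, optionally `agreement`; invisibly.
#' @export
run_pipeline <- function(input, config = cb_config(), out_dir = NULL,
                         name = NULL, temperature = NULL) {
  traj <- if (is.character(input)) {
    message("pipeline: reading trajectory from ", input)
    read_trajectory(input)
  } else input
  stopifnot(inherits(traj, "cb_traj"))
  message(sprintf("pipeline: %d frames, %d atoms, config %s",
                  n_frames(traj), nrow(traj$atoms), config_hash(config)))
  message("pipeline: computing observables")
  obs <- trajectory_observables(traj, "adjacent", config)
  message("pipeline: analyzing events")
  analysis <- analyze_trajectory(traj, config)
  events <- detect_events(traj, config, analysis)
  verdict <- stability_verdict(traj, config, events, analysis)
  census <- oligomer_census(traj, config, analysis)
  message(sprintf("pipeline: verdict %s (key event %s, dRg %+.3f nm)",
                  verdict$verdict, verdict$key_event, verdict$delta_rg))
  out <- list(verdict = verdict, events = events, census = census,
              observables = obs, analysis = analysis)
  if (!is.null(name) && !is.null(temperature)) {
    vd <- data.frame(name = name, temperature = temperature,
                     verdict = verdict$verdict,
                     key_event = verdict$key_event)
    out$agreement <- compare_to_reference(vd)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(obs, file.path(out_dir, "observables.csv"),
                     row.names = FALSE)
    utils::write.csv(census, file.path(out_dir, "census.csv"),
                     row.names = FALSE)
    jsonlite::write_json(events, file.path(out_dir, "events.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(verdict = verdict$verdict, key_event = verdict$key_event,
           delta_rg = verdict$delta_rg, detached = verdict$detached,
           config_hash = config_hash(config),
           seed = traj$provenance$seed),
      file.path(out_dir, "verdict.json"), auto_unbox = TRUE, digits = NA)
    write_config(config, file.path(out_dir, "config.json"))
    message("pipeline: report bundle written to ", out_dir)
  }
  invisible(out)
}
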