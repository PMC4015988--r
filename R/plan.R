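# Study design: the simulation matrix and the reference stability outcomes.

.cb_mutants <- c("N2D", "N2S", "N6D")
.cb_sizes <- 5:8
.cb_temps <- c(300L, 330L)
.cb_termini <- c("charged", "neutral")

# Systems whose runs were extended to 100 ns, and systems re-run with a
# second random seed (stated per neutral-termini system and temperature).
.cb_extended <- data.frame(
  name = c("5N6D*", "6N2D*", "8N2S*", "5N2S*", "7N2S*", "7N6D*"),
  temperature = c(300L, 300L, 300L, 330L, 330L, 330L)
)
.cb_reinitiated <- data.frame(
  name = c("6N2D*", "7N2S*"),
  temperature = c(300L, 330L)
)

#' Construct a simulation specification
#'
#' One cell of the study's experiment matrix: a mutant sheet of a given
#' size, temperature and termini protonation state.
#'
#' @param mutant one of `"N2D"`, `"N2S"`, `"N6D"`.
#' @param n_peptides peptides per sheet, 5-8.
#' @param temperature simulation temperature in kelvin (300 or 330).
#' @param termini `"charged"` (NH3+/COO-) or `"neutral"` (NH2/COOH).
#' @param replicate replicate index (>= 2 only for the two re-seeded runs).
#' @param duration_ns nominal run length in ns (50; 100 for extended runs).
#' @param flags character vector, subset of `c("extended", "reinitiated")`.
#' @return A list of class `cb_simspec`.
#' @examples
#' simulation_name(simulation_spec("N2D", 5, 300, "charged"))
#' @export
simulation_spec <- function(mutant, n_peptides, temperature = 300L,
                            termini = c("charged", "neutral"),
                            replicate = 1L, duration_ns = 50L,
                            flags = character()) {
  termini <- match.arg(termini)
  if (!mutant %in% .cb_mutants)
    stop("invalid simulation spec: unknown mutant label '", mutant, "'")
  if (!n_peptides %in% .cb_sizes)
    stop("invalid simulation spec: n_peptides must be 5-8, got ", n_peptides)
  if (!temperature %in% .cb_temps)
    stop("invalid simulation spec: temperature must be 300 or 330 K")
  if (replicate < 1) stop("invalid simulation spec: replicate must be >= 1")
  stopifnot(all(flags %in% c("extended", "reinitiated")))
  spec <- list(mutant = mutant, n_peptides = as.integer(n_peptides),
               temperature = as.integer(temperature), termini = termini,
               replicate = as.integer(replicate),
               duration_ns = as.integer(duration_ns), flags = flags)
  spec$name <- simulation_name(spec)
  class(spec) <- "cb_simspec"
  spec
}

#' Simulation name under the study's naming scheme
#'
#' Names follow `nXpY`: `n` is the number of peptides per sheet and `XpY`
#' the mutation (parent residue, position, mutant residue); a trailing
#' `"*"` marks neutral termini.
#'
#' @param spec a `cb_simspec` or a list with fields `n_peptides`, `mutant`,
#'   `termini`.
#' @return A string such as `"5N2D"` or `"7N2S*"`.
#' @export
simulation_name <- function(spec) {
  if (!spec$mutant %in% .cb_mutants)
    stop("invalid simulation spec: unknown mutant label '", spec$mutant, "'")
  paste0(spec$n_peptides, spec$mutant,
         if (identical(spec$termini, "neutral")) "*" else "")
}

#' @export
print.cb_simspec <- function(x, ...) {
  cat(sprintf("simulation %s/%d K (replicate %d, %d ns%s)\n",
              x$name, x$temperature, x$replicate, x$duration_ns,
              if (length(x$flags)) paste0("; ", paste(x$flags, collapse = ",")) else ""))
  invisible(x)
}

#' Enumerate the full simulation plan
#'
#' The cross product of 3 mutants x 4 sheet sizes x 2 temperatures x
#' 2 termini states (48 systems), plus one extra replicate each for the two
#' re-seeded runs (6N2D*/300 and 7N2S*/330), for 50 simulations in total.
#' Runs extended to 100 ns carry the `extended` flag and duration 100.
#' Order is deterministic: mutant, size, temperature, termini, replicate.
#'
#' @return A data.frame with one row per simulation: `name`, `mutant`,
#'   `n_peptides`, `temperature`, `termini`, `replicate`, `duration_ns`,
#'   `flags` (comma-separated, `""` if none).
#' @examples
#' plan <- enumerate_plan()
#' nrow(plan)            # 50
#' table(plan$mutant)    # 17 / 17 / 16
#' @export
enumerate_plan <- function() {
  rows <- list()
  for (mut in .cb_mutants) for (n in .cb_sizes) for (tk in .cb_temps)
    for (term in .cb_termini) {
      nm <- paste0(n, mut, if (term == "neutral") "*" else "")
      ext <- any(.cb_extended$name == nm & .cb_extended$temperature == tk)
      rein <- any(.cb_reinitiated$name == nm & .cb_reinitiated$temperature == tk)
      rows[[length(rows) + 1L]] <- data.frame(
        name = nm, mutant = mut, n_peptides = n, temperature = tk,
        termini = term, replicate = 1L,
        duration_ns = if (ext) 100L else 50L,
        flags = if (ext) "extended" else "")
      if (rein)
        rows[[length(rows) + 1L]] <- data.frame(
          name = nm, mutant = mut, n_peptides = n, temperature = tk,
          termini = term, replicate = 2L, duration_ns = 50L,
          flags = "reinitiated")
    }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Load the packaged reference stability outcomes
#'
#' One entry per (system, temperature) cell of the study's summary table:
#' the 50 ns stability verdict and, for unstable systems, the key molecular
#' event.  Extended (100 ns) and re-initiated runs are recorded as flags;
#' the single system that became unstable only during its extension
#' (5N2S*/330, dissociation at ~95 ns) keeps its 50 ns verdict `stable`
#' with the `late_instability` flag.
#'
#' @param path optional path to an alternative outcomes CSV (defaults to
#'   the packaged table).
#' @return A data.frame with columns `name`, `temperature`, `termini`,
#'   `verdict`, `key_event`, `footnotes`.
#' @examples
#' ref <- load_reference_outcomes()
#' subset(ref, name == "5N2D" & temperature == 300)
#' @export
load_reference_outcomes <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "reference_outcomes.csv",
                        package = "crossbeta", mustWork = TRUE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "temperature", "termini", "verdict", "key_event", "footnotes")
  if (!all(need %in% names(out)))
    stop("reference outcomes: missing columns ",
         paste(setdiff(need, names(out)), collapse = ", "))
  out$footnotes[is.na(out$footnotes)] <- ""
  events <- c("none", "disorder", "dissociation", "disintegration",
              "rearrangement", "collapse")
  for (i in seq_len(nrow(out))) {
    r <- out[i, ]
    if (!r$verdict %in% c("stable", "unstable"))
      stop("reference outcomes row ", i, " (", r$name, "/", r$temperature,
           "): bad verdict '", r$verdict, "'")
    if (!r$key_event %in% events)
      stop("reference outcomes row ", i, " (", r$name, "/", r$temperature,
           "): bad key_event '", r$key_event, "'")
    fl <- .split_flags(r$footnotes)
    if (!all(fl %in% c("extended", "reinitiated", "late_instability")))
      stop("reference outcomes row ", i, " (", r$name, "/", r$temperature,
           "): bad footnote")
    if (r$verdict == "stable" && r$key_event != "none" &&
        !"late_instability" %in% fl)
      stop("reference outcomes row ", i, " (", r$name, "/", r$temperature,
           "): stable verdict with key event")
  }
  if (anyDuplicated(out[, c("name", "temperature")]))
    stop("reference outcomes: duplicated (name, temperature) entry")
  out
}

.split_flags <- function(s) {
  if (is.na(s) || !nzchar(s)) character() else strsplit(s, ",", fixed = TRUE)[[1]]
}

#' Extended and re-initiated run instances
#'
#' Expands the reference outcomes into one row per extended or re-initiated
#' run (a system carrying both flags contributes two runs).  A run counts
#' as stable throughout when its system's verdict is stable and the system
#' is not flagged `late_instability`.
#'
#' @param outcomes the table from [load_reference_outcomes()].
#' @return A data.frame with columns `name`, `temperature`, `run`
#'   (`"extended"` or `"reinitiated"`) and `stable_throughout`.
#' @export
flagged_runs <- function(outcomes = load_reference_outcomes()) {
  rows <- list()
  for (i in seq_len(nrow(outcomes))) {
    fl <- .split_flags(outcomes$footnotes[i])
    for (run in intersect(c("extended", "reinitiated"), fl))
      rows[[length(rows) + 1L]] <- data.frame(
        name = outcomes$name[i], temperature = outcomes$temperature[i],
        run = run,
        stable_throughout = outcomes$verdict[i] == "stable" &&
          !"late_instability" %in% fl)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare computed stability verdicts to the reference outcomes
#'
#' @param verdicts a data.frame with columns `name`, `temperature`,
#'   `verdict` and optionally `key_event` (as produced by the pipeline).
#' @param outcomes reference table from [load_reference_outcomes()].
#' @return A list of class `cb_agreement`: `per_system` (row-wise match
#'   table), `agreement` (fraction of matching verdicts; `NA` and
#'   `undefined = TRUE` when `verdicts` is empty) and
#'   `key_event_agreement`.
#' @export
compare_to_reference <- function(verdicts, outcomes = load_reference_outcomes()) {
  if (NROW(verdicts) == 0) {
    out <- list(per_system = data.frame(), agreement = NA_real_,
                key_event_agreement = NA_real_, undefined = TRUE)
    class(out) <- "cb_agreement"
    return(out)
  }
  if (is.null(verdicts$key_event)) verdicts$key_event <- NA_character_
  rows <- list()
  for (i in seq_len(nrow(verdicts))) {
    v <- verdicts[i, ]
    j <- which(outcomes$name == v$name & outcomes$temperature == v$temperature)
    if (length(j) != 1)
      stop("no reference outcome for '", v$name, "'/", v$temperature, " K")
    o <- outcomes[j, ]
    rows[[i]] <- data.frame(
      name = v$name, temperature = v$temperature,
      verdict = v$verdict, ref_verdict = o$verdict,
      key_event = v$key_event, ref_key_event = o$key_event,
      verdict_match = identical(v$verdict, o$verdict),
      key_event_match = identical(v$key_event, o$key_event))
  }
  per <- do.call(rbind, rows)
  out <- list(per_system = per,
              agreement = mean(per$verdict_match),
              key_event_agreement = mean(per$key_event_match),
              undefined = FALSE)
  class(out) <- "cb_agreement"
  out
}

#' @export
print.cb_agreement <- function(x, ...) {
  if (isTRUE(x$undefined)) {
    cat("agreement report: empty verdict list (agreement undefined)\n")
  } else {
    cat(sprintf("agreement report: %d systems, verdict agreement %.3f, key-event agreement %.3f\n",
                nrow(x$per_system), x$agreement, x$key_event_agreement))
    mism <- x$per_system[!x$per_system$verdict_match, , drop = FALSE]
    if (nrow(mism)) {
      cat("mismatches:\n")
      print(mism[, c("name", "temperature", "verdict", "ref_verdict")])
    }
  }
  invisible(x)
}
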