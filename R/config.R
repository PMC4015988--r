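#' Analysis configuration
#'
#' Collects every numeric cutoff used by the observables and event layers.
#' Defaults reproduce the study's printed criteria where the study prints
#' one (tyrosine stacking < 0.5 nm, stability gate |dRg| < 0.1 nm); the
#' remaining cutoffs are documented conventions exposed here so they can be
#' varied.
#'
#' @param hbond_dist donor-acceptor heavy-atom distance cutoff (nm) for
#'   hydrogen-bond detection.
#' @param hbond_angle minimum antecedent-donor-acceptor angle (degrees).
#' @param stack_cutoff tyrosine ring-plane distance below which two rings
#'   count as stacked (nm); the flag is strict (`< cutoff`).
#' @param delta_rg_cutoff stability gate on |Rg(final) - Rg(initial)| (nm);
#'   stable requires strictly less than this value.
#' @param contact_cutoff minimum heavy-atom distance (nm) under which two
#'   peptides count as in contact for connectivity clustering.
#' @param min_bb_hbonds alternative connectivity criterion: number of
#'   inter-peptide backbone-backbone hydrogen bonds.
#' @param orient_parallel_max pair twist (degrees) below which a peptide
#'   pair is classed parallel.
#' @param orient_antiparallel_min pair twist (degrees) above which a pair is
#'   classed antiparallel; between the two bounds the pair is "crossed".
#' @param persistence number of consecutive frames a triggering condition
#'   must hold before an event is recorded (suppresses noise flicker).
#' @param window_frac fraction of frames averaged at each trajectory end
#'   when computing the Rg drift (minimum one frame).
#' @param extended_min minimum Ca(1)-Ca(7) end-to-end distance (nm) for a
#'   peptide to count as an extended strand; orientation changes of
#'   non-extended (conformationally disordered) peptides are not scored
#'   as rearrangements.
#' @param spacing default inter-strand spacing for built sheets (nm).
#' @param ring_method `"plane"` for the symmetrized centroid-to-plane
#'   projection, `"centroid"` for the plain centroid-centroid distance.
#' @param frame_dt default time between trajectory frames (ns).
#'
#' @return An object of class `cb_config` (a named list).
#' @examples
#' cfg <- cb_config()
#' cfg$stack_cutoff
#' @export
cb_config <- function(hbond_dist = 0.35,
                      hbond_angle = 90,
                      stack_cutoff = 0.5,
                      delta_rg_cutoff = 0.1,
                      contact_cutoff = 0.45,
                      min_bb_hbonds = 2,
                      orient_parallel_max = 50,
                      orient_antiparallel_min = 130,
                      persistence = 5,
                      window_frac = 0.05,
                      extended_min = 1.9,
                      spacing = 0.48,
                      ring_method = c("plane", "centroid"),
                      frame_dt = 0.5) {
  ring_method <- match.arg(ring_method)
  cfg <- list(
    hbond_dist = hbond_dist, hbond_angle = hbond_angle,
    stack_cutoff = stack_cutoff, delta_rg_cutoff = delta_rg_cutoff,
    contact_cutoff = contact_cutoff, min_bb_hbonds = min_bb_hbonds,
    orient_parallel_max = orient_parallel_max,
    orient_antiparallel_min = orient_antiparallel_min,
    persistence = persistence, window_frac = window_frac,
    extended_min = extended_min, spacing = spacing,
    ring_method = ring_method, frame_dt = frame_dt
  )
  stopifnot(all(vapply(cfg[names(cfg) != "ring_method"], is.numeric, logical(1))))
  class(cfg) <- "cb_config"
  cfg
}

#' @export
print.cb_config <- function(x, ...) {
  cat("crossbeta configuration\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read or write a configuration as JSON
#'
#' Serialization is lossless for every field; fields missing from the file
#' fall back to the [cb_config()] default (and are reported via `message()`).
#'
#' @param config a `cb_config` object.
#' @param path file path.
#' @return `read_config()` returns a `cb_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "cb_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  def <- cb_config()
  known <- intersect(names(raw), names(def))
  missing <- setdiff(names(def), names(raw))
  if (length(missing))
    message("config: defaults applied for ", paste(missing, collapse = ", "))
  do.call(cb_config, raw[known])
}

# Short stable hash of a config (polynomial rolling hash over its JSON
# form), used to tag report bundles for reproducibility.
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
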