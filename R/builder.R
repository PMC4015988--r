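# Builder: idealized heavy-atom strands and parallel in-register sheets.

#' Apply a point mutation label to a peptide sequence
#'
#' Labels follow the `XpY` convention: parent residue `X` at (1-based)
#' position `p` replaced by `Y`, e.g. `"N2D"` on `GNNQQNY` gives
#' `GDNQQNY`.
#'
#' @param base parent sequence (one-letter codes), default the wild type.
#' @param label mutation label `XpY`.
#' @return The mutated sequence string.
#' @examples
#' mutate_sequence("GNNQQNY", "N2D")
#' @export
mutate_sequence <- function(base = "GNNQQNY", label) {
  m <- regmatches(label, regexec("^([A-Z])([1-9])([A-Z])$", label))[[1]]
  if (length(m) != 4) stop("malformed mutation label '", label, "'")
  p <- as.integer(m[3])
  if (p > nchar(base)) stop("mutation position ", p, " outside sequence")
  if (substr(base, p, p) != m[2])
    stop("inconsistent mutation label '", label, "': position ", p,
         " of ", base, " is ", substr(base, p, p), ", not ", m[2])
  paste0(substr(base, 1, p - 1), m[4], substr(base, p + 1, nchar(base)))
}

#' Peptide specification
#'
#' @param sequence 7-residue sequence in one-letter codes; alternatively
#'   give `mutant` to derive it from the wild type.
#' @param termini `"charged"` (NH3+/COO-) or `"neutral"` (NH2/COOH);
#'   termini protonation decides the donor/acceptor roles of the terminal
#'   groups (heavy atoms are identical).
#' @param mutant optional mutation label (`"N2D"`, `"N2S"`, `"N6D"`, ...)
#'   applied to the wild-type sequence.
#' @return A list of class `cb_pepspec`.
#' @examples
#' peptide_spec(mutant = "N2S", termini = "neutral")
#' @export
peptide_spec <- function(sequence = "GNNQQNY",
                         termini = c("charged", "neutral"),
                         mutant = NULL) {
  termini <- match.arg(termini)
  if (!is.null(mutant)) sequence <- mutate_sequence("GNNQQNY", mutant)
  res <- strsplit(sequence, "")[[1]]
  if (length(res) != 7) stop("sequence must have 7 residues")
  bad <- setdiff(res, names(.cb_aa3))
  if (length(bad))
    stop("no residue template for code(s): ", paste(bad, collapse = ", "))
  structure(list(sequence = sequence, residues = res, termini = termini),
            class = "cb_pepspec")
}

#' Aggregate specification
#'
#' Geometry of a stacked single sheet.  The default reproduces the planar
#' in-register parallel arrangement: zero register offset, zero twist, all
#' adjacent pairs parallel.
#'
#' @param n_peptides number of strands (>= 2 for a sheet).
#' @param spacing inter-strand spacing along the stacking axis (nm).
#' @param register_offset register shift between successive strands, in
#'   residues (0 = in-register).
#' @param per_pair_twist cumulative twist applied per adjacent pair
#'   (degrees, about the stacking axis).
#' @param orientation `"parallel"`/`"antiparallel"` per adjacent pair
#'   (length 1 is recycled).
#' @return A list of class `cb_aggspec`.
#' @export
aggregate_spec <- function(n_peptides, spacing = 0.48, register_offset = 0L,
                           per_pair_twist = 0, orientation = "parallel") {
  n_peptides <- as.integer(n_peptides)
  stopifnot(n_peptides >= 1, spacing > 0)
  orientation <- rep_len(orientation, max(1L, n_peptides - 1L))
  stopifnot(all(orientation %in% c("parallel", "antiparallel")))
  structure(list(n_peptides = n_peptides, spacing = spacing,
                 register_offset = as.integer(register_offset),
                 per_pair_twist = per_pair_twist, orientation = orientation),
            class = "cb_aggspec")
}

# ---- cb_frame -------------------------------------------------------------

# A frame holds an atom table (metadata, constant over a trajectory) and an
# n x 3 coordinate matrix in nm.
cb_frame <- function(atoms, xyz, time = 0, termini = "charged") {
  stopifnot(nrow(atoms) == nrow(xyz), ncol(xyz) == 3)
  structure(list(atoms = atoms, xyz = xyz, time = time, termini = termini),
            class = "cb_frame")
}

#' @export
print.cb_frame <- function(x, ...) {
  ids <- unique(x$atoms$peptide)
  cat(sprintf("cb_frame: %d atoms, %d peptide(s) [%s], termini %s, t = %g ns\n",
              nrow(x$atoms), length(ids), paste(ids, collapse = ""),
              x$termini, x$time))
  invisible(x)
}

#' Peptide identifiers of a frame or trajectory
#' @param x a `cb_frame` or `cb_traj`.
#' @return Character vector of chain letters in build order.
#' @export
peptide_ids <- function(x) unique(x$atoms$peptide)

.sel_atoms <- function(frame, peptide = NULL, resid = NULL, atom = NULL) {
  keep <- rep(TRUE, nrow(frame$atoms))
  if (!is.null(peptide)) keep <- keep & frame$atoms$peptide %in% peptide
  if (!is.null(resid)) keep <- keep & frame$atoms$resid %in% resid
  if (!is.null(atom)) keep <- keep & frame$atoms$atom %in% atom
  which(keep)
}

.atom_masses <- function(frame) unname(.cb_mass[frame$atoms$element])

# Donor/acceptor/antecedent annotation from atom names + termini state.
.annotate_atoms <- function(atoms, residues, termini) {
  n <- nrow(atoms)
  atoms$element <- .cb_element(atoms$atom)
  atoms$backbone <- atoms$atom %in% .cb_backbone_atoms
  atoms$donor <- FALSE
  atoms$acceptor <- FALSE
  atoms$ante <- NA_integer_
  idx_of <- function(pep, r, nm) {
    i <- which(atoms$peptide == pep & atoms$resid == r & atoms$atom == nm)
    if (length(i) != 1) stop("annotation: missing atom ", nm, " in ", pep, r)
    i
  }
  for (i in seq_len(n)) {
    pep <- atoms$peptide[i]; r <- atoms$resid[i]; nm <- atoms$atom[i]
    code <- residues[r]
    if (nm == "N") {                      # backbone amide (or terminal amine)
      atoms$donor[i] <- TRUE
      atoms$ante[i] <- idx_of(pep, r, "CA")
    } else if (nm == "O") {
      atoms$acceptor[i] <- TRUE
    } else if (nm == "OXT") {
      if (termini == "charged") atoms$acceptor[i] <- TRUE   # carboxylate
      else { atoms$donor[i] <- TRUE; atoms$ante[i] <- idx_of(pep, r, "C") }
    } else {
      don <- .cb_sc_donors[[code]]
      if (nm %in% names(don)) {
        atoms$donor[i] <- TRUE
        atoms$ante[i] <- idx_of(pep, r, don[[nm]])
      }
      if (nm %in% .cb_sc_acceptors[[code]]) atoms$acceptor[i] <- TRUE
    }
  }
  atoms
}

# ---- strand construction --------------------------------------------------

#' Build one extended beta-strand
#'
#' Heavy atoms only, ideal extended-strand dihedrals (phi = -120, psi =
#' +120, omega = 180) and one fixed side-chain rotamer per residue type.
#' The strand is oriented with its Ca2->Ca6 axis along +x and rolled so
#' that, stacked at the default spacing along +y, both backbone
#' hydrogen-bond ladders of a strand pair form.
#'
#' @param pspec a [peptide_spec()].
#' @param peptide chain letter to assign (default `"A"`).
#' @return A `cb_frame` with one peptide.
#' @examples
#' s <- build_strand(peptide_spec("GNNQQNY"))
#' @export
build_strand <- function(pspec, peptide = "A") {
  stopifnot(inherits(pspec, "cb_pepspec"))
  g <- .cb_geom
  res <- pspec$residues
  nres <- length(res)
  pos <- list()   # named "r.name" -> xyz
  key <- function(r, nm) paste0(r, ".", nm)
  put <- function(r, nm, xyz) pos[[key(r, nm)]] <<- xyz
  at <- function(r, nm) pos[[key(r, nm)]]
  rows <- list()
  rec <- function(r, nm) rows[[length(rows) + 1L]] <<- list(r = as.integer(r), nm = nm)

  put(1, "N", c(0, 0, 0)); rec(1, "N")
  put(1, "CA", c(g$b_n_ca, 0, 0)); rec(1, "CA")
  put(1, "C", c(g$b_n_ca - g$b_ca_c * cos(.deg2rad(g$a_n_ca_c)),
                g$b_ca_c * sin(.deg2rad(g$a_n_ca_c)), 0)); rec(1, "C")
  for (r in seq_len(nres)) {
    if (r > 1) {
      put(r, "N", .nerf(at(r - 1, "N"), at(r - 1, "CA"), at(r - 1, "C"),
                        g$b_c_n, g$a_ca_c_n, g$psi)); rec(r, "N")
      put(r, "CA", .nerf(at(r - 1, "CA"), at(r - 1, "C"), at(r, "N"),
                         g$b_n_ca, g$a_c_n_ca, g$omega)); rec(r, "CA")
      put(r, "C", .nerf(at(r - 1, "C"), at(r, "N"), at(r, "CA"),
                        g$b_ca_c, g$a_n_ca_c, g$phi)); rec(r, "C")
    }
    put(r, "O", .nerf(at(r, "N"), at(r, "CA"), at(r, "C"),
                      g$b_c_o, g$a_ca_c_o, g$psi + 180)); rec(r, "O")
    code <- res[r]
    if (code != "G") {
      cb <- .cb_cb_row
      put(r, "CB", .nerf(at(r, cb$r3), at(r, cb$r2), at(r, cb$r1),
                         cb$bond, cb$angle, cb$dihedral)); rec(r, "CB")
      for (row in .cb_sidechain[[code]]) {
        put(r, row$name, .nerf(at(r, row$r3), at(r, row$r2), at(r, row$r1),
                               row$bond, row$angle, row$dihedral))
        rec(r, row$name)
      }
    }
  }
  put(nres, "OXT", .nerf(at(nres, "N"), at(nres, "CA"), at(nres, "C"),
                         g$b_c_oxt, g$a_ca_c_oxt, g$psi)); rec(nres, "OXT")

  xyz <- do.call(rbind, lapply(rows, function(a) at(a$r, a$nm)))
  atoms <- data.frame(
    peptide = peptide,
    resid = vapply(rows, function(a) a$r, integer(1)),
    resname = .cb_aa3[res[vapply(rows, function(a) a$r, integer(1))]],
    atom = vapply(rows, function(a) a$nm, character(1)),
    stringsAsFactors = FALSE)
  rownames(atoms) <- NULL

  # canonical orientation: Ca2->Ca6 along +x, fixed roll, CA centroid at 0
  ca2 <- xyz[atoms$resid == 2 & atoms$atom == "CA", ]
  ca6 <- xyz[atoms$resid == 6 & atoms$atom == "CA", ]
  R <- .rotmat(c(1, 0, 0), g$roll) %*% .rot_between(ca6 - ca2, c(1, 0, 0))
  xyz <- xyz %*% t(R)
  xyz <- sweep(xyz, 2, colMeans(xyz[atoms$atom == "CA", , drop = FALSE]))

  atoms <- .annotate_atoms(atoms, res, pspec$termini)
  fr <- cb_frame(atoms, xyz, time = 0, termini = pspec$termini)
  attr(fr, "sequence") <- pspec$sequence
  fr
}

#' Build a stacked beta-sheet
#'
#' Copies of the idealized strand are stacked along the +y axis at
#' `spacing`, optionally register-shifted, 180-degree flipped for
#' antiparallel pairs (about the strand axis), and cumulatively twisted
#' about the stacking axis.  Chain letters A, B, C, ... follow build
#' order along the stacking axis.
#'
#' @param pspec a [peptide_spec()].
#' @param aspec an [aggregate_spec()].
#' @return A `cb_frame` with `n_peptides` chains.
#' @examples
#' sheet <- build_sheet(peptide_spec(mutant = "N2S", termini = "neutral"),
#'                      aggregate_spec(5))
#' @export
build_sheet <- function(pspec, aspec) {
  stopifnot(inherits(aspec, "cb_aggspec"))
  n <- aspec$n_peptides
  strand <- build_strand(pspec)
  ca2 <- strand$xyz[.sel_atoms(strand, resid = 2, atom = "CA"), ]
  ca6 <- strand$xyz[.sel_atoms(strand, resid = 6, atom = "CA"), ]
  res_step <- sqrt(sum((ca6 - ca2)^2)) / 4   # x-advance per residue
  flipped <- c(FALSE, cumsum(aspec$orientation == "antiparallel") %% 2 == 1)

  frames <- vector("list", n)
  for (k in seq_len(n)) {
    xyz <- strand$xyz
    # antiparallel flip: 180 degrees about the sheet-plane normal, which
    # reverses the strand direction while keeping the strand in plane
    if (flipped[k]) xyz <- xyz %*% t(.rotmat(c(0, 0, 1), 180))
    if (aspec$per_pair_twist != 0)
      xyz <- xyz %*% t(.rotmat(c(0, 1, 0), (k - 1) * aspec$per_pair_twist))
    shift <- c((k - 1) * aspec$register_offset * res_step,
               (k - 1) * aspec$spacing, 0)
    frames[[k]] <- sweep(xyz, 2, shift, "+")
  }
  atoms <- do.call(rbind, lapply(seq_len(n), function(k) {
    a <- strand$atoms
    a$peptide <- LETTERS[k]
    a$ante <- a$ante + (k - 1L) * nrow(strand$atoms)
    a
  }))
  rownames(atoms) <- NULL
  xyz <- do.call(rbind, frames)
  fr <- cb_frame(atoms, xyz, time = 0, termini = pspec$termini)
  attr(fr, "sequence") <- pspec$sequence

  # steric clash check between peptides
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    d2 <- .dist2(xyz[atoms$peptide == LETTERS[i], , drop = FALSE],
                 xyz[atoms$peptide == LETTERS[j], , drop = FALSE])
    if (min(d2) < 0.15^2)
      stop(sprintf("steric clash building sheet: peptides %s and %s at %.3f nm",
                   LETTERS[i], LETTERS[j], sqrt(min(d2))))
  }
  fr
}

#' Rigidly transform one peptide of a frame
#'
#' Rotates the named peptide about `center` (its centre of mass by
#' default) and translates it; all other peptides are untouched.  The
#' identity transform returns the frame unchanged.
#'
#' @param frame a `cb_frame`.
#' @param peptide chain letter.
#' @param R 3x3 rotation matrix.
#' @param t translation vector (nm).
#' @param center rotation centre (nm); default the peptide's centre of mass.
#' @return The transformed `cb_frame`.
#' @export
apply_rigid_transform <- function(frame, peptide, R = diag(3),
                                  t = c(0, 0, 0), center = NULL) {
  sel <- .sel_atoms(frame, peptide = peptide)
  if (!length(sel)) stop("unknown peptide id '", peptide, "'")
  if (identical(R, diag(3)) && all(t == 0)) return(frame)
  if (is.null(center)) {
    m <- .atom_masses(frame)[sel]
    center <- colSums(frame$xyz[sel, , drop = FALSE] * m) / sum(m)
  }
  frame$xyz[sel, ] <- .transform_xyz(frame$xyz[sel, , drop = FALSE],
                                     R, t, center)
  frame
}
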