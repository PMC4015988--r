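# Residue templates: chemistry tables and internal coordinates for the
# heavy-atom builder.  Distances in nm, angles/dihedrals in degrees.
#
# Side chains use one fixed rotamer per residue type, chosen so that at the
# canonical 0.48 nm inter-strand spacing the Asn/Gln amide groups form the
# in-register side-chain hydrogen-bond ladders ("polar zipper") of a
# parallel sheet, with a definite up-sheet/down-sheet donation direction
# set by residue-position parity.

.cb_aa3 <- c(G = "GLY", N = "ASN", D = "ASP", S = "SER", Q = "GLN", Y = "TYR")
.cb_aa1 <- structure(names(.cb_aa3), names = .cb_aa3)

.cb_mass <- c(C = 12.011, N = 14.007, O = 15.999)

# Ideal extended-strand backbone geometry
.cb_geom <- list(
  phi = -120, psi = 120, omega = 180,
  b_n_ca = 0.1458, b_ca_c = 0.1525, b_c_n = 0.1329,
  b_c_o = 0.1231, b_c_oxt = 0.1250,
  a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_n_ca_c = 111.2,
  a_ca_c_o = 120.8, a_ca_c_oxt = 117.0,
  # roll of the strand about its own axis relative to the sheet plane;
  # chosen (once, geometrically) so both backbone H-bond ladders of a
  # 0.48 nm-spaced pair fall inside the donor-acceptor criterion
  roll = 55
)

# Side-chain internal coordinates: atom placed from three reference atoms
# (NeRF construction: bond to ref1, angle ref2-ref1-atom, dihedral
# ref3-ref2-ref1-atom).  CB is common to all non-Gly residues.
.cb_cb_row <- list(name = "CB", r1 = "CA", r2 = "N", r3 = "C",
                   bond = 0.1530, angle = 110.5, dihedral = -122.6)

.cb_sidechain <- list(
  G = list(),
  S = list(
    list(name = "OG", r1 = "CB", r2 = "CA", r3 = "N",
         bond = 0.1417, angle = 110.8, dihedral = -60)
  ),
  N = list(
    list(name = "CG",  r1 = "CB", r2 = "CA", r3 = "N",
         bond = 0.1516, angle = 112.6, dihedral = -60),
    list(name = "OD1", r1 = "CG", r2 = "CB", r3 = "CA",
         bond = 0.1231, angle = 120.8, dihedral = 150),
    list(name = "ND2", r1 = "CG", r2 = "CB", r3 = "CA",
         bond = 0.1328, angle = 116.4, dihedral = -30)
  ),
  D = list(
    list(name = "CG",  r1 = "CB", r2 = "CA", r3 = "N",
         bond = 0.1516, angle = 112.6, dihedral = -60),
    list(name = "OD1", r1 = "CG", r2 = "CB", r3 = "CA",
         bond = 0.1249, angle = 118.4, dihedral = 150),
    list(name = "OD2", r1 = "CG", r2 = "CB", r3 = "CA",
         bond = 0.1249, angle = 118.4, dihedral = -30)
  ),
  Q = list(
    list(name = "CG",  r1 = "CB", r2 = "CA", r3 = "N",
         bond = 0.1520, angle = 114.1, dihedral = 150),
    list(name = "CD",  r1 = "CG", r2 = "CB", r3 = "CA",
         bond = 0.1516, angle = 112.6, dihedral = 180),
    list(name = "OE1", r1 = "CD", r2 = "CG", r3 = "CB",
         bond = 0.1231, angle = 120.8, dihedral = 90),
    list(name = "NE2", r1 = "CD", r2 = "CG", r3 = "CB",
         bond = 0.1328, angle = 116.4, dihedral = -90)
  ),
  Y = list(
    list(name = "CG",  r1 = "CB",  r2 = "CA",  r3 = "N",
         bond = 0.1512, angle = 113.9, dihedral = 180),
    list(name = "CD1", r1 = "CG",  r2 = "CB",  r3 = "CA",
         bond = 0.1389, angle = 120.98, dihedral = 90),
    list(name = "CD2", r1 = "CG",  r2 = "CB",  r3 = "CA",
         bond = 0.1389, angle = 120.98, dihedral = -90),
    list(name = "CE1", r1 = "CD1", r2 = "CG",  r3 = "CB",
         bond = 0.1389, angle = 121.0, dihedral = 180),
    list(name = "CE2", r1 = "CD2", r2 = "CG",  r3 = "CB",
         bond = 0.1389, angle = 121.0, dihedral = 180),
    list(name = "CZ",  r1 = "CE1", r2 = "CD1", r3 = "CG",
         bond = 0.1389, angle = 119.8, dihedral = 0),
    list(name = "OH",  r1 = "CZ",  r2 = "CE1", r3 = "CD1",
         bond = 0.1376, angle = 119.9, dihedral = 180)
  )
)

.cb_backbone_atoms <- c("N", "CA", "C", "O", "OXT")
.cb_ring_atoms <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")

# Side-chain hydrogen-bond chemistry: donor heavy atoms with their
# antecedents, and acceptor heavy atoms, per residue type.  Asp is modelled
# as the carboxylate (acceptor only); Ser/Tyr hydroxyls are both.
.cb_sc_donors <- list(
  G = character(), D = character(),
  N = c(ND2 = "CG"), Q = c(NE2 = "CD"), S = c(OG = "CB"), Y = c(OH = "CZ")
)
.cb_sc_acceptors <- list(
  G = character(),
  N = "OD1", D = c("OD1", "OD2"), Q = "OE1", S = "OG", Y = "OH"
)

.cb_element <- function(atom) substr(sub("^[0-9]", "", atom), 1, 1)
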