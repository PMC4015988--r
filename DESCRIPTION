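Package: crossbeta
Title: Stability Analysis of Single-Sheet Cross-Beta Peptide Aggregates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds idealized parallel in-register single beta-sheet aggregates
    of GNNQQNY sequence variants (N2D, N2S, N6D), generates synthetic
    trajectories that exhibit the molecular events seen in aggregate
    simulations (disorder, dissociation, rearrangement, disintegration,
    collapse), and computes the geometric observables used to classify
    aggregate stability: radius of gyration and its drift, inter-peptide
    twist, registry distances, tyrosine ring stacking, hydrogen-bond
    censuses, sheet content and end fraying. Includes the encoded study
    design (simulation plan and reference stability outcomes), connectivity
    clustering, event detection with persistence filtering, an ordered
    oligomer census with lifetimes, and multi-model PDB trajectory I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
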