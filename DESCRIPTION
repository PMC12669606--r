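Package: ionpore
Title: Single-Channel Pore Characterization from Bilayer Recordings and
    Ion-Permeation Trajectories
Version: 0.1.0
Authors@R:
    person("Pore", "Biophysics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to characterize ion-conducting membrane pores from
    planar-bilayer voltage-clamp recordings and from molecular-dynamics
    style ion trajectories. Provides closed-form biophysical relations
    (Nernst equilibrium potentials, the Fatt-Ginsborg bi-ionic
    permeability ratio, a two-ion Goldman-Hodgkin-Katz permeability
    estimate), a seed-deterministic synthetic recording generator
    (two-state Markov gating, ohmic or saturating open-channel current,
    band-limited Gaussian noise, a four-pole Bessel acquisition chain),
    automated level estimation and half-amplitude idealization with a
    dead time, current-voltage fitting with junction-potential
    correction and saturation detection, and transmembrane
    crossing-event accounting that converts charge flux to conductance
    and partitions current by ion species.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    Rcpp,
    data.table,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
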