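Package: condtension
Title: Surface Tension of Biomolecular Condensates from Critical Scaling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Coarse-grained Langevin dynamics of sticker-spacer associative
    polymers in slab geometry, together with the analysis chain that turns
    trajectories into condensate surface tension: the Kirkwood-Buff
    pressure-tensor route, tanh interface-profile fits, correlation lengths,
    Ising power-law fits for the critical temperature and amplitudes, and
    prediction of the full gamma(T) curve from the critical temperature and a
    single interface-width measurement via the universal amplitude ratio
    R-minus of the 3D Ising universality class. Includes synthetic-observable
    generators with known ground truth for validating every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    graphics,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
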