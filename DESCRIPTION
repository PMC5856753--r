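Package: rodcolony
Title: Agent-Based Mechanics of Rod-Shaped Bacterial Microcolony Morphogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates surface-attached microcolonies of rod-shaped bacteria
    (e.g. Escherichia coli) as spherocylinders discretized into six balls,
    growing on an adhesive substrate.  Cell-cell interactions derive from a
    Yukawa-like potential, cell-substrate adhesion from punctual worm-like-chain
    elastic links that detach above a critical force, and motion follows
    overdamped dynamics with slender-body friction.  The package also provides
    the energetics of the monolayer-to-multilayer transition (adhesive and
    repulsive energy scalings, Hertz gel-indentation cost, the closed-form
    transition size and its inversion to infer adhesion forces) together with
    the quantitative observables used to compare simulations with time-lapse
    and traction-force experiments: single-cell adhesion asymmetry, colony
    aspect ratio, substrate force grids, adhesion-focus forces, global adhesive
    stress and nematic orientational order.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
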