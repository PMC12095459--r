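Package: polarscape
Title: Noise-Induced Macrophage Polarization on Boolean-Derived Epigenetic Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study macrophage polarization as noise-driven motion on a
    Waddington (epigenetic) landscape derived from a Boolean regulatory
    network. Provides synchronous Boolean network simulation with exhaustive
    and sampled attractor and basin enumeration, phenotype labelling of
    attractors, overexpression/knockout perturbation scans, construction of a
    min-of-paraboloids potential from embedded attractors (basin size sets
    well steepness), mollified gradients, mountain-pass (saddle) location,
    stochastic simulation of the resulting gradient system as a
    reaction-diffusion field with additive white or colored noise (and its
    zero-dimensional reduction), and analysis of basin occupancy, transition
    events, polarization itineraries, and first-exit times versus noise
    magnitude.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
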