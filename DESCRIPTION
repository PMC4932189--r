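Package: mdeflux
Title: Dispersal-Event Flux Through Time from Divergence-Time Credibility Intervals
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Meta-analysis of biotic interchange through time from dated
    phylogenies. Bins 95% highest-posterior-density (HPD) divergence-time
    intervals of inferred dispersal events into one-million-year slices to
    obtain the maximal number of observed dispersal events per Myr (MDE),
    smooths the resulting series with a sliding-window mean, truncates the
    recent past where avian sampling bias dominates, and detects shifts in
    dispersal dynamics with a divisive hierarchical (e-divisive) multiple
    change-point algorithm built on the Szekely-Rizzo energy divergence with
    within-segment permutation significance testing. Includes a synthetic
    event-table generator (piecewise-constant dispersal intensities,
    age-dependent dating uncertainty) for benchmarking change-point recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
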