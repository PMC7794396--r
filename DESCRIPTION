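Package: otostream
Title: Sound-Evoked Steady Streaming and Particle Transport in a
    Two-Chamber Cochlea Model
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates acoustic steady streaming in a two-dimensional,
    two-chamber model of the cochlea and its use for transporting
    drug-carrying nanoparticles along the basilar membrane.  A WKB
    travelling-wave solution for the basilar-membrane velocity drives a
    frequency-domain unsteady Stokes solver on a staggered grid; Reynolds
    stresses, the oscillating-boundary slip and the Stokes drift combine
    into the time-averaged Lagrangian mean (steady streaming) flow.
    Multi-frequency tone combs with a prescribed tonotopic peak spacing
    produce extended "streaming channels"; finite-mass particle tracking
    with wall collisions predicts transport times.  A small time-domain
    Navier-Stokes solver is included as an independent numerical oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
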