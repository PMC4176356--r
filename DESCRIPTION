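Package: coilsim
Title: Brownian Dynamics of Supercoiled Polymer Rings and
    Enhancer-Promoter Contact Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Coarse-grained Brownian dynamics of closed worm-like
    bead chains with bending and torsional elasticity, for studying how
    DNA/chromatin supercoiling and site-site affinity jointly control
    enhancer-promoter contact statistics. Provides the polymer energy
    model (harmonic bonds, discrete worm-like-chain bending, a
    1-cos dihedral twist potential on parallel-transported material
    frames, soft-sphere excluded volume and truncated Lennard-Jones
    affinity wells), an overdamped Euler-Maruyama integrator with
    periodic boundary conditions and deterministic seeding, exact
    Gauss-integral writhe and twist bookkeeping (Lk = Tw + Wr),
    telegraph-signal contact analysis with dwell-time statistics and
    moving-block bootstrap errors, scenario generators for supercoiled
    plasmids, crowded chromatin loops and tethered topological domains,
    and tidy/ggplot2 reporting of fraction-on surfaces and dwell-time
    profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
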