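Package: walkmmd
Title: Model-Free Comparison of Single-Particle Trajectory Sets with Learnt
    Summary Statistics and Kernel Two-Sample Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical comparison of groups of single-particle tracking
    trajectories without committing to a generative model. Trajectories are
    simulated from five canonical random-walk models (fractional and scaled
    Brownian motion, Ornstein-Uhlenbeck, continuous-time random walk, Levy
    walk), encoded into fixed-size summary-statistic vectors by a graph
    neural network trained by simulation-based inference, and groups of
    trajectories are compared with an unbiased kernel maximum mean
    discrepancy (MMD) permutation test. Includes witness-function
    interpretation of detected differences, critical-region extraction,
    classical per-trajectory descriptors (effective diffusivity, fractal
    dimension, convex hull, asymmetry), Hotelling baselines, and
    uncertainty-weighted multidimensional scaling of pairwise group
    distances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    mgcv,
    MASS
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
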