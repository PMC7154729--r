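Package: caprare
Title: Simulation and Analysis of Functional Capillary Rarefaction in
    Skeletal Muscle
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulates skeletal-muscle cross-sections with typed fibre
    mosaics, capillary networks organised into terminal-arteriole supply
    units, and matching twitch-tension / femoral-flow / arterial-pressure
    recordings; quantifies capillarisation by Voronoi capillary-domain
    morphometry within unbiased counting frames; models stochastic
    microsphere blockade of terminal arterioles and femoral ligation;
    solves steady-state tissue oxygen transport with Michaelis-Menten
    consumption and myoglobin-facilitated diffusion; and computes muscle
    fatigue-index and vascular-conductance endpoints together with the
    statistical stage (polynomial least-squares fits with confidence
    bands, one-way ANOVA with Tukey HSD and compact letter display, and
    paired t tests) used to relate perfused capillarity to fatigue
    resistance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    Matrix,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
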