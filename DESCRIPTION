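Package: glycak
Title: Kinetic Models of Glycolytic ATP Homeostasis Under Adenylate Kinase
    Equilibrium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinetic ODE models of upper glycolysis (hexokinase,
    glucose-phosphate isomerase, phosphofructokinase) coupled to ATP-consuming
    processes in human erythrocytes and resting anaerobic skeletal muscle,
    with and without the adenylate kinase (AK) equilibrium that ties ATP, ADP
    and AMP together under adenine-nucleotide pool conservation. Computes
    steady-state glycolysis characteristics (net ATP production versus clamped
    ATP), locates and classifies steady states, builds bifurcation diagrams
    over ATPase activity with saddle-node bracketing, quantifies ATP
    stabilization by metabolic control coefficients, decomposes the transient
    contribution of the adenylate kinase reaction to ATP production after
    ATPase steps, and analyses energy-charge and pool-invariance properties.
    Includes a linear toy model of ATP production and consumption, a scenario
    generator for parameter sweeps and regulation knockouts, and CSV/JSON
    exporters with a thin command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
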