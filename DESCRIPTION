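Package: afmindent
Title: AFM Force-Curve Analysis and Prestressed Membrane Indentation Mechanics
Version: 0.1.0
Authors@R:
    person("AFM Indent", "Developers", email = "afmindent@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing atomic force microscopy (AFM) indentation
    experiments on adherent cells under substrate stretch. Generates seeded
    synthetic force-distance curves with the four-stage approach morphology
    (non-contact, linear elastic loading, membrane puncture force drop,
    substrate stiffening); extracts contact points, Hertz elastic moduli,
    A-B loading slopes and membrane-insertion events from single curves;
    aggregates per-condition insertion statistics and histograms; and runs a
    quasi-static finite-element simulation of a conical tip indenting a
    prestressed membrane supported by an orthogonal actin filament and stress
    fibre network, including the geometric (stress) stiffness of prestress and
    an analytic tensioned-beam reference solution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
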