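Package: onhmorph
Title: Optic Nerve Head OCT Morphometry and Diurnal Cohort Statistics
Version: 0.1.0
Authors@R:
    person("ONH", "Morphometry Contributors", email = "onhmorph@example.org",
           role = c("aut", "cre"))
Description: Computes optic nerve head (ONH) morphometry from segmented
    radial and circular optical coherence tomography (OCT) scans: Bruch's
    membrane opening (BMO) minimum rim width, BMO height relative to a 4-mm
    Bruch's membrane reference line, anterior lamina cribrosa surface depth,
    best-fit BMO ellipse area, total retinal thickness maps and annuli, and
    circumpapillary layer thicknesses.  Companion physiology routines derive
    mean arterial pressure, hydrostatically corrected mean ocular perfusion
    pressure, and optic nerve sheath diameter from ultrasound traces.  A
    cohort-statistics layer implements within-subject repeatability
    (Sw, CV, 2.77*Sw), change-from-baseline tables, repeated-measures ANOVA
    with Dunnett many-to-one contrasts against a 7 a.m. baseline, and the
    regression analyses used in diurnal ONH studies.  Analytic ONH phantoms
    and a diurnal seated/head-down-tilt cohort simulator provide ground truth
    for end-to-end validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
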