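Package: rollnav
Title: Rolling-Regulated Sperm Navigation: Beat Asymmetry, Rheotaxis and
    Wall Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Biophysical models and track statistics for mammalian sperm
    motility regulated by rolling. Constructs asymmetric flagellar beating
    patterns (Fourier ansatz with a zeroth harmonic), maps beats to planar
    swimming kinematics through resistive force theory, models rolling as a
    stochastic sign-switching process, and derives its consequences for
    progressive motion, Adler-equation rheotaxis, far-field Stokeslet
    swimmer-wall hydrodynamics, near-field wall dynamics with an S1-S4
    interaction taxonomy, and diffusive circular surface exploration with
    intermittent search. Includes a synthetic-track generator emulating
    microscopy data and the corresponding measurement stack (circle fitting,
    center mean-square displacement, curvature signal-to-noise ratio,
    wall-detention metrics, thermal bounds).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
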