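Package: emrnet
Title: Entropy-Maximization Recurrent Network Model of Early Auditory
    Processing and Tinnitus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates an overcomplete recurrent rate network trained by
    regularized entropy maximization to represent synthetic auditory
    stimuli on a log-frequency axis. Provides the stimulus generator,
    steady-state solvers (Newton-Raphson with Euler fallback), the
    regularized entropy-maximization objective and its analytic gradients,
    the three-phase training schedule, and a criticality measurement
    battery (spectral radius, convergence time, population vector,
    pairwise correlations). Includes the sensory-deprivation experiment in
    which band attenuation of inputs drives the recurrent gain toward the
    critical point and produces stimulus-independent, single-peaked
    activity in the deprived frequency zone, together with simulated
    audiograms and connectivity profiling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
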