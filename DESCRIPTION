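Package: movehold
Title: Move-to-Hold Integration Analysis of Limb Motor Commands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing the serial move-to-hold integrator hypothesis of
    limb postural control: event-aligned preprocessing of per-trial EMG and
    force recordings, the move/hold decomposition and the integration statistic
    relating the change in hold-period output to the time-integral of the
    preceding move-period output, two-dimensional spring-field modelling of
    postural restoring forces with bootstrap null-point estimation, curl and
    zero-integral force-field adaptation analysis including endpoint-error and
    integration-gain estimators, and a forward simulator of the integrator
    architecture that generates synthetic cohorts with ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    pracma,
    jsonlite
Suggests:
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
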