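Package: relcen
Title: EEG Channel Selection with Iterative Centered Relief
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Channel selection for motor-imagery electroencephalography (EEG)
    built around an iterative, center-targeted variant of the Relieff feature
    weighting algorithm. Epoched multichannel recordings are spatially
    sharpened with a surface Laplacian filter, decomposed into 13 overlapping
    constant-Q sub-bands between 5 and 35 Hz, and summarized per trial as
    min-max normalized Hilbert-envelope band powers. Features are weighted by
    Relieff with target samples taken in order of distance to their class
    center, the lowest-weight features are removed, and the process repeats
    until the feature set is empty; the smallest channel set reaching the best
    cross-validated support-vector-machine accuracy is reported as optimal.
    Includes readers and writers for EDF and a delimited matrix format, a
    bundled 10-20 montage with Laplacian neighbor sets, a synthetic generator
    of motor-imagery-like EEG with planted event-related desynchronization,
    and stratified cross-validation reporting utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
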