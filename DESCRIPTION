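Package: nodsync
Title: Behavior-Based Synchronization of Eye-Tracking and Motion-Capture Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Device-free synchronization of a head-mounted eye tracker with an
    optical motion-capture system using a deliberate head nod performed at the
    start (and optionally the end) of each recording. The nod produces a sharp
    synchronous dip in the vertical head-marker trajectory and in the vertical
    pupil coordinate; each stream is gap-filled, differentiated with a
    zero-phase Butterworth smoothing filter, prefix-zeroed, and z-scored, after
    which a thresholded peak-picking step locates the velocity minimum of the
    nod and the frame before the following zero-crossing becomes the stream's
    synchronization point. The inter-stream offset trims the earlier-started
    stream, and a second nod at the end of the recording quantifies clock
    drift. Includes readers for motion-capture TSV and eye-tracker text
    exports, a two-stream session simulator with known ground truth,
    broom-style tidiers, ggplot2 visualisations, and command-line entry
    points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
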