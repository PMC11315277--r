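Package: kinectqa
Title: Quality Assurance Metrics for Markerless Body-Tracking Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality-assurance pipeline for Azure Kinect DK depth recordings
    and Azure Kinect Body Tracking SDK skeleton output. Implements per-pixel
    random error of repeated depth measurements over regions of interest with
    invalid-pixel accounting, the sliding-window-centroid mean distance error
    (MDE) of joint trajectories, inter-joint distance series such as stance
    width, and a nonparametric comparison protocol (Kolmogorov-Smirnov
    normality screening, Kruskal-Wallis and Friedman omnibus tests with
    Bonferroni-corrected pairwise post-hocs) for comparing recordings across
    lighting conditions or repeated sessions. A synthetic-data module
    generates depth-frame stacks and static-pose joint trajectories with the
    sensor's noise structure (per-pixel Gaussian depth noise, invalid-pixel
    dropout, moving drop-out blobs, per-joint jitter, start-up transients,
    transient position peaks) so the whole pipeline is testable without large
    deposited recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    nortest,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
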