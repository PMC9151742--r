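Package: firetrackr
Title: Object-Based Tracking of Fire Events from Active-Fire Detections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tracks the growth of individual fire events from half-daily
    satellite active-fire detections. Detections are clustered by spatial
    proximity at each overpass and appended to existing active fire objects
    or used to seed new ones; fire perimeters are delineated with an
    alpha-shape concave hull plus a half-pixel buffer, active fire fronts are
    extracted as perimeter segments near newly detected pixels, and fires are
    classified by dominant land cover and 1000-hr dead fuel moisture. The
    package writes a multi-layer fire-events data suite (restartable state
    serialization, half-daily snapshots, large-fire time series, and season
    summaries), scores tracked perimeters against reference perimeter sets
    with confusion-matrix metrics (accuracy, precision, recall, IoU, F1),
    and ships a seeded synthetic-detection simulator (elliptical fire spread
    sampled as imperfect gridded detections, persistent static hotspots,
    synthetic land-cover and fuel-moisture rasters) so the full system can be
    exercised offline with known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    grDevices,
    stats,
    utils
Suggests:
    geosphere,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
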