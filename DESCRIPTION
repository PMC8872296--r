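Package: metropm
Title: Surrogate-Assisted Fine-Particulate Exposure Assessment in Subway Stations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trajectory-resolved assessment of pedestrian PM2.5 exposure in an
    underground subway station with platform screen doors. Simulates pedestrian
    itineraries and particulate sources with a queueing waypoint model, computes
    steady depth-averaged concentration fields per airflow-organization state
    with an upwind finite-volume advection-diffusion solver, fuses the state
    fields with sparse measurements through clustered epsilon-SVR surrogates
    tuned by particle swarm optimization, and integrates per-pedestrian
    exposure along 1-s trajectories, comparing against the microenvironment
    average-concentration method.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
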