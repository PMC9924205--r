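Package: leanclinic
Title: Lean Outpatient Capacity Planning by Min-Max Integer Programming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the reallocation of outpatient examination services between
    senior and associate senior doctors as a min-max integer program: each
    doctor has a booked caseload, per-patient examination and diagnosis
    durations, and a working-time cap, and the optimizer transfers integer
    numbers of examination services so that the largest post-transfer working
    time (LWT) is minimized. Provides an exact solver-free optimizer (integer
    binary search with a greedy feasibility certificate), a mixed-integer
    programming backend for cross-checking, efficiency and patient-flow
    metrics (RTS, RTDS), before/after workload reports, deterministic
    generators for the benchmark instances, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
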