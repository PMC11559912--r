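Package: caselogr
Title: Benchmarking Resident Clinical Experience from EHR Encounter Exports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the volume and variety of outpatient clinical
    experience accrued by residency trainees from flat-file electronic
    health record (EHR) encounter exports. Maps ICD-10 visit diagnoses to
    curated diagnostic groups via an exact/prefix/range code-set grammar,
    counts each trainee's unique qualifying visits per group, benchmarks
    individuals against class averages and graduated-resident averages,
    and renders percent-of-benchmark radar charts that expose training
    gaps. Ships a calibrated synthetic encounter generator so the whole
    pipeline is testable without access to protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
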