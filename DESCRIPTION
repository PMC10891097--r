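Package: sonoquant
Title: Quantitative Analysis of Implantable-Ultrasound Blood-Brain-Barrier
    Disruption Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis toolkit for clinical studies of
    blood-brain-barrier (BBB) disruption by a nine-emitter implantable
    low-intensity pulsed ultrasound array. Provides cylindrical
    region-of-interest rasterization on voxel grids, automated per-emitter
    BBB-opening grading from pre/post-gadolinium T1-weighted MRI,
    exponential BBB-closure kinetics with bootstrap confidence intervals,
    in-field tumor-growth and distance-to-emitter progression analyses,
    exact single-arm binomial design statistics (objective performance
    criterion testing, Clopper-Pearson intervals, power), a
    Rayleigh-Sommerfeld acoustic field simulator for the emitter array,
    and a synthetic MRI study generator that exercises the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
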