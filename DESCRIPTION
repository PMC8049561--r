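Package: qpadmix
Title: Simulation-Based Evaluation of qpAdm Admixture Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the qpAdm/qpWave family of admixture tests from first
    principles: f4-statistics with weighted block-jackknife covariances,
    rank-constrained generalized least-squares fitting of the f4 matrix,
    admixture weights with jackknife standard errors, and likelihood-ratio
    P-values for admixture-model plausibility. Ships a coalescent
    synthetic-data stage (driving 'msprime' through a bundled Python helper)
    that reproduces a 16-population benchmark demography with two admixture
    pulses, plus ancient-DNA degradation operators (down-sampling,
    missingness, pseudohaploidization, deamination damage, heterozygote
    ascertainment, sample-size reduction), base and rotating model-comparison
    protocols, and figure-level experiment drivers for P-value calibration,
    admixture-proportion accuracy, and failure-mode studies.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with msprime and numpy, available as
    'python' on the PATH (used only by the simulation stage).
Config/testthat/edition: 3
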