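Package: meioscope
Title: Crossover Mapping, Interference Statistics and Aneuploidy Detection for F2 Populations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing meiotic recombination in F2 populations
    genotyped by low-coverage sequencing. Provides a meiosis simulator with
    tunable crossover interference (stationary gamma renewal placement of
    class I crossovers plus a Poisson class II pathway), genotype-table
    filtering, a deterministic sliding-window crossover caller,
    coverage-based per-chromosome and per-arm ploidy classification,
    cis-double-crossover distance statistics (randomised expected-distance
    null, gamma fits with bootstrap shape comparison, coefficient-of-
    coincidence profiles), windowed crossover landscapes, and a closed-form
    recombination-frequency estimator for fluorescent-seed counts.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus
Config/testthat/edition: 3
biocViews: Genetics, SNP, Sequencing, Coverage
RoxygenNote: 7.3.3
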