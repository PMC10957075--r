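Package: abliab
Title: Antibody Sequence Liability Profiling with Low-Risk Flags
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects chemical liability motifs (deamidation, isomerization,
    fragmentation, oxidation, glycosylation, unpaired cysteines, integrin
    binding) in IMGT-numbered antibody variable domains using a codified
    liability reference, and annotates each detected liability with three
    low-risk flags: presence in the assigned human germline, prevalence at
    the same IMGT position among marketed therapeutics, and burial assessed
    from per-residue relative solvent accessibility of a paired Fv structure.
    Includes dataset-level survey summaries, flag-reduction accounting,
    benchmark statistics, and a fully synthetic fixture generator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    withr,
    jsonlite,
    ggplot2,
    generics,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
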