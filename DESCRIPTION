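Package: vulnprior
Title: Prioritization of Cancer-Type-Specific Therapeutic Vulnerabilities
    from CRISPR Dependency Screens
Version: 0.9.0
Authors@R:
    person("Vulnprior", "Developers", email = "vulnprior@example.org",
           role = c("aut", "cre"))
Description: Filters genome-wide CRISPR loss-of-function screen results
    (Chronos gene-effect scores and gene-dependency probabilities in the
    DepMap layout) down to a ranked list of druggable, cancer-type-specific
    therapeutic targets. Provides the full filtration waterfall with a
    per-stage audit, validation of targets by dependency-quartile drug
    response stratification, discovery of genetic biomarkers of dependency
    (mutation status, expression, copy number, amplicon stratification,
    survival), self-contained statistical kernels (Welch t, exact
    Mann-Whitney U, Welch ANOVA with Dunnett correction, Holm-Sidak,
    Cohen's d), and a seeded synthetic-panel generator with planted ground
    truth so the entire pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    data.table,
    survival
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
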