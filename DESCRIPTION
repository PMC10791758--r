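Package: fertREML
Title: Pedigree-Based REML Animal Models for Dairy Fertility Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation of genetic parameters for dairy-cattle fertility
    traits with pedigree-based animal models. Builds the numerator
    relationship matrix, its sparse inverse (Henderson's rules with the
    inbreeding adjustment) and Meuwissen-Luo inbreeding coefficients;
    derives interval, count and binary fertility traits (calving interval,
    days open, calving to first insemination, first insemination to
    conception, gestation length, age at first service/calving, number of
    services, 56-day non-return rate) from raw insemination and calving
    records with the usual editing rules; and fits single-trait and
    bivariate animal models with herd-year and service-sire random effects
    by average-information REML on sparse mixed-model equations, reporting
    variance components, heritabilities, genetic correlations and their
    standard errors. A Mendelian-sampling simulator generates pedigrees and
    fertility event records with known true parameters for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, Matrix
Suggests: testthat (>= 3.0.0), jsonlite, igraph, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
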