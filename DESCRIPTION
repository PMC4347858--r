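Package: wolbdyn
Title: Wolbachia Prevalence Dynamics with Parasitoid-Vectored Horizontal
    Transmission
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discrete-generation models of Wolbachia prevalence in whitefly
    populations when aphelinid parasitoid wasps act as phoretic ("dirty
    needle") vectors of the symbiont. Provides the deterministic prevalence
    recursion with imperfect maternal transmission, relative fecundity and
    cytoplasmic incompatibility extended by a horizontal-transmission step;
    fixed-point, stability and invasion-threshold analysis of the recursion;
    a stochastic individual-based simulation of the wasp contamination
    mechanism that yields an effective horizontal transmission rate; seeded
    generators for synthetic transmission, persistence, infectivity-decay
    and host-fitness experiments; and the statistical analyses used on such
    experiments (logit-scale prevalence estimation, binomial likelihood
    ratio heterogeneity tests, logistic trend tests, replicate-level fitness
    comparisons including a stratified proportional-hazards longevity
    model).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    survival,
    jsonlite,
    withr,
    ggplot2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
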