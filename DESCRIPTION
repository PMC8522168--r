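Package: AdmixWF
Title: Forward-Time Wright-Fisher Simulation of Admixed Populations
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An individual-based, forward-time extension of the Wright-Fisher
    model for simulating admixed populations from phased founder haplotypes.
    Descendant chromosomes are represented as mosaics of labelled founder
    segments, so arbitrarily dense SNV panels are carried through the
    simulation at no per-site cost; sequences are materialised only on
    output. Supports user-defined multi-wave demography with time-varying
    population sizes, sex-specific admixture proportions, Poisson
    recombination on a piecewise-linear genetic map (female-only on the X
    chromosome), Poisson de novo mutation with locus-specific rates, and
    additive natural selection that may be single- or multi-locus,
    population-, sex- and generation-specific. Emits phased haplotypes,
    local-ancestry tracks, selected-allele frequency trajectories and an
    updated variant table that can seed follow-up simulations. Includes
    closed-form validation theory (selection recursion, exponential
    ancestry-tract lengths, Poisson event counts) and a brute-force per-site
    simulator used as an independent correctness oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, Rcpp, vcfR
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AdmixWF-package.R'
    'AllClasses.R'
    'DemographicModel.R'
    'FounderPanel.R'
    'GenomeSpec.R'
    'RcppExports.R'
    'accessors.R'
    'ancestry.R'
    'fixtures.R'
    'outputs.R'
    'engine.R'
    'cli.R'
    'oracle.R'
    'theory.R'
    'vcf.R'
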