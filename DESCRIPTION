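Package: polyseg
Title: IBD Haplotype Estimation and QTL Interval Mapping in Polyploid F1 Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates identity-by-descent (IBD) parental-homologue inheritance
    probabilities in outcrossing autopolyploid F1 populations from phased
    linkage maps and SNP dosage data, using either a hidden Markov model that
    accommodates multivalent pairing and double reduction (offspring ploidies
    2, 3, 4 and 6) or a fast heuristic suitable for any ploidy. The IBD
    probabilities drive genome-wide QTL interval mapping with experimental
    blocks, genetic co-factors, automatic multi-QTL searches and permutation
    significance thresholds, as well as exploration of QTL allele
    configurations by BIC. Meiotic diagnostics include predicted pairing
    (valency) counts, double-reduction landscapes, chi-square tests of
    preferential chromosome pairing, recombination detection, outlier
    screening, the genotypic information coefficient and IBD-informed dosage
    imputation. A built-in forward simulator of polysomic meiosis generates
    ground-truth data for any supported cross.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
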