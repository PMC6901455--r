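Package: geiscan
Title: Additive Gene-Environment Interaction Scans for Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Genome scan for additive-scale interaction between SNPs and a
    binary environmental exposure in case-control data. Each SNP is coded
    under a dominant model, individuals are partitioned into the four
    joint-exposure combination groups (carrier x exposed), and a
    covariate-adjusted logistic regression yields group odds ratios from
    which the attributable proportion due to interaction (AP) is estimated
    with delta-method confidence intervals and p-values, followed by
    Benjamini-Hochberg FDR control and LD-based priority pruning of lead
    signals. Includes PLINK BED/BIM/FAM and plain-TSV genotype input,
    smoking-exposure harmonization, LD pruning with ancestry principal
    components, a no-genetics exposure association baseline with optional
    stratification, and a synthetic cohort generator with known interaction
    structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
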