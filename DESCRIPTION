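Package: lineageRank
Title: Rank-Based Lineage-Specificity Scoring for Multi-Group Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies transcripts specific to a developmental lineage from
    multi-group expression microarray data. Given probe-by-sample intensity
    matrices and a sample sheet designating target-lineage and reference
    groups, the pipeline log2-transforms and quantile-normalizes intensities,
    summarizes groups, computes per-probe fold changes against the
    maximum-expressing reference group, tests differences with an
    empirical-Bayes moderated t-statistic and Benjamini-Hochberg false
    discovery rate control, ranks probes within each target category, assigns
    threshold-based consensus groups, and aggregates category ranks into a
    rank-sum consensus score that prioritizes lineage-specific genes.
    Includes sample-level quality control (principal component scores,
    Spearman correlation, hierarchical clustering) and a synthetic-data
    generator with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), limma, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
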