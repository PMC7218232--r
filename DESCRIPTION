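Package: toxomix
Title: Multi-Omics Systems Toxicology Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis toolkit for five-modality inhalation
    systems-toxicology studies (mRNA, miRNA, protein, metabolite, lipid).
    Provides per-modality preprocessing and empirical-Bayes moderated-t
    differential abundance, causal-network perturbation amplitude scoring with
    permutation companions and relative biological impact factors, a
    latent-factor model for missing-block multi-omics integration with a
    sparse generalized canonical correlation cross-check, assembly of an
    aggregated gene-metabolite-miRNA interaction network, prize-collecting
    Steiner forest module extraction with grid search and a randomized
    ensemble, edge-betweenness clustering, preranked gene-set enrichment and
    Fisher overrepresentation, plus a calibrated synthetic-study generator
    that emulates the study design the pipeline expects.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    igraph,
    jsonlite,
    yaml,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
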