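Package: dualvae
Title: Cross-Modality Translation of Single-Cell Profiles with Dual-Aligned Variational Autoencoders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Translates single-cell profiles between measurement modalities
    (chromatin accessibility to transcriptome and back, transcriptome to
    surface proteome, control to perturbed transcriptome) with a pair of
    variational autoencoders coupled through a shared latent translator and
    adversarially aligned by per-modality discriminators. Includes the
    modality-specific pre-processing transforms (median-depth normalisation
    and highly variable gene selection for RNA, binarisation plus TF-IDF for
    ATAC peaks, centered log-ratio for antibody-derived tags) together with
    their inversions, cell-type and cluster based training-set augmentation,
    proportion-matched pairing of unpaired datasets, exact optimal-transport
    pairing of control and stimulated cells, a clustering- and
    classification-based evaluation suite, and a synthetic multi-omics data
    generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    graphics,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    e1071,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
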