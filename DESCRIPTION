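Package: PatchAL
Title: Pool-Based Deep Active Learning for Histopathology Patch Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Label-efficient training of binary image-patch classifiers by
    pool-based active learning. A conditional VAE-GAN backbone (encoder,
    class-conditioned generator, discriminator, classifier) is trained
    jointly under a six-term composite loss; unlabeled candidates are scored
    by BALD mutual information estimated with Monte Carlo dropout, by a
    centroid-distance diversity score in latent space, and by their min-max
    scaled combination; selected samples are labeled by a (simulated)
    oracle, reconstructed by the generator, and folded back into the
    labeled pool for retraining. Includes a synthetic two-class
    histology-like image generator with screening, dihedral-group
    augmentation and stratified splitting, plus evaluation tools (AUC,
    confusion metrics, learning curves, convergence fractions, classical
    MDS embeddings) and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
biocViews: Classification, ActiveLearning, Pathology
RoxygenNote: 7.3.3
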