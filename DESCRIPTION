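Package: molcluster
Title: Deep Clustering of Small-Molecule Libraries via Autoencoder Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for unsupervised clustering of chemical
    libraries given as SMILES strings. Molecules are featurized into global
    molecular descriptors and one-hot atomic/bond feature matrices; local
    features are aggregated per molecule by first-principal-component scores
    and reduced dataset-wide by PCA; the fused feature table is embedded with
    an autoencoder or variational autoencoder; embeddings are clustered with
    K-means or BIRCH; the cluster count is selected by a Silhouette scan; and
    results are validated with Silhouette, Calinski-Harabasz and
    Davies-Bouldin internal indices and visualized via t-SNE scatter plots,
    ECFP Tanimoto similarity matrices and atom-weighted similarity maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    yaml
Config/testthat/edition: 3
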