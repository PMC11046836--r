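Package: softalign
Title: Embedding-Based Soft Alignment and Annotation of Protein Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Residue-level protein homology detection from per-residue
    embeddings. Builds cosine-similarity matrices between query and subject
    residues, classifies mutual and secondary best matches, filters spurious
    off-diagonal matches, rescues single identical-residue gaps, and chains
    the retained matches into a maximum-score soft alignment with a
    significance threshold. Includes exact cosine k-nearest-neighbour
    retrieval over mean-pooled embeddings, a combinatorial null model for
    chance gap-free diagonal runs, an annotation-transfer pipeline with
    two-stage neighbour escalation, a deterministic synthetic embedding
    provider, and fixture generators with planted homologous blocks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
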