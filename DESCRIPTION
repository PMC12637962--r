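Package: suppbioc
Title: Convert, Categorize, and Search Supplementary-Material Tables in BioC Format
Version: 0.1.0
Authors@R:
    person("Maintainer", "Unattributed", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for turning heterogeneous supplementary-material files
    (delimited text, OOXML spreadsheets and word-processor documents, slide
    decks, PDFs, plain text, and archives) into structure-preserving
    BioC-XML/BioC-JSON collections; for categorizing the extracted tables by
    embedding, k-means clustering with principled cluster-count selection
    (elbow, gap statistic, silhouette), and nearest-neighbour assignment with
    an "Other" fallback; and for serving type-filtered, cosine-ranked semantic
    retrieval over the resulting index, including pre-ranked neighbour lists
    and a small local query service. A seeded synthetic-corpus generator with
    full ground truth makes the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
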