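---
title: "suppbioc: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{suppbioc: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suppbioc)
```

# The problem

Most of the data behind a biomedical article lives in its supplementary
materials (SM), and most of that data is tabular — yet it is distributed as
CSVs, OOXML spreadsheets and word-processor documents, slide decks, PDFs,
plain text and archives, none of which search engines index. `suppbioc`
implements a complete pipeline for this situation: convert SM files into a
standardized, structure-preserving BioC representation; categorize the
extracted tables semantically; and serve type-filtered, cosine-ranked
retrieval over the result. This vignette records the models, the tunable
parameters, and the places where the design was genuinely open.

# The BioC table encoding

BioC is a community XML/JSON vocabulary for text collections (documents,
passages, annotations, key–value infons). It has no canonical table schema,
so ours is a documented convention:

* one passage per table; the passage **text** is the row-major linearization
  of the grid, TAB between cells, NEWLINE between rows — minable as plain
  text by any downstream tool;
* each cell carries an annotation with `row`/`col` infons and a character
  span into the passage text, so the grid is recovered **from the spans, not
  by splitting the text** — cells containing tabs or newlines survive;
* empty cells are empty strings with zero-length spans, never absent; a
  table with `n_rows × n_cols` cells always has exactly that many
  annotations;
* offsets are 0-based **character** (not byte) offsets with half-open spans
  (BioC deployments differ; byte offsets would be encoding-dependent);
* captions are separate `table_caption` passages immediately preceding their
  table, linked by a `caption_for` infon;
* document text is the newline-separated concatenation of passage texts,
  which fixes every offset deterministically.

Both codecs canonicalize infon order (reserved keys first, then
lexicographic), making the writers pure functions of the model:
writing the same collection twice is byte-identical, and
XML → model → JSON → model → XML reproduces the original bytes. One
limitation is inherited from XML itself: carriage returns in passage text
are rejected at validation, because conforming XML parsers normalize line
endings and would silently break round-tripping.

# Format extraction

Media classes are detected extension-first with magic-byte
tiebreak/fallback: a `.txt` whose bytes begin with a ZIP signature is an
archive; OOXML extensions legitimately carry the ZIP signature and keep
their class; unknown extensions with undecodable content are `non_textual`
and are never passed to an extractor.

Decisions the formats forced:

* **Delimited text** is parsed by an RFC-4180 state machine written for this
  package (quoting, embedded delimiters/newlines, doubled quotes), with the
  delimiter sniffed over comma/tab/semicolon by the most consistent modal
  column count across the first 20 records. Ragged rows are right-padded
  with empty cells rather than rejected — padding maximizes the conversion
  rate, which is the pipeline's point. A bare trailing empty record is
  indistinguishable from a terminating newline under RFC-4180; we follow
  `read.csv` (trailing newline ends the last record).
* **Spreadsheets**: one table per non-empty sheet, grid bounded by the
  minimal rectangle covering all non-empty cells, merged ranges expanded by
  duplicating the anchor value (duplication keeps grids rectangular), all
  values rendered as text (integers plainly; other numerics as the shortest
  round-tripping decimal).
* **Word-processor documents**: paragraphs and tables in document order;
  horizontal merges (`gridSpan`) and vertical merges (`vMerge`) expanded by
  value duplication.
* **PDFs are the deliberate exception**: tabular structure is *not*
  reconstructed — PDF gives no reliable row/column semantics — so PDF input
  yields raw text paragraphs only, and the test suite asserts that no table
  object ever comes out of a PDF. The bundled extractor handles uncompressed
  text streams (one paragraph per `Tj`/`TJ`); FlateDecode or encrypted
  streams are recorded as conversion failures rather than mis-extracted.
* **Archives** (ZIP/TAR/GZ) expand recursively to depth 3 by default, member
  names prefixed with the archive path; a 1 GiB total-expansion ceiling
  guards against archive bombs (mirroring the pipeline's database-import
  cutoff for files over 1 GB).
* **Encodings**: UTF-8 first, then a byte-level binary screen, then Latin-1
  as last resort; the chosen encoding is recorded in the document infons.

Failures are data, not errors: a corrupt container becomes a document with
`conversion_status = "failed"` and the corpus-level `conversion_report`
conserves counts (`n_converted + n_failed = n_total`, success rate 1.0 for
an empty corpus by convention).

# Embeddings and cosine geometry

Tables are linearized (caption, then cells joined with spaces, rows joined
with `" | "`, truncation only at cell boundaries) and encoded to fixed
dimension **d = 768** by default — the width of the production biomedical
sentence encoder this design targets. Encoders are pluggable by registry
name; nothing in the package downloads model weights. The built-in fixture
encoder is a deterministic signed bag-of-tokens hasher (lowercase, split on
non-alphanumerics, 32-bit polynomial hash into d buckets with ±1 signs, L2
normalization). It is not a semantic model, but it has exactly the
properties the pipeline's correctness rests on: determinism across sessions,
order-invariance, unit norm, and near-orthogonality for disjoint
vocabularies (|cos| < 0.15 at d = 768 is asserted in the tests). Empty text
encodes to the zero vector, and cosine involving a zero vector is defined as
0 so that rankings stay total.

The production encoder family is a dual-encoder (separate query/article
models); which encoder embedded the tables is not something we could pin
down, so the package defaults to a single shared encoder with both slots
exposed.

# Categorization

The seed input is a labeled table set: free-text category labels attached to
table embeddings (in the original setting these labels come from an LLM
pass; here they are an input artifact, never computed). Clustering is
**frequency-weighted k-means** by default: each distinct label contributes
one point (the mean of its tables' embeddings) weighted by its count — our
reading of grouping categories "based on their count and the semantic
similarity"; plain unweighted table-level clustering is available. Vectors
are L2-normalized, so Euclidean k-means centroids are compatible with cosine
geometry. The implementation is in-package (k-means++ initialization,
`n_init` restarts keeping the best WCSS, empty clusters repaired by
reseeding to the farthest point, every stochastic step seeded) because the
contract — weights, determinism, warm starts — is more specific than
`stats::kmeans` offers. On instances small enough to enumerate every
partition (n ≤ 8) the restarts provably reach the exhaustive optimum in the
seeded test suite.

**Choosing k** uses three curves computed on one grid: WCSS (elbow = maximum
discrete second difference, interior points only), the gap statistic
(uniform bounding-box references, the same B seeded draws reused across k,
standard one-standard-error rule), and mean silhouette (argmax; singleton
clusters contribute 0). `select_k` takes the median of the three votes with
ties toward smaller k — our operationalization of "the curves flatten".
Two structural notes:

* the median vote **cannot return k = 1**: silhouette requires ≥ 2 clusters
  and the second difference needs interior points, so only the gap vote can
  say "no cluster structure". For a single tight blob the gap rule does
  select k = 1 (tested); the vote is meaningful only for multi-cluster data.
  The full report is always emitted so users can override (e.g. pin k = 40
  to mirror a known production configuration).
* gap-statistic benchmarks use tight blobs (σ = 0.05) at seeded random
  centers with pairwise separation ≥ 1 in a `[0, 4]³` box. Exactly
  equidistant center configurations (simplex or cube corners) are avoided
  deliberately: there, the data's dispersion tracks the uniform reference at
  every k below the truth and the one-standard-error rule fires almost
  immediately — a known property of the statistic, not an implementation
  artifact.

The WCSS curve in the k-selection report is guaranteed non-increasing in k
by warm-starting each k from the previous fit plus the farthest points.

**Naming and codes**: each cluster is represented by its most frequent raw
label (ties lexicographic). Codes come from an editable registry TSV
shipping 14 standard entries (`GPED` = Gene Expression Data, `CPC` = Cohort
and Patient Characteristics, ...; two registry codes are historically 2
letters); labels absent from the registry get a generated 4-letter
consonant-preferring code with digit suffixing on collision. `OTHR` is
reserved for the fallback and never assigned to a real cluster.

**Assignment** is 1-nearest-neighbour by cosine against the categorized seed
tables (ties to the smaller table id); an optional centroid mode compares
against cluster centroids instead — the two readings of the published
pipeline description disagree, and we implement the explicit one with the
other as an option. If the best similarity falls below **tau** the table is
`OTHR`. The original work reports only that ~1% of tables were unassignable,
not the criterion; the default is tau = 0.30 for the fixture encoder,
`calibrate_tau()` sets tau from a target Other-fraction on a calibration
set, and the Other-fraction is monotone non-decreasing in tau by
construction.

# Retrieval

The index holds one entry per table (embedding, code, shape), ordered by
(article, filename, table id), persisted as a single versioned JSON file —
rebuildable from the corpus at any time. All rankings are **exact** cosine
computations; pre-ranked neighbour lists store the top min(1000, n−1)
matches per table (ties by entry key, owner excluded). Query mode filters
entries to the requested category code — registry codes plus any generated
codes present in the index are valid — and scores each article by the
maximum cosine over its filtered tables ("max" rather than "mean" because
the interface surfaces *articles with the highest similarity*); table mode
unions the file's neighbour lists, deduplicates by key keeping the maximum,
and truncates to 1000. The fetch endpoint enforces the service limits: at
most 50 article ids per request and an `attachment` flag on any response
whose serialized UTF-8 BioC-JSON body exceeds 5 MB. PMIDs and PMCIDs are
treated as opaque keys in one namespace; live id conversion belongs to the
production resolver, not this artifact.

# The synthetic corpus, and what a green test does not establish

`generate_corpus()` emits a PMC-like tree (`article/filename`) of CSV/TSV,
minimal OOXML spreadsheet and word-processor containers, tab-delimited plain
text, single-page uncompressed text PDFs and ZIP archives, with cells drawn
from per-category vocabularies, plus full ground truth (media classes,
grids, labels, planted corruption counts). Defaults: 50 articles, 5
categories with disjoint 60-token vocabularies, 1–3 files per article, 5%
planted failures, 10% archives — a small but structurally faithful stand-in
for a real SM corpus. Corruption is planted by truncating container formats
at a random byte (truncation provably breaks ZIP/OOXML/PDF trailers;
truncated delimited text would still parse, so text files are never chosen
as corruption targets). Generation is deterministic: the same spec yields a
byte-identical tree, which is why archives are written by an in-package
store-only ZIP writer with fixed timestamps rather than an external tool.

What the generator does **not** emulate: real biomedical vocabulary
distributions, overlapping category semantics (an `overlap` knob exists for
stress tests, with no accuracy guarantee), formatting pathology beyond
truncation, scanned PDFs, legacy binary Office formats. Consequently a green
end-to-end test establishes that the machinery is correct — structure
preservation, exact accounting, exact retrieval, parameter recovery under
clean separability — not that any particular accuracy holds on real PMC
data with a real encoder.

# Numerical and interface choices

* Zero-vector cosine = 0; empty text → zero vector (keeps ranking total).
* k-means tolerance 1e-10 on the WCSS decrease, 100 Lloyd iterations cap,
  10 restarts for final fits (5 inside k-selection scans).
* Reference WCSS values are floored at 1e-300 before logs so the gap values
  stay finite on any non-degenerate input; all-identical data is an error.
* Exact FP ties in rankings are broken by entry key / article id / smaller
  table id, making every ranking byte-stable.
* Config files are JSON (the declared dependency set has a JSON parser but
  no YAML/TOML parser); unknown keys are rejected at load, before any work.
* The local service is a deliberately small blocking HTTP/1.0 loop over base
  R sockets with the request handler factored out as a pure function — the
  tests exercise the handler directly and one live loopback request.
* Index/model/ground-truth persistence is text (JSON) at ~15 significant
  digits; persistence is not promised to be bit-exact, rebuild-from-corpus
  is.

# Known limitations

* The PDF extractor reads uncompressed text streams only (exactly what the
  synthetic generator emits); compressed streams are honest failures.
* Spreadsheet date cells are not detected (no style parsing); they surface
  as serial numbers. The generator never emits dates.
* `convert_file()` on an archive returns a list of documents (one per
  textual member) rather than a single document; corpus-level accounting
  lives in `convert_corpus()`.
* The hashing encoder's retrieval quality statements hold for
  disjoint-vocabulary fixtures; semantic retrieval quality requires plugging
  in a real biomedical encoder via `register_encoder()`.
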