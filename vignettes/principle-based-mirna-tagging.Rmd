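---
title: "Statistical principle-based recognition and normalization of miRNA mentions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical principle-based recognition and normalization of miRNA mentions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spba)
```

## The problem

MicroRNAs (miRNAs) are ~22-nt regulatory RNAs whose names follow a loose
nomenclature — a species code, an indicator word, a numbering part, and
optional precursor and hairpin-arm suffixes — written with enormous surface
variation: `hsa-miR-181b`, `pre-miR-149`, `microRNA (miRNA)-146a`, or list
mentions such as `miR-21, 221, 128a, 128b`. This package recognizes such
mentions in scientific text and grounds them to Rfam family accessions
(`RF#####`). It is a statistical principle-based approach (SPBA): knowledge
about what a miRNA name looks like is held in a human-readable *slot
scheme*, surface patterns (*principles*) are induced from an annotated
corpus, and recognition is an edit-tolerant alignment whose scores are
estimated from corpus statistics. The approach combines the transparency of
hand-written patterns with the adaptivity of supervised learning: every
decision the recognizer makes can be read off the matched, inserted and
deleted slots and their scores.

## Slots and the knowledge scheme

A *slot* is a named lexical category. Closed-class slots carry literal term
lists (`Species` = {hsa, cel}, `Conj` = {and, or}); open-class slots carry a
recognizer pattern (`Order`, the numbering part, matches 1–4 digits, up to
two letters and an optional digit — covering `21`, `181b`, `16a1`, `128c`).
Slots form a hierarchy: `Hairpin` ("3p", "5p") generalizes to `Suffix`,
`Let` ("let", "lin" — the lethal-7 and lin-4 precursor families) to the
`miRNA` indicator slot, and `Precursor`/`Species` to `Prefix`. A token
labeled with a child slot is always retrievable under the parent, which
lets induced principles stay specific while hand-written principles may be
general. The bundled scheme (`default_slot_scheme()`) covers exactly the
slots above; it is a plain-text file users can edit and extend, which is
the point of keeping the knowledge human-interpretable.

Matching is case-insensitive throughout — recognition, statistics and the
normalization lexicon share one case-folding — so `miR`, `MIR` and `mir`
are one term. The tokenizer splits on whitespace and then splits off each
of `-`, `,`, `/`, `(`, `)` as single-character tokens. This convention is
load-bearing: insertion counts (e.g. "two insertions of `-`" for
`miR-16-2`) and the span arithmetic of strict evaluation both depend on it,
so it is pinned and tested rather than delegated to an external tagger.
Multi-token terms ("micro rna") label all covered tokens and are treated
as a single slot occurrence by principle extraction and by the aligner.

## Principle induction and the dominating-set summary

Each gold mention yields a candidate principle: the ordered sequence of
slot labels inside its span, unlabeled tokens (hyphens, commas) dropped but
remembered as "non-slot" words. Identical sequences merge with summed
support. To compress the many observed variants into a few representative
patterns, principles are vertices of a directed graph with an edge from
`p` to `q` when `q` is derivable from `p` within configured
insertion/deletion/substitution limits (`ids_criteria()`; default: up to 3
deletions, no insertions, no substitutions — a dominant may omit slots, not
the reverse). Summarization is a minimum-dominating-set problem, which is
NP-hard, so a greedy approximation is used: repeatedly select the vertex
covering the most uncovered vertices (itself plus out-neighbors). Ties
break by coverage, support, principle length, then lexicographic order,
making training fully deterministic. The exact solver exists only in the
test suite, as an oracle on graphs of up to 12 vertices, where the greedy
cover is verified to lie within the classical `(1 + ln n)` factor of the
optimum.

Each selected dominant and its dominated principles form a cluster that
records its *core* slots (present in every member), *optional* slots
(present in some), and the non-slot words of its source mentions, the
latter two with occurrence probabilities estimated from support counts.

## Scoring

All scores derive from two corpus frequencies per symbol: occurrences
inside gold mention spans and outside them.

* **Matched slot** — `Score_m(S) = λ · freq_in(S) / (freq_in(S) +
  freq_out(S))`, with `λ = 100` by default; a mention-exclusive slot scores
  exactly `λ`.
* **Insertion** — the inverse entropy `1 / H` of the inside/outside
  distribution, `H = −(p·log2 p + q·log2 q)`. A symbol never seen outside
  mentions inserts for free; a symbol never seen inside cannot be inserted
  (infinite penalty, rejecting the candidate). Between the endpoints the
  penalty is symmetric in `(p, q)` and equals 1 at maximum entropy.
* **Deletion** — `−log2` of the slot's inside probability, i.e. the matched
  score normalized by `λ` before the logarithm (without the normalization a
  score above 1 would yield a negative penalty, which would reward
  deletions).

Insertion and deletion values are non-negative penalties *subtracted* from
the candidate score; diagnostics print them negated, matching the usual
presentation of insertion scores as negative contributions. A candidate's
score is the sum of matched-slot gains minus all insertion and deletion
penalties; any infinite penalty makes it `−Inf`.

The acceptance threshold of a cluster follows the same decomposition: the
summed matched scores of the core slots, minus the deletion penalties of
the dominant's non-core slot positions, minus the probability-weighted
insertion penalties of optional slots and non-slot words. The last two
terms are the *expected* insertion cost of a typical member mention; with
the penalty sign convention they lower the threshold (an
`insertion_sign = +1` option flips them, since the printed form of the
formula is ambiguous about the orientation). Deletion penalties of
duplicate core slots (a dominant may contain `Order` twice) are charged
per non-core *position*, not per slot identity. A candidate is accepted iff
its score is at least the threshold of the cluster it matched; on a
noise-free corpus every penalty and every threshold correction vanishes,
so score and threshold coincide exactly for grammar mentions — the reason
acceptance uses `>=` rather than `>`.

## Recognition

Principle matching is implemented as dynamic programming over (token
index, slot index) with three moves — match (slot among the token's
labels), insert token, delete slot — which maximizes the candidate score
exactly; ties prefer fewer insertions, then fewer deletions, then leftmost
matches. Candidate windows are anchored on indicator-labeled tokens
(`miRNA` or descendants) and extend up to 20 tokens each way while tokens
are labeled or are non-slot symbols previously seen inside mentions; the
20-token default accommodates long conjunction lists while bounding cost.
Windows are aligned against cluster dominants only — dominated variants
are reached through deletions, which is precisely what the dominating-set
compression buys. Leading and trailing insertions are trimmed from the
reported span with their penalties refunded, so spans start and end on
matched material; overlapping accepted mentions merge, keeping the higher
score. Anaphoric bare indicators ("this miR") form candidates but score
one matched slot against a threshold that demands at least the core of
some cluster, and are filtered — by design, since resolving them would
require co-reference resolution, which is out of scope.

## Normalization

The lexicon is compiled from the tab-separated Rfam `family` table: column
1 the accession, column 2 the family id, column 4 the description (from
which miRNA-shaped names are extracted, expanding slash alternatives like
`mir-103/107`), column 11 the previous names (`\N` meaning none). Columns
are 1-based and re-pointable for other dump layouts. Names are case-folded
and hyphen/underscore→space variants added. Every name is slot-labeled and
aligned against the cluster dominants; each matched (slot, value) pair
indexes the accession, with numbering values additionally indexed under
their digit stem so `133a` can reach a family named `mir-133`. Names that
match no principle fall back to raw-token indexing.

A recognized mention retrieves candidates through its value-bearing
(open-class) slots — the numbering discriminates between families, whereas
the indicator word alone would nominate the whole lexicon — so a numbering
value absent from the lexicon leaves the mention unnormalized rather than
tying every family. Candidates are scored by a token-level alignment
against the entry's names reusing the same matched/insertion/deletion
scores; an exact numbering match gains the full matched score, a
stem-only match half of it, so exact names outrank letter variants.
Conjunction and slash mentions are split into sub-mentions sharing the
indicator tokens, each normalized independently, and the union of the
per-group top accessions is returned — the extended-corpus convention for
mentions annotated with several ids. Rfam families are not organism
specific, so no inter-species disambiguation is attempted.

## Evaluation

`evaluate_annotations()` implements strict-span micro-averaged
precision/recall/F1: a prediction counts only when its `(doc, start, end)`
exactly equals a gold annotation's; in normalization mode the predicted
and gold accession sets must additionally intersect (intersection, not
equality, because gold mentions may carry several ids, and a multi-id gold
mention counts once, not once per id).

## The synthetic corpus generator

Real annotated miRNA corpora are external resources, so the package ships
a generator (`generate_corpus()`) that emulates the statistical structure
the method assumes: mentions drawn from the grammar
`[Precursor]? [Species]? [indicator] [Order] ([Conj|,|/] [Order])*
[Suffix]?` joined with hyphens (conjunction items joined by commas, a
final "and"/"or", or a slash as in `mir-1/133a`, each item contributing
its own gold accession), embedded in filler sentences, with slot terms
and punctuation injected outside mentions as decoys at a configured noise
rate. The two filler positions flanking a mention are never replaced by
decoys: a slot term directly abutting a mention would be absorbed into
the gold span by any consistent annotation, so such text/gold
combinations are artifacts a real corpus would not contain. Defaults — 40 documents, 1–4 sentences each, 0/1/2 mentions
per sentence with probabilities 0.3/0.5/0.2, species present in half the
mentions, precursor in 0.15, suffix in 0.25, conjunction lists mostly
absent with a tail up to 3 extra items, noise rate 0.05 — were chosen once
as plausible for abstracts-style text with roughly one mention per
sentence. Hairpin-suffix and `Let` terms are deliberately never decoys, so
those slots remain mention-exclusive, reproducing the situation where a
slot attains the maximal matched score of 100. The matched toy family
table uses the real Rfam column layout, and every fifth family carries a
hyphen-free previous name to exercise the raw-token fallback. A manifest
records the generated counts for test assertions, and a fixed seed makes
regeneration byte-identical.

What the generator does *not* emulate: real tokenization edge cases
(abbreviations, unicode dashes), annotation inconsistencies, abbreviated
non-miRNA RNA names (U2, HhR) that plague figure-caption corpora, and
anaphora beyond the bare-indicator case. Passing the held-out recovery
test (micro-F ≥ 0.95 at noise 0.05 on ~230 training mentions; F = 1.0
noiseless) therefore demonstrates internal consistency of induction,
scoring, matching and evaluation — not performance on real literature.

## Numerical and design choices

* Log base 2 throughout; probabilities are plain ratios with no smoothing
  by default (a pseudo-count option exists).
* Unseen symbols: matched score falls back to `λ/2`, insertion penalty to
  a ceiling of 30, so unseen material neither silently accepts nor
  rejects.
* Problem sizes in the test suite — 100-document training corpora (~230
  mentions), 500 random alignment cases up to 8 tokens × 5 slots, 40
  random graphs up to 12 vertices, lexicons under 200 entries — were
  chosen so each oracle comparison is exhaustive yet the whole suite runs
  in about two minutes.
* The domination limits (3 deletions) reproduce the expected dominance
  relations between full mentions and their abbreviated variants; they are
  configuration, not constants.
* Thresholds are stored on clusters at train time; retraining on the same
  corpus is bit-reproducible.

## Limitations

Anaphoric and abbreviated mentions are rejected by construction; nested or
discontinuous mentions are not produced (a conjunction list is one span);
normalization targets Rfam, not miRBase, so organism-level grounding is
out of reach; and the quality of recognition on real text depends on the
slot scheme's term coverage, which the bundled default keeps minimal on
purpose — it is meant to be extended from a user's own corpus.
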