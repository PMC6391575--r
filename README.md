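# spba — statistical principle-based miRNA mention recognition and Rfam normalization

MicroRNA (miRNA) names in the literature — `hsa-miR-181b`, `pre-miR-149`,
`let-7e`, `miR-21, 221, 128a, 128b`, `miR-1/133a` — vary too much for rigid
regular expressions, yet a corpus-trained black box gives curators no way
to see *why* a span was tagged. `spba` implements a statistical
principle-based approach for people building biomedical text-mining
pipelines (database curation, literature indexing): it learns
human-readable slot-sequence patterns ("principles") from a span-annotated
corpus, recognizes mentions with an insertion/deletion-tolerant alignment,
and grounds them to Rfam family accessions (`RF#####`) through a
slot-indexed lexicon.

## The model

Tokens are labeled with **slots** from a hierarchical scheme — `Species`
(hsa, cel), the `miRNA` indicator (mir, microRNA, with `Let` for the
lethal-7/lin-4 families), the open-class numbering slot `Order` (21, 181b,
16a1), `Conj`, `Precursor`, and `Suffix` generalizing the hairpin arms
3p/5p. Each gold mention's ordered slot labels form a candidate principle;
candidates are summarized by a greedy approximation to the NP-hard minimum
dominating set on the graph whose edge p → q means q is derivable from p
within configured insertion/deletion/substitution limits.

Recognition aligns a candidate token window C against each cluster's
dominant principle, producing matched (M), inserted (I) and deleted (D)
sets, and scores

    Score(C) = Σ_{S ∈ M} Score_m(S) − Σ_{S ∈ I} Score_i(S) − Σ_{S ∈ D} Score_d(S)

with, for per-slot corpus frequencies inside/outside gold mentions,

* `Score_m(S) = λ · freq_in(S) / (freq_in(S) + freq_out(S))`, λ = 100;
* `Score_i(S) = 1 / H(S)` (inverse entropy of the inside/outside
  distribution; 0 when the symbol never occurs outside mentions, ∞ — a
  rejection — when it never occurs inside);
* `Score_d(S) = −log2 (Score_m(S) / λ)`.

A candidate is accepted iff its score reaches the cluster threshold: core
matched scores, minus deletion penalties of non-core dominant slots, minus
probability-weighted expected insertion penalties. One dominant such as
`[Precursor][Species][miRNA][Order][Conj][Order][Suffix]` thereby covers
everything from `miR-21` to eight-item conjunction lists, while a bare
anaphoric "miR" scores below threshold and is filtered.

Normalization compiles a lexicon from the Rfam `family` table (accession,
family id, description names with `mir-103/107`-style slash expansion,
previous names), indexes every name by its matched (slot, value) pairs,
retrieves candidates through a mention's numbering values, and ranks them
with the same scoring; multi-miRNA mentions are split and return the union
of per-part accessions. Evaluation is strict-span micro-averaged P/R/F.

## Worked example

Everything below is runnable as-is: the corpus is synthesized by the
package's generator, so no external data is needed.

```r
library(spba)

train <- generate_corpus(fixture_config(n_documents = 100, seed = 101))
model <- spba_train(train$corpus)
model
#> <spba_model> 10 principle cluster(s), lambda=100
#>   [Precursor][Species][miRNA][Order][Conj][Order][Hairpin]  support=2  threshold=184.889
#>   [Precursor][Species][miRNA][Order][Order][Conj][Order]  support=1  threshold=184.589
#>   ...

lex <- read_family_file(system.file("extdata", "toy_family_synthetic.txt",
                                    package = "spba"))
idx <- build_slot_index(lex, model$scheme, model$clusters, model$stats)

txt <- paste("Expression of hsa-miR-1255 was increased in tumor cells.",
             "Knockdown of miR-1/133a reversed this effect,",
             "but this miR was not resolved.")
spba_annotate(model, text = txt, index = idx)
#>   doc_id start end      surface      accessions    score
#> 1   doc1    14  26 hsa-miR-1255         RF00994 270.3526
#> 2   doc1    70  80   miR-1/133a RF00103;RF00446 288.5336
```

Both mentions are found with exact spans (0-based, half-open offsets into
the text). `hsa-miR-1255` grounds to RF00994 through the indexed numbering
value 1255; the slash mention `miR-1/133a` is split into `mir-1` and
`mir-133a` and returns both families. The anaphoric bare "miR" is
generated as a candidate but scores below its cluster threshold and is
suppressed. The alignment itself is inspectable:

```r
align_window(label_slots(tokenize("miR-16-2"), model$scheme),
             c("Species", "miRNA", "Order", "Order"), model$stats)
#> <spba_alignment> vs [Species][miRNA][Order][Order]  score=279.845
#>   M: miR->miRNA, 16->Order, 2->Order
#>   I: -, -
#>   D: Species
```

— the principle tolerates the two hyphen insertions and the missing
species prefix, which is the point of the approach.

A command-line interface wraps the same pipeline
(`exec/spba train | annotate | evaluate | make-fixtures | lexicon-stats`),
reading standoff TSV or BioC XML and writing either. See the vignette
(`vignettes/principle-based-mirna-tagging.Rmd`) for the full model
description, parameter defaults and limitations.

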