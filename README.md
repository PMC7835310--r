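# gcnbench

Amplicon sequencing of the 16S rRNA gene counts reads, not cells: a
bacterium carrying ten 16S gene copies per genome contributes ten times
the reads of an equally abundant bacterium carrying one. Dividing each
genus's read count by its mean gene copy number (GCN) — with a default,
conventionally 1.8 copies per genome, for genera without a database entry
and for reads left unidentified at genus level — is the proposed fix.
Whether that correction actually moves community profiles *closer* to the
truth can only be tested on mock communities, where the true composition
is known. `gcnbench` is a toolkit for exactly that test, aimed at
microbiome researchers deciding whether to apply GCN correction and at
methodologists probing when it fails.

## The statistic

For one community, let `y_i` be the expected (mock) relative abundance of
genus category `i` and `f(x_i)` the observed relative abundance — raw, or
GCN-corrected and renormalized. The fit of a pipeline is its residual sum
of squares over the aligned union of categories:

    RSS = Σ_i (y_i − f(x_i))²

The unidentified category participates with expected abundance 0 (mocks
contain none by construction), which is what makes the default copy
number consequential: when the identified genera carry high copy numbers
but unidentified reads are divided by only 1.8, correction inflates the
unidentified fraction and *raises* the RSS. Alongside RSS the package
computes Shannon diversity (natural log), genus richness, the
unidentified and other-genera misidentification fractions, a
Shannon-ratio exclusion rule for failed runs, and cohort means ± SE
(sample SD / √n).

## Worked example

The package ships a benchmark of eleven mockrobiota mock communities
(genus level, 16S V4) evaluated with and without GCN correction:

```r
library(gcnbench)
ref <- referenceEvaluations()
ref[["Mock-19"]]
#> CommunityEvaluation 'Mock-19'
#>   misidentified: NA 0.3074, other genera 0.0000
#>   Shannon: mock 2.3581, raw 2.4581, GCN 2.1697
#>   richness: mock 15, raw 15
#>   RSS: raw 0.8829, GCN 1.1353 -> best fit raw
aggregateCohort(ref)
#> CohortSummary over 10 communities
#>   RSS(GCN) - RSS(raw): 7.1% (SE 3.7%)
#>   richness overrepresentation: 27.4% (SE 12.1%)
#>   unidentified reads: 4.0% (SE 3.1%)
#>   other genera: 1.4% (SE 0.9%)
#>   raw fits better in 7 of 10 communities
```

Reading: Mock-19 leaves 30.7% of reads unidentified; correcting its
high-copy-number genera while dividing the unidentified mass by 1.8
worsens the fit (RSS 1.14 vs 0.88), so the raw pipeline wins. Across the
ten retained communities (Mock-12 is excluded — its sequenced Shannon
diversity is ~19% of the mock's), the uncorrected profiles fit 7.1
percentage points better on average, and sequencing overestimates genus
richness by 27.4%.

The same mechanism can be generated from scratch:

```r
sim <- scenarioMock19(depth = 1e5, seed = 7)   # 7 genera, mean GCN 6.6, 30% unidentified
db  <- gcnDatabase(copyNumbers(sim), defaultGCN = 1.8)
evaluateCommunity(observedCounts(sim), mockTruth(sim), db)@bestFit
#> [1] "raw"
```

`simulateMock()` draws reads multinomially with weight ∝ abundance × copy
number, plus configurable unidentified and spurious-genus mass, so every
pipeline stage is testable with known ground truth. File readers cover
mockrobiota-dialect taxonomy files, genus count TSVs and GCN lookup
tables; `inst/scripts/gcnbench.R` wraps the workflow as a command line
(`evaluate`, `cohort`, `simulate`, `fixture` subcommands).

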