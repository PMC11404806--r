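# epicons

Cross-species consensus B-cell epitope comparison for immunoglobulins.

## What this is for

Wildlife immunology routinely lacks species-specific reagents. A practical
workaround is to ask whether antibodies against a well-characterized
homolog — usually the human protein — are likely to cross-react with the
target species' molecule. For an immunoglobulin heavy chain, the most
informative evidence is at the **epitope** level: do the regions that
prediction algorithms consistently flag as linear B-cell epitopes on the
target species' sequences also exist, nearly identically, on the human
chain?

`epicons` implements that analysis as a tested, fully offline R pipeline
for a family of homologous protein sequences (the motivating case is five
partial Florida manatee IgA heavy chains compared against human IgA1 and
IgA2):

* **Propensity prediction** — seven published physicochemical scales
  (Parker hydrophilicity, Karplus–Schulz flexibility, Emini accessibility,
  Chou–Fasman turns, exposed surface, Grantham polarity,
  Kolaskar–Tongaonkar antigenicity), sliding-window smoothed, rescaled per
  sequence to [−3, +3], thresholded into epitope calls.
* **Ingestion** of external predictor exports (per-residue score tables or
  per-window peptide tables), validated against the sequences, with
  deterministic overlap deduplication.
* **Two-level consensus** — an alignment column supports an epitope when
  ≥ 3 member sequences carry a prediction there *and* match the majority
  residue; final epitopes are columns covered by ≥ 3 distinct algorithms.
* **Conservation index** — six components averaged into a score in [0, 1]
  per epitope (member presence, per-position residue conservation,
  normalized algorithm scores, interquartile localization, algorithm
  count, cross-algorithm coverage agreement), with mismatches penalized:

  `index = mean(presence, position, score, iqr, algorithms, agreement)`

* **Identity vs reference chains** — global alignment (EMBOSS-Needle-style
  BLOSUM62 with free end gaps, or a simple +1/0/−1 scheme), target trimmed
  to the aligned span, identity = matches / query length.
* **Shared-amino-acid similarity** — mode (M), range (R) and count (#) of
  positions shared with a table of experimentally confirmed reference
  epitopes.
* **Supporting metrics** — p-distance + neighbor-joining trees from an
  MSA; Kabsch superposition RMSD and TM-score for matched Cα sets.
* **Synthetic data generator** — families with planted conserved epitopes
  and noisy multi-algorithm predictions, so every stage is testable
  without downloads.

The shipped human IgA1/IgA2 constant-region chains are *synthetic
reconstructions* from model knowledge of UniProt P01876/P01877 (the
package is built and tested offline); see `?humanIgAChains` before using
them for anything beyond demonstration.

## Worked example

Align the strongest manatee consensus epitope against the human IgA1
constant region:

```r
library(epicons)
refs <- humanIgAChains()
needlemanWunsch("HLLPPPAEEL", as.character(refs[["IGHA1"]]))
#> AlignmentResult: score 52.0, identity 0.900 (9 matches), target span 231-240
```

Nine of the ten residues match the human chain (HLLPPPAEEL vs
HLLPPP**S**EEL at positions 231–240) — 90% identity, the kind of region a
polyclonal anti-human-IgA reagent could plausibly recognize. The table
form over several published epitopes:

```r
eps <- manateeConsensusEpitopes()
epitopeIdentityTable(eps[c(7, 10, 12)], refs)
#>      epitope reference identity target_start target_end
#> 1     APERDS     IGHA1     0.67          174        179
#> 2     APERDS     IGHA2     0.67          161        166
#> 3 HLLPPPAEEL     IGHA1     0.90          231        240
#> 4 HLLPPPAEEL     IGHA2     0.90          218        227
#> 5     PRQEPG     IGHA1     0.67          281        286
#> 6     PRQEPG     IGHA2     0.67          268        273
```

A full simulated pipeline run — family, predictions, consensus,
conservation, identity — in one call:

```r
out <- runPipeline(list(seed = 7,
  simulate = list(ancestorLength = 300, nPlantedEpitopes = 3),
  references = system.file("extdata", "human_iga_constant_synthetic.fasta",
                           package = "epicons")), "run_out")
out$report[, c("epitope", "conservation", "identity_IGHA1", "identity_IGHA2")]
#>            epitope conservation identity_IGHA1 identity_IGHA2
#> 1    IPRKCNILQISVF    0.8028138           0.23           0.23
#> 2    IKKYQMYIVDVPV    0.8058049           0.38           0.38
#> 3            QFPDW    0.5245719           0.40           0.60
#> 4 GQQLYLLADKRADFHM    0.8571139           0.44           0.38
```

The three planted (conserved) regions come out with high conservation
indices (~0.80–0.86); the low-scoring short row is a decoy that scraped
past the consensus thresholds. `run_out/` also contains `report.tsv`,
`conservation.tsv`, `identity.tsv`, `tree.nwk` and a `manifest.json`
recording the config hash and seed. A thin shell wrapper with
`run` / `simulate` / `tree` / `struct` subcommands ships at
`inst/scripts/epicons`.

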