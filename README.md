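# startbias

Quantifies how strongly the placement of next-generation-sequencing read
starts depends on the local nucleotide composition of the genome — the
family of effects of which GC bias is the best-known member — and
expresses that strength as a single calibrated number, the **Pattern
Effect Index (PEI)**. It is aimed at anyone who needs to know whether a
library's read positioning is composition-driven, or whether a bias
correction actually removed the dependence.

## Method in brief

For one chromosome, positions are stratified by the number of reads
starting there (0, 1, …, 10, 11+) and sampled into a pool of ±20 bp
windows. Each 41-bp window yields normalized k-mer distribution features
(4 mono, 16 di, 64 tri, 256 tetra; M_i/∑M_i per order). Balanced
datasets contrast no-read positions against positions with ≥ 1, ≥ 6 or
≥ 11 reads, and a 3-nearest-neighbor classifier with the Euclidean
metric √(∑_x (F1(x) − F2(x))²) predicts read presence from composition
alone. The index is

    PEI = (accuracy% − 50) / 50

with 0 = random positioning and 1 = positioning fully determined by
window composition. The affected threshold 0.05 derives from the
label-shuffling null (mean 49.98%, SD 0.81; 49.98 + 3×0.81 = 52.41% ⇒
PEI 0.0482). The package also computes local-vs-global distribution
distances and GC content per frequency group, genetic-algorithm feature
selection (population 50, 20 generations, crossover 0.8, mutation 0.05,
elitism), a transition/entropy sequence-complexity score
√((q/q_max)(h/h_max)), and — crucially for testing — a simulator that
places reads with probability ∝ exp(β·d(p)) so the whole pipeline can be
validated against a known bias strength β.

## Worked example

```r
library(startbias)

ref   <- simulate_reference(50000, gc_distribution(0.4), seed = 7)
model <- bias_model(order = 2, beta = 20,
                    background = global_distribution(ref, 2))
track <- place_reads(ref, model, n_reads = 1e5, seed = 8)

pool <- build_pool(ref, track, pool_config(scale = 0.1, seed = 3))
pool_distance_table(pool, global_distribution(ref, 1),
                    global_distribution(ref, 2))
#>   group   n    distance
#> 1     0 500 0.008058511
#> 2   1-5 250 0.007064901
#> 3  6-10 250 0.030823421
#> 4   11+ 500 0.093778821

measure_pei(ref, track, min_reads = 1, feature_set = "all",
            pool_config = pool_config(scale = 0.1),
            replicates = 5, seed = 1)
#> <pei_result> 0vs1+, features: all
#>   accuracies: 81.40 80.00 80.40 82.20 82.40
#>   mean 81.28% (sd 1.06) -> PEI 0.6256 (affected)
```

The distance column rises with read frequency — windows where many reads
start are compositionally far from the chromosome average — and the PEI
of 0.63 is far above the 0.05 threshold, correctly flagging the strong
simulated bias. The same pipeline on a `beta = 0` track returns
accuracies near 50% and PEI ≈ 0.007, "not affected".

The same stages are scriptable from a shell via the thin CLI wrapper
(`inst/cli/startbias`): subcommands `simulate`, `pool`, `distances`,
`gc-summary`, `features`, `pei`, `ga-select`, `complexity`, each writing
a manifest of all parameters and seeds. Real data enter as a FASTA
reference plus a `chrom pos count` TSV (or BED3/BAM) of read starts.

See `vignettes/quantifying-read-start-bias.Rmd` for the model,
assumptions, parameter defaults and limitations.

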