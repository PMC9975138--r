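# introPaint

Detection and characterisation of introgression between diverged gene
pools from phased biallelic SNP data.

When a cultivated or wild population hybridises with a diverged relative
and then backcrosses, it can retain a compact chromosomal segment of
foreign ancestry. Rice is a textbook case: upland varieties grown far from
the centre of domestication can carry multi-megabase segments from a gene
pool (circum-Aus) otherwise absent in their region, and those segments can
be adaptive. introPaint implements the complete inference chain used to
find, test and interpret such segments, plus a seeded synthetic-data
generator with machine-readable truth so the whole chain can be validated
end to end without any external dataset.

## What it computes

**Chromosome painting (windowed PCA + KDE).** For each half-overlapping
window of 150 SNPs, a PCA is fitted on all haplotypes jointly; each
reference panel gets a Gaussian product-kernel density on the first five
components (Scott's-rule bandwidths), and each target haplotype receives a
posterior per panel. Labels follow the ideogram convention: a single group
at posterior ≥ 0.8, a shared two-group label (joint ≥ 0.8, each ≥ 0.1),
`unspecific` (grey) or `absent` (black). Slices are merged into tracts and
drawn as ideograms.

**ABBA-BABA tests.** With population ALT frequencies p1..p4 at each site,

    ABBA = (1 - p1) p2 p3 (1 - p4),   BABA = p1 (1 - p2) p3 (1 - p4)
    D = [sum(ABBA) - sum(BABA)] / sum(ABBA + BABA)

with a delete-one block jackknife (379 contiguous equal-SNP blocks,
|Z| > 3 significant), the admixture fraction
f = S(P1,P2,P3,P4) / S(P1,P3,P3,P4), and windowed fd / fdM.

**Window diversity statistics.** Nucleotide diversity pi, absolute
divergence Dxy, Hudson window Fst (1 − mean(pi)/Dxy as ratio of sums), a
global pairwise Fst matrix, and Tajima's D, on 100 kb / 50 kb sliding
windows; windows with fewer than 10 SNPs are flagged excluded.

**iHS selection scan.** EHH decay per core allele, trapezoidal iHH,
iHS = ln(iHH_ref / iHH_alt) standardized within ALT-frequency bins, the
Gaussian p-value transform p = −log10[1 − 2|Φ(iHS) − 0.5|], outliers at
p > 5, and candidate genes within 30 kb of any outlier SNP.

**Synthetic data.** Balding–Nichols panels (per-site ancestral frequency
p ~ U(0.1, 0.9); population frequency ~ Beta(p(1−F)/F, (1−p)(1−F)/F)),
admixed target mosaics with planted donor tracts, four-taxon quartets with
block-wise gene flow, and founder-copy partial sweeps — all seeded, all
emitting truth files (VCF + population TSV + truth BED/JSON).

## A worked example

```r
library(introPaint)

## three diverged panels + 20 targets carrying a planted 3.8 Mb donor
## tract (chr6:17.9-21.7 Mb, carrier fraction 0.5), 30 Mb at 1 SNP/kb
sc <- scenario_painting(seed = 1)
pg <- paint_genome(sc$combined, sc$samples)
pg
#> <painting> 40 haplotypes, 399 windows, groups: cAus, GJ, XI
#>   slice labels:
#>     GJ              14887 (93.0%)
#>     cAus             1113 (7.0%)
ev <- evaluate_painting(pg, sc$truth, background = "GJ")
ev$accuracy
#> [1] 0.9991875

## ABBA-BABA on a quartet with 20% gene flow from P3 into P2
q <- simulate_quartet(0.2, seed = 3)
abba_baba_test(q$quartet, q$samples, "P1", "P2", "P3", "P4")
#> ABBA-BABA test  (P1,P2,P3,P4) = (P1, P2, P3, P4)
#>   D = 0.0790   SE = 0.0099   Z = 7.99   (significant at |Z| > 3)
#>   f = 0.1790   over 30000 sites in 379 jackknife blocks
```

The painting slice accuracy of 0.999 means that essentially every 75-SNP
slice of every target haplotype received the correct ancestry label; the
7% of slices labelled `cAus` are the planted tract on carrier haplotypes.
In the quartet, Z = 7.99 rejects incomplete lineage sorting and the
admixture fraction recovers the simulated 20% gene flow (f is averaged
over 20 seeds in the validation suite, where it lands within ±0.05 of
0.2).

A one-command end-to-end demo (simulate → validate → paint → D/f →
window scans → iHS → genes, with an ideogram and a JSON report):

```r
run_demo("demo-out", seed = 1)
```

A thin command-line wrapper with subcommands
`simulate | validate | paint | dstat | windows | ihs | genes | demo`
is installed at `inst/cli/introPaint.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/introPaint.R", package="introPaint"))')" demo --out demo-out --seed 1
```

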