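# asmrescue

Forensics and targeted correction for de novo genome assemblies.

BUSCO completeness classes (Complete single-copy, Duplicated, Fragmented,
Missing) drive most assembly-quality decisions, yet they are sensitive to
artifacts of the assembly process itself: a gene fragmented in one
assembly of a genome is often complete in an alternative assembly of the
same reads, classes can flip when a scaffold is reverse complemented, a
failed contig merge can manufacture duplicated genes, and long-read gap
filling can *overfill* gaps — extending sequence inward from both flanks
without ever closing the gap. `asmrescue` packages the computational
methods for diagnosing and, where safe, repairing these artifacts:

* **Cross-assembly gene rescue** — find genes Fragmented in a focal
  assembly but Complete single-copy in an alternative assembly, and
  translocate the complete copy into the focal assembly by k-mer
  anchoring: the donor gene's flanks must match the focal scaffold on
  unique, collinear k = 31 exact k-mers (≥ 80% of flank k-mers per
  side), the donor scaffold's orientation is synced by shared-k-mer
  majority, and the focal contig(s) enclosing the fragmented gene are
  replaced by the donor segment. Unsafe cases are skipped with the
  reason recorded: ambiguous orientation, repeat-borne flanks, a
  neighboring complete gene inside the replaced interval, or
  inconsistent anchors. The accounting always conserves
  (identified = applied + skipped).
* **Seeded long-read subsampling** — uniform draws without replacement
  from reads within an inclusive length window `[minLen, maxLen]` until
  `total bases ≥ genomeSize × coverage` (the crossing read included),
  fully reproducible from a seed.
* **Hybrid-merge diagnostics** — the OVL/n-OVL decision rule
  (merge iff `OVL/n-OVL ≥ 1.5`, where OVL is the union of aligned query
  intervals and n-OVL the rest of the aligned extent) computed from PAF
  or nucmer show-coords alignments, plus attribution of duplicated
  genes in a merged assembly to `merge_failure`, `preexisting`, or
  `unknown` mechanisms.
* **Gap-fate classification** — each pre-assembly gap is re-located in
  the gap-filled assembly by flank anchoring and classified `closed`
  (no residual N), `partially_filled` (residual N, span ≤ original),
  `overfilled` (residual N, span > original), or `unresolved`.
* **Assembly utilities** — FASTA/FASTQ I/O (gzip transparent), BUSCO
  full_table parsing (v3 and v5 dialects), scaffold segmentation into
  contigs and gaps, N50 and Ns-per-100-kb statistics, reverse
  complementation, scaffold splitting at a gap.
* **Synthetic data** — seeded generators for toy genomes with repeat
  families, focal/donor pairs with planted rescuable genes, planted gap
  fates, merge/duplication scenarios, and simulated long reads with
  chimera and substitution-error truth labels.

The package is aimed at assembly practitioners reconciling multiple
assemblies of one genome (different k-mer sizes, different read types,
hybrid merges) who need their completeness numbers to be explainable.

## Worked example

```r
library(asmrescue)

# A 200 kb toy genome; a focal assembly with 5 planted genes, all
# fragmented by an inserted gap, and a donor assembly carrying each gene
# intact: 3 rescuable, 1 with a repeat-borne flank, 1 with an
# orientation-ambiguous donor scaffold.
g  <- makeToyGenome(2e5, seed = 42)
fx <- makePlantedAssemblyPair(g$genome, nGenes = 5, geneLen = 2000,
                              nFragmented = 3, nRepeatFlanked = 1,
                              nOrientAmbiguous = 1, seed = 43)

res <- correctAssembly(fx$focal, fx$focalBusco,
                       list(fx$donor), list(fx$donorBusco),
                       k = 31, flankLen = 1000)
res$report
#> CorrectionReport: 5 case(s) identified (applied=3, skipped_orientation=1,
#>   skipped_no_anchor=1, skipped_neighbor_conflict=0,
#>   skipped_inconsistent=0); 0 unrescuable gene(s)

replacementPlans(res$report)[, c("busco_id", "status", "orientation")]
#>   busco_id              status orientation
#> 1     g001   skipped_no_anchor     forward
#> 2     g002 skipped_orientation   ambiguous
#> 3     g003             applied     forward
#> 4     g004             applied     forward
#> 5     g005             applied     reverse
```

Three genes were translocated (g005 from a reverse-complemented donor
scaffold, detected and synced automatically); the repeat-flanked gene and
the orientation-ambiguous donor were refused with their reasons recorded.
The corrected assembly contains each applied donor gene as an exact
substring, and every base outside the replaced intervals is untouched.

Subsampling follows the same worked arithmetic everywhere: 1,000 reads of
exactly 10 kb against a 1 Mb genome at 5× coverage selects exactly 500
reads:

```r
reads <- setNames(rep(strrep("A", 10000), 1000), paste0("r", 1:1000))
sampleToCoverage(reads, SamplingSpec(1e6, 5, seed = 7))
#> SampleResult: 500 reads, 5,000,000 bp (5x of 1,000,000 bp; target 5x)
```

A command-line front end covering all pipelines is installed with the
package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/asmrescue", package="asmrescue"))')" \
    correct --focal focal.fa --focal-busco focal.tsv \
    --donor donor.fa --donor-busco donor.tsv -k 31 --flank 1000 \
    -o corrected.fa --report report.tsv
```

Subcommands: `stats`, `revcom`, `compare`, `correct`, `sample`,
`merge-diag`, `gap-fates`, `split-at-gap`, `simulate`.

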