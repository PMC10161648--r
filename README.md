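# markergt

Genotyping known polymorphic sites from short reads against a *pangenome* of
phased haplotypes, using a BWT/FM-index whose locate machinery is replaced by
a **marker array**: a sparse, suffix-rank-ordered map from index positions to
the polymorphic sites they overlap.

## The problem and the method

Genotypers that align reads to one linear reference suffer *reference bias*:
reads carrying non-reference alleles match the reference worse, so evidence is
skewed toward REF. Indexing a whole panel of haplotypes `T_0, T_1, ..., T_n`
(reference plus alternatives, concatenated into one text `T`) removes that
asymmetry, but the classical way to interpret a BWT match — a suffix-array
locate query — is exactly the expensive part of a compressed index.

The marker array sidesteps locate queries. For every variant in the panel VCF,
the position of the first substituted base (or, for an indel, the base just
left of it) is *marked* in every document with a 64-bit word
`(chromosome | reference offset | allele id)`. Two structures are built over
the suffix-array order of `T`:

- `MA[i] = M[SA[i]]` — the markers permuted into suffix-rank order, where
  identical markers group into long runs and compress well;
- `MA^w[i] = [M[SA[i]], ..., M[SA[i]+w]]` — the **smeared** array, which
  widens each mark `w` positions leftward so a backward search only needs to
  consult it every `w` steps.

Both are stored with a sparse run-length encoding (bitvectors `S`/`E` for run
boundaries, payload array `X`, boundary bits `B`).

A read is scanned right-to-left by FM-index backward search. Each maximal run
of successful steps (an *extension*) queries `MA^w` on a fixed schedule while
the suffix-array range is no larger than the number of indexed haplotypes
`N_h` (bigger ranges are ambiguous multi-locus matches). Evidence from an
extension is discarded wholesale if two alleles conflict at one site, if its
sites span several chromosomes, or if fewer than 80 bp matched. Per site, `k`
allele observations of which `l` are REF feed the ploidy-2 genotype
likelihood with global error rate `ε` (default 0.01):

```
L(g) = (1/2)^k [(2−g)ε + g(1−ε)]^l [(2−g)(1−ε) + gε]^(k−l),   g ∈ {0,1,2}
```

and the call is `argmax L(g)` (haploid mode: majority allele, REF on ties).
A fully sensitive — but `O(|q|·occ)` — oracle based on FL steps
(`fl_marker_query()`) backs the test suite.

## Worked example

```r
library(markergt)
library(dplyr)

# 1. simulate a phased panel: 20 kb chromosome, 10 haplotypes
sim <- simulate_panel(sim_config(chrom_len = 20000, n_haplotypes = 10, seed = 42))

# 2. hold haplotypes 9 and 10 out as the diploid donor; index the rest
donor <- simulate_diploid_donor(sim, haps = c(9, 10))
idx   <- build_marker_index(as_haplotype_panel(sim, haps = 1:8), w = 19)
idx
#> <marker_index> |T| = 179996, 9 document(s), w = 19, 219 marked site(s), min_af > 0

# 3. simulate 30x 150 bp reads from the donor and scan them
reads <- simulate_reads(donor, coverage = 30, error_rate = 0.01, seed = 1)
calls <- reads |>
  genotype_reads(idx, min_seed_len = 80) |>
  tally_evidence() |>
  call_diploid(epsilon = 0.01, sites = idx$sites)
glance(calls)
#> # A tibble: 1 × 6
#>   n_sites n_with_evidence mean_depth n_hom_ref n_het n_hom_alt
#>     <int>           <int>      <dbl>     <int> <int>     <int>
#> 1     219             219       33.4        66    73        80

# 4. compare to the donor's true genotypes
truth <- idx$sites |>
  inner_join(donor$truth, by = c("chrom_id", "ref_pos")) |>
  transmute(chrom_id, ref_off = mark_off, truth_g, ref = ref.x, alt = alt.x)
evaluate_calls(calls, truth, level = "alt_allele")
#> # A tibble: 4 × 9
#>   stratum level         tp    fp    fn    tn precision recall    f1
#>   <chr>   <chr>      <int> <int> <int> <int>     <dbl>  <dbl> <dbl>
#> 1 All     alt_allele   233     0     0   205         1      1     1
#> 2 SNV     alt_allele   214     0     0   188         1      1     1
#> 3 Indel   alt_allele    19     0     0    17         1      1     1
#> 4 SV      alt_allele     0     0     0     0        NA     NA    NA
```

The `<marker_index>` line says the concatenated text holds 9 documents (the
reference `T_0` plus 8 panel haplotypes) and 219 marked polymorphic sites.
`glance(calls)` summarizes the call set — every marked site received
evidence, at a mean depth of 33 observations. The evaluation scores each
diploid genotype as a pair of allele calls (the ALT calls are the positive
class), stratified by variant class: here every donor allele is recovered
exactly. `tidy()`, `glance()` and `autoplot()` work on call sets and
evaluation reports.

A command-line wrapper with `simulate`, `build`, `genotype` and `eval`
subcommands is installed at `inst/cli/markergt`:

```sh
Rscript inst/cli/markergt build --vcf panel.vcf --fasta ref.fa --min-af 0.01 --out idx/
Rscript inst/cli/markergt genotype --index idx/ --reads reads.fq --out calls.vcf
Rscript inst/cli/markergt eval --calls calls.vcf --truth truth.vcf --report report.tsv
```

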