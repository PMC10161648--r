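---
title: "Marker-array pangenome genotyping: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-array pangenome genotyping: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markergt)
```

This vignette is the package's own account of the method: the index and its
assumptions, the scanning algorithm and every tunable that matters, the
numerical and tie-breaking decisions, what the simulator emulates, and where
the guarantees stop.

## The pangenome text and its markers

A panel is a reference genome plus `n` phased alternative haplotypes, related
by a multiple alignment given in VCF form. We materialize each haplotype as a
*document*: all its chromosomes concatenated in reference order, terminated
by a separator that sorts below every base (`$`; the final document ends with
`#`, the global minimum, so suffix order is total). The concatenation
`T = T_0 $ T_1 $ ... T_n #` is indexed with a suffix array, its BWT, C-counts,
and rank/select support — a plain FM-index. At this package's working scale
the full suffix array is retained and doubles as the locate oracle for
testing; no run-length-sampled suffix array is built.

Every variant contributes one *marked position per document*: the first
substituted base for substitutions (runs of consecutive substitutions
collapse into one edit), or the base immediately **left** of an indel in the
alignment — left, because suffixes extend rightward, so a suffix starting at
the marked base includes the allele itself. The mark is a 64-bit word:
12 bits of chromosome index, 48 of reference offset, 4 of allele id (0 = REF;
the printed widths of the three fields elsewhere sum past 64, so the offset
field is what gives). Reference copies of a site carry allele id 0 — "this
locus, no edit". Edit details (kind, sequence, reference span) live in a
separate dense-id table.

Two derived structures serve queries:

* `MA[i] = M[SA[i]]` (the marker array): markers permuted into suffix-rank
  order. Suffixes that begin with the same allele cluster, so identical
  markers form runs.
* `MA^w[i] = [M[SA[i]], ..., M[SA[i]+w]]` (the augmented, "smeared" array):
  each entry lists the markers in a `w+1`-position window to the right of the
  suffix start, clipped at the document's separator (a suffix near a document
  end cannot overlap the next haplotype). Payloads are ordered by increasing
  text offset, so a position's own marker comes first; the order is a
  convention of this package.

Both are stored sparsely: bitvectors `S` and `E` mark the first and last
position of each maximal run of identical non-empty entries, `X` holds the
payloads run by run, and `B` flags each run's first payload. Membership is
`S.rank1(i+1) > E.rank1(i)`; the run index is `E.rank1(i)`. Rank support is
a plain cumulative-count array — the contract here is query semantics, not
succinctness.

## Scanning a read

Reads are matched right-to-left by backward search. When the range empties,
it resets to the all-inclusive range and matching restarts at the next
character; each maximal run of successful steps is an *extension*. Evidence
is only as good as its filters:

* **Ambiguity gate.** The marker array is consulted only while the SA range
  has at most `N_h` rows (`N_h` = number of documents, `T_0` included): a
  larger range means the current suffix occurs more than once in some
  haplotype, so any marker hit would be unanchored.
* **Query schedule.** `MA^w` is consulted every `w` steps, and once more when
  the extension ends. The offsets are chosen so the window always lies inside
  the matched substring: queries fire at matched lengths `w+1, 2w+1, 3w+1,
  ...`, plus a terminal query when at least `w+1` characters matched. Two
  facts follow. *Coverage*: a marker `d` positions left of the extension's
  right end is visible at matched lengths `[d, d+w]`, an interval of `w+1`
  consecutive integers, which always contains a scheduled length (or, if the
  extension ends first, the terminal query's length) — no in-match marker is
  ever missed by the schedule alone. *Containment*: because the window
  `SA[i]..SA[i]+w` needs `w+1` matched characters to stay inside the match, a
  query at matched length exactly `w` would inspect one position *past* the
  match and could collect evidence the match never observed; starting at
  `w+1` makes every reported marker provably overlapped by the matched
  substring, which the test suite checks against the exact FL oracle.
* **Extension-level discards.** Within one extension: conflicting alleles at
  one site, or sites on more than one chromosome (documents concatenate
  chromosomes without separators, so junction-spanning matches are possible
  and meaningless), or a total matched length under `min_seed_len` — any of
  these discards the extension's evidence wholesale.
* **Strand heuristic.** A random initial strand is chosen per read
  (deterministically from `strand_seed` and the read ordinal); the opposite
  strand is scanned only when no extension on the first reached
  `min_seed_len`. Evidence that survives on the second strand is used even
  though the first strand produced only sub-threshold extensions.

Tallying keeps at most one observation per read per site — windows overlap at
their boundary step and both strands of one read are not independent
evidence.

### Parameters

| parameter | default | units | why |
|---|---|---|---|
| `w` | 19 | positions | window of the smeared array; long enough that a `w`-mer rarely matches by chance at this genome scale, small enough that the array stays sparse. Queries cost one array access per `w` matched bases. |
| `min_seed_len` | 80 | bp | an extension must anchor most of a 150 bp read before its evidence counts; short matches are where false evidence lives. |
| `epsilon` | 0.01 | per-base error | the likelihood model's global substitution rate; matches the simulator's default read error rate. |
| `min_af` | 0 | fraction | minor-allele frequency floor among panelists (strictly greater-than; `T_0` is excluded from the denominator — it is a reporting convenience, not a panelist). |

## Calling genotypes

With `k` observations at a site, `l` of them REF, ploidy 2 and error `ε`:

$$L(g) = \tfrac{1}{2^k}\,[(2-g)\varepsilon + g(1-\varepsilon)]^{\,l}\,
         [(2-g)(1-\varepsilon) + g\varepsilon]^{\,k-l},\qquad g\in\{0,1,2\}.$$

This is the standard ploidy-2, global-error genotype likelihood (the exponent
on the first bracket is `l`, the REF count — the two brackets must split `k`
into `l` and `k−l` for the distribution to normalize, which the tests verify
by summing binomial-weighted likelihoods to 1). `L(1)` is constant in `l`
(`2^{-k}`), so heterozygous wins exactly in the middle band of `l` values.
Ties break toward larger `g` (more REF copies), and a site with no evidence
is called homozygous REF — the diploid mirror of the haploid rule "on a tie,
call REF". Haploid calls are the majority allele, REF on ties; alleles
outside the site's REF/ALT set never arise from the marker path by
construction.

Numerical notes: likelihoods are products of at most `k ≈ coverage` factors
in `[0, 2]`, so underflow is not a concern at tested depths; VCF output
stores `log10 L` floored at −999. `ε` is validated to the open interval
(0, 1); the `ε → 0` closed forms (`L(2)=1, L(1)=2^{-k}, L(0)=0` at `l=k`) are
exercised at `ε = 10^{-12}`.

## Evaluation

Diploid calls are scored two ways, stratified into SNV, Indel (length
difference ≤ 50 bp), SV (> 50 bp) and All: *allele-level* — each genotype is
a pair of allele calls; an ALT call is TP iff the truth holds at least one
ALT, a REF call is TN iff the truth holds at least one REF — and
*heterozygous-site-level* — called-het versus truly-het. Haploid evaluation
takes truly-ALT sites as the positive class and requires the called allele to
match the true one.

## The simulator, and what passing means

`simulate_panel()` draws a uniform-random reference, places non-overlapping
SNVs (0.01/bp) and anchored indels (0.001/bp, geometric lengths of mean 3
capped at 60 — raise the cap to exercise the SV stratum), and assigns
carriers per variant from a clamped Beta(0.8, 0.8) so every variant has at
least one carrier and one non-carrier. Reads come from a (possibly held-out)
diploid donor: uniform starts over both haplotypes and strands, 150 bp, 25×
by default, substitution-only errors at 1%, constant quality — the genotyper
never reads qualities. Fixed seeds reproduce byte-identical files. The test
suite runs panels of 0.5–2 kb for the exact definition oracles and 20–50 kb
(10 haplotypes) for recovery experiments; those sizes are the package's
chosen working scale.

What the simulator deliberately omits — and hence what green tests do *not*
show about real data:

* **No linkage disequilibrium**: carriers are independent across sites, so a
  read's local haplotype is often a novel allele combination. Real panels
  have LD, which makes full-length matches to panel haplotypes *more* likely;
  in that one respect the simulation is conservative.
* **No indel-placement normalization**: a simulated deletion may share its
  boundary base with the deleted run, making its VCF placement ambiguous. A
  match that begins exactly at such an indel's marked anchor is genuinely
  consistent with both alleles, so "no wrong-allele evidence on exact
  matches" is an **SNV guarantee only**; the scan-mechanics acceptance check
  therefore runs on an SNV panel, and indel evidence near match boundaries
  should be read as weaker than SNV evidence.
* Substitution-only errors, single-end reads, no PCR/GC bias, no coverage
  waviness, uniform base composition, no repeat structure beyond what chance
  provides at 50 kb. Human-scale repetitiveness would engage the `N_h`
  ambiguity gate far more often than these tests do.

## Degenerate inputs and tie-breaks, collected

* Overlapping VCF records: the later record is skipped (tallied), because the
  column model assumes consistent alignment columns. Records failing the
  REF-against-FASTA check, with more than 15 ALTs (4-bit allele field), or
  length-changing without a shared anchor base are likewise skipped and
  tallied; an absent chromosome or unphased genotype is fatal.
* Reference `N` is indexed verbatim and never matches a read character; a
  read `N` simply empties the range (ending the extension) rather than
  erroring.
* Equal adjacent multimap entries merge into one run only on element-wise
  payload equality.
* `w = 0` degenerates `MA^w` to `MA` and is allowed for testing; production
  indexes use `w ≥ 1`.
* Subsetting a panel (holding out donor haplotypes) re-applies the MAF
  filter, so sites monomorphic among the remaining panelists drop out of the
  index — and out of the evaluation, which is defined over marked sites.

## Known limitations

The index is rebuilt in memory per session at O(n) space — run-length
compression is applied to the marker structures but not the BWT, and no
prefix-free-parse construction or r-index locate machinery is included; this
bounds practical panels to megabases, which is the package's intended scale.
Symbolic ALTs, breakends and rearrangements are out of scope. Genotype
quality emission and imputation are out of scope. Marking only the left
flank of each variant means matches that end exactly at an indel's anchor
carry limited allele information (see above); indexing the reverse text and
combining both flanks would strengthen this at twice the index cost.
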