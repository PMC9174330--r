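---
title: "Contact-set missense constraint: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact-set missense constraint: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Large population sequencing catalogs make it possible to ask, for every
amino acid site of a human protein, whether missense variation is
depleted relative to what neutral mutation would produce. Depletion
(constraint) marks sites whose substitution tends to be removed by
purifying selection, and is strongly associated with pathogenicity.
Most constraint metrics aggregate over genes or 1D sequence windows.
This package scores constraint over each site's *3D contact set* — the
residue itself plus all residues whose side chains sit within a contact
radius in the folded structure — on the premise that selection acts on
the local 3D environment a residue physically interacts with.

## The model

For a protein of $L$ amino acid sites with a validated coding sequence
(starts with ATG, ends with a stop codon, translation matches the
protein sequence):

1. **Mutability.** A $64 \times 3$ matrix gives the per-generation
   probability of each single-nucleotide change as a function of its
   trinucleotide context. Each of the 9 possible changes of every codon
   is looked up under its context *in the coding sequence* and
   classified against the standard genetic code, giving per-codon
   synonymous, missense and nonsense mutabilities
   $(u^{syn}_j, u^{mis}_j, u^{non}_j)$. The matrix can be estimated
   from context occurrence/mutation count tables
   (`estimate_mutation_matrix()`) or supplied as TSV.

2. **Expected counts.** Across transcripts, the observed number of
   unique synonymous variants is regressed on total synonymous
   mutability $\mu_{syn}$ (ordinary least squares). Because synonymous
   variation is under minimal selection, the fitted line
   $\hat{y} = a\mu + b$ converts mutability into the count expected
   without constraint; the expected unique missense count of a
   transcript is $t_e = a\,\mu_{mis} + b$, floored at 0 (a
   non-positive prediction marks the protein unscorable).

3. **Contact sets.** Residues are reduced to one representative
   coordinate each: the C$\beta$ atom, or C$\alpha$ for glycine. The
   contact set $S_r$ of site $r$ contains $r$ and every mapped residue
   strictly within 8 Å (configurable; 6 and 10 Å supported). In
   oligomers, residues of all chains mapping to the same protein are
   pooled and recorded by protein position *with multiplicity*, so a
   partner-chain copy of a contacting position contributes again to
   the observed and expected sums.

4. **The null and the score.** Site probabilities are the normalized
   missense mutabilities $p_j = u_j / \sum_i u_i$. Each of $N$
   permutations (default 10,000) distributes $\mathrm{round}(t_e)$
   variants over the $L$ sites as a multinomial draw and records the
   total falling in each contact set. With null mean $m_e$ and
   population standard deviation $m_\sigma$, and the observed number of
   unique missense variants $m_o$ in $S_r$,

   $$\mathrm{COSMIS}_r = \frac{m_o - m_e}{m_\sigma}, \qquad
     p_r = \frac{K + 1}{N + 1},$$

   where $K$ counts permutations with simulated count $\le m_o$.
   Negative scores mean depletion; sites with $p < 0.01$ are flagged
   high-confidence constrained. The same machinery applied to
   synonymous variants and synonymous mutability gives a control score
   expected to center at 0.

5. **Enrichment.** For labeled variant sets, per-score-percentile-bin
   odds ratios use $OR = (a/b)/(c/d)$ with
   $s.e. = \sqrt{1/a + 1/b + 1/c + 1/d}$ and 95% bounds
   $\exp(\ln OR \mp 1.96\,s.e.)$.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| contact radius | 8 Å (strict `<`) | contact definition between representative atoms; 6/10 Å supported |
| permutations `N` | 10,000 | resolution of the empirical p (minimum attainable $1/(N+1)$) |
| high-confidence cutoff | $p < 0.01$ | $\approx$ COSMIS $< -2.33$ in the Gaussian limit |
| pLDDT cutoff | strictly $> 50$ | residues of predicted models kept; model rejected if $< 1/3$ survive |
| structure filters | resolution $< 5$ Å, coverage $\ge 1/3$, sidechains resolved | experimental-structure eligibility; homology models need identity $\ge 25\%$ |
| matrix scaling constant | 1 | per-generation proportionality; scores are provably invariant to it |
| trial count | `round(t_e)` | `"poisson"` draws Poisson($t_e$) trials per permutation instead |
| long-range threshold | 15 residues | 1D separation defining a long-range contact |

## Numerical and design choices

* **CDS termini.** The first base of the start codon and the last base
  before the stop lack one coding-sequence neighbor. By default those
  single-base changes contribute zero mutability (`boundary = "zero"`)
  rather than fabricating a context; `"require"` turns this into an
  error. At transcript scale the effect is a few parts in $10^3$.
* **Stop codons** encode no site: they are excluded from per-site
  tables, and stop-loss changes are classified but never counted.
* **Unique variants** are unique nucleotide-level (position, ref, alt)
  triples with FILTER `PASS`; two changes causing the same amino acid
  substitution count twice. Observed counts are unique variants while
  the null counts raw multiplicities — the asymmetry follows the
  scoring procedure and is absorbed, at the totals level, by fitting
  the expected-count regression on observed unique counts.
* **$m_\sigma$** is the divide-by-$N$ (population) standard deviation
  of the simulated counts; with $N = 10^4$ the estimator choice is
  negligible. Sites with $m_\sigma = 0$ (e.g. a contact set spanning
  every site) are reported with a status code, not a number.
* **Rescaling invariance.** Multiplying the mutation matrix by $c > 0$
  rescales $\mu$ by $c$ and the refitted slope by $1/c$; $p_j$, $t_e$
  and hence all scores are unchanged (the suite checks the score table
  is bit-identical at $c \in \{0.1, 10\}$).
* **Altlocs** collapse to the highest-occupancy conformer (ties by
  altloc identifier); insertion codes are carried through verbatim.
  Non-glycine residues missing a C$\beta$ fall back to C$\alpha$ with
  a warning (configurable), rather than discarding the whole model.
* **Ties at percentile-bin edges** use left-closed intervals with the
  top edge closed; scores outside the reference range clamp to the
  extreme bins.
* **Spatial clustering** of flagged sites is summarized as the mean
  pairwise distance of their representative coordinates divided by the
  same statistic averaged over random equal-size subsets of resolved
  sites, with an add-one permutation p. The choice of statistic and
  permutation scheme is this package's own.

## The synthetic data generator

`toy_protein_spec()` / `make_toy_protein()` build a fully synthetic
protein: random sequence (first residue methionine), back-translated
CDS under a uniform or GC-skewed codon profile, and idealized
coordinates — an $\alpha$-helix (C$\alpha$ radius 2.3 Å, rise 1.5
Å/residue, 100°/residue turn, C$\beta$ displaced radially to 3.8 Å), a
3.8 Å-step random coil, or a two-chain helix dimer with a controllable
inter-chain gap (default 5 Å closest C$\beta$ approach, so facing
residues form inter-chain contacts at 8 Å). Glycines get no C$\beta$,
exercising the C$\alpha$ rule.

`simulate_observed_variants()` draws `round(t_e_true)` missense
placements from the multinomial over normalized site mutabilities,
thins each site by its retention fraction $f_j$ ($f = 1$ neutral,
$f = 0$ fully depleted), and materializes placements as *distinct*
nucleotide changes within each codon (weighted sampling without
replacement, saturating when a codon's missense changes are
exhausted). Materializing distinct changes matters: sampling with
replacement and collapsing to unique SNVs would deflate observed
counts by roughly 15% at typical intensities (hundreds of placements
over a few hundred sites), which is a property of unique-variant
tallies, not of neutral evolution. Synonymous variants are drawn the
same way with $f \equiv 1$ and a total scaled by the transcript's
synonymous/missense mutability ratio.

What the generator does *not* emulate: realistic folds or side-chain
packing, CpG hypermutability beyond what the supplied matrix encodes,
population demography, sequencing depth or calling artifacts.
Passing tests on these fixtures show the statistical machinery is
correct, not that real structures or variant catalogs are handled at
proteome scale.

## Calibration, and a caveat on discreteness

Under the null (observed counts drawn from the same multinomial the
permutations use), the empirical p is super-uniform: with the
inclusive tie count $K$, $P(p < \alpha) \le \alpha$ for every
$\alpha$. For small contact-set counts the gap is visible: with
$L = 200$, $t_e = 400$ and helix contact sets of ~9 sites, null
counts are integers with mean ~18 and standard deviation ~4, so the
largest achievable level below a nominal 0.01 averages about 0.006.
The fraction of neutral sites flagged at $p < 0.01$ is therefore
*below* 0.01 by that amount — conservative, never anti-conservative.
The effect fades as $t_e \cdot P_S$ grows; in the large-count limit
the $p = 0.01$ boundary sits at COSMIS
$\approx \Phi^{-1}(0.01) = -2.33$, which the test suite and the
acceptance script verify directly.

## Problem sizes used by the checks

The packaged checks run on desk-scale fixtures chosen to keep Monte
Carlo error well inside the asserted tolerances: a 200-site helix with
$t_e = 400$ and $N = 10{,}000$ permutations (50 replicate neutral
draws against one per-protein null, mirroring how a real run computes
one null per protein), a 120-site dimer with $t_e = 600$ for the
interface analysis, a 30-transcript panel spanning 50–400 codons for
the regression, and 1000-replicate simulations for OR coverage.

## Known limitations

* Scores depend on the chosen structure; alternative conformations,
  disordered regions and unresolved residues are reported as
  `unresolved`, not imputed.
* The regression transfers the synonymous mutability–count
  relationship to missense expectations; systematic differences
  between classes (e.g. CpG composition) are absorbed only through
  the context-dependent matrix.
* Oligomer scoring assumes identical chains represent the same
  transcript; hetero-complex support is limited to what the mapping
  expresses.
* The interface rule (strictly larger oligomeric contact set) is
  binary; partial burial does not grade the call.
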