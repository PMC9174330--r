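# cosmis

Per-site quantification of **3D missense constraint** in proteins.

Population variant catalogs show that some amino acid sites tolerate
almost no missense variation. Much of that intolerance is shaped by a
residue's *3D neighborhood* — the residues it physically contacts in
the folded structure — rather than by its 1D sequence window. This
package scores each site by comparing the observed number of unique
missense variants in its **contact set** (the site plus every residue
whose representative atom lies strictly within 8 Å) against a
sequence-context-aware neutral expectation. It is aimed at anyone
interpreting protein-coding variation with a structure in hand:
statistical geneticists, structural biologists, variant curators.

## The score

For site $r$ with contact set $S_r$:

$$\mathrm{COSMIS}_r = \frac{m_o - m_e}{m_\sigma},\qquad
  p_r = \frac{K+1}{N+1}$$

* $m_o$ — observed unique missense variants (FILTER `PASS`, SNVs only)
  in $S_r$;
* $m_e, m_\sigma$ — mean and standard deviation of the simulated null:
  each of $N = 10{,}000$ permutations drops $\mathrm{round}(t_e)$
  variants on the transcript's sites from a multinomial with
  probabilities $p_j = u_j / \sum_i u_i$, where $u_j$ is codon $j$'s
  trinucleotide-context missense mutability;
* $t_e$ — expected unique missense count, predicted by a linear
  regression of observed unique synonymous counts on synonymous
  mutability across transcripts (synonymous variation ≈ no selection);
* $K$ — permutations with simulated count $\le m_o$.

Negative scores mean depletion (constraint); empirical $p < 0.01$
(≈ COSMIS < −2.33 in the Gaussian limit) flags high-confidence
constrained sites. The identical machinery run on synonymous variants
gives a control score centered at 0. Structure handling includes the
C$\beta$/C$\alpha$-for-glycine representative-atom rule, experimental
structure filters (resolution < 5 Å, coverage ≥ 1/3, sidechains
resolved), pLDDT > 50 filtering of predicted models, oligomeric
contact sets with partner-chain multiplicity, and interface detection
(a site whose oligomer contact set is strictly larger than its monomer
one). An odds-ratio module (OR = (a/b)/(c/d), log-scale s.e., 95% CI)
quantifies enrichment of labeled variants across score percentile
bins. See `vignettes/cosmis-methods.Rmd` for the full model.

## Worked example

Everything below is synthetic — the package ships a generator that
builds a toy protein (sequence, CDS, helical PDB, residue mapping) and
a variant table with a known depleted region (sites 31–50 retain only
20% of neutral missense variation):

```r
library(cosmis)

m       <- uniform_mutation_matrix(1e-8)
spec    <- toy_protein_spec(L = 80, t_e_true = 240, seed = 1,
             constraint_profile = c(rep(1, 30), rep(0.2, 20), rep(1, 30)))
fx      <- make_toy_protein(spec)
tx      <- transcript(fx$cds, matrix = m)
model   <- parse_structure(fx$paths$structure_pdb)
mapping <- read_residue_mapping(fx$paths$mapping_tsv)
cs      <- build_contact_sets(model, mapping, radius = 8)
counts  <- tally_variants(tx, simulate_observed_variants(spec, m))
scores  <- score_protein(tx, counts, cs, t_e = 240, N = 10000, seed = 42)
```

`scores` holds one row per site:

```
  pos aa cs_size m_o  m_e m_sigma  cosmis p_value high_confidence
1   1  M       4  12 11.9    3.37  0.0205   0.584           FALSE
2   2  E       5  22 17.0    3.97  1.2709   0.915           FALSE
3   3  H       5  17 17.0    3.95  0.0122   0.568           FALSE
4   4  A       6  17 18.3    4.13 -0.3141   0.434           FALSE
...
   pos aa cs_size m_o  m_e m_sigma cosmis p_value high_confidence
38  38  I       8   6 24.2    4.65  -3.92   1e-04            TRUE
39  39  N       8   4 24.2    4.66  -4.33   1e-04            TRUE
40  40  G       9   6 27.8    4.94  -4.42   1e-04            TRUE
41  41  H       7   4 21.0    4.35  -3.91   1e-04            TRUE
```

Sites in the engineered depleted region carry strongly negative
scores and tiny empirical p values (1e-04 is the floor at
N = 10,000), while neutral flanks hover near 0:

```
median COSMIS, depleted region (31-50): -4.03
median COSMIS, flanks:                  -0.06
high-confidence sites: 22 of 80
```

A thin CLI wraps the same functions
(`inst/cli/cosmis.R score|contacts|fit-expected|enrich|simulate`).

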