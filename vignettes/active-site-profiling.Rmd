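---
title: "Active-site profiling: model, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active-site profiling: model, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(daspr)
library(dplyr)
```

## The model

`daspr` scores a protein sequence by how well it matches the *active-site
profile* of a reference set of structures. The underlying assumption is that
detailed molecular function — reaction specificity rather than fold — is
carried by the residues that form the catalytic microenvironment, and that
this microenvironment leaves a recognisable, discontiguous sequence imprint.

Three modelling layers build on each other:

**Geometry → signature.** Given curated key catalytic residues (typically
three per protein), a residue belongs to the microenvironment when the
Euclidean distance between its centre of geometry and any key residue's
centre of geometry is at most the radius $r$ (default 10 Å, inclusive at the
boundary — "within" is read as $\le$; exact ties are measure-zero for real
coordinates). Maximal runs of selected residues form fragments; fragments of
three or fewer residues are discarded because such short windows carry too
little discriminative signal (the package's *legacy* mode keeps length-3
fragments, discarding only lengths 1–2, so the behaviour of earlier
implementations of this method family can be compared side by side).
Retaining length-4 fragments matters: functionally informative motifs of
exactly four residues occur in real superfamilies (e.g. the GGLG motif of
the peroxiredoxins), which is why the cutoff sits at 3, not 4.

**Signature → profile.** Fragments are aligned *individually* across
proteins rather than as concatenated signatures, because variable fragment
numbers and lengths misalign whole-signature alignments. The $k$-th
key-residue fragment (N→C) of each protein forms key block $k$; this is only
well defined when every protein has the same number of key fragments, so a
mismatch is a hard error rather than a warning — the remedy is better key
residues, not a silently degraded profile. Non-key fragments are assigned to
the interval between key fragments in which they fall and paired by rank
within the interval; rank pairing is the only reading consistent with
placing them "in N→C order", and similarity-based pairing is deliberately
not attempted. Each motif's length is set by the **longest** fragment in its
block and shorter fragments are extended with flanking residues from the
complete protein sequence; the legacy mode instead truncates every row to
the shortest fragment's columns. Extension can make two motifs of one
protein overlap; this is detected immediately after extension and is again a
hard error naming the protein and blocks. Two invariants are enforced by
construction and covered by tests: extension never rewrites residues inside
the original fragment interval, and in DASP3 mode block length never shrinks
when a profile is rebuilt from the proteins its own search recovers —
the property that makes iterative search loops stable.

**Profile → score.** Each block becomes a position-specific scoring matrix
with cells

$$s_{aj} = \mathrm{round}\!\left(c \cdot \log_2
  \frac{n_{aj} + \beta b_a}{(N_j + \beta)\, b_a}\right),$$

where $n_{aj}$ counts residue $a$ in column $j$, $N_j$ is the column's
count, $b_a$ the background frequency, $\beta$ the pseudocount mass
(background-proportional pseudocounts), and $c$ the integer scale. For a
database sequence, each motif is placed by sliding window — longest motif
first, later motifs excluded from already-claimed intervals — at the
position with the most significant exact per-window p-value; the per-window
p-value is corrected for the number of windows actually scanned, and the
per-motif p-values are combined with QFAST,

$$P_{\mathrm{comb}} = q \sum_{k=0}^{n-1} \frac{(-\ln q)^k}{k!},
  \qquad q = \prod_i p_i,$$

the exact distribution function of a product of $n$ independent uniforms.
The combined p-value is the search score; under the null hypothesis of a
background sequence it is (slightly super-) uniform, so thresholds have
their nominal interpretation.

## Tunable parameters

| Parameter | Default | Units | Why this default |
|---|---|---|---|
| `radius` | 10 | Å | the microenvironment radius that defines the signature; the value at which active-site profiling has been validated |
| `min_len` | 4 (dasp3), 3 (legacy) | residues | shortest fragment kept; see above |
| `beta` | 1 | pseudocount mass | one observation's worth of background smoothing, the standard choice for small row counts |
| `scale` | 100 | score units per bit (centibits) | fine enough that rounding is negligible, coarse enough that the exact-distribution DP stays small |
| `background` | Robinson–Robinson composition | frequencies | a fixed, widely used general-protein composition; configurable for databases with unusual composition |
| `report / generous / trusted thresholds` | 1e-5 / 1e-8 / 1e-14 (1e-16 iterative) | combined p | the established operating points for this score: reporting cutoff, near-certain superfamily membership, and high-confidence functional-group membership |

## Numerical choices

* **Exact p-values, not approximations.** Integer scores make the window
  score distribution under the background computable by exact convolution
  over the score lattice (one pass per column, one shift-add per residue).
  `window_pvalue()` is then a table lookup of the upper tail. The tests pin
  this DP against exhaustive enumeration over small alphabets.
* **Best-of-$n$ correction.** $1-(1-p)^n$ (evaluated as
  `-expm1(n*log1p(-p))` so $p \sim 10^{-15}$ survives) rather than the
  Bonferroni $\min(1, np)$: bounded, exact under independence, and
  conservative under the positive dependence of overlapping windows.
* **QFAST in log space.** $q$ underflows long before scores stop being
  meaningful; the implementation works with $\ln q$ and a log-sum-exp over
  the series terms.
* **Deterministic tie-breaks everywhere.** Equal window scores go to the
  N-terminal start; equal motif lengths are processed in N→C profile order;
  fragment placement ties put gaps at the C-terminal side; report ordering
  breaks score ties lexicographically. Fixed inputs give byte-stable
  outputs.
* **Degenerate inputs.** Unknown residues (`X`, unmapped modified residues)
  score 0 — background expectation — rather than being errors; motifs that
  cannot be placed (sequence too short, no allowed window) contribute
  $p = 1$ to QFAST, so short sequences score 1 instead of failing.

## Alignment engine

Within a motif block every fragment is placed against the block's longest
fragment at the offset maximising the summed BLOSUM62 score, allowing
terminal gaps only. For the short (4–25 residue), unbroken fragments this
method produces, an internal gap would claim an indel *inside* a structural
active-site fragment — precisely what fragment-wise alignment is meant to
avoid — and offset placement is equivalent to global alignment with high
gap penalties while being trivially deterministic. It also keeps a full
Needleman–Wunsch implementation (`Biostrings::pairwiseAlignment`) available
as an independent oracle in the test suite rather than as part of the thing
being tested. Ties go to the smallest offset, i.e. gaps at the C-terminal
side, so extension pulls C-terminal flanking residues.

## What the synthetic fixtures do and do not show

`generate_family()` emulates the evaluation setting at desk scale: each
member's sequence is background spacers interleaved with point-mutated
copies of the motif templates, and the paired structure places one
pseudo-atom per residue so that planted motif residues fall inside the
10 Å ball of their key residue and everything else falls far outside. The
reference conditions — 20 members, motifs of lengths 8/6/5, per-column
substitution rate 0.1, 500 background decoys — are what the acceptance
checks run against; `trim_max` shortens the *structural* fragment while the
sequence keeps the full template, creating the heterogeneous fragment
lengths with conserved flanks that separate extension-to-longest from
legacy truncation.

What passing these fixtures shows: the geometry, alignment, extension,
exact-p-value and combination machinery are correct, calibrated on
background sequences, and behave in the documented direction when motifs
are lengthened. What it does not show: performance on real structures
(side-chain geometry, domain movements, crystallographic artefacts), real
evolutionary divergence (indels inside motifs, compositional bias,
homologous decoys that are *near* the family), or database-scale score
distributions. Thresholds quoted for real searches are taken from the
method's published operating points, not re-derived from these toys.

```{r example, eval = FALSE}
spec <- family_spec(seed = 7)
fam  <- generate_family(spec)
signatures <- bind_rows(lapply(seq_len(nrow(fam$key_residues)), function(i) {
  id <- fam$key_residues$protein_id[i]
  st <- read_structure(fam$structures[[id]])
  extract_signature(st, fam$key_residues$residue_refs[[i]], protein_id = id)
}))
prof <- build_profile(signatures, fam$sequences)
res  <- search_database(c(fam$sequences, generate_decoys(500, seed = 11)), prof)
glance(res)
autoplot(res)
```

## Design decisions that were genuinely open

* **Centres of geometry use heavy atoms only** (hydrogens excluded when
  present). Most depositions lack hydrogens; including them when present
  would make signatures deposition-dependent. All-atom selection is a flag
  (`heavy_only = FALSE`) for sensitivity analysis.
* **Altloc resolution**: highest occupancy, ties to `A`; **first model
  only** for multi-model files. Deterministic and matching common practice.
* **Key residues are addressed by author numbering** (what curators
  publish) and resolved to 0-based sequence positions internally.
* **Signatures are per-chain**; key residues spanning chains are rejected
  because a multi-chain site adds coordinate-frame ambiguity the method
  does not model.
* **Two key residues in one contiguous run** yield one key fragment
  (maximal runs); the key-fragment-count consistency check operates on the
  resulting fragments.
* **Partially occupied non-key blocks** are dropped by default (the
  `min_occupancy` threshold is configurable): PSSM columns are only
  meaningful with a row from every profile protein.
* **Unplaced motifs score $p = 1$** instead of aborting the sequence —
  strictly penalising missing motifs keeps the score defined and ranked
  sensibly for short sequences.

## Problem sizes

The shipped tests and the acceptance script run entirely on generated data:
families of 3–20 proteins, databases of up to 2,000 decoy sequences of
100–200 residues, 10⁷-draw Monte Carlo oracles for QFAST and 100-trial
enumeration oracles for the exact distribution. These sizes give the
statistical checks (3 Monte Carlo standard errors; 50 % relative slack on
null calibration at 10⁻²/10⁻³) enough resolution to be meaningful while the
whole suite completes in about two minutes.

## Known limitations

* No mmCIF input, ligand/cofactor awareness, or biological-assembly
  expansion; one chain per signature.
* Motifs are ungapped by construction; a true insertion inside an
  active-site fragment will cost score rather than open a gap.
* The exact p-value model assumes i.i.d. background residues; low-complexity
  regions violate it and can score optimistically, as in any PSSM scanner
  without a compositional correction.
* Numeric identity with historical implementations of this method family is
  not claimable: the PSSM construction details and p-value machinery of
  those binaries are not published; this package's construction honours the
  stated dependencies (motif length, protein length, background
  composition) with standard, documented choices.
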