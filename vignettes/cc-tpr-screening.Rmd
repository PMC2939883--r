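---
title: "Screening proteomes for carboxylate-clamp TPR co-chaperone candidates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening proteomes for carboxylate-clamp TPR co-chaperone candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cctpr)
```

## The biological question

Cytosolic Hsp90 ends in the pentapeptide MEEVD, and cytosolic Hsp70 in
GPTIEEVD. Many co-chaperones dock onto these acidic tails through a
tetratricopeptide-repeat (TPR) domain: three tandem copies of a degenerate
34-residue helix-turn-helix motif whose concave face forms a peptide-binding
groove. In clamp-type TPR domains, a set of basic and polar side chains --
the *carboxylate clamp* -- grips the EEVD carboxylates. Projected onto the
three motifs, the clamp consensus is Lys5 and Asn9 in motif I, Asn6 in motif
II, and Lys2 and Arg6 in motif III (positions 1-based within each motif).
Because these five residues are conserved across known Hsp90/Hsp70
co-chaperones (Hop, CHIP, PP5, Cyp40, FKBP51/52 and relatives), their
conservation in an otherwise uncharacterized TPR protein is a strong
predictor of Hsp90/Hsp70 binding. `cctpr` implements this screen as a
reusable, fully offline pipeline, validated against the curated Arabidopsis
(36 proteins) and rice (35 proteins) CC-TPR families shipped with the
package.

## The pipeline

### 1. Position profiles for the three motifs

Each motif index (I, II, III) gets its own 34-column position profile built
from the packaged motif alignments (`default_profiles()` pools both
families together with the human Hop TPR2a reference row). The score of
residue $a$ at column $c$ is a Laplace-regularized log-odds:

$$ S(c, a) = \log_2 \frac{(n_{c,a} + \alpha) / (N + 20\alpha)}{q_a} $$

with pseudocount $\alpha = 1$, $N$ training rows, and uniform background
$q_a = 1/20$. A window score is the sum over the 34 columns; `X` scores 0
at its column. Design notes:

* **Uniform background.** Proteome-specific residue frequencies would
  change scores by fractions of a bit; uniformity keeps the model fully
  reproducible from the packaged tables alone.
* **Pseudocount 1.** Keeps all scores finite; as $\alpha \to \infty$ the
  profile flattens to zero everywhere (a property the tests assert).
* **Scan threshold.** Per motif, `training_min_score - 2` bits, where
  `training_min_score` is the minimum self-score over the training rows.
  Every curated motif is admitted by construction, near relatives pass, and
  uniformly random 34-mers (mean score around -30 bits, Monte-Carlo checked
  in the tests) essentially never do. One curated outlier -- the highly
  divergent motif II of AtTPR4 -- pulls the motif-II minimum down to about
  -1.6 bits, making that threshold permissive; downstream domain assembly
  and clamp evaluation carry the specificity burden there, and the measured
  false-positive rate on background proteins is zero.
* **No insert/delete states.** This is a fixed-length profile scanner, not
  a profile HMM, and it attaches no E-value statistics; what is validated
  is recovery of the curated families and of planted synthetic domains.

### 2. Domain assembly and register rescue

`scan_protein()` scores every 34-mer against all three profiles and
collapses same-index hits within 17 residues to the local score maximum
(tandem TPR motifs are homologous, so one window can legitimately pass a
sister profile's threshold; assembly resolves this). `assemble_domains()`
chains every I→II→III triplet whose two linkers
(`start(next) - end(prev) - 1`) lie in `[-2, 60]` -- the range bracketing
the spacings observed in the curated families (-1 to 56) -- and keeps a
maximal non-overlapping set greedily by summed score. A protein may carry
more than one domain.

A repeat's assigned start can be off by one residue. The canonical case is
AtTPR5: the printed second motif starts at residue 118 with the consensus
Asn at position 5; re-initiating the motif at 117 restores the Asn to
position 6. `register_rescue()` shifts a motif by ±1 only when that
strictly increases the number of clamp positions holding their exact
consensus residue (ties keep the printed register; a tie between -1 and +1
prefers -1). The shift is bounded at one residue because that is the only
magnitude the curated data exhibit (AtTPR5 and its rice counterpart
Os05g03910, whose printed motif II is 33 residues for the same reason).
When only the printed window is available (no full-length sequence), the
unknown flanking residue enters as `X`. A side effect worth knowing: the
rule also re-registers the motif III of the Hop-family proteins (+1 moves a
Lys into clamp position 2); their verdicts are unchanged (4/5 matches
either way), so the rule is kept in its simplest strict-improvement form.

### 3. Clamp evaluation and the verdict

`evaluate_clamp()` reads the five clamp positions of an assembled (and
possibly rescued) domain and types each as `consensus`, `conservative`
(same substitution class) or `radical` (different class; `X` is always
radical). The classes -- \{K,R,H\}, \{D,E\}, \{N,Q\}, \{S,T\}, \{F,Y,W\},
\{L,I,V,M\}, \{A,G\}, \{C\}, \{P\} -- partition the 20 residues by
side-chain volume and polarity, and are fixed so that the substitutions
tolerated in confirmed co-chaperones (K↔R, N→Q) come out conservative
while K→E, R→A, R→M and N→S come out radical.

`classify_protein()` calls a protein CC-TPR-positive when its best domain
(most consensus-or-conservative positions, then highest summed score, then
smallest start) matches at **3 or more** of the five positions. Three is
the smallest threshold consistent with the curated families: AtTPR4 keeps
exactly 3 exact matches (with two radical losses) and is accepted. The
historical accept/reject rule involved manual judgment, so `min_matches`
is exposed as a parameter rather than hard-coded. Under the defaults, all
36 Arabidopsis and all 35 rice curated proteins classify positive, and the
architecture census of the 24 newly identified Arabidopsis proteins splits
8 / 7 / 3 / 6 over single-TPR, single-TPR-plus-domain, multi-TPR and
multi-TPR-plus-domain (additional-domain annotations come from the
packaged metadata table; the package deliberately does not re-implement a
domain database search).

### 4. Phylogeny

`neighbor_joining()` is a textbook NJ implementation (Q-criterion joins,
closed-form branch lengths, negative lengths clamped to zero, ties broken
by lowest label index, final edge split equally to give a rooted binary
representation). On any additive matrix it reproduces all path distances
within 1e-9, and the tests cross-check it against both a brute-force
4-taxon oracle and `ape::nj`. Distances come either from pairwise global
alignment (BLOSUM62, affine gaps 10/0.5) via `pairwise_distance()` -- the
argument order is canonicalized internally because co-optimal alignments
would otherwise make the p-distance asymmetric in the last decimals -- or,
for the curated families, from the concatenated 102-column motif alignment
(`motif_alignment()`), which needs no alignment step at all.
`bootstrap_support()` resamples alignment columns with replacement and
counts, for each internal bipartition of the point tree, the replicates
containing it; an alignment of identical rows degenerates to zero distances
and a deterministic topology, so supports equal the replicate count. The
published tree for these families was built from a progressive full-length
alignment that this package does not reconstruct, so published topology
and bootstrap values are explicitly not reproduction targets; the motif
alignment tree is a desk-scale analogue (71 leaves).

## The synthetic proteome generator

`generate_proteome()` produces test proteomes with known ground truth,
emulating the statistical structure the screen assumes -- not real
evolutionary data:

* **Background** proteins: i.i.d. draws from a residue background
  (default uniform), lengths uniform in 200-800 residues.
* **Planted** proteins: one I-II-III triplet sampled per column from the
  motif profiles, clamp residues forced to consensus, linkers uniform in
  0-56 (the curated range), embedded at a random offset.
* **Decoys**: as planted, but with 3 (configurable up to 5) clamp
  positions overwritten by residues from a *different* substitution class,
  so a decoy can match at most 2 of 5 positions. Decoy motifs additionally
  force the residues flanking each clamp position to differ from that
  clamp's consensus; without this, profile-sampled neighbours occasionally
  hold the consensus residue and a ±1 register rescue would "repair" a
  decoy that was meant to stay broken. With it, decoys are negative by
  construction, which is precisely the decision boundary they exist to
  probe.

Generation is a pure function of the spec (seed included). Defaults are
50/50/50 proteins per category. Under these conditions the full pipeline
attains planted-domain recall of at least 0.9 with exact coordinate
recovery, and zero false positives on decoys and background (asserted in
the acceptance tests at seed 1). What passing these tests does *not* show:
robustness to indels inside motifs, to evolutionary divergence beyond the
curated families, or to compositional bias in real proteomes -- the
generator simulates none of these.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere; a motif spans
  `[start, start + 33]`.
* Proteins shorter than 34 residues scan to an empty hit list (not an
  error); an empty FASTA file is an error.
* Printed 33-residue motif rows are loaded exactly as printed
  (`length_anomaly = TRUE`), excluded from profile training, and handled
  by the rescue path -- never silently padded. A clamp position beyond a
  short window reads `X` and types radical.
* Profile JSON serialization uses 17 significant digits so models
  round-trip bit-exactly.
* All randomness (bootstrap, generator) flows through explicit integer
  seeds; RNG state is restored on exit so library calls do not perturb a
  session.

## Worked example

```{r example, eval = FALSE}
library(cctpr)

# classify the packaged Arabidopsis family from its printed motif triplets
at <- classify_motif_table("arabidopsis")
sum(at$is_cc_tpr[grepl("^AT", at$locus_id)])   # 36

# the AtTPR5 register rescue
at[at$protein_name == "AtTPR5", c("start_II", "register_shifts")]

# end-to-end screen of a synthetic proteome with known truth
gp  <- generate_proteome(synthetic_spec(seed = 1))
res <- cc_screen(gp$records)
table(gp$truth$category, res$verdicts$is_cc_tpr)
```

## Known limitations

* The motif-II scan threshold is permissive (one divergent training row);
  specificity there rests on assembly and clamp evaluation.
* `min_matches = 3` is a reconstruction of a partly manual decision rule,
  not a mechanistic binding model; the package predicts clamp-residue
  conservation, not binding affinity.
* Degenerate TPR-like repeats (variable motif length, no clamp
  conservation) are out of scope by design.
* The NJ tree over the concatenated motif alignment ignores everything
  outside the TPR domain; it is a similarity summary, not a species-level
  phylogeny.
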