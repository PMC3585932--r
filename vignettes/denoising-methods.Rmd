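---
title: "Reference-anchored denoising of protein-coding pyrosequences: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-anchored denoising of protein-coding pyrosequences: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliclean)
```

## The model

`ampliclean` denoises pyrosequenced amplicons of protein-coding genes. Its
central assumption is biological: in genes such as mitochondrial COI,
insertions and deletions are essentially absent from real variation, so any
frameshift in a read relative to a reference must be a sequencing artifact.
The platform assumption is technical: 454-style pyrosequencers mis-call
homopolymer run lengths far more often than they substitute bases, so those
artifactual indels sit next to runs of two or more identical nucleotides.

Both assumptions feed a single scoring device. A **consensus reference
sequence** over the IUPAC ambiguity alphabet summarises the nucleotide
states expected at each position of the amplicon across a taxon. A read is
compared to it **positionally** — read position $i$ against consensus
position $\mathrm{offset}+i$ — with no realignment, and position $i$ is
scored by the suffix mismatch count

$$m_i = \sum_{j \ge i} \left[ \text{read}[j] \not\sim \text{consensus}[\mathrm{offset}+j] \right],$$

where $\sim$ is ambiguity-aware matching: two symbols match when their
IUPAC base sets intersect. An indel-free, error-free read of a known
haplotype scores $m_1 = 0$; a read with one homopolymer indel scores near
zero up to the indel and then mismatches a large fraction of downstream
positions. That step in the mismatch profile localizes the error; reverting
it is a one-base edit.

Reads that carry ambiguity codes themselves (the gap-filling rules below
can write them) are matched by the same set-intersection rule — the weakest
rule consistent with set semantics; anything stricter would penalise the
corrector's own conservative fills.

## The correction procedure

Correction operates on dereplicated unique sequences, with read counts
carried as weights and a re-dereplication afterwards to merge corrected
sequences that collide.

At each mismatch position $i$, scanned 5′→3′, two candidate repairs are
built:

* **Insertion removal** — if a homopolymer (run of ≥ 2 identical bases)
  ends at $i-1$, delete one of its bases, shifting the suffix left.
* **Deletion fill** — insert one base before $b_i$, shifting the suffix
  right. The inserted symbol extends the left-flank homopolymer if that
  base matches the consensus column, else the right flank if it matches,
  else it is the consensus symbol itself (which may be an ambiguity code).
  Bases pushed past the maximum read length are discarded.

Whichever candidate decreases the **total** mismatch count more is
accepted (ties prefer insertion removal); an edit that does not strictly
decrease the total is rejected. The mismatch vector is recomputed after
every accepted edit and scanning resumes just before the edit site.

Competing the two repairs at one site — rather than running a full
insertion pass before a full deletion pass — is a deliberate design
choice. Against the noisy background of a frameshifted suffix (roughly
three quarters of shifted positions mismatch a random consensus column),
a *spurious* single-base removal strictly decreases the total mismatch
count by chance alone with probability approaching one half per scanned
site. An insertions-first pass therefore corrupts a large fraction of
deletion-error reads before the gap fill ever sees them; in a side-by-side
comparison on reads carrying one injected run indel, pass-ordered
correction restored barely half of deletion-error reads while sitewise
competition restored all of them. The true repair lowers the total by an
order of magnitude more than a chance fluctuation, so the competition is
seldom close.

A third pass handles **compensated indels**: an insertion and a nearby
deletion whose net length change is zero, leaving mismatches only between
the two events. A region $b_{[i\text{–}j]}$ qualifies when it holds more
than one mismatch with at most one mismatched position upstream of $i$ and
downstream of $j$; the implementation takes the first/last mismatch
positions as bounds, optionally sparing one isolated mismatch on either
side, and tries both orientations (remove a homopolymer base at the $i$
end and insert a filled gap at $j$, or vice versa). The gap fill evaluates
the two flanking bases: if exactly one would extend to a homopolymer
consistent with the consensus column it is used; if both or neither
qualify, the ambiguity code pooling the flanking bases is written. The
best strictly improving orientation is accepted.

The sitewise and compensation passes iterate to a fixpoint. Acceptance
requires strict improvement, so the procedure terminates and is
idempotent; a per-read cap of 20 accepted edits (generous — a legitimate
read needs a handful) bounds pathological inputs, which are emitted in
their current state and flagged. Everything is deterministic for a fixed
input and parameter set.

Positions beyond the consensus coverage are scored as mismatches inside
the corrector. This matters when the reference is no longer than the
reads, as with a consensus built from same-length templates: a read
lengthened by an insertion error overhangs by one base, and the overhang
penalty is what lets the removal repair strictly win. The public
`suffix_mismatch_counts()` keeps a strict contract instead and rejects
overhanging reads, reporting the overhang size.

## Filtering parameters

All defaults (`pipeline_config()`) are the parameterization validated on
half-plate 454 COI test pools:

| parameter | default | meaning |
|---|---|---|
| `min_length` | 170 nt | reads shorter than this (post-trim) are dropped |
| `max_length` | 300 nt | reads truncated here before correction |
| `min_count` | 2 | singleton exclusion before the consensus filter |
| `max_mismatch` | 1 | permitted ambiguity-aware mismatches to the consensus |
| `trim_to` | 220 nt | alignment length kept at step 4 |
| `max_divergence` | 0.01 | step-5 divergence threshold (fraction of length) |
| `min_freq_ratio` | 0.10 | step-5 frequency threshold vs a retained neighbour |

The 220-nt trim reflects the corrector's intrinsic 3′ weakness: with few
anchor positions downstream, a mismatch step near the read end is
statistically indistinguishable from noise, so errors there often survive.
The divergence threshold is applied as $\lfloor 0.01 \times L \rfloor$
mismatches ($=2$ at $L=220$): a floor, because "at most 1% divergent"
should not round a third mismatch into the removable class. The frequency
rule is strict (`count(u) < 0.10 * count(v)`): a satellite at exactly 10%
is kept, which errs toward retaining genuine rare haplotypes.

The step-5 filter compares each sequence (descending count, names break
ties) against **already-retained** sequences only. The alternative —
single-linkage clusters — lets removals chain below sequences that were
themselves removed; greedy comparison prevents that, guarantees the
globally most frequent sequence survives, and makes the outcome
independent of input order.

Ambiguity-consistent merging (step 4) treats sequences as identical when
every position is compatible under set intersection; the merged sequence
takes the positionwise intersection, so unambiguous states win. Merging is
greedy by descending count into the highest-count compatible target (ties
by name) and repeats to a fixpoint, conserving total counts. The number of
resolvable positions per pair is unbounded — no cap is imposed because a
cap would make the outcome depend on how earlier merges reduced ambiguity.

The consensus **offset** (read position 1 ↔ consensus position
offset + 1) defaults to 0 and is configurable: where a published
full-barcode consensus begins relative to the sequenced fragment is not
derivable in general — the bundled 658-nt reference consensus, for
instance, does not register the bundled worked-example read at any offset
— so registration is left to the user rather than guessed.

Primer trimming removes the full matched primer by default. `trim_length`
is exposed as an integer because demultiplexing conventions differ: the
bundled worked example was demultiplexed upstream with 18 of the primer's
25 bases consumed, and reproducing its published unique sequence requires
`trim_length = 18`. No reverse-primer search is performed; the 220/300-nt
trims make it irrelevant.

## The consensus builder

`build_consensus()` follows EMBOSS-style ambiguity-consensus semantics:
per column, every row symbol expands to its base set, gaps are ignored,
and the IUPAC symbol for the union is emitted. Union semantics over many
hundreds of reference sequences degenerate toward an N-rich consensus, so
`min_state_freq` optionally drops bases below a column frequency before
the union; the default is 0 (pure union) because an over-inclusive
consensus only weakens filtering, whereas a cutoff silently narrows what
counts as "expected variation". All-gap or all-dropped columns emit `N`.

## What the simulator emulates — and what it does not

`simulate_templates()` draws indel-free, equal-length templates whose
pairwise Hamming distances are exact by construction (disjoint mutated
position sets) and verified before returning. The default community — 27
templates of 220 nt with pairwise divergence between 1 and 60 nt — mirrors
the mixed inter-/intraspecific structure of a validation pool of known
composition; for wide divergence ranges the templates split into two
clades (split $= \lfloor 2/3 \cdot \mathrm{max\_div} \rfloor$ positions)
with small within-clade distances, otherwise a single clade is used.
Abundances default to uniform: read abundance on this platform correlates
poorly with template input, so nothing is gained by skewing them.

`simulate_reads()` mutates each sampled read: every homopolymer run of
length $\ell \ge 2$ gains or loses one base with probability
$\min(1, r(\ell-1))$ — linear in run length, consistent with the
platform's error literature — with insertion and deletion equally likely
($r$ = `hp_indel_rate`, default 0.005), and every base substitutes with
`point_error_rate` (default 0.001). Numts enter as extra pool members, 2
per template at 1–2 mismatches from their parent and 5% of its abundance,
subject to the same read-error process. A truth table records every pool
member and read assignment. All randomness flows from an explicit seed and
the caller's RNG state is restored afterwards.

The simulator does **not** model flowgram signal intensities, quality
scores, chimeras, cross-contamination, length-dependent error gradients,
or primer-binding bias. Passing tests therefore demonstrate that the
algorithm inverts the error process it assumes — homopolymer-adjacent
indels plus sparse substitutions around known templates — not that it
removes every artifact class in field data; chimera screening and
taxonomic vetting remain external steps, and the step-6 flags exist
precisely because some artifacts (uncorrected compensated indels,
consensus-consistent numts) are only *probable* artifacts that merit eyes
before deletion.

## Validation design and problem sizes

The test suite validates each operation against an independent oracle
rather than against itself: suffix mismatch scoring against a naive
double-loop recount over IUPAC sets restated in the test helpers;
correction against an exhaustive enumeration of every single-base indel
repair; the indel-only error model against optimal global alignments
(`Biostrings::pairwiseAlignment`) required to contain no substitutions.
Property tests cover count conservation through dereplication and merging,
corrector idempotence, monotonicity of both filters in their thresholds,
retention of the most frequent sequence, and order invariance.

End-to-end checks run the full pipeline at the validation scale the
package targets — 27 templates, 10,000 reads, five independent seeds —
asserting complete template recovery and removal of every injected numt
still inside its target regime (count strictly below 10% of its parent at
the filter's input; binomial sampling occasionally lifts a 5%-abundance
numt to the boundary, and a boundary case is retained by design). Unit
and property tests use smaller sizes (tens of sequences, hundreds of
reads) chosen to exercise the code paths, not the scale.

## Known limitations

* Correction power decays toward the 3′ end (hence the 220-nt trim);
  errors in the final ~30 nt are often uncorrectable in principle under
  positional scoring.
* An N-rich consensus weakens both correction (fewer scoring positions)
  and filtering (step 4 passes more variants); `min_state_freq` trades
  this against inclusiveness.
* The frequency filter deliberately risks discarding genuine haplotypes
  that are both rare and close to an abundant relative; sampling more
  communities, not tighter thresholds, is the remedy.
* Numts indistinguishable from orthologous mtDNA — normal frequency, no
  indels, typical substitutions — pass every filter by construction.
* The pipeline is FASTA-only by design: flowgram-space denoising and
  quality scores are out of scope.
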