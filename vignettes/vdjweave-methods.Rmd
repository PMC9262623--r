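---
title: "Assembling full-length TCR coding sequences: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling full-length TCR coding sequences: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdjweave)
```

## The problem

T cell receptor (TCR) chains arise by V(D)J recombination: a variable (V)
and joining (J) gene segment are joined with imprecise trimming and
non-templated nucleotide addition at the junction, producing the
hypervariable CDR3. Rearrangements are almost always reported in compressed
form — a V gene call, a J gene call, and the CDR3 junction (the residues
running inclusively from the conserved V-gene cysteine to the conserved
J-gene phenylalanine or equivalent) — while expression, engineering and many
computational applications need the complete spliced coding sequence:
leader, V, junction, J and constant region. vdjweave reconstructs that
sequence deterministically, and ships the machinery needed to validate the
reconstruction end to end on simulated ground truth.

## The stitching procedure

Given a reference set (IMGT-dialect germline FASTA plus a codon-usage
table), a single rearrangement is assembled as

```
extra5' + leader + V(trimmed) + junction + J(trimmed) + constant + extra3'
```

The only non-trivial step is deciding which junction positions the germline
genes can wholly encode. Both junction ends are anchored at conserved
residues located once per reference:

* **V side.** The conserved cysteine is found by scanning the last twelve
  translated V residues for the final `C`. The junction's first residue is
  anchored there and the germline match extended rightward maximally. This
  is the fixed-point form of the usual description — incrementally deleting
  germline V residues until the junction start matches — and it places the
  junction correctly even when recombination deleted part of a codon and
  the insertion re-encoded that residue. A junction that does not begin
  with `C` simply gets zero V attribution plus a warning.
* **J side.** The conserved terminal residue is the `[FWC]` of the
  `[FWC]-G-x-G` motif nearest the J's 3' end (scanned over all three
  frames). The junction's last residue must sit there — otherwise the
  rearrangement is rejected as unstitchable, the dominant real-world
  failure mode for truncated junction reports — and the match is extended
  leftward maximally.

Whatever neither gene can encode is the non-templated fill. Its nucleotide
source depends on the input mode:

* **aa** — the junction is amino acids; fill residues are back-translated
  with the most common codon per residue from the species codon-usage
  table (ties broken alphabetically, so output is reproducible).
* **nt** — the junction is the exact nucleotide junction; it is translated,
  decomposed as above, and the fill copies the provided nucleotides
  verbatim. Germline-attributed residues still take germline codons, so a
  synonymous variant at a recombination edge (e.g. `AGT` where germline has
  `AGC`) is normalized to germline — the one residual source of nucleotide
  differences in this mode, and it is always synonymous.
* **sl** (seamless) — the provided sequence extends beyond the junction
  into germline context. Overlap detection is at the nucleotide level: the
  provided 5' end is searched against the incrementally deleted V 3' end,
  the provided 3' end against the J 5' end, exact match only, at least
  `sl_min_overlap` (default 10) nt per side. The provided sequence is then
  integrated verbatim, reproducing the original nucleotide sequence
  exactly when the context matches germline.

All three modes encode the same protein; they differ only in how much of
the original nucleotide sequence can be preserved.

Leaders default to the V gene's own, falling back to the prototypical `*01`
leader (with a warning) when the requested allele has none recorded.
Constant regions default by locus: beta chains follow the TRBJ cluster
digit (`TRBJ1-n → TRBC1`, `TRBJ2-n → TRBC2`), alpha takes TRAC, gamma
TRGC1, delta TRDC. Because other species can differ in locus architecture,
non-human/non-mouse requests must name the constant region explicitly.
Both defaults can be overridden per rearrangement. Non-canonical junctions
(not starting `C`, not ending `F/W/C`), internal stops and leader fallback
are reported as structured warnings, upgradeable to errors with
`strict = TRUE`, because engineered receptors legitimately violate the
canonical pattern.

The batch driver applies this row-wise over an AIRR-style tab-separated
table (`alpha_v_call`, `beta_junction_aa`, ...), captures every failure
per row without aborting the run, and can link paired chains into one
bicistronic open reading frame: the 5' chain's stop codon is removed and a
linker inserted — the standard 2A self-cleaving peptides (P2A, T2A, E2A,
F2A) are built in, arbitrary in-frame sequences are accepted. An IRES is
deliberately not offered as a named linker because it is not a
single-ORF element, which is the invariant `link_chains()` guarantees;
users can still pass any sequence explicitly.

## The tiled-tag annotator

To recover V/J calls (and ultimately unrecorded alleles) from reads, every
allele of every V and J gene is tiled with 20-nt tags every 10 nt, plus a
terminal tag anchored at the 3' end; interior positions are therefore
covered by exactly two tags. The tags populate a Biostrings `PDict`
multi-pattern matcher. A read's candidate alleles are scored by the number
of *collinear* tag matches — matches whose read-to-allele offset agrees
exactly — which suppresses chance k-mer hits; the call set is the alleles
attaining the maximal count, with at least two matches required, and ties
flagged as ambiguous. Jump values report coverage: `v_jump = 0` exactly
when the read covers the V-REGION start, which is the full-length filter
used throughout. The junction is extracted verbatim from the read between
the projected V-cysteine and J-anchor codons.

A single-nucleotide variant (SNV) relative to the recorded germline makes
exactly the two tags covering it fail while their neighbours match. The
novel-allele inference clusters identical break-spanning sequences per V
gene and applies four thresholds to separate germline variants from
PCR/sequencing noise: the variant must (i) occur in a gene with ≥ 10
distinct unambiguous recombinations, (ii) account for ≥ 5% of the gene's
reads, (iii) occur in ≥ 3 unique recombinations, and (iv) account for
≥ 10% of the gene's break-bearing reads. Thresholds are applied first and
the genotype rank filter (top two most abundant break sequences per gene)
second; the order is a design choice — the two filters interact, and
threshold-first means a noise flood can never displace a genuine variant
from the genotype before it is tested. Candidates are named by suffixing
the variant to the base allele (`TRAV27*01_A233G`, 1-based V-REGION
coordinates), emitted as IMGT-dialect FASTA, and can be merged back into
the reference, after which both the annotator and the stitcher accept the
suffixed call (leaders fall back to `*01`).

Two noted limitations: substitutions within half a tag of an allele end
break only one tag and are invisible to the two-tag rule; and indels shift
tag spacing and are reported as unresolved breaks, never as candidates —
the inference deliberately targets SNVs only.

## The simulator and what passing tests mean

The simulator provides exact ground truth over any reference, including
the bundled fixture: a deterministic, synthetic, human-like TRA/TRB
reference (7 V genes + one extra allele, 6 J genes, 3 constants, leaders,
realistic anchors; all segments codon-aligned). The fixture's sequences
are random-but-constrained, not real germline genes — small enough to
hand-check and free of licensing entanglements.

Each simulated rearrangement draws a V and J allele, uniform exonuclease
trims on `[0, 6]` nt per side (never removing the conserved anchors),
and a bounded-geometric insertion (mean 4 nt, cap 20) padded by 0–2 nt to
preserve the reading frame. Draws are rejected and redrawn until the
junction is stop-free, at least 8 residues long, and terminates in F/W/C —
the standard productive-chain filters. Trim and insertion distributions
are fixture knobs chosen once as plausible magnitudes, not biological
claims; the junction length floor and terminal-residue set are the
field-standard filters. A rejection-rate guard (500 consecutive rejects)
catches pathological parameter combinations. Everything is a pure function
of the seed; the caller's RNG state is saved and restored.

What the simulator does **not** emulate: sequencing/PCR error (beyond
deliberately injected SNVs), biologically calibrated gene-usage and
trimming distributions, D genes as explicit segments (insertions subsume
them), allele-specific leaders, and non-codon-aligned segment ends. Tests
passing on this fixture therefore demonstrate algorithmic correctness —
round-trip identity, localization, threshold logic — not robustness to
noisy real-world reads, which upstream error correction is expected to
handle.

## Numerical and design choices

* Determinism everywhere: modal-codon ties alphabetical, allele call sets
  sorted, seeds mandatory for all randomness, byte-identical reruns.
* Seamless overlap is exact-match only; a below-minimum overlap is an
  error, never a silent fallback to nt mode, preserving the "seamless
  means identical" guarantee. Pads containing a SNV relative to germline
  simply shorten the detected overlap; the provided sequence is always
  retained verbatim once the minimum is met.
* V attribution is capped at junction length − 1 so the terminal residue
  is always anchored at the J.
* Pseudogene (`P`) records stitch only behind an explicit flag; `F` and
  `ORF` are usable by default — an expression-construct-oriented choice.
* Partial IMGT records are parsed and flagged but not rejected; the flag
  lets downstream analyses filter them, mirroring common practice.
* Constants are stored as single pre-spliced coding blocks; exon
  bookkeeping (membrane vs secreted variants) is treated as a
  reference-preparation concern, out of scope here.
* Validation problem sizes, chosen to give tight percentages while keeping
  the suite quick: 1,000 simulated rearrangements for the round-trip and
  annotator checks, 200 junctions against the brute-force decomposition
  oracle, 10,000 rows for batch robustness, and 10²/10³/10⁴ rows for the
  linear-scaling fit.

## Worked example

```{r example}
ref <- fixture_reference()
res <- stitch_tcr(ref, "TRBV1", "TRBJ1-1", "CASSLGNTEAYF", mode = "aa")
res
substr(res$translation, 17, 40)
res$offsets$junction_fill
```

The result object records the assembled sequence, its translation, the
0-based half-open offsets of every segment (extra5, leader, v_germline,
junction_fill, j_germline, constant, extra3 — they tile the sequence
contiguously), and any warnings.

## Known limitations

Only substitution-type novel alleles are inferred; gamma/delta loci are
supported by the stitching rules but not present in the bundled fixture;
and junction decomposition trusts the reported V/J calls — a wrong call
produces a fluent but wrong construct, which is why the seamless mode with
sequencing-derived context is preferred whenever nucleotide-level fidelity
matters.
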