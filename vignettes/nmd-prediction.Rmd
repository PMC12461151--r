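---
title: "Predicting NMD from splicing events: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting NMD from splicing events: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Nonsense-mediated decay (NMD) in its canonical, exon-junction-complex
dependent form degrades a transcript when translation terminates at a
premature termination codon (PTC) lying 50–55 nt or more upstream of the
final exon–exon junction. `splice2nmd` operationalizes this rule for four
splicing event types quantified by Whippet — exon skipping (ES, Whippet's
core-exon CE nodes), retained intron (RI), alternative acceptor (AA) and
alternative donor (AD) — applied one at a time to the Ensembl canonical
transcript of each gene.

For an event with net length change $\Delta$ applied to a canonical
transcript with start codon at transcript coordinate $c$:

1. **Surgery.** The exon block list is edited (exon removed; intron fused
   between its flanking exons; acceptor or donor edge moved), the mature
   sequence re-concatenated in transcription order (reverse-complemented
   for minus-strand genes), and junction coordinates recomputed as the
   cumulative block lengths.
2. **Frame.** The reported `predicted_frame` is $\Delta \bmod 3$ for events
   that touch the CDS, and 0 otherwise; frame 0 means the annotated frame
   is preserved downstream of the event.
3. **PTC scan.** Stops (TAA/TAG/TGA) are enumerated in each of the three
   frames anchored at $c$. Frame 0 of the *modified* transcript is the
   frame the ribosome actually reads; the mapped annotated terminator is
   excluded from its list, so frame-0 entries are premature by
   construction. Codons containing `N` are never stops.
4. **Call.** Translation terminates at the first frame-0 stop $p$. The
   event is called NMD-true iff $p$ exists and is not the annotated
   terminator, the modified transcript retains at least one junction, and
   $d = J - (p + 2) \ge t$, where $J$ is the last junction position and
   $t$ the rule threshold. Everything else maps to a reason code
   (`NO_PTC`, `PTC_IN_LAST_EXON`, `PTC_TOO_CLOSE`, `NO_JUNCTION`,
   `NO_CDS_CHANGE`, `START_LOST`, `NOT_ON_CANONICAL`, `UNSUPPORTED_TYPE`).

### Why the call uses the translation frame

The per-frame PTC lists are anchored at the start codon of the modified
transcript, so the stops a ribosome actually encounters are exactly the
frame-0 list — for a frameshifting event the *annotation-relative* frame
differs, which is what `predicted_frame` reports. A decision rule indexed
by `predicted_frame` into the per-frame lists would diverge from literal
translation for frameshifts; we therefore report the frame label and the
three per-frame counts, but always derive the call from the frame-0
(translation) scan. This is also what makes the pipeline provably
equivalent to the brute-force oracle (below).

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `ptc_junction_threshold_nt` | 50 | nt | conservative edge of the canonical 50–55 band; validated to stay in the band unless explicitly overridden |
| `prob_min` | 0.9 | posterior prob. | Whippet documentation's significance recommendation (inclusive) |
| `abs_dpsi_min` | 0.1 | ΔΨ fraction | Whippet recommendation; strict inequality |
| `stop_codons` | TAA, TAG, TGA | — | standard genetic code |

Distance is measured from the **last base** of the PTC codon to the final
junction, matching the point where the terminating ribosome sits relative
to downstream exon-junction complexes; codons overlapping a junction are
positioned by their first base.

## Design decisions

* **Coordinates.** Everything internal is 0-based half-open; Whippet
  `Coord` (1-based inclusive) and GTF are converted at the parse boundary.
* **Canonical selection.** The `Ensembl_canonical` tag wins; without it,
  the transcript with the longest summed CDS is chosen, ties broken by
  lexicographic transcript id — deterministic and close to Ensembl's own
  definition. Genes whose selected transcript has no CDS are
  non-processable and skipped with `NOT_ON_CANONICAL`. (The repeated GTF
  `tag` attribute is collapsed by `rtracklayer`, so the canonical tag is
  additionally detected from the raw attribute text.)
* **Stop dialects.** GTFs that include the stop codon in CDS features and
  GTFs that emit separate `stop_codon` features are both accepted; the
  extent is normalized to stop-included, resolved against the genome
  sequence when ambiguous.
* **Event placement.** CE must match one internal exon exactly (terminal
  exons belong to AF/AL/TS/TE, which are out of surgery scope); RI accepts
  both the bare-intron and the exon–intron–exon coordinate dialects,
  detected by boundary matching; AA/AD must share the fixed exon edge,
  the other boundary defining the shifted site. Unplaceable events are
  counted and skipped, never guessed.
* **Isoform modeled.** The pipeline always models the non-canonical
  (event) isoform — exon skipped, intron retained, shifted site used —
  regardless of the sign of ΔΨ, since that is the PTC-generating form the
  decision concerns; ΔΨ's sign is used only by the protein-direction rule.
* **ES of the stop-codon exon** is allowed; the transcript loses its
  annotated terminator, translation is re-scanned, and the result carries
  the `StopExonSkipped` note.
* **Events outside the CDS** (entirely 5′ of the start or 3′ of the stop)
  that leave translation ending at the annotated terminator are reported
  `NO_CDS_CHANGE`; a lost start codon is a skip (`START_LOST`), not a
  call.
* **Statistics.** 2×2 comparisons use the chi-square test with Yates
  correction when any expected cell is below 5 (the conventional rule);
  continuous comparisons are gated by Shapiro–Wilk at α = 0.05 between t
  and Wilcoxon; |ΔΨ| magnitude comparisons report Anderson–Darling
  normality p-values for context and a Wilcoxon rank-sum p-value (exact
  for small untied samples, normal approximation with continuity
  correction otherwise, R's standard behavior).
* **Boundary semantics.** `probability ≥ 0.9` is inclusive and
  `|ΔΨ| > 0.1` strict; `d ≥ t` is inclusive, so `d = 50` is NMD-true at
  the default threshold.

## The synthetic-data generator

`make_toy_genes()` builds one gene per short chromosome (a few kb), with
4 exons (2 for the no-junction design), a 12 nt 5′UTR, and CDS spanning
all exons. Gene bodies are generated over `{A, C, G}` only, so the
background contains no stop codon in any frame; the start codon, the
normal terminator and every designed PTC are planted explicitly at known
positions and phases. Truth labels — net length change, frame,
PTC-to-junction distance, PTC count, NMD flag, reason — are therefore pure
arithmetic, computed without running the pipeline.

Defaults encode the baseline study conditions: type mix ES/RI/AA/AD =
76.3/9.5/8.1/6.1%, NMD-true fraction 0.907, per-type PTC-count medians
37/23/24/30. Counts are jittered within ±3 with extra mass at the designed
value so the population median stays exact despite the low-count NMD-false
designs. Degenerate branches (start lost, no junction, no CDS change,
unplaceable events, transcription-related types) and both strands are
generated at configurable proportions; `make_boundary_genes()` produces
exact PTC-to-junction distances (49/50/51/54/55/56) around the rule
threshold.

What the toys do **not** emulate: splice-site motifs (GT–AG), realistic
base composition (the T-free background is a control device), psi
estimation noise, multiple simultaneous events per transcript, overlapping
genes, and real exon/intron length distributions. Passing tests therefore
demonstrate the correctness of the coordinate arithmetic, surgery,
scanning and rule logic — not calibration against biological cohorts.

## Validation strategy

An independent brute-force oracle (`oracle_nmd`) re-derives each call
naively: literal string surgery on the exon chain, a per-base
genomic-position vector for coordinate mapping, codon-by-codon translation
from the start codon, and a direct distance comparison. It shares no code
with the surgery or classification modules. The test suite requires 100%
agreement between pipeline and oracle over mixed cohorts of 200 genes ×
seeds 1–5 × thresholds {50, 55} (2,000 calls, both strands, all degenerate
branches represented), plus exact truth recovery, strand-mirror invariance
(reverse-complemented genome with reflected coordinates yields an
identical result table) and boundary flips exactly at the configured
threshold. Cohort-level recovery is checked on 1,000 genes (rate within 3
binomial SDs of the designed 0.90; ES PTC median at the designed 37 ± 1).
These sizes keep the full suite under a couple of minutes while giving
every branch double-digit coverage.

## Known limitations

* Only PTC-dependent, EJC-based NMD is modeled: no long-3′UTR or
  uORF-triggered branches, no decay kinetics or NMD efficiency.
* One event at a time on one canonical isoform; combinatorial isoforms and
  non-canonical transcripts are out of scope.
* AF/AL/TS/TE events are categorized and counted but never surgically
  applied.
* The protein-direction rule is deliberately minimal (defined only for
  genes without significant differential expression) and is a hypothesis
  generator, not a quantitative predictor.
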