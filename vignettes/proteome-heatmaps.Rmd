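---
title: "Methods: one-versus-all proteome heat maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: one-versus-all proteome heat maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repliconmap)
```

## The model

repliconmap summarizes the relationship between one bacterial genome (the
*seed*) and an arbitrary collection of replicons as a matrix of best-hit
percent identities. The design follows three commitments:

1. **Protein, not nucleotide, comparison.** Amino-acid identity remains
   informative at evolutionary distances where nucleotide alignments have
   decayed into noise, at the cost of ignoring intergenic sequence.
2. **Gene-order-preserving columns.** Columns are the seed's proteins ranked
   by the start coordinate of their genes, so runs of adjacent columns are
   physical gene blocks: deletions, islands and prophages appear as
   contiguous features even though only proteins are compared.
3. **One row per replicon**, not per genome. Plasmid-to-chromosome
   integration and inter-replicon translocations stay visible.

For a seed protein $p$ (length $m$) and a database of $n$ total residues,
every database protein is aligned to $p$ by Smith–Waterman local alignment
with affine gaps. An alignment with raw score $S$ is significant when its
Karlin–Altschul E-value

$$E = K\,m\,n\,e^{-\lambda S}$$

is strictly below the cutoff (default $10^{-20}$; equality is excluded, and
the cutoff is deliberately conservative — it gates which cells *exist*, not
how they are coloured). Significant hits are consolidated to one best hit
per replicon, ranked by bit score, then E-value, then percent identity,
then subject id; ranking by identity first is available via
`rank_by = "identity"`, since "closest homolog" admits either reading. The
stored value is the BLAST-convention identity,
$100 \cdot \text{identities} / \text{alignment length}$, with gap columns
counted in the length. Note the best *hit* is the closest scoring homolog,
which is not necessarily the ortholog.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| substitution matrix | BLOSUM62, X ≡ 0 | BLASTP default; the mask letter X scores 0 against everything, itself included, so masked runs can neither create nor destroy significance |
| gap open / extend | 11 / 1 | BLASTP default; a gap of length $L$ costs $11 + L$ |
| $\lambda$, $K$ | 0.267, 0.041 | gapped-BLOSUM62 Karlin–Altschul constants |
| E-value cutoff | $10^{-20}$, strict `<` | cell-existence gate |
| search space | $m \times n$ (query × database residues) | no edge-effect or composition corrections |
| PID threshold | 0 (display) | masks cells *strictly below*; the boundary value is kept |

The internal E-value model is intentionally the plain ungapped-style formula
with fixed gapped constants: deterministic, documented, and accurate enough
for thresholding at $10^{-20}$, where true homologs at fixture scale sit
many orders of magnitude below the cutoff and random alignments many above
it. It does not reproduce NCBI composition-based statistics; when the
external BLAST+ backend is used, borderline low-identity cells can therefore
differ between backends while matrix layout is guaranteed identical.

## Rendering

The display pipeline is `reorder rows → threshold mask → max-downscale →
colourize`:

* **Max-sampling.** Averaging a block of cells lets one transferred gene
  vanish into its faint neighbourhood. Representing each block by its
  maximum instead makes high values "rise to the top" as the image shrinks:
  a single unmasked cell in a 1000×1000 grid survives a 10×10 downscale by
  construction. Blocks are contiguous rectangles with integer boundaries
  $\lfloor i \cdot n / \text{out} \rfloor$, a deterministic near-even
  partition with no padding; every input cell belongs to exactly one block.
* **Masking precedes downscaling**, so a filtered value can never win a
  block maximum and reappear zoomed out.
* **Colour.** Anchors at 0% → `#FFFFE0`, 20% → yellow-green `#9ACD32`,
  70% → blue `#0000FF`, 100% → red `#FF0000`; masked/missing cells render
  as white. Between anchors each RGB channel is interpolated linearly —
  colour-space-correct interpolation was considered and rejected in favour
  of exact reproducibility of the integer arithmetic across platforms. The
  named anchor colours are conventional for identity legends; the scale is
  user-replaceable.
* **Sorting** orders rows by ascending mean identity over chosen columns so
  the most similar proteomes sit at the image bottom. Missing cells count
  as 0 by default — a proteome that lacks a protein is maximally dissimilar
  for that column — with hits-only averaging behind an option. Ties break
  by accession so renders are reproducible.

## Ingestion choices

* Gene order is the rank of the CDS start coordinate, ascending, strand
  ignored. Strand-aware or join-aware orderings were considered; start
  coordinate is the only choice that is total, deterministic and
  annotation-robust, at the cost of possibly differing from a
  transcription-order reading for rare wrap-around genes.
* Pseudo-genes and CDS without a `/translation` are skipped and counted in
  a parse report, not fatal — real GenBank files contain both routinely.
* Multi-replicon seeds concatenate their replicons' columns in argument
  order (no inter-replicon order is inherent in the data, so the call makes
  it explicit).
* Ambiguity letters B, Z, U, J, O and `*` fold to X with a warning, keeping
  the scoring table closed.
* The structured FASTA dialect writes two optional fields
  (`locus_tag`, `replicon_kind`) beyond the minimal five so that a
  proteome round-trips field-for-field; five-field headers still parse.

## The matrix file

"Labelled and tab-delimited" is made concrete as: `#` header lines
(format version, seed, cutoff, backend, note), one `#%col` line per column
for locus tag and product, a column-label line, then one row per replicon
with three label fields and fixed-point two-decimal cells; missing cells are
empty fields. Two decimals make the round trip exact (serialization
quantizes to 0.01, which is below any biologically meaningful identity
difference); files re-validate all invariants on load, and row order in the
file is authoritative — renderers never re-sort on read.

## The synthetic universe

`make_test_universe()` generates the fixture set every end-to-end claim is
tested on: a 20-protein seed (protein lengths uniform in 150–300 aa,
uniform amino-acid composition) and nine derivatives:

* divergence at substitution rates **0.02, 0.10, 0.30** — spanning
  strain-level to cross-genus protein identity;
* a **5-protein deletion** (seed ordinals 8–12) at background rate 0.02;
* an **HGT recipient** (rate 0.02) whose 4-protein block at ordinals 3–6 is
  a near-verbatim copy (rate 0.01) of the rate-0.30 genome's block;
* four near-identical strains (rate 0.01) sharing one **fast-clock column**
  (ordinal 15) at rate 0.25.

The mutation model is substitution-only — each residue is independently
replaced with probability equal to the rate, by a uniformly chosen
different letter. This keeps the identity-rate mapping analytic
(expected identity $\approx 100(1-p)$, self-alignments gap-free), which is
what the parameter-recovery assertions need; within-protein indels would
add realism but nothing the matrix semantics test. Uniform composition
(rather than natural amino-acid frequencies) maximizes the significance of
true homologs in a tiny database, so all planted homologies clear the
$10^{-20}$ gate with 150–300 aa proteins. Generators are pure functions of
their seeds; the default universe is byte-reproducible.

What passing these fixtures does **not** show: behaviour on real proteomes
with biased composition, low-complexity regions, domain shuffling, true
paralogy networks, or the scale (thousands of replicons, matrices of
millions of cells) of a full database — at that scale the per-query
alignment loop, not the renderer, is the bottleneck, and the external
BLAST+ backend is the practical choice.

Problem sizes used throughout the tests and the acceptance script — 20-seed
proteins against a ~200-protein database, 100-pair oracle checks at ≤ 30
aa, 100 random grids up to 40×40, a single 1000×1000 survivor grid — were
chosen so the full suite re-runs comfortably on a laptop core while still
exercising every code path at full strength.

## Degenerate inputs and tie-breaks

* Alignment of pure-X sequences has optimal score 0 → "no alignment", by
  design (X ≡ 0).
* Co-optimal local alignments: the traceback Biostrings chooses can depend
  on argument order, so `align_pair()` canonicalizes pair orientation,
  making score *and* identity exactly symmetric.
* `sort_rows()` under hits-only averaging maps an all-missing row to mean
  0 rather than NaN.
* `max_downscale()` refuses upscaling; the high-level renderer instead
  clamps requested raster sizes to the matrix dimensions.
* Empty seed proteomes, duplicate accessions, duplicate or gapped ordinals,
  out-of-range cells and ragged matrix files are all hard errors that name
  the offending record or line.

## Known limitations

* The internal aligner is quadratic per pair and R-resident; it is built
  for fixture-scale and method-validation use, with BLAST+ as the scale-out
  path.
* E-values ignore edge effects and composition; do not compare internal
  E-values numerically with BLAST's, only through the cutoff.
* `parse_genbank()` reads the feature-table subset it needs (CDS locations,
  the handful of qualifiers, LOCUS/DEFINITION/ORGANISM); it is not a
  general GenBank round-tripper.
* The interactive GUI experience (live zoom, clickable cells) is out of
  scope; the HTML export's hover text covers the identify-this-cell use
  case statically.
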