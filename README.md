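# repliconmap

One-versus-all proteome comparison for bacteria: compare a *seed* genome's
proteins against every chromosome and plasmid in a protein database and view
the result as a gene-order-preserving heat map.

## The problem

Bacterial genomes are remodelled by gene loss, duplication, divergence,
prophage integration and horizontal gene transfer, so the relationship
between two genomes is rarely a single number. A one-versus-all comparison
keeps the whole picture: for every protein *p* of a chosen seed genome and
every replicon *r* (one chromosome or plasmid) in the database, the cell

> M[r, p] = percent identity of the best significant local alignment of
> *p* against the proteins encoded on *r*, or missing if none

forms a matrix whose columns follow the seed's gene order and whose rows are
replicons. Rendered as a heat map, vertical stripes mark unusually conserved
or unusually unique gene clusters, gaps mark deletions and genomic islands,
high-variance columns mark fast-clock genes useful for strain subtyping, and
anomalously red cells in otherwise faint rows expose horizontal transfer
between distant lineages.

Concretely, each cell comes from Smith–Waterman local alignment (BLOSUM62,
affine gaps 11/1), with significance assessed by the Karlin–Altschul
E-value

```
E = K · m · n · e^(−λS),   λ = 0.267, K = 0.041
```

(*m* = query length, *n* = database residues, *S* = raw score), keeping
alignments with `E < 1e-20` strictly and consolidating them to the
best hit per replicon (bit score, then E-value, then identity, then subject
id). `PID = 100 · identities / alignment length`, the BLAST convention.
An external BLAST+ backend (`backend = "blast"`) is available when the
executables are installed; it changes cell values only, never layout.

Because a full matrix can dwarf a monitor, rendering uses **max-sampling**
downscaling: each block of cells is represented by its *maximum*, never its
mean, so a single high-identity cell — one transferred gene — survives any
zoom level. A percent-identity threshold masks faint cells before
downscaling, and rows can be sorted by mean identity to the whole proteome,
a column range, or a single column.

## Worked example

The package ships a synthetic-evolution simulator, so a complete study runs
in seconds without downloads:

```r
library(repliconmap)

uni <- make_test_universe(42)   # seed + 9 derived genomes, planted events
m   <- build_matrix(uni$seed, uni$db)
m
#> <identity_matrix> 10 replicon(s) x 20 seed protein(s), 97.5% cells filled
glance(m)
#>   n_replicons n_seed_proteins fill_fraction mean_identity median_identity
#> 1          10              20         0.975      94.08358        98.68421
```

Mean identity tracks the planted substitution rates (rate 0.30 genome ≈ 70%
identity), and the deletion genome's row is missing at exactly the deleted
columns:

```r
library(dplyr)
tidy(m) |>
  filter(replicon_accession == "SYNDIV30") |>
  summarise(mean_pid = mean(percent_identity, na.rm = TRUE))
#>   mean_pid
#> 1     71.0
which(is.na(m$cells["SYNDEL01", ]))
#> 9 10 11 12 13          # the planted 5-gene deletion at ordinals 8-12
```

Sort, search and render:

```r
sort_rows(m)                      # ascending mean identity; self row sinks
#> [1]  4  1  3  9  6  5  7  8  2 10  # SYNDIV30 on top, SYNSEED01 at bottom
locate_matrix(m, "lacunosa")
#>   kind index matched_field               label
#> 1  row     1 organism_name Synthetica lacunosa
render_heatmap(m, "map.png",
               render_spec(pid_threshold = 20, row_order = sort_rows(m)),
               html_path = "map.html")   # PNG raster + hover-text HTML
autoplot(m, pid_threshold = 20)          # ggplot quick look
```

Matrices round-trip through a labelled tab-delimited file
(`write_matrix()` / `read_matrix()`), and a thin CLI wraps the same
functions: see `inst/cli/repliconmap` (`ingest`, `build`, `render`,
`simulate`, `validate`).

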