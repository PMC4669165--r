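# Reference tables (drop-in location)

The desk-scale reproduction tests and the acceptance script look here for
the published supplementary tables of the WNT-network study this pipeline
mirrors. The tables are journal supplements (XLS) and are **not
redistributed** with this package; to run the reproduction checks, download
them, export each sheet as TSV, and place the files here:

| file | content |
| --- | --- |
| `s2_canonical.sif` | merged canonical WNT network (`source`, `target`, `weight` 1/-1) |
| `s2_noncanonical.sif` | merged non-canonical WNT network |
| `s2_inhibition.sif` | inhibition-of-canonical network |
| `s2_regulation.sif` | regulation-of-WNT network |
| `s3_wnt_genes.txt` | 121 reviewed WNT genes, one HGNC symbol per line |
| `s4_microarray_degs.tsv` | microarray DEG table (`gene`, `log_fc`, `p_value`, `adj_p`) |
| `s5_rnaseq_degs.tsv` | RNA-Seq DEG table (same columns) |
| `s6_noncanonical_original.edges.tsv` | non-canonical module edge list (SIF columns) |
| `s6_noncanonical_validation.edges.tsv` | its RNA-Seq validation counterpart |
| `s6_canonical_original.edges.tsv` | canonical module edge list |
| `s6_canonical_validation.edges.tsv` | its RNA-Seq validation counterpart |

With the files absent the corresponding test blocks fail (they are checks
against published numbers, not synthetic stand-ins); all other tests are
self-contained.
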