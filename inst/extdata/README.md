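# Bundled fixtures

`chr17q23_genes_hg19.tsv` — a minimal hand-curated gene annotation for the
chr17q23 neighborhood (GRCh37/hg19 gene spans, approximate to the gene
level), down-sampled to the genes needed to exercise amplicon/gene overlap
counting: the six protein-coding genes of the 17q23.2 amplicon (PPM1D,
BCAS3, TBX2, C17orf82, TBX4, NACA2) plus flanking and non-coding context
entries. It is not a complete or authoritative annotation; analyses of real
data should use a current Ensembl/bioMart export in the same column layout
(`gene_id`, `symbol`, `chrom`, `start`, `end`, `strand`, `biotype`,
`is_tf`).
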