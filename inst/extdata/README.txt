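rcc_index_snps_synthetic.tsv

The nine published renal-cell-carcinoma susceptibility loci (cytoband and
index rsID) in the package's index-SNP table layout. The `pos` column is a
SYNTHETIC placeholder coordinate (the published table lists loci and rsIDs
only); it exists so the loader and downstream plumbing can be exercised,
and must not be treated as a genome-build position.
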