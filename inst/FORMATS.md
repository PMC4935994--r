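# Output file formats

All tabular outputs are headered TSV.

## mining.tsv (satminer_loop / run_pipeline)
iteration, reads_sampled (pairs), pairs_after_filter, clusters_examined,
new_satellites.

## catalog.tsv (tidy(sat_catalog))
family_id, variant_index, seq, abundance (% genome proportion),
n_variants, monomer_length (bp), at_content (%), superfamily_id,
catalog_number, name.

## catalog.fasta
One record per variant, header `Name#variant_index` (e.g. `LmiSat01-193#1`).

## quantification.tsv (family_abundance)
family, abundance (% of sampled nucleotides), mean_divergence
(abundance-weighted Kimura 2-parameter %, empty when no hits).

## landscape.tsv (repeat_landscape)
family, bin (lower edge of the 1% divergence bin), abundance (%).

## hit tables (align_reads_to_library)
query_id, family, variant, q_start, q_end (1-based inclusive), strand,
aligned_nt (non-gap columns), identity (%), P (transition proportion),
Q (transversion proportion), k2p (%).

## assembly scan summary (scan_assembly)
family, n_contigs (contigs with >= 200 aligned bp), mnrpc (max repeats
per contig = aligned_nt / monomer length, rounded down).

## annotation table (read_annotation_table)
family, length (bp), at (%), v (number of variants), ab_sl/ab_nl
(abundance % per individual), div_sl/div_nl (divergence %), contigs,
mnrpc, one column per chromosome with comma-separated location tokens
(p proximal, i interstitial, d distal, t telomeric), pattern (c clustered,
nc non-clustered, m mixed, empty = not assessed).
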