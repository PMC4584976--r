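# shared candidate-locus fixture row: passes every phylogenetic
# criterion unless a field is overridden
phylo_row <- function(identity = 98.4, orthologs = 1, introns = 2,
                      intron_bp = 800, shares = c(30, 35, 35)) {
  data.frame(contig_id = "c1", pairwise_identity_pct = identity,
             ortholog_count = orthologs, intron_count = introns,
             intron_total_bp = intron_bp,
             read_share_1 = shares[1], read_share_2 = shares[2],
             read_share_3 = shares[3], stringsAsFactors = FALSE)
}
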