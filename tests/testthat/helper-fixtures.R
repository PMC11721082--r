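# Shared small fixtures, built once per test run.

# 4 orders x 2 families, 15 genomes per family: big enough for the
# classifiers to be exercised, small enough to regenerate in seconds.
fix_sigs <- make_signatures(n_orders = 4, families_per_order = 2,
                            gvogs_total = 250, core_size = 20,
                            family_size = 8, seed = 101)
fix_ds <- sample_dataset(fix_sigs, genomes_per_class = 15,
                         genome_length = 8000, n_contigs = 3,
                         locus_length = 400, seed = 101)
fix_mat <- synthetic_feature_matrix(fix_ds)
fix_orders <- fix_ds$labels$order
fix_truth_order <- stats::setNames(fix_ds$labels$order,
                                   fix_ds$labels$genome_id)

random_genome <- function(id, n_contigs, contig_len, seed) {
  set.seed(seed)
  contigs <- vapply(seq_len(n_contigs), function(i) {
    paste(sample(c("A", "C", "G", "T"), contig_len, replace = TRUE),
          collapse = "")
  }, "")
  names(contigs) <- sprintf("%s_c%d", id, seq_len(n_contigs))
  genome_record(id, contigs)
}

write_fasta <- function(seqs, path) {
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
}

tblout_line <- function(protein, gvog, evalue, score = 100) {
  sprintf("%-20s -          %-12s -          %9.3g  %5.1f   0.0",
          protein, gvog, evalue, score)
}
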