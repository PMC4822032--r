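# Small programmatic fixtures shared across test files.

random_count_matrix <- function(n_genes, samples, assay = "mRNA",
                                lambda = 50, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * length(samples), lambda), nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)), samples))
  count_matrix(m, assay)
}

design_2v2 <- function() {
  sample_design(c("ctrl", "ctrl", "trt", "trt"),
                samples = c("c1", "c2", "t1", "t2"))
}

# Counts built so that each gene's true mRNA/RPF fold changes are known.
constructed_pair <- function(base_mrna, base_rpf, fc_mrna, fc_rpf,
                             reps = 2) {
  n <- length(base_mrna)
  gene_ids <- sprintf("g%03d", seq_len(n))
  mk <- function(base, fc) {
    m <- cbind(matrix(rep(round(base), reps), n),
               matrix(rep(round(base * fc), reps), n))
    rownames(m) <- gene_ids
    colnames(m) <- c(paste0("c", seq_len(reps)), paste0("t", seq_len(reps)))
    m
  }
  list(mrna = count_matrix(mk(base_mrna, fc_mrna), "mRNA"),
       rpf = count_matrix(mk(base_rpf, fc_rpf), "RPF"),
       design = sample_design(rep(c("ctrl", "trt"), each = reps),
                              samples = c(paste0("c", seq_len(reps)),
                                          paste0("t", seq_len(reps)))))
}

# Minimal GTF with a plus-strand single-exon gene, a minus-strand
# two-exon gene, and a pair of overlapping plus-strand genes.
write_test_gtf <- function(path) {
  attr_of <- function(gid)
    sprintf('gene_id "%s"; transcript_id "%s.t1";', gid, gid)
  rows <- c(
    paste("chr1", "test", "CDS", 101, 400, ".", "+", "0", attr_of("geneA"),
          sep = "\t"),
    paste("chr1", "test", "CDS", 1001, 1150, ".", "-", "0", attr_of("geneB"),
          sep = "\t"),
    paste("chr1", "test", "CDS", 1201, 1350, ".", "-", "0", attr_of("geneB"),
          sep = "\t"),
    paste("chr2", "test", "CDS", 501, 800, ".", "+", "0", attr_of("geneC"),
          sep = "\t"),
    paste("chr2", "test", "CDS", 701, 1000, ".", "+", "0", attr_of("geneD"),
          sep = "\t"))
  writeLines(rows, path)
  path
}

sam_header <- function() {
  c("@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr1\tLN:5000",
    "@SQ\tSN:chr2\tLN:5000",
    "@SQ\tSN:chr9\tLN:5000")
}

sam_record <- function(qname, flag, rname, pos, mapq, len, nh = 1L) {
  seq <- paste(rep("A", len), collapse = "")
  qual <- paste(rep("I", len), collapse = "")
  paste(qname, flag, rname, pos, mapq, paste0(len, "M"), "*", 0, 0,
        seq, qual, paste0("NH:i:", nh), sep = "\t")
}

write_test_sam <- function(path, records) {
  writeLines(c(sam_header(), records), path)
  path
}
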