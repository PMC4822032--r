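# geneA: chr1 +, CDS 101-400 (300 nt). Allowed 5'-end window after edge
# exclusion (15 + 5 codons): transcript positions [45, 285), i.e. genomic
# 146..385.
# geneB: chr1 -, CDS blocks 1001-1150 and 1201-1350 (300 nt); transcript
# runs from genomic 1350 downwards.
# geneC/geneD: chr2 +, overlapping CDS 501-800 and 701-1000.

local_annotation <- function() {
  gtf <- withr::local_tempfile(fileext = ".gtf", .local_envir = parent.frame())
  write_test_gtf(gtf)
  read_cds_annotation(gtf)
}

test_that("annotation windows exclude the first 15 and last 5 codons", {
  ann <- local_annotation()
  expect_equal(sort(ann$genes$gene_id), c("geneA", "geneB", "geneC", "geneD"))
  expect_equal(ann$genes$cds_length[ann$genes$gene_id == "geneB"], 300)
  a <- ann$allowed[ann$allowed$gene_id == "geneA"]
  expect_equal(BiocGenerics::start(a), 146)
  expect_equal(BiocGenerics::end(a), 385)
  b <- ann$allowed[ann$allowed$gene_id == "geneB"]
  expect_equal(sort(BiocGenerics::start(b)), c(1016, 1201))
  expect_equal(sort(BiocGenerics::end(b)), c(1150, 1305))
})

test_that("per-read filters match the documented rules", {
  ann <- local_annotation()
  sam <- withr::local_tempfile(fileext = ".sam")
  write_test_sam(sam, c(
    sam_record("keep_codon16", 0, "chr1", 146, 30, 30),    # tx pos 45: keep
    sam_record("keep_last", 0, "chr1", 385, 30, 30),       # tx pos 284: keep
    sam_record("start_excl", 0, "chr1", 101, 30, 30),      # tx pos 0
    sam_record("start_excl_44", 0, "chr1", 145, 30, 30),   # tx pos 44
    sam_record("end_excl", 0, "chr1", 386, 30, 30),        # tx pos 285
    sam_record("short", 0, "chr1", 200, 30, 25),
    sam_record("long", 0, "chr1", 200, 30, 35),
    sam_record("multi", 0, "chr1", 200, 30, 30, nh = 3),
    sam_record("off_chrom", 0, "chr9", 200, 30, 30),
    sam_record("intergenic", 0, "chr1", 30, 30, 30)))
  aln <- read_sam_alignments(sam)
  dec <- filter_rpf_read(aln, ann)
  expect_equal(unname(dec$reason),
               c("kept", "kept", "start_exclusion", "start_exclusion",
                 "end_exclusion", "length", "length", "not_unique",
                 "no_annotation", "not_cds"))
  expect_equal(dec$gene_id[1:2], c("geneA", "geneA"))
})

test_that("minus-strand 5' ends use the alignment end coordinate", {
  ann <- local_annotation()
  sam <- withr::local_tempfile(fileext = ".sam")
  write_test_sam(sam, c(
    # 5' end (genomic end) 1305 = tx pos 45: boundary keep
    sam_record("minus_keep", 16, "chr1", 1276, 30, 30),
    # 5' end 1306 = tx pos 44: excluded
    sam_record("minus_start_excl", 16, "chr1", 1277, 30, 30),
    # 5' end 1150 = tx pos 150: keep, second CDS block
    sam_record("minus_block2", 16, "chr1", 1121, 30, 30),
    # plus-strand read over a minus-strand gene: no sense-strand CDS
    sam_record("wrong_strand", 0, "chr1", 1276, 30, 30)))
  dec <- filter_rpf_read(read_sam_alignments(sam), ann)
  expect_equal(dec$reason,
               c("kept", "start_exclusion", "kept", "not_cds"))
  expect_equal(dec$gene_id[c(1, 3)], c("geneB", "geneB"))
})

test_that("reads in two genes' windows are dropped as ambiguous", {
  ann <- local_annotation()
  sam <- withr::local_tempfile(fileext = ".sam")
  write_test_sam(sam, c(
    sam_record("both", 0, "chr2", 750, 30, 30),   # in geneC and geneD windows
    sam_record("only_c", 0, "chr2", 600, 30, 30)))
  dec <- filter_rpf_read(read_sam_alignments(sam), ann)
  expect_equal(dec$reason, c("ambiguous", "kept"))
  expect_equal(dec$gene_id[2], "geneC")
})

test_that("counting is order invariant and conserves records", {
  ann <- local_annotation()
  set.seed(4)
  recs <- c(
    vapply(1:10, function(i)
      sam_record(paste0("a", i), 0, "chr1", 146 + 3 * i, 30, 30), ""),
    vapply(1:5, function(i)
      sam_record(paste0("b", i), 16, "chr1", 1230 + i, 30, 28), ""),
    sam_record("bad_len", 0, "chr1", 200, 30, 20),
    sam_record("multi", 0, "chr1", 200, 30, 30, nh = 2))
  sam1 <- withr::local_tempfile(fileext = ".sam")
  sam2 <- withr::local_tempfile(fileext = ".sam")
  write_test_sam(sam1, recs)
  write_test_sam(sam2, sample(recs))
  r1 <- count_rpf_per_gene(sam1, ann)
  r2 <- count_rpf_per_gene(sam2, ann)
  expect_identical(r1$counts, r2$counts)
  expect_equal(r1$counts[["geneA"]], 10)
  expect_equal(r1$counts[["geneB"]], 5)
  expect_equal(sum(r1$counts) + sum(r1$drop_reasons[names(r1$drop_reasons)
                                                    != "kept"]),
               r1$n_records)
})

test_that("counts equal a brute-force replay of the filter rules", {
  ann <- local_annotation()
  set.seed(11)
  pos <- sample(90:420, 60, replace = TRUE)
  len <- sample(24:36, 60, replace = TRUE)
  recs <- vapply(seq_along(pos), function(i)
    sam_record(paste0("r", i), 0, "chr1", pos[i], 30, len[i]), "")
  sam <- withr::local_tempfile(fileext = ".sam")
  write_test_sam(sam, recs)
  got <- count_rpf_per_gene(sam, ann)$counts[["geneA"]]
  # independent arithmetic for the plus-strand single-exon gene
  expected <- sum(len >= 26 & len <= 34 & pos >= 101 + 45 & pos <= 400 - 15)
  expect_equal(got, expected)
})

test_that("malformed SAM records are skipped and tallied", {
  ann <- local_annotation()
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(sam_header(),
               sam_record("fine", 0, "chr1", 150, 30, 30),
               "broken\trecord\twith\tfive\tfields"), sam)
  expect_warning(aln <- read_sam_alignments(sam), "malformed")
  expect_equal(attr(aln, "rejects"), 1L)
  expect_length(aln, 1L)
})
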