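#' Load CDS annotation from a GTF file
#'
#' Imports CDS features, groups them by gene, merges overlapping
#' intervals, and derives each gene's allowed counting window: the CDS in
#' transcript orientation with the first `exclude_start_codons` and last
#' `exclude_end_codons` codons removed (ribosomes accumulate around the
#' starts and ends of coding regions, so footprints there are excluded).
#' Coordinates are handled 0-based half-open internally; GTF input is
#' converted from 1-based inclusive.
#'
#' @param gtf Path to a GTF file with CDS features carrying `gene_id`.
#' @param exclude_start_codons,exclude_end_codons Codons trimmed from the
#'   CDS 5' and 3' ends (defaults 15 and 5).
#' @return A `cds_annotation` object.
#' @export
read_cds_annotation <- function(gtf, exclude_start_codons = 15L,
                                exclude_end_codons = 5L) {
  feats <- rtracklayer::import(gtf, format = "gtf", feature.type = "CDS")
  if (length(feats) == 0L) stop("no CDS features found in ", gtf)
  gene_ids <- as.character(feats$gene_id)
  grl <- GenomicRanges::reduce(GenomicRanges::split(feats, gene_ids))
  exon_rows <- list()
  allowed_rows <- list()
  gene_rows <- list()
  a_nt <- 3L * exclude_start_codons
  b_trim <- 3L * exclude_end_codons
  for (gid in names(grl)) {
    gr <- grl[[gid]]
    strand <- as.character(BiocGenerics::strand(gr))[1L]
    chrom <- as.character(GenomeInfoDb::seqnames(gr))[1L]
    ord <- order(BiocGenerics::start(gr))
    if (strand == "-") ord <- rev(ord)
    st <- BiocGenerics::start(gr)[ord]; en <- BiocGenerics::end(gr)[ord]
    w <- en - st + 1L
    off <- cumsum(c(0L, w[-length(w)]))  # 0-based tx start of each block
    total <- sum(w)
    if (total %% 3L != 0L)
      warning("CDS length of gene '", gid, "' is not a multiple of 3")
    exon_rows[[gid]] <- data.frame(gene_id = gid, chrom = chrom,
                                   strand = strand, start = st, end = en,
                                   off = off, stringsAsFactors = FALSE)
    gene_rows[[gid]] <- data.frame(gene_id = gid, chrom = chrom,
                                   strand = strand, cds_length = total,
                                   stringsAsFactors = FALSE)
    lo_tx <- a_nt; hi_tx <- total - b_trim
    if (hi_tx > lo_tx) {
      for (e in seq_along(st)) {
        lo <- max(lo_tx, off[e]); hi <- min(hi_tx, off[e] + w[e])
        if (lo < hi) {
          if (strand == "-") {
            g_end <- en[e] - (lo - off[e])
            g_start <- en[e] - (hi - 1L - off[e])
          } else {
            g_start <- st[e] + (lo - off[e])
            g_end <- st[e] + (hi - 1L - off[e])
          }
          allowed_rows[[length(allowed_rows) + 1L]] <-
            data.frame(gene_id = gid, chrom = chrom, strand = strand,
                       start = g_start, end = g_end, stringsAsFactors = FALSE)
        }
      }
    }
  }
  exons <- do.call(rbind, exon_rows)
  allowed_df <- if (length(allowed_rows)) do.call(rbind, allowed_rows) else
    data.frame(gene_id = character(0), chrom = character(0),
               strand = character(0), start = integer(0), end = integer(0))
  allowed <- GenomicRanges::GRanges(
    allowed_df$chrom,
    IRanges::IRanges(allowed_df$start, allowed_df$end),
    strand = allowed_df$strand, gene_id = allowed_df$gene_id)
  structure(list(genes = do.call(rbind, gene_rows), exons = exons,
                 allowed = allowed,
                 exclude_start_codons = exclude_start_codons,
                 exclude_end_codons = exclude_end_codons),
            class = "cds_annotation")
}

# Transcript-orientation coordinate (0-based) of a genomic position
# within a gene's merged CDS, or NA when outside it.
tx_position <- function(ann, gene_id, chrom, pos, strand) {
  ex <- ann$exons[ann$exons$gene_id == gene_id, , drop = FALSE]
  if (nrow(ex) == 0L || ex$chrom[1L] != chrom || ex$strand[1L] != strand)
    return(NA_integer_)
  hit <- which(ex$start <= pos & pos <= ex$end)
  if (length(hit) == 0L) return(NA_integer_)
  e <- hit[1L]
  if (ex$strand[e] == "-") ex$off[e] + (ex$end[e] - pos)
  else ex$off[e] + (pos - ex$start[e])
}

#' Per-read RPF filter decisions
#'
#' Applies the footprint quality filters to aligned reads: read length
#' within `[min_len, max_len]`, unique mapping (NH tag equal to 1 when
#' present, otherwise mapping quality >= 10), and the strand-aware
#' 5'-end position falling inside a single gene's allowed CDS window
#' (edge codons excluded). Reads whose 5' end lies in the allowed window
#' of two or more genes are dropped as ambiguous.
#'
#' @param aln A `GAlignments` object (e.g. from [read_sam_alignments()]),
#'   optionally carrying an `NH` metadata column.
#' @param ann A [read_cds_annotation()] object.
#' @param min_len,max_len Accepted read lengths (nt).
#' @return Data frame per read: `gene_id` (NA unless kept) and `reason`
#'   (`"kept"`, `"length"`, `"not_unique"`, `"no_annotation"`,
#'   `"start_exclusion"`, `"end_exclusion"`, `"not_cds"`,
#'   `"ambiguous"`).
#' @export
filter_rpf_read <- function(aln, ann, min_len = 26L, max_len = 34L) {
  n <- length(aln)
  reason <- rep("kept", n)
  gene <- rep(NA_character_, n)
  qlen <- GenomicAlignments::qwidth(aln)
  reason[qlen < min_len | qlen > max_len] <- "length"
  nh <- S4Vectors::mcols(aln)$NH
  mapq <- S4Vectors::mcols(aln)$mapq
  unique_ok <- if (!is.null(nh) && !all(is.na(nh))) {
    ifelse(is.na(nh), !is.na(mapq) & mapq >= 10L, nh == 1L)
  } else {
    !is.na(mapq) & mapq >= 10L
  }
  reason[reason == "kept" & !unique_ok] <- "not_unique"

  chrom <- as.character(GenomeInfoDb::seqnames(aln))
  strand <- as.character(BiocGenerics::strand(aln))
  pos5 <- ifelse(strand == "-", BiocGenerics::end(aln),
                 BiocGenerics::start(aln))
  known_chrom <- chrom %in% unique(ann$genes$chrom)
  reason[reason == "kept" & !known_chrom] <- "no_annotation"

  todo <- which(reason == "kept")
  if (length(todo)) {
    pts <- GenomicRanges::GRanges(chrom[todo],
                                  IRanges::IRanges(pos5[todo], width = 1L),
                                  strand = strand[todo])
    hits <- GenomicRanges::findOverlaps(pts, ann$allowed)
    gene_hit <- split(ann$allowed$gene_id[S4Vectors::subjectHits(hits)],
                      S4Vectors::queryHits(hits))
    for (i in seq_along(todo)) {
      r <- todo[i]
      gh <- unique(gene_hit[[as.character(i)]])
      if (is.null(gh)) {
        reason[r] <- classify_miss(ann, chrom[r], pos5[r], strand[r])
      } else if (length(gh) > 1L) {
        reason[r] <- "ambiguous"
      } else {
        gene[r] <- gh
      }
    }
  }
  data.frame(gene_id = gene, reason = reason, stringsAsFactors = FALSE)
}

# Why a 5' end missed every allowed window: inside an excluded edge of
# some gene's CDS, or outside any CDS entirely.
classify_miss <- function(ann, chrom, pos, strand) {
  cand <- ann$genes[ann$genes$chrom == chrom & ann$genes$strand == strand,
                    , drop = FALSE]
  for (gid in cand$gene_id) {
    tx <- tx_position(ann, gid, chrom, pos, strand)
    if (!is.na(tx)) {
      total <- cand$cds_length[cand$gene_id == gid]
      if (tx < 3L * ann$exclude_start_codons) return("start_exclusion")
      if (tx >= total - 3L * ann$exclude_end_codons) return("end_exclusion")
    }
  }
  "not_cds"
}

#' Read alignments from a SAM (or BAM) file
#'
#' Text SAM input is converted to BAM on the fly; records with fewer
#' than 11 fields are skipped with a warning and reported in the
#' `rejects` attribute. Mapping quality and the NH tag are loaded for
#' the uniqueness filter.
#'
#' @param path SAM or BAM file path.
#' @return A `GAlignments` object with `mapq` and `NH` metadata columns
#'   and a `rejects` attribute (count of malformed records).
#' @export
read_sam_alignments <- function(path) {
  rejects <- 0L
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    body <- !startsWith(lines, "@")
    bad <- body & vapply(strsplit(lines, "\t"), length, integer(1)) < 11L
    rejects <- sum(bad)
    if (rejects > 0L) {
      warning(rejects, " malformed SAM record(s) skipped")
      lines <- lines[!bad]
    }
    tmp_sam <- tempfile(fileext = ".sam")
    writeLines(lines, tmp_sam)
    bam <- Rsamtools::asBam(tmp_sam, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  } else {
    bam <- path
  }
  param <- Rsamtools::ScanBamParam(what = "mapq", tag = "NH")
  aln <- GenomicAlignments::readGAlignments(bam, param = param)
  attr(aln, "rejects") <- rejects
  aln
}

#' Count filtered RPF reads per gene
#'
#' @param alignments A `GAlignments` object or a SAM/BAM file path.
#' @param ann A [read_cds_annotation()] object.
#' @param min_len,max_len Accepted read lengths.
#' @return List: `counts` (named integer vector over annotation genes),
#'   `drop_reasons` (table of filter outcomes), `n_records`.
#' @export
count_rpf_per_gene <- function(alignments, ann, min_len = 26L,
                               max_len = 34L) {
  if (is.character(alignments)) alignments <- read_sam_alignments(alignments)
  dec <- filter_rpf_read(alignments, ann, min_len = min_len,
                         max_len = max_len)
  counts <- integer(nrow(ann$genes))
  names(counts) <- ann$genes$gene_id
  kept <- table(dec$gene_id[dec$reason == "kept"])
  counts[names(kept)] <- as.integer(kept)
  list(counts = counts, drop_reasons = table(dec$reason),
       n_records = nrow(dec))
}
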