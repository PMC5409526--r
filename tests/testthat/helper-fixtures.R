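## Shared fixture builders. Everything is generated in code at test time.

## a minimal 4-target, 2-chromosome panel
tiny_targets <- function() {
  as_target_set(data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(100L, 500L, 9000L, 200L),
    end   = c(200L, 650L, 9100L, 300L),
    gene  = c("G1", "G1", "G1", "G2"),
    custom_number = c(1L, 2L, 3L, 1L)))
}

tiny_matrix <- function(counts = NULL, n_samples = 3L) {
  tg <- tiny_targets()
  if (is.null(counts)) {
    counts <- matrix(100L + seq_len(nrow(tg) * n_samples), nrow(tg),
                     dimnames = list(NULL, sprintf("T%d", seq_len(n_samples))))
  }
  coverage_matrix(tg, counts)
}

## a three-gene panel large enough that one whole gene is a minority of targets
panel3_model <- function() {
  panel_model(genes = list(
    list(name = "GENEA", chrom = "chrA", strand = "+", n_exons = 23L,
         span = 8e4),
    list(name = "GENEB", chrom = "chrB", strand = "-", n_exons = 26L,
         span = 8.5e4),
    list(name = "GENEC", chrom = "chrC", strand = "+", n_exons = 30L,
         span = 9e4)))
}

## Write a SAM file and convert to an indexed BAM; returns the BAM path.
## reads: data.frame(qname, chrom, pos (1-based), mapq, cigar, flag)
make_bam <- function(reads, seqlens = c(chr1 = 100000L, chr2 = 100000L),
                     dir = withr::local_tempdir(.local_envir = parent.frame())) {
  sam <- file.path(dir, "reads.sam")
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlens), seqlens))
  body <- if (nrow(reads) == 0L) character(0) else
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
            reads$qname, reads$flag, reads$chrom, reads$pos, reads$mapq,
            reads$cigar,
            strrep("A", vapply(reads$cigar, cigar_query_len, integer(1))),
            strrep("I", vapply(reads$cigar, cigar_query_len, integer(1))))
  writeLines(c(hdr, body), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "reads"), overwrite = TRUE,
                          indexDestination = TRUE)
  bam
}

## cigar helpers for the brute-force oracle
cigar_ops <- function(cigar) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  data.frame(len = as.integer(sub("[A-Z=]$", "", toks)),
             op = sub("^\\d+", "", toks), stringsAsFactors = FALSE)
}

cigar_ref_len <- function(cigar) {
  ops <- cigar_ops(cigar)
  sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
}

cigar_query_len <- function(cigar) {
  ops <- cigar_ops(cigar)
  as.integer(sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")]))
}

## independent oracle: per-read interval-overlap scan
brute_force_counts <- function(reads, targets, min_mapq = 20L) {
  counts <- integer(nrow(targets))
  for (r in seq_len(nrow(reads))) {
    if (reads$mapq[r] < min_mapq) next
    if (bitwAnd(reads$flag[r], 256L + 1024L + 2048L + 4L) != 0L) next
    span <- c(reads$pos[r], reads$pos[r] + cigar_ref_len(reads$cigar[r]) - 1L)
    for (t in seq_len(nrow(targets))) {
      if (targets$chrom[t] == reads$chrom[r] &&
          span[1] <= targets$end[t] && span[2] >= targets$start[t] + 1L) {
        counts[t] <- counts[t] + 1L
      }
    }
  }
  counts
}

## a clean default pool shared by several test files (cached per session)
default_pool <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_pool(sim_spec(n_samples = 48, seed = 11),
                              make_panel(seed = 7))
    }
    cache
  }
})
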