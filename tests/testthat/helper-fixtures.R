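# Small programmatic fixtures shared across tests.

# Write a minimal GTF of gene records; spans are given 0-based half-open and
# converted to the GTF 1-based inclusive convention here.
write_gtf <- function(path, gene_id, chrom, strand, start0, end0) {
  writeLines(sprintf(
    '%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
    chrom, start0 + 1L, end0, strand, gene_id
  ), path)
  path
}

write_bed <- function(path, chrom, start, end, extra = NULL) {
  rows <- paste(chrom, start, end, sep = "\t")
  if (!is.null(extra)) rows <- paste(rows, extra, sep = "\t")
  writeLines(rows, path)
  path
}

# Random annotation + peaks on a couple of chromosomes, for oracle scans.
random_fixture <- function(n_genes = 30, n_peaks = 150) {
  chroms <- c("chr1", "chr2")
  start <- sample.int(2e6, n_genes)
  ann <- gene_annotation(
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    chrom = sample(chroms, n_genes, replace = TRUE),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    start = start, end = start + sample(500:20000, n_genes, replace = TRUE)
  )
  pstart <- sample.int(2100000L, n_peaks)
  peaks <- peak_set(
    "cond", chrom = sample(chroms, n_peaks, replace = TRUE),
    start = pstart, end = pstart + sample(50:1000, n_peaks, replace = TRUE),
    magnitude = round(runif(n_peaks, 0.5, 20), 3)
  )
  list(annotation = ann, peaks = peaks)
}

# Exhaustive O(genes x peaks) interval-overlap oracle for windowed models.
naive_assignment <- function(peaks, annotation, model) {
  if (is.character(model)) model <- peak2gene_model(model)
  pk <- peaks$peaks
  out <- lapply(seq_len(nrow(annotation)), function(i) {
    tss <- annotation$tss[i]
    w0 <- max(tss - model$window_bp, 0L)
    w1 <- tss + model$window_bp + 1L
    hit <- pk$chrom == annotation$chrom[i] & pk$start < w1 & pk$end > w0
    if (model$genebody) {
      hit <- hit | (pk$chrom == annotation$chrom[i] &
                      pk$start < annotation$end[i] &
                      pk$end > annotation$start[i])
    }
    which(hit)
  })
  stats::setNames(out, annotation$gene_id)
}

# A small deterministic score frame for evaluation tests.
toy_scores <- function(scores, method = "PC",
                       sign = rep("+", length(scores)),
                       valid = rep(TRUE, length(scores))) {
  data.frame(gene_id = names(scores), method = method,
             score = unname(scores), sign = sign, valid = valid,
             stringsAsFactors = FALSE)
}

toy_gold <- function(labels, kd = "c1") {
  gold_standard(kd, labels = labels)
}
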