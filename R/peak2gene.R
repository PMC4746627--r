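# Peak-to-gene assignment under the seven cumulative regulatory models and
# construction of genes x conditions binding matrices.

.P2G_WINDOWS <- c(tss1kb = 1000L, tss5kb = 5000L, tss10kb = 10000L,
                  tss50kb = 50000L, tss1kb_genebody = 1000L,
                  tss5kb_genebody = 5000L)

#' Define a peak-to-gene regulatory model
#'
#' Seven cumulative models map ChIP-seq peaks to candidate target genes:
#' fixed windows of 1/5/10/50 kb around the TSS (`tss1kb` ... `tss50kb`),
#' the nearest TSS (`nearest_tss`), and 1/5 kb TSS windows extended by the
#' gene body (`tss1kb_genebody`, `tss5kb_genebody`). "W kb around the TSS"
#' is read symmetrically: a peak is assigned when it overlaps
#' `[tss - W, tss + W + 1)` by at least one base.
#'
#' @param name one of `tss1kb`, `tss5kb`, `tss10kb`, `tss50kb`,
#'   `nearest_tss`, `tss1kb_genebody`, `tss5kb_genebody`.
#' @return A list of class `peak2gene_model` with `name`, `window_bp`
#'   (0 for `nearest_tss`) and `genebody` flag.
#' @export
peak2gene_model <- function(name = c("tss1kb", "tss5kb", "tss10kb", "tss50kb",
                                     "nearest_tss", "tss1kb_genebody",
                                     "tss5kb_genebody")) {
  name <- match.arg(name)
  structure(
    list(name = name,
         window_bp = if (name == "nearest_tss") 0L else .P2G_WINDOWS[[name]],
         genebody = grepl("genebody", name)),
    class = "peak2gene_model"
  )
}

# TSS windows as GRanges, clipped at position 0.
.tss_windows <- function(annotation, window_bp) {
  GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(
      start = pmax(annotation$tss - window_bp, 0L),
      end = annotation$tss + window_bp   # IRanges end is inclusive
    )
  )
}

#' Assign peaks to genes under a regulatory model
#'
#' Windowed models assign a peak to every gene whose TSS window it overlaps
#' (>= 1 shared bp); gene-body variants additionally accept overlap with the
#' gene span `[start, end)`. The nearest-TSS model assigns each peak to
#' exactly one gene -- the one whose TSS is closest to the peak midpoint
#' `floor((start + end) / 2)` -- with distance ties broken by the
#' lexicographically smallest gene id. Peaks on chromosomes absent from the
#' annotation are ignored (a message reports the count).
#'
#' @param peaks a `peak_set`.
#' @param annotation a `gene_annotation`.
#' @param model a `peak2gene_model` (or model name).
#' @return Named list, one element per gene id, each a data.frame of the
#'   assigned peaks (`chrom`, `start`, `end`, `magnitude`). Genes with no
#'   assigned peaks map to an empty data.frame.
#' @export
assign_peaks <- function(peaks, annotation, model) {
  if (is.character(model)) model <- peak2gene_model(model)
  stopifnot(inherits(peaks, "peak_set"), inherits(annotation, "gene_annotation"))
  if (nrow(annotation) == 0L) stop("annotation is empty")
  pk <- peaks$peaks
  assigned <- stats::setNames(
    rep(list(integer(0)), nrow(annotation)), annotation$gene_id
  )
  on_known <- pk$chrom %in% unique(annotation$chrom)
  if (any(!on_known)) {
    message(sum(!on_known), " peak(s) on chromosomes absent from the ",
            "annotation ignored (", peaks$condition_id, ")")
  }
  pk_idx <- which(on_known)
  if (length(pk_idx) > 0L) {
    if (model$name == "nearest_tss") {
      mid <- (pk$start[pk_idx] + pk$end[pk_idx]) %/% 2L
      gene <- .nearest_tss_gene(pk$chrom[pk_idx], mid, annotation)
      for (g in unique(gene)) {
        assigned[[g]] <- pk_idx[gene == g]
      }
    } else {
      pk_gr <- GenomicRanges::GRanges(
        seqnames = pk$chrom[pk_idx],
        ranges = IRanges::IRanges(start = pk$start[pk_idx],
                                  end = pk$end[pk_idx] - 1L)  # half-open -> inclusive
      )
      win <- .tss_windows(annotation, model$window_bp)
      hits <- GenomicRanges::findOverlaps(pk_gr, win)
      if (model$genebody) {
        body <- GenomicRanges::GRanges(
          seqnames = annotation$chrom,
          ranges = IRanges::IRanges(start = annotation$start,
                                    end = annotation$end - 1L)
        )
        hits <- S4Vectors::union(hits, GenomicRanges::findOverlaps(pk_gr, body))
      }
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      for (j in unique(sh)) {
        assigned[[annotation$gene_id[j]]] <- pk_idx[qh[sh == j]]
      }
    }
  }
  lapply(assigned, function(idx) pk[idx, , drop = FALSE])
}

# For each peak midpoint, the gene id with the nearest TSS on the same
# chromosome; ties (equal distance, or several genes sharing one TSS) go to
# the lexicographically smallest gene id.
.nearest_tss_gene <- function(chrom, mid, annotation) {
  out <- character(length(mid))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    ann <- annotation[annotation$chrom == ch, , drop = FALSE]
    # order by tss, then gene_id so the first gene at any position wins ties
    ord <- order(ann$tss, ann$gene_id, method = "radix")
    tss <- ann$tss[ord]
    ids <- ann$gene_id[ord]
    m <- mid[sel]
    right <- findInterval(m, tss) + 1L          # first tss >= m (approx)
    left <- right - 1L
    pick <- character(length(m))
    for (k in seq_along(m)) {
      cand <- c(left[k], right[k])
      cand <- cand[cand >= 1L & cand <= length(tss)]
      dd <- abs(tss[cand] - m[k])
      best <- dd == min(dd)
      # expand to every gene sharing a best tss position, tie-break by id
      best_tss <- unique(tss[cand[best]])
      pool <- ids[tss %in% best_tss]
      pick[k] <- min(pool)
    }
    out[sel] <- pick
  }
  out
}

#' Build a binding matrix from per-condition peak sets
#'
#' Entry `(g, c)` is the number of peaks assigned to gene `g` in condition
#' `c` (`mode = "count"`) or the sum of their magnitudes
#' (`mode = "magnitude"`). Every annotated gene appears as a row, possibly
#' all-zero. With `normalize_magnitude = TRUE`, each condition's peak
#' magnitudes are first divided by that condition's total magnitude and
#' multiplied by the mean total across conditions (library-size style
#' scaling).
#'
#' @param peaksets list of `peak_set`s with unique condition ids.
#' @param annotation a `gene_annotation`.
#' @param model a `peak2gene_model` (or model name).
#' @param mode `"count"` or `"magnitude"`.
#' @param normalize_magnitude logical; magnitude mode only.
#' @return A numeric genes x conditions matrix with attributes `mode` and
#'   `model`.
#' @export
build_binding_matrix <- function(peaksets, annotation, model,
                                 mode = c("count", "magnitude"),
                                 normalize_magnitude = FALSE) {
  mode <- match.arg(mode)
  if (is.character(model)) model <- peak2gene_model(model)
  if (length(peaksets) == 0L) stop("need at least one peak set")
  conds <- vapply(peaksets, function(p) p$condition_id, character(1))
  if (anyDuplicated(conds)) {
    stop("duplicate condition id(s): ",
         paste(unique(conds[duplicated(conds)]), collapse = ", "))
  }
  if (normalize_magnitude && mode == "magnitude") {
    totals <- vapply(peaksets, function(p) sum(p$peaks$magnitude), numeric(1))
    mean_total <- mean(totals)
    peaksets <- lapply(peaksets, function(p) {
      tot <- sum(p$peaks$magnitude)
      if (tot > 0) p$peaks$magnitude <- p$peaks$magnitude / tot * mean_total
      p
    })
  }
  m <- matrix(0, nrow = nrow(annotation), ncol = length(peaksets),
              dimnames = list(annotation$gene_id, conds))
  for (j in seq_along(peaksets)) {
    asg <- assign_peaks(peaksets[[j]], annotation, model)
    m[, j] <- vapply(asg, function(p) {
      if (mode == "count") nrow(p) else sum(p$magnitude)
    }, numeric(1))
  }
  attr(m, "mode") <- mode
  attr(m, "model") <- model$name
  m
}
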