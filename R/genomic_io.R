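# Readers/writers for the formats the pipeline touches. Internal coordinate
# convention everywhere: 0-based, half-open [start, end) -- i.e. BED; GTF/GFF
# 1-based inclusive coordinates are converted on read.

#' Construct a gene annotation table
#'
#' Builds the internal per-gene annotation used throughout the package:
#' one row per gene with its chromosome, strand, span in 0-based half-open
#' coordinates, and the strand-aware transcription start site (TSS). The TSS
#' of a `+` gene is `start`; the TSS of a `-` gene is `end - 1` (the last
#' base of the annotated span).
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param chrom character vector of chromosome names.
#' @param strand character vector, `"+"` or `"-"`.
#' @param start,end integer vectors, 0-based half-open span (`start < end`).
#' @return A `data.frame` of class `gene_annotation` with columns
#'   `gene_id`, `chrom`, `strand`, `start`, `end`, `tss`.
#' @examples
#' gene_annotation("G1", "chr1", "+", 10000L, 20000L)$tss  # 10000
#' gene_annotation("G2", "chr1", "-", 10000L, 20000L)$tss  # 19999
#' @export
gene_annotation <- function(gene_id, chrom, strand, start, end) {
  gene_id <- as.character(gene_id)
  chrom <- as.character(chrom)
  strand <- as.character(strand)
  start <- as.integer(start)
  end <- as.integer(end)
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene_id in annotation: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  }
  if (!all(strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  if (any(start >= end)) {
    stop("annotation requires start < end for every gene")
  }
  ann <- data.frame(
    gene_id = gene_id, chrom = chrom, strand = strand,
    start = start, end = end,
    tss = ifelse(strand == "+", start, end - 1L),
    stringsAsFactors = FALSE
  )
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Read gene annotations from a GTF/GFF file
#'
#' Imports records of one feature type (default `"gene"`) and returns one
#' annotation row per unique gene identifier. GTF/GFF 1-based inclusive
#' coordinates are converted to the internal 0-based half-open convention
#' and a strand-aware TSS is derived. Duplicated gene identifiers keep the
#' first record with a warning.
#'
#' @param path path to a GTF or GFF file (format auto-detected by
#'   [rtracklayer::import()]).
#' @param feature feature type to keep (column 3), default `"gene"`.
#' @param gene_id_attr attribute holding the gene identifier; default
#'   `"gene_id"`, falling back to `"ID"` when absent.
#' @return A `gene_annotation` data.frame (see [gene_annotation()]).
#' @export
read_annotation <- function(path, feature = "gene", gene_id_attr = "gene_id") {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  body <- !grepl("^#", lines) & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 8)) {
    bad <- which(body)[which(nf < 8)[1L]]
    stop("malformed annotation record at line ", bad,
         " (expected >= 8 tab-separated fields, got ", nf[nf < 8][1L], ")")
  }
  gr <- rtracklayer::import(path)
  if ("type" %in% names(S4Vectors::mcols(gr))) {
    gr <- gr[as.character(gr$type) == feature]
  }
  if (length(gr) == 0L) {
    stop("no '", feature, "' records in ", path)
  }
  mc <- S4Vectors::mcols(gr)
  ids <- if (gene_id_attr %in% names(mc)) {
    as.character(mc[[gene_id_attr]])
  } else if ("ID" %in% names(mc)) {
    as.character(mc$ID)
  } else {
    stop("records carry neither '", gene_id_attr, "' nor 'ID' attributes")
  }
  if (anyNA(ids)) stop("gene records without a gene identifier attribute")
  if (anyDuplicated(ids)) {
    warning(sum(duplicated(ids)), " duplicated gene id(s); keeping first record")
    keep <- !duplicated(ids)
    gr <- gr[keep]
    ids <- ids[keep]
  }
  strand <- as.character(BiocGenerics::strand(gr))
  if (!all(strand %in% c("+", "-"))) {
    stop("gene records must carry '+' or '-' strand")
  }
  gene_annotation(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    start = BiocGenerics::start(gr) - 1L,   # GTF 1-based -> 0-based
    end = BiocGenerics::end(gr)             # inclusive -> half-open
  )
}

#' Construct a peak set
#'
#' @param condition_id condition (cell type / time point) identifier.
#' @param chrom,start,end peak coordinates, 0-based half-open.
#' @param magnitude non-negative per-peak signal; defaults to 1 for every
#'   peak so count and magnitude modes coincide when no signal is available.
#' @return A list of class `peak_set` with elements `condition_id` and
#'   `peaks` (data.frame `chrom`, `start`, `end`, `magnitude`).
#' @export
peak_set <- function(condition_id, chrom = character(), start = integer(),
                     end = integer(), magnitude = NULL) {
  if (is.null(magnitude)) magnitude <- rep(1, length(chrom))
  stopifnot(length(chrom) == length(start), length(start) == length(end),
            length(end) == length(magnitude))
  if (any(start >= end)) stop("peaks require start < end")
  if (any(magnitude < 0)) stop("peak magnitudes must be non-negative")
  structure(
    list(condition_id = as.character(condition_id),
         peaks = data.frame(chrom = as.character(chrom),
                            start = as.integer(start), end = as.integer(end),
                            magnitude = as.numeric(magnitude),
                            stringsAsFactors = FALSE)),
    class = "peak_set"
  )
}

#' Read a BED3+/narrowPeak peak file
#'
#' Coordinates are BED 0-based half-open and preserved as-is. Peak magnitude
#' is taken from `magnitude_column` when given (ENCODE narrowPeak
#' signalValue is column 7) and defaults to 1 otherwise. Records with an
#' empty interval (`start >= end`) are dropped with a message.
#'
#' @param path path to a tab-separated BED3+ or narrowPeak file.
#' @param condition_id identifier of the condition the peaks belong to.
#' @param magnitude_column 1-based column index holding a non-negative real
#'   signal value, or `NULL` for unit magnitudes.
#' @return A `peak_set`.
#' @export
read_peaks <- function(path, condition_id, magnitude_column = NULL) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  if (file.size(path) == 0L) {
    return(peak_set(condition_id))
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          data.table = FALSE)
  if (nrow(dt) > 0L) {
    dt <- dt[!grepl("^(track|browser|#)", dt[[1L]]), , drop = FALSE]
  }
  if (nrow(dt) == 0L) {
    return(peak_set(condition_id))
  }
  if (ncol(dt) < 3L) stop("peak file needs >= 3 tab-separated columns: ", path)
  start <- suppressWarnings(as.integer(dt[[2L]]))
  end <- suppressWarnings(as.integer(dt[[3L]]))
  if (anyNA(start) || anyNA(end)) {
    stop("non-integer peak coordinates in ", path)
  }
  magnitude <- if (is.null(magnitude_column)) {
    rep(1, nrow(dt))
  } else {
    if (magnitude_column > ncol(dt)) {
      stop("magnitude_column ", magnitude_column, " not present (file has ",
           ncol(dt), " columns)")
    }
    mg <- suppressWarnings(as.numeric(dt[[magnitude_column]]))
    if (anyNA(mg)) stop("non-numeric magnitude in column ", magnitude_column)
    mg
  }
  keep <- start < end
  if (any(!keep)) {
    message(sum(!keep), " empty-interval peak record(s) dropped from ", path)
  }
  peak_set(condition_id, chrom = dt[[1L]][keep], start = start[keep],
           end = end[keep], magnitude = magnitude[keep])
}

#' Read a genes x conditions matrix from TSV
#'
#' Expects a header row of condition ids with the first column named for the
#' gene identifier. Rows containing missing values are dropped with a
#' message (the analysis universe is data-driven).
#'
#' @param path path to the TSV file.
#' @return A numeric matrix with gene ids as rownames and condition ids as
#'   colnames.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1L) {
    stop("ragged row at line ", which(nf != nf[1L])[1L], " of ", path,
         " (", nf[nf != nf[1L]][1L], " fields, expected ", nf[1L], ")")
  }
  dt <- tryCatch(
    data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE,
                      fill = FALSE),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(dt) == 0L) stop("no data rows in ", path)
  if (ncol(dt) < 2L) stop("matrix needs a gene_id column plus >= 1 condition")
  genes <- as.character(dt[[1L]])
  if (anyDuplicated(genes)) {
    warning(sum(duplicated(genes)), " duplicated gene id(s); keeping first")
    dt <- dt[!duplicated(genes), , drop = FALSE]
    genes <- genes[!duplicated(genes)]
  }
  m <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  complete <- stats::complete.cases(m)
  if (any(!complete)) {
    message(sum(!complete), " gene(s) with missing values dropped from ", path)
    m <- m[complete, , drop = FALSE]
  }
  if (nrow(m) == 0L) stop("no complete data rows in ", path)
  m
}

#' Write a genes x conditions matrix to TSV
#'
#' Values are formatted with up to 10 significant digits (`%.10g`); a write
#' followed by [read_matrix()] reproduces the values exactly as formatted,
#' and repeated writes of the same matrix are byte-identical.
#'
#' @param m numeric matrix with gene rownames and condition colnames.
#' @param path output path.
#' @param id_column name for the first (gene id) column.
#' @export
write_matrix <- function(m, path, id_column = "gene_id") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  header <- paste(c(id_column, colnames(m)), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%.10g", m[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Construct a knockdown gold standard
#'
#' @param knockdown_condition identifier of the condition in which the TF
#'   knockdown was performed.
#' @param labels named logical vector: `TRUE` for functional (differentially
#'   expressed on knockdown) genes. Derived from `pvalues` when those are
#'   supplied.
#' @param pvalues optional named numeric vector of differential-expression
#'   p-values in `[0, 1]`.
#' @param de_threshold p-value cutoff below which a gene is labelled
#'   positive; default 0.05.
#' @return A list of class `gold_standard`.
#' @export
gold_standard <- function(knockdown_condition, labels = NULL, pvalues = NULL,
                          de_threshold = 0.05) {
  if (is.null(labels) && is.null(pvalues)) {
    stop("supply labels or pvalues")
  }
  if (!is.null(pvalues)) {
    if (is.null(names(pvalues))) stop("pvalues must be named by gene_id")
    if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
    labels <- pvalues < de_threshold
  }
  if (is.null(names(labels))) stop("labels must be named by gene_id")
  structure(
    list(knockdown_condition = as.character(knockdown_condition),
         labels = as.logical(labels) |> stats::setNames(names(labels)),
         pvalues = pvalues, de_threshold = de_threshold),
    class = "gold_standard"
  )
}

#' Read a knockdown differential-expression gold standard from TSV
#'
#' The file must have a `gene_id` column plus either a `pvalue` column
#' (positives are genes with `pvalue < de_threshold`) or a binary `label`
#' column (`1`/`positive` vs `0`/`negative`).
#'
#' @inheritParams gold_standard
#' @param path path to the TSV file.
#' @return A `gold_standard`.
#' @export
read_gold_standard <- function(path, knockdown_condition,
                               de_threshold = 0.05) {
  if (!file.exists(path)) stop("gold-standard file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  if (nrow(dt) == 0L) stop("no data rows in ", path)
  if (!"gene_id" %in% names(dt)) stop("gold standard needs a gene_id column")
  genes <- as.character(dt$gene_id)
  if ("pvalue" %in% names(dt)) {
    pv <- stats::setNames(as.numeric(dt$pvalue), genes)
    gold_standard(knockdown_condition, pvalues = pv,
                  de_threshold = de_threshold)
  } else if ("label" %in% names(dt)) {
    lab <- dt$label %in% c("1", 1, "positive", "TRUE", TRUE)
    gold_standard(knockdown_condition,
                  labels = stats::setNames(lab, genes),
                  de_threshold = de_threshold)
  } else {
    stop("gold standard needs a 'pvalue' or 'label' column")
  }
}

#' Write predicted targets to TSV
#'
#' Emits one row per gene with its contributing method(s), score(s), sign
#' and predicted flag, sorted by gene id so output is stable across runs.
#'
#' @param targets a `target_set` (see [predict_targets()]) or a data.frame
#'   with at least `gene_id`, `method`, `score`, `sign` columns.
#' @param path output path.
#' @export
write_targets <- function(targets, path) {
  df <- as.data.frame(targets)
  stopifnot(all(c("gene_id", "method", "score", "sign") %in% names(df)))
  if (!"predicted" %in% names(df)) df$predicted <- TRUE
  df <- df[order(df$gene_id, df$method), , drop = FALSE]
  out <- data.frame(
    gene_id = df$gene_id, method = df$method,
    score = sprintf("%.10g", df$score), sign = df$sign,
    predicted = as.integer(df$predicted), stringsAsFactors = FALSE
  )
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

# Restrict an annotation to genes present in an expression matrix; the
# analysis universe is data-driven, so unmatched genes are dropped with a
# logged count.
#' Drop annotation genes absent from an expression matrix
#'
#' @param annotation a `gene_annotation`.
#' @param expression numeric matrix with gene rownames.
#' @return The filtered annotation; a message reports how many genes were
#'   dropped.
#' @export
align_annotation <- function(annotation, expression) {
  keep <- annotation$gene_id %in% rownames(expression)
  if (any(!keep)) {
    message(sum(!keep), " annotated gene(s) absent from the expression ",
            "matrix; dropped from all analyses")
  }
  out <- annotation[keep, , drop = FALSE]
  class(out) <- c("gene_annotation", "data.frame")
  out
}
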