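# Seeded synthetic compendia with planted binding-expression relations.
# Three planted archetypes, each in both signs, mirror the relation types
# the correlation measures are designed for: linear (PC), monotone
# non-linear (SC), and single-condition "on-off" outlier (CARS), plus null
# genes with independent binding and expression.

#' Simulation configuration for a synthetic compendium
#'
#' Defaults describe the benchmark conditions used throughout the package's
#' tests: 15 conditions, 20 genes per planted class (6 classes: linear,
#' monotone and on-off relations in both signs), 80 null genes, Poisson
#' binding counts, Gaussian expression noise of sd 0.1 on an RPKM-like
#' scale of roughly 0-8, and a noisy gold standard (sensitivity 0.9, false
#' positive rate 0.02) whose knockdown condition is the on-off outlier
#' condition.
#'
#' @param t_conditions number of conditions (>= 6).
#' @param class_counts named integer vector with entries `linear_pos`,
#'   `linear_neg`, `monotone_pos`, `monotone_neg`, `onoff_pos`,
#'   `onoff_neg`, `null`; their sum is the number of genes.
#' @param noise_sd Gaussian sd added to expression (clamped at 0).
#' @param onoff_condition index of the condition where on-off genes are
#'   jointly bound/expressed ("on").
#' @param gold_sensitivity probability a functional gene is labelled
#'   positive in the gold standard.
#' @param gold_fp_rate probability a null gene is labelled positive.
#' @param seed integer RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(t_conditions = 15L,
                       class_counts = c(linear_pos = 20L, linear_neg = 20L,
                                        monotone_pos = 20L, monotone_neg = 20L,
                                        onoff_pos = 20L, onoff_neg = 20L,
                                        null = 80L),
                       noise_sd = 0.1, onoff_condition = 1L,
                       gold_sensitivity = 0.9, gold_fp_rate = 0.02,
                       seed = 1L) {
  required <- c("linear_pos", "linear_neg", "monotone_pos", "monotone_neg",
                "onoff_pos", "onoff_neg", "null")
  if (!setequal(names(class_counts), required)) {
    stop("class_counts must name exactly: ", paste(required, collapse = ", "))
  }
  class_counts <- class_counts[required]
  if (any(class_counts < 0)) stop("class counts must be non-negative")
  if (t_conditions < 6L) stop("need t_conditions >= 6")
  if (onoff_condition < 1L || onoff_condition > t_conditions) {
    stop("onoff_condition out of range")
  }
  structure(
    list(t_conditions = as.integer(t_conditions),
         class_counts = as.integer(class_counts) |>
           stats::setNames(required),
         n_genes = sum(class_counts),
         noise_sd = noise_sd, onoff_condition = as.integer(onoff_condition),
         gold_sensitivity = gold_sensitivity, gold_fp_rate = gold_fp_rate,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Expression noise, clamped to the non-negative RPKM-like support.
.sim_noise <- function(mu, sd) pmax(0, mu + stats::rnorm(length(mu), 0, sd))

#' Generate a synthetic binding/expression compendium
#'
#' Binding values are Poisson peak counts with gene- and condition-specific
#' rates. Planted relations: linear genes have expression affine in binding
#' (positive or negative slope); monotone genes follow a convex cubic
#' transform of binding (monotone but deliberately non-linear); on-off genes
#' are near-silent in binding everywhere except one designated outlier
#' condition where binding is strongly elevated and expression is jointly
#' elevated (`+`) or suppressed (`-`); null genes draw expression
#' independently of binding. All draws are reproducible from the config
#' seed.
#'
#' @param cfg a [sim_config()].
#' @return List with `binding` and `expression` (genes x conditions
#'   matrices, identical dimnames), `truth` (data.frame `gene_id`, `class`,
#'   `sign`, `functional`), and `config`.
#' @export
generate_compendium <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  restore <- .with_seed(cfg$seed)
  on.exit(restore())
  t_len <- cfg$t_conditions
  conds <- sprintf("c%02d", seq_len(t_len))
  n <- cfg$n_genes
  genes <- sprintf("g%04d", seq_len(n))
  classes <- rep(names(cfg$class_counts), cfg$class_counts)
  signs <- ifelse(grepl("_pos$", classes), "+",
                  ifelse(grepl("_neg$", classes), "-", "n/a"))
  binding <- matrix(0, n, t_len, dimnames = list(genes, conds))
  expression <- matrix(0, n, t_len, dimnames = list(genes, conds))
  for (i in seq_len(n)) {
    cls <- sub("_(pos|neg)$", "", classes[i])
    pos <- signs[i] == "+"
    if (cls %in% c("linear", "monotone", "null")) {
      lambda <- stats::runif(t_len, 0, 8)
      b <- stats::rpois(t_len, lambda)
    } else {                                   # onoff
      b <- stats::rpois(t_len, 0.3)
      b[cfg$onoff_condition] <- 8L + stats::rpois(1L, 12)
    }
    e <- switch(cls,
      linear = if (pos) 1 + 0.8 * b else 8 - 0.8 * b,
      monotone = if (pos) 0.5 + 6 * (b / 8)^3 else 6.5 - 6 * (b / 8)^3,
      onoff = {
        base <- if (pos) rep(0.5, t_len) else rep(6, t_len)
        base[cfg$onoff_condition] <- if (pos) 8 else 0.3
        base
      },
      null = stats::rgamma(t_len, shape = 2, scale = 1.5)
    )
    binding[i, ] <- b
    expression[i, ] <- .sim_noise(e, cfg$noise_sd)
  }
  truth <- data.frame(gene_id = genes, class = classes, sign = signs,
                      functional = classes != "null",
                      stringsAsFactors = FALSE)
  list(binding = binding, expression = expression, truth = truth,
       config = cfg)
}

#' Generate a noisy knockdown gold standard from simulation truth
#'
#' Each functional gene is labelled positive (differentially expressed on
#' knockdown) with probability `sensitivity`; each non-functional gene with
#' probability `fp_rate`.
#'
#' @param truth truth data.frame from [generate_compendium()].
#' @param sensitivity detection probability for functional genes.
#' @param fp_rate false-positive labelling rate for null genes.
#' @param knockdown_condition condition id recorded on the gold standard.
#' @param seed integer RNG seed.
#' @return A `gold_standard` covering every gene in `truth`.
#' @export
generate_gold_standard <- function(truth, sensitivity = 0.9, fp_rate = 0.02,
                                   knockdown_condition = "c01", seed = 1L) {
  stopifnot(sensitivity >= 0, sensitivity <= 1, fp_rate >= 0, fp_rate <= 1)
  restore <- .with_seed(seed)
  on.exit(restore())
  p <- ifelse(truth$functional, sensitivity, fp_rate)
  labels <- stats::rbinom(nrow(truth), 1L, p) == 1L
  gold_standard(knockdown_condition,
                labels = stats::setNames(labels, truth$gene_id))
}

#' Write a genomic fixture reproducing a target count matrix
#'
#' Emits a GTF annotation of non-overlapping genes on one synthetic
#' chromosome plus per-condition BED peak files, constructed so that
#' [build_binding_matrix()] under the stated model rebuilds `target_counts`
#' exactly. Genes are spaced far enough apart (500 kb) that no peak can
#' fall into two genes' windows under any windowed model up to 50 kb.
#'
#' @param target_counts integer genes x conditions matrix of desired peak
#'   counts (gene rownames, condition colnames).
#' @param dir output directory (created if needed).
#' @param model windowed peak-to-gene model the fixture is built for.
#' @return List with `gtf` (path), `beds` (named vector of per-condition
#'   paths), and `annotation` (the `gene_annotation` as read back).
#' @export
generate_genomic_fixture <- function(target_counts, dir,
                                     model = "tss5kb") {
  stopifnot(is.matrix(target_counts), !is.null(rownames(target_counts)),
            !is.null(colnames(target_counts)))
  if (is.character(model)) model <- peak2gene_model(model)
  if (model$name == "nearest_tss") {
    stop("fixture construction targets windowed models")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(target_counts)
  spacing <- 500000L
  start0 <- spacing * seq_len(n)                 # 0-based gene starts
  end0 <- start0 + 20000L
  strand <- rep(c("+", "-"), length.out = n)
  tss <- ifelse(strand == "+", start0, end0 - 1L)
  gtf <- file.path(dir, "genes.gtf")
  writeLines(sprintf(
    'chrS\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
    start0 + 1L, end0, strand, rownames(target_counts)
  ), gtf)
  width <- 50L
  beds <- vapply(colnames(target_counts), function(cond) {
    rows <- character(0)
    for (i in seq_len(n)) {
      k <- target_counts[i, cond]
      if (k > 0) {
        # k disjoint peaks inside [tss - W, tss + W + 1)
        offs <- seq(from = -model$window_bp + 10L, by = 2L * width,
                    length.out = k)
        stopifnot(max(offs) + width <= model$window_bp)
        rows <- c(rows, sprintf("chrS\t%d\t%d\tpk\t0\t.",
                                tss[i] + offs, tss[i] + offs + width))
      }
    }
    path <- file.path(dir, paste0("peaks_", cond, ".bed"))
    writeLines(rows, path)
    path
  }, character(1))
  list(gtf = gtf, beds = beds,
       annotation = read_annotation(gtf))
}
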