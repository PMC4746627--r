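# Threshold selection, target-set construction and evaluation against
# knockdown gold standards: multiple-binding baseline, evaluation universes,
# precision-recall curves, fold-precision / top-fraction thresholds, unions
# across methods, and hypergeometric enrichment.

#' Multiple-binding baseline scores
#'
#' The traditional predictor: a gene's score is its binding (peak count or
#' magnitude) in the single condition where the knockdown was performed.
#' Genes with no binding there (`score < 1`) carry no information for this
#' baseline and are flagged invalid. Signs are not applicable.
#'
#' @param binding genes x conditions binding matrix.
#' @param knockdown_condition condition id present in the matrix.
#' @return A data.frame as [score_associations()] with `method = "MB"`.
#' @export
multiple_binding_scores <- function(binding, knockdown_condition) {
  if (!knockdown_condition %in% colnames(binding)) {
    stop("condition '", knockdown_condition, "' not in binding matrix; ",
         "available: ", paste(colnames(binding), collapse = ", "))
  }
  sc <- binding[, knockdown_condition]
  data.frame(gene_id = rownames(binding), method = "MB", score = as.numeric(sc),
             sign = "n/a", valid = sc >= 1, stringsAsFactors = FALSE)
}

# Pull the rows of one method out of a long score frame.
.method_scores <- function(scores, method) {
  df <- scores[scores$method == method, , drop = FALSE]
  if (nrow(df) == 0L) stop("no scores for method '", method, "'")
  if (anyDuplicated(df$gene_id)) stop("duplicated gene ids for one method")
  df
}

#' Evaluation universe for one method
#'
#' Precision, recall and enrichment are computed on the intersection of the
#' reference gene set (genes with knockdown differential-expression data)
#' and the genes the method can score: genes with non-constant binding and
#' expression profiles for PC/SC, every scored gene for CARS (degenerate
#' profiles are penalized, not excluded), and genes with at least one peak
#' in the knockdown condition for MB. The per-gene `valid` flag set by the
#' scoring functions encodes exactly this rule.
#'
#' @param scores long score data.frame from [score_associations()] /
#'   [multiple_binding_scores()].
#' @param gold a `gold_standard`.
#' @param method method whose universe to build.
#' @return Character vector of gene ids; error when empty.
#' @export
evaluation_universe <- function(scores, gold, method) {
  df <- .method_scores(scores, method)
  universe <- intersect(df$gene_id[df$valid], names(gold$labels))
  if (length(universe) == 0L) {
    stop("empty evaluation universe for method '", method,
         "' (no overlap between valid scores and reference genes)")
  }
  universe
}

#' Precision-recall curve over an evaluation universe
#'
#' Sweeps the distinct score values in descending order; genes with tied
#' scores enter together, one curve point per distinct value. Precision is
#' the fraction of predicted genes in the gold standard, recall the
#' fraction of gold-standard positives predicted; the true-positive count
#' per point is also reported.
#'
#' @param scores named numeric vector of scores over the universe.
#' @param labels named logical vector over the same genes (`TRUE` =
#'   gold-standard positive); must contain both classes.
#' @return data.frame `threshold`, `precision`, `recall`, `tp`, `n_predicted`.
#' @export
precision_recall_curve <- function(scores, labels) {
  stopifnot(!is.null(names(scores)), !is.null(names(labels)))
  labels <- labels[names(scores)]
  if (anyNA(labels)) stop("labels missing for some scored genes")
  if (all(labels) || !any(labels)) {
    stop("precision-recall needs both positive and negative labels")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  cum_tp <- cumsum(l)
  n_pred <- seq_along(s)
  last_of_group <- c(s[-1L] != s[-length(s)], TRUE)
  idx <- which(last_of_group)
  data.frame(
    threshold = s[idx],
    precision = cum_tp[idx] / n_pred[idx],
    recall = cum_tp[idx] / sum(labels),
    tp = cum_tp[idx],
    n_predicted = n_pred[idx],
    row.names = NULL
  )
}

#' Select a score threshold
#'
#' Two modes. `fold_precision` (the gold-standard-driven rule): with
#' background `f` the fraction of the universe that is positive, return the
#' lowest distinct score value whose predicted set (`score >= value`)
#' achieves precision `>= fold * f` -- the largest qualifying set, i.e. the
#' highest recall at the requested precision. `top_fraction` (no gold
#' standard): the value selecting the `ceiling(q * N)` highest-scoring
#' genes, boundary ties included.
#'
#' @param scores named numeric scores over the evaluation universe (or, for
#'   `top_fraction`, any scored set).
#' @param labels named logical gold labels (required for `fold_precision`).
#' @param mode `"fold_precision"` or `"top_fraction"`.
#' @param fold required fold increase in precision over background
#'   (default 1.5).
#' @param fraction top fraction `q` (default 0.01).
#' @return List with `threshold`, `mode`, and mode-specific fields
#'   (`fold`, `background_f`, `precision`, `n_predicted` or `fraction`).
#' @export
select_threshold <- function(scores, labels = NULL,
                             mode = c("fold_precision", "top_fraction"),
                             fold = 1.5, fraction = 0.01) {
  mode <- match.arg(mode)
  if (mode == "top_fraction") {
    stopifnot(fraction > 0, fraction <= 1)
    n_sel <- ceiling(fraction * length(scores))
    thr <- sort(scores, decreasing = TRUE)[n_sel]
    return(list(threshold = unname(thr), mode = mode, fraction = fraction,
                n_predicted = sum(scores >= thr)))
  }
  if (is.null(labels)) stop("fold_precision mode requires gold labels")
  stopifnot(fold > 1)
  labels <- labels[names(scores)]
  f <- mean(labels)
  if (fold * f > 1) {
    stop("target precision unreachable: fold * background = ",
         signif(fold * f, 4), " exceeds 1")
  }
  pr <- precision_recall_curve(scores, labels)
  ok <- pr$precision >= fold * f
  if (!any(ok)) stop("target precision unreachable: no cut attains ",
                     signif(fold * f, 4))
  pick <- max(which(ok))   # lowest qualifying distinct score
  list(threshold = pr$threshold[pick], mode = mode, fold = fold,
       background_f = f, precision = pr$precision[pick],
       n_predicted = pr$n_predicted[pick])
}

#' Apply a learned threshold genome-wide
#'
#' A threshold selected on the evaluation universe is applied to every
#' scored gene, irrespective of knockdown-data availability; signs carry
#' through.
#'
#' @param scores long score data.frame (one method's rows are used).
#' @param method method to threshold.
#' @param threshold numeric score cutoff (genes with `score >= threshold`
#'   are predicted).
#' @return A data.frame of class `target_set` (`gene_id`, `method`, `score`,
#'   `sign`) with attributes `threshold` and `method`.
#' @export
predict_targets <- function(scores, method, threshold) {
  stopifnot(is.finite(threshold))
  df <- .method_scores(scores, method)
  out <- df[df$score >= threshold, c("gene_id", "method", "score", "sign")]
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, threshold = threshold, method = method,
            class = c("target_set", "data.frame"))
}

#' Union of per-method target sets
#'
#' @param sets list of `target_set`s.
#' @return A `target_set` whose rows keep per-gene provenance: `method` and
#'   `sign` collapse the contributing methods (comma-separated, method
#'   order), `score` is the maximum contributing score, `n_methods` counts
#'   contributors. The union is at least as large as each input.
#' @export
union_of_methods <- function(sets) {
  stopifnot(length(sets) >= 1L)
  all_rows <- do.call(rbind, lapply(sets, as.data.frame))
  sp <- split(all_rows, all_rows$gene_id)
  out <- do.call(rbind, lapply(sp, function(g) {
    g <- g[order(g$method), , drop = FALSE]
    data.frame(gene_id = g$gene_id[1L],
               method = paste(g$method, collapse = ","),
               score = max(g$score),
               sign = paste(g$sign, collapse = ","),
               n_methods = nrow(g), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, method = "union",
            class = c("target_set", "data.frame"))
}

#' Hypergeometric enrichment of a predicted set in the gold standard
#'
#' Upper-tail probability of drawing at least the observed overlap when
#' sampling the predicted set without replacement from the universe: with
#' `N` universe genes of which `K` are gold positives and `n` predicted
#' (restricted to the universe), `p = P[X >= k]`,
#' `X ~ Hypergeometric(N, K, n)`.
#'
#' @param predicted character vector of predicted gene ids (genes outside
#'   the universe are dropped from `k` and `n`).
#' @param gold a `gold_standard`.
#' @param universe character vector, the evaluation universe.
#' @return List of class `enrichment_result`: `k`, `n`, `K`, `N`, `p_value`.
#'   `n = 0` gives `p = 1` with a warning.
#' @export
hypergeometric_enrichment <- function(predicted, gold, universe) {
  predicted <- intersect(predicted, universe)
  positives <- intersect(names(gold$labels)[gold$labels], universe)
  k <- length(intersect(predicted, positives))
  n <- length(predicted)
  K <- length(positives)
  N <- length(universe)
  if (n == 0L) {
    warning("empty predicted set within the universe; enrichment p = 1")
    p <- 1
  } else {
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  }
  structure(list(k = k, n = n, K = K, N = N, p_value = p),
            class = "enrichment_result")
}

#' Count positively vs negatively associated targets per method
#'
#' @param set a `target_set`.
#' @return data.frame `method`, `positive`, `negative`. Genes whose sign is
#'   not applicable (the MB baseline) are excluded.
#' @export
sign_summary <- function(set) {
  df <- as.data.frame(set)
  df <- df[df$sign %in% c("+", "-"), , drop = FALSE]
  if (nrow(df) == 0L) {
    return(data.frame(method = character(), positive = integer(),
                      negative = integer()))
  }
  agg <- lapply(split(df, df$method), function(g) {
    data.frame(method = g$method[1L],
               positive = sum(g$sign == "+"),
               negative = sum(g$sign == "-"), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Evaluation restricted to a gene subset
#'
#' Re-runs threshold selection and enrichment on the intersection of a
#' method's evaluation universe with a user-supplied gene list (e.g. a
#' promoter-class stratum), so complementary subsets partition the
#' true-positive counts.
#'
#' @inheritParams evaluation_universe
#' @param gene_subset character vector of gene ids defining the stratum.
#' @param mode,fold,fraction forwarded to [select_threshold()].
#' @return List with `universe`, `pr` (PR curve), `threshold` (selection
#'   result), `targets` (qualifying genes in the stratum universe), and
#'   `enrichment`.
#' @export
stratified_evaluation <- function(scores, gold, method, gene_subset,
                                  mode = "fold_precision", fold = 1.5,
                                  fraction = 0.01) {
  universe <- intersect(evaluation_universe(scores, gold, method), gene_subset)
  if (length(universe) == 0L) {
    stop("gene subset does not intersect the evaluation universe")
  }
  df <- .method_scores(scores, method)
  sc <- stats::setNames(df$score, df$gene_id)[universe]
  lab <- gold$labels[universe]
  pr <- precision_recall_curve(sc, lab)
  thr <- select_threshold(sc, lab, mode = mode, fold = fold,
                          fraction = fraction)
  targets <- names(sc)[sc >= thr$threshold]
  list(universe = universe, pr = pr, threshold = thr, targets = targets,
       enrichment = hypergeometric_enrichment(targets, gold, universe))
}
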