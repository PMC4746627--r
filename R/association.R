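# Per-gene binding-vs-expression association scores across conditions:
# absolute Pearson (PC), absolute Spearman (SC), and CARS, with signs,
# pooled permutation empirical p-values, and calibration of the CARS
# angular penalty c against a uniform-null criterion.

#' Absolute Pearson correlation score
#'
#' @param x numeric expression vector (length `t >= 3`).
#' @param y numeric binding vector across the same conditions.
#' @return List with `score` (`|r|`, in `[0, 1]`), `sign` (`"+"`, `"-"`, or
#'   `"n/a"`), and `valid` (`FALSE`, with score 0, when either vector is
#'   constant so the coefficient is undefined).
#' @export
pearson_abs <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("association scores require t >= 3 conditions")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(score = 0, sign = "n/a", valid = FALSE))
  }
  r <- stats::cor(x, y, method = "pearson")
  list(score = abs(r), sign = if (r >= 0) "+" else "-", valid = TRUE)
}

#' Absolute Spearman correlation score
#'
#' Pearson correlation of average-ranked data (ties receive mean ranks).
#'
#' @inheritParams pearson_abs
#' @return As [pearson_abs()].
#' @export
spearman_abs <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("association scores require t >= 3 conditions")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(score = 0, sign = "n/a", valid = FALSE))
  }
  r <- stats::cor(x, y, method = "spearman")
  list(score = abs(r), sign = if (r >= 0) "+" else "-", valid = TRUE)
}

# --- vectorized row-wise machinery used by the permutation null ------------

# Row-wise Pearson between aligned matrices; rows with zero variance give NA.
.row_pearson <- function(X, Y) {
  Xc <- X - rowMeans(X)
  Yc <- Y - rowMeans(Y)
  den <- sqrt(rowSums(Xc^2) * rowSums(Yc^2))
  ifelse(den > 0, rowSums(Xc * Yc) / den, NA_real_)
}

.row_rank <- function(M) t(apply(M, 1L, rank))

# Method-specific scorer factory: returns processed X/Y matrices plus a
# function scoring any row-permuted version of the processed Y. Processing
# (centering, ranking, max-scaling) commutes with within-row permutation.
.association_engine <- function(X, Y, method, cars_c) {
  switch(method,
    PC = list(X = X, Y = Y, score = function(Xp, Yp) abs(.row_pearson(Xp, Yp))),
    SC = list(X = .row_rank(X), Y = .row_rank(Y),
              score = function(Xp, Yp) abs(.row_pearson(Xp, Yp))),
    CARS = list(X = .cars_scale_center(X), Y = .cars_scale_center(Y),
                score = function(Xp, Yp) {
                  .cars_score(.cars_stats(Xp, Yp), cars_c)$score
                }),
    stop("unknown method: ", method)
  )
}

# Align a binding and an expression matrix on shared genes and identically
# ordered conditions.
.align_matrices <- function(binding, expression) {
  if (!setequal(colnames(binding), colnames(expression))) {
    stop("binding and expression matrices must share condition ids")
  }
  genes <- intersect(rownames(binding), rownames(expression))
  if (length(genes) == 0L) stop("no shared genes between matrices")
  list(binding = binding[genes, colnames(binding), drop = FALSE],
       expression = expression[genes, colnames(binding), drop = FALSE],
       genes = genes)
}

#' Score every gene's binding-expression association
#'
#' Computes, for each gene shared between the two matrices, the association
#' between its expression profile and its binding profile across conditions
#' under one or more measures: `PC` (absolute Pearson), `SC` (absolute
#' Spearman) and `CARS` (combined angle ratio statistic, see [cars()]).
#' PC/SC scores on a constant binding or expression profile are undefined
#' and flagged `valid = FALSE` (score 0, sign `"n/a"`); CARS scores every
#' gene, degenerate profiles being down-weighted by the angular penalty
#' rather than excluded.
#'
#' @param binding numeric genes x conditions binding matrix (counts or
#'   magnitudes), see [build_binding_matrix()].
#' @param expression numeric genes x conditions expression matrix with the
#'   same condition ids.
#' @param methods subset of `c("PC", "SC", "CARS")`.
#' @param cars_c CARS angular penalty half-width in radians.
#' @return A data.frame with columns `gene_id`, `method`, `score`, `sign`,
#'   `valid`, one row per gene per method.
#' @export
score_associations <- function(binding, expression,
                               methods = c("PC", "SC", "CARS"),
                               cars_c = 0.3) {
  methods <- match.arg(methods, c("PC", "SC", "CARS"), several.ok = TRUE)
  al <- .align_matrices(binding, expression)
  if (ncol(al$binding) < 3L) stop("association scores require t >= 3 conditions")
  out <- lapply(methods, function(mth) {
    eng <- .association_engine(al$expression, al$binding, mth, cars_c)
    if (mth == "CARS") {
      sc <- .cars_score(.cars_stats(eng$X, eng$Y), cars_c)
      data.frame(gene_id = al$genes, method = mth, score = sc$score,
                 sign = sc$sign, valid = TRUE, stringsAsFactors = FALSE)
    } else {
      r <- .row_pearson(eng$X, eng$Y)
      data.frame(gene_id = al$genes, method = mth,
                 score = ifelse(is.na(r), 0, abs(r)),
                 sign = ifelse(is.na(r), "n/a", ifelse(r >= 0, "+", "-")),
                 valid = !is.na(r), stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

# One permutation replicate: independently permute the entries within each
# row of the processed binding matrix.
.permute_rows <- function(M) {
  t_len <- ncol(M)
  idx <- vapply(seq_len(nrow(M)), function(i) sample.int(t_len), integer(t_len))
  matrix(M[cbind(rep(seq_len(nrow(M)), each = t_len), as.vector(idx))],
         nrow = nrow(M), byrow = TRUE)
}

#' Pooled permutation empirical p-values for association scores
#'
#' Builds a null distribution by shuffling the condition order of each
#' gene's binding profile independently, `B` times, re-scoring, and pooling
#' the null scores across genes. Each gene's empirical p-value uses the
#' add-one estimator `p = (1 + #null >= observed) / (1 + #null)`, so p is
#' never 0.
#'
#' @inheritParams score_associations
#' @param method one of `"PC"`, `"SC"`, `"CARS"`.
#' @param B number of permutation replicates (>= 1).
#' @param seed integer RNG seed; results are deterministic given the seed.
#' @param observed optional named vector of observed scores to reuse;
#'   computed from the matrices when `NULL`.
#' @return Named numeric vector of empirical p-values in `(0, 1]`, one per
#'   gene.
#' @export
empirical_pvalues <- function(binding, expression, method = "CARS",
                              B = 1000L, seed = 1L, cars_c = 0.3,
                              observed = NULL) {
  stopifnot(B >= 1L)
  al <- .align_matrices(binding, expression)
  eng <- .association_engine(al$expression, al$binding, method, cars_c)
  if (is.null(observed)) {
    observed <- stats::setNames(eng$score(eng$X, eng$Y), al$genes)
    observed[is.na(observed)] <- 0
  } else {
    observed <- observed[al$genes]
  }
  withr_seed <- .with_seed(seed)
  on.exit(withr_seed())
  null_scores <- unlist(lapply(seq_len(B), function(b) {
    s <- eng$score(eng$X, .permute_rows(eng$Y))
    s[is.na(s)] <- 0
    s
  }), use.names = FALSE)
  .empirical_p(observed, null_scores)
}

# p = (1 + #{null >= obs}) / (1 + N) via a sorted null pool.
.empirical_p <- function(observed, null_scores) {
  srt <- sort(null_scores)
  n_lt <- findInterval(observed, srt, left.open = TRUE)
  stats::setNames((1 + length(srt) - n_lt) / (1 + length(srt)),
                  names(observed))
}

# Seed the RNG restorably.
.with_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Calibrate the CARS angular penalty against a uniform null
#'
#' The penalty half-width `c` is chosen so that empirical p-values satisfy
#' a correct null distribution: p-values above 0.5 should be uniform. For
#' each candidate `c`, the binding profiles are permuted to create `B + 1`
#' null replicates; the first replicate is scored against the pooled null of
#' the remaining `B`, p-values above 0.5 are rescaled to `(0, 1]`, and a
#' Kolmogorov-Smirnov statistic against Uniform(0, 1] is recorded. The `c`
#' minimizing the KS statistic is returned (ties to the smallest `c`).
#'
#' @inheritParams empirical_pvalues
#' @param grid candidate values of `c` in `(0, pi/4]`.
#' @return List with `c_star` (selected value) and `diagnostics` (data.frame
#'   of `c`, `ks_stat`, `ks_p`, `n_tail`). Deterministic given the seed; the
#'   same permutations are reused for every candidate.
#' @export
calibrate_cars_c <- function(binding, expression,
                             grid = c(0.1, 0.2, 0.3, 0.4, pi / 4),
                             B = 200L, seed = 1L) {
  if (length(grid) == 0L) stop("grid of candidate c values is empty")
  if (any(grid <= 0 | grid > pi / 4)) stop("c candidates must lie in (0, pi/4]")
  al <- .align_matrices(binding, expression)
  XS <- .cars_scale_center(al$expression)
  YS <- .cars_scale_center(al$binding)
  restore <- .with_seed(seed)
  on.exit(restore())
  replicates <- lapply(seq_len(B + 1L), function(b) .permute_rows(YS))
  diagnostics <- do.call(rbind, lapply(grid, function(cc) {
    scores <- lapply(replicates, function(Yb) {
      .cars_score(.cars_stats(XS, Yb), cc)$score
    })
    obs <- scores[[1L]]
    null_pool <- unlist(scores[-1L], use.names = FALSE)
    p <- .empirical_p(stats::setNames(obs, al$genes), null_pool)
    tail_p <- p[p > 0.5]
    u <- 2 * tail_p - 1       # (0.5, 1] -> (0, 1]
    ks <- suppressWarnings(stats::ks.test(u, "punif"))
    data.frame(c = cc, ks_stat = unname(ks$statistic),
               ks_p = ks$p.value, n_tail = length(u))
  }))
  list(c_star = diagnostics$c[which.min(diagnostics$ks_stat)],
       diagnostics = diagnostics)
}
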