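# Combined angle ratio statistic (CARS): an outlier-association score for a
# gene's binding-vs-expression scatter across t conditions. Points far from
# the medoid of the max-scaled, median-centered scatter score highly, with
# an angular penalty for deviating from the y = x (positive association) or
# y = -x (negative association) diagonal.

# Scale each row by its maximum (all-zero rows pass through as zeros), then
# median-center each row. Both steps are invariant to permutation of the
# entries within a row, which the permutation-null code exploits.
.cars_scale_center <- function(M) {
  mx <- apply(M, 1L, max)
  M <- M / ifelse(mx > 0, mx, 1)
  M - apply(M, 1L, stats::median)
}

# Per-point geometry for genes-in-rows matrices of scaled/centered
# expression (XS) and binding (YS):
#   d     Euclidean distance of (x_i, y_i) from the origin (the medoid)
#   r     d_i over the leave-one-out mean distance of the other t-1 points
#   theta angle from the positive x-axis
#   a_pos angular distance to the nearer branch of y = x
#   a_neg angular distance to the nearer branch of y = -x
# a_pos + a_neg == pi/2 for every point (orthogonal diagonals).
.cars_stats <- function(XS, YS) {
  t_len <- ncol(XS)
  if (t_len < 3L) stop("CARS requires t >= 3 conditions")
  d <- sqrt(XS^2 + YS^2)
  loo_mean <- (rowSums(d) - d) / (t_len - 1L)
  r <- ifelse(loo_mean > 0, d / loo_mean, 0)
  theta <- atan2(YS, XS)
  a_pos <- abs(((theta - pi / 4 + pi / 2) %% pi) - pi / 2)
  a_neg <- abs(((theta + pi / 4 + pi / 2) %% pi) - pi / 2)
  list(d = d, r = r, theta = theta, a_pos = a_pos, a_neg = a_neg)
}

# Angular penalty weight: linear decay to zero at half-width c.
.cars_weight <- function(a, c) pmax(0, 1 - a / c)

# Score genes (rows) from precomputed stats at penalty half-width c.
# Returns score, sign ("+" / "-"), and the winning condition index; ties
# resolve + over -, then the lowest condition index.
.cars_score <- function(st, c) {
  s_pos <- st$r * .cars_weight(st$a_pos, c)
  s_neg <- st$r * .cars_weight(st$a_neg, c)
  i_pos <- max.col(s_pos, ties.method = "first")
  i_neg <- max.col(s_neg, ties.method = "first")
  n <- nrow(s_pos)
  best_pos <- s_pos[cbind(seq_len(n), i_pos)]
  best_neg <- s_neg[cbind(seq_len(n), i_neg)]
  plus <- best_pos >= best_neg
  list(score = ifelse(plus, best_pos, best_neg),
       sign = ifelse(plus, "+", "-"),
       index = ifelse(plus, i_pos, i_neg),
       s_pos = s_pos, s_neg = s_neg)
}

#' Combined angle ratio statistic for one gene
#'
#' Scores the association between one gene's expression profile `x` and
#' binding profile `y` across the same `t >= 3` conditions. The pipeline:
#' (1) scale each vector by its maximum (all-zero vectors pass through);
#' (2) median-center each scaled vector; (3) compute each point's Euclidean
#' distance `d_i` from the origin (the medoid after centering); (4) form the
#' ratio statistic `r_i = d_i / mean(d_j, j != i)` (0 when that mean is 0);
#' (5) take each point's angle from the x-axis and its angular distances
#' `a_i+` / `a_i-` to the nearer branch of `y = x` / `y = -x`; (6) weight
#' `s_i+/- = r_i * max(0, 1 - a_i+/- / c)`; (7) the score is the maximum of
#' all `s_i+` and `s_i-`, its sign recording which diagonal won (ties
#' resolve `+` over `-`, then the lowest condition index).
#'
#' Genes with a constant (degenerate, one-dimensional) binding or expression
#' profile are scored, not excluded: their points sit at angular distance
#' `pi/4` from both diagonals and are down-weighted by the penalty alone,
#' which keeps the permutation null well behaved.
#'
#' @param x numeric expression vector across conditions.
#' @param y numeric binding vector across the same conditions, same length.
#' @param c angular penalty half-width in radians, in `(0, pi/4]`.
#' @return A list of class `cars_result`: `score`, `sign` (`"+"`/`"-"`),
#'   `index` (winning condition), and `intermediates` (per-point
#'   `x_scaled`, `y_scaled`, `d`, `r`, `theta`, `a_pos`, `a_neg`, `s_pos`,
#'   `s_neg`).
#' @examples
#' # a single condition where binding and expression are jointly "on"
#' cars(c(0, 0, 0, 0, 0, 1), c(0, 0, 0, 0, 0, 1))$sign  # "+"
#' @export
cars <- function(x, y, c = 0.3) {
  stopifnot(length(x) == length(y), is.numeric(x), is.numeric(y))
  if (length(x) < 3L) stop("CARS requires t >= 3 conditions")
  if (!(c > 0 && c <= pi / 4)) stop("c must lie in (0, pi/4]")
  XS <- .cars_scale_center(matrix(x, nrow = 1L))
  YS <- .cars_scale_center(matrix(y, nrow = 1L))
  st <- .cars_stats(XS, YS)
  sc <- .cars_score(st, c)
  structure(
    list(score = sc$score[1L], sign = sc$sign[1L], index = sc$index[1L],
         c = c,
         intermediates = list(
           x_scaled = drop(XS), y_scaled = drop(YS),
           d = drop(st$d), r = drop(st$r), theta = drop(st$theta),
           a_pos = drop(st$a_pos), a_neg = drop(st$a_neg),
           s_pos = drop(sc$s_pos), s_neg = drop(sc$s_neg))),
    class = "cars_result"
  )
}

# Vectorized CARS over aligned genes x conditions matrices (rows = genes).
# Returns list(score, sign, index) of per-gene vectors.
.cars_matrix <- function(X, Y, c) {
  st <- .cars_stats(.cars_scale_center(X), .cars_scale_center(Y))
  .cars_score(st, c)[c("score", "sign", "index")]
}
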