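# Quantile normalization of expression matrices across conditions.

#' Quantile-normalize an expression matrix
#'
#' Forces every condition column to share one value distribution while
#' preserving within-column rank order: each column's values are replaced by
#' the mean across columns of the column-wise sorted values at the same
#' rank. Tied values within a column receive the mean of the reference
#' values across their tied ranks (the conventional tie rule, as in
#' [limma::normalizeQuantiles()] with `ties = TRUE`, which performs the
#' computation here).
#'
#' @param m numeric genes x conditions matrix with at least 2 columns.
#' @return The normalized matrix, same dimnames. After normalization every
#'   column holds an identical multiset of values (up to tie averaging) and
#'   the transform is idempotent.
#' @examples
#' m <- matrix(c(1, 3, 4, 2), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("c1", "c2")))
#' quantile_normalize(m)  # rank means 1.5 and 3.5
#' @export
quantile_normalize <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (ncol(m) < 2L) stop("quantile normalization needs >= 2 conditions")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  for (a in c("mode", "model")) attr(out, a) <- attr(m, a)
  out
}
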