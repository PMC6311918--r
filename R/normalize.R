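#' Laplacian normalization of a symmetric weight matrix
#'
#' Rescales `M(i, j)` to `M(i, j) / sqrt(D(i, i) * D(j, j))` where `D` is
#' the diagonal of row sums, the normalized-adjacency form whose spectral
#' radius is at most 1 for connected nonnegative input. Rows/columns with a
#' nonpositive sum are zeroed (an empty neighbourhood has no scale).
#'
#' @param m Square symmetric numeric matrix.
#' @return The symmetric normalized matrix.
#' @export
#' @examples
#' laplacian_normalize(matrix(c(2, 1, 1, 2), 2))
laplacian_normalize <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) abort("input must be a square matrix")
  if (max(abs(m - t(m))) > 1e-8) abort("input must be symmetric")
  d <- rowSums(m)
  ok <- d > 0
  out <- m * 0
  if (any(ok)) {
    inv <- 1 / sqrt(d[ok])
    out[ok, ok] <- m[ok, ok] * outer(inv, inv)
  }
  out
}

# Shared first step of the two-step normalizations: divide each nonzero
# entry by sqrt(column sum * row sum) of the source matrix. Rows/columns
# whose sum is nonpositive (possible when negative expression correlations
# dominate) are zeroed with a warning: a negative mass has no square root in
# this pipeline.
normalize_step1 <- function(s) {
  rs <- rowSums(s)
  cs <- colSums(s)
  bad_r <- rs <= 0 & apply(s != 0, 1, any)
  bad_c <- cs <= 0 & apply(s != 0, 2, any)
  if (any(bad_r) || any(bad_c)) {
    warn(paste0("zeroing ", sum(bad_r), " row(s) and ", sum(bad_c),
                " column(s) with nonpositive similarity mass"))
  }
  keep_r <- rs > 0
  keep_c <- cs > 0
  out <- s * 0
  if (any(keep_r) && any(keep_c)) {
    block <- s[keep_r, keep_c, drop = FALSE]
    denom <- outer(1 / sqrt(rs[keep_r]), 1 / sqrt(cs[keep_c]))
    out[keep_r, keep_c] <- ifelse(block != 0, block * denom, 0)
  }
  out
}

# Shared second step: rescale along one margin so that every margin with
# surviving nonzero entries sums to 1. A margin whose entries are nonzero
# but cancel exactly cannot be rescaled and raises an error.
normalize_step2 <- function(s1, margin, what) {
  if (margin == 2) return(t(normalize_step2(t(s1), 1, what)))
  out <- s1 * 0
  for (i in seq_len(nrow(s1))) {
    nz <- s1[i, ] != 0
    if (!any(nz)) next
    tot <- sum(s1[i, ])
    if (tot == 0) {
      abort(paste0("degenerate ", what, " ", i,
                   ": nonzero similarities cancel to zero mass"))
    }
    out[i, nz] <- s1[i, nz] / tot
  }
  out
}

#' Two-step normalization of the lncRNA similarity matrix
#'
#' First a Laplacian-style rescaling of every nonzero entry by
#' `sqrt(row sum * column sum)`, then a row rescaling so that every row with
#' surviving entries sums to exactly 1. The result is the lncRNA transition
#' matrix applied on the right of the score matrix during the walk; it is
#' generally asymmetric, and its zero pattern contains that of the input.
#'
#' @param sl Fused lncRNA similarity matrix (see
#'   [combine_lncrna_similarity()]).
#' @return Row-stochastic (over nonzero rows) normalized matrix `LL`.
#' @export
normalize_lncrna <- function(sl) {
  if (!is.matrix(sl) || nrow(sl) != ncol(sl)) abort("SL must be square")
  normalize_step2(normalize_step1(sl), 1, "lncRNA row")
}

#' Two-step normalization of the disease similarity matrix
#'
#' Same first step as [normalize_lncrna()], but the second step rescales
#' COLUMNS to unit mass: the disease transition matrix multiplies the score
#' matrix on the left, so its columns, not rows, carry the outgoing weights.
#'
#' @param sd Logistic-transformed disease similarity matrix (see
#'   [logistic_disease_similarity()]).
#' @return Column-stochastic (over nonzero columns) normalized matrix `LD`.
#' @export
normalize_disease <- function(sd) {
  if (!is.matrix(sd) || nrow(sd) != ncol(sd)) abort("SD must be square")
  normalize_step2(normalize_step1(sd), 2, "disease column")
}
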