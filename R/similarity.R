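#' Gaussian interaction-profile kernel similarity
#'
#' Similarity between two lncRNAs (or two diseases) is a Gaussian kernel on
#' their binary interaction profiles: for lncRNAs the profiles are the
#' columns of the association matrix, for diseases the rows. The kernel is
#' `exp(-gamma * ||IP(i) - IP(j)||^2)` with bandwidth
#' `gamma = gamma_prime / mean(||IP||^2)`, i.e. scaled by the average number
#' of associations per entity, so the kernel adapts to network density.
#'
#' @param assoc Association matrix (diseases x lncRNAs); must contain at
#'   least one association, otherwise the bandwidth is undefined.
#' @param axis `"lncrna"` (profiles are columns) or `"disease"` (rows).
#' @param gamma_prime Bandwidth scaling, positive; default 1.
#' @return A symmetric similarity matrix with unit diagonal and entries in
#'   `(0, 1]`, labelled by the identifiers of the chosen axis.
#' @export
#' @examples
#' a <- as_assoc_matrix(diag(2))
#' gip_kernel(a, "lncrna")[1, 2]  # exp(-2)
gip_kernel <- function(assoc, axis = c("lncrna", "disease"), gamma_prime = 1) {
  axis <- match.arg(axis)
  a <- as_assoc_matrix(assoc)
  stopifnot(gamma_prime > 0)
  if (sum(a) == 0) {
    abort("association matrix has no associations: kernel bandwidth undefined")
  }
  p <- if (axis == "lncrna") t(a) else a   # profiles on rows
  sq <- rowSums(p^2)
  gamma <- gamma_prime / mean(sq)
  g <- p %*% t(p)
  d2 <- outer(sq, sq, "+") - 2 * g
  d2[d2 < 0] <- 0                          # numeric guard
  k <- exp(-gamma * d2)
  diag(k) <- 1
  (k + t(k)) / 2
}

#' Spearman expression similarity over an lncRNA universe
#'
#' Rank correlation (average ranks for ties) of the expression vectors of
#' every pair of profiled lncRNAs, placed into a matrix over the full
#' association universe: any pair involving an unprofiled lncRNA is 0. The
#' diagonal is 1 for profiled lncRNAs and 0 otherwise. A zero-variance
#' expression vector has no rank information and correlates 0 with every
#' partner.
#'
#' @param expr Expression matrix (lncRNAs x tissues) with rownames; may have
#'   zero rows.
#' @param universe Character vector of lncRNA identifiers in association
#'   matrix column order.
#' @return A symmetric `length(universe)` square matrix with entries in
#'   `[-1, 1]`.
#' @export
spearman_similarity <- function(expr, universe) {
  stopifnot(is.character(universe), !anyDuplicated(universe))
  nl <- length(universe)
  spc <- matrix(0, nl, nl, dimnames = list(universe, universe))
  if (is.null(expr) || nrow(expr) == 0) return(spc)
  stopifnot(is.matrix(expr), is.numeric(expr), ncol(expr) >= 2,
            !is.null(rownames(expr)))
  keep <- rownames(expr) %in% universe
  expr <- expr[keep, , drop = FALSE]
  if (nrow(expr) == 0) return(spc)
  cc <- suppressWarnings(cor(t(expr), method = "spearman"))
  cc[!is.finite(cc)] <- 0                  # zero-variance profiles
  diag(cc) <- 1
  idx <- match(rownames(expr), universe)
  spc[idx, idx] <- cc
  spc
}

#' Fuse expression and interaction-profile lncRNA similarities
#'
#' For pairs where both lncRNAs carry expression profiles the similarity is
#' the weighted average `ew * SPC + (1 - ew) * KL`; for every other pair it
#' falls back to the interaction-profile kernel alone.
#'
#' @param spc Spearman expression similarity matrix (see
#'   [spearman_similarity()]).
#' @param kl lncRNA interaction-profile kernel matrix.
#' @param l1 Logical vector (or identifier vector) marking the lncRNAs with
#'   expression profiles.
#' @param ew Expression weight in `[0, 1]`.
#' @return The fused symmetric lncRNA similarity matrix.
#' @export
combine_lncrna_similarity <- function(spc, kl, l1, ew = 0.5) {
  stopifnot(is.matrix(spc), is.matrix(kl), ew >= 0, ew <= 1)
  if (!identical(dim(spc), dim(kl))) {
    abort("SPC and KL dimensions differ")
  }
  ids <- colnames(kl)
  if (is.character(l1)) l1 <- ids %in% l1
  stopifnot(is.logical(l1), length(l1) == ncol(kl))
  both <- outer(l1, l1, "&")
  sl <- kl
  sl[both] <- ew * spc[both] + (1 - ew) * kl[both]
  sl
}

#' Logistic transform of the disease kernel
#'
#' Entry-wise map `1 / (1 + exp(c * k + d))` sharpening the disease
#' interaction-profile kernel: with the defaults `c = -15`, `d = log(9999)`
#' a kernel value of 0 maps to 1e-4 and 1 maps to about 0.997, and the map
#' is strictly increasing (for `c < 0`), so weak similarities are suppressed
#' without ever becoming exact zeros.
#'
#' @param kd Disease interaction-profile kernel matrix.
#' @param c,d Logistic parameters; see [lnc_config()].
#' @return A symmetric disease similarity matrix with entries in `(0, 1)`.
#' @export
logistic_disease_similarity <- function(kd, c = -15, d = log(9999)) {
  stopifnot(is.matrix(kd))
  1 / (1 + exp(c * kd + d))
}
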