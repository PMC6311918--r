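#' Seed score matrix for the walk
#'
#' The restart distribution spreads unit mass uniformly over the known
#' associations: `Rt0 = A / sum(A)`.
#'
#' @param assoc Association matrix with at least one association.
#' @return A nonnegative matrix of the same shape summing to 1.
#' @export
init_scores <- function(assoc) {
  a <- as_assoc_matrix(assoc)
  if (sum(a) == 0) abort("cannot seed the walk: no known associations")
  a / sum(a)
}

#' One bi-random-walk step
#'
#' Runs one propagation step on each layer of the heterogeneous network —
#' over lncRNA similarity by right-multiplication, over disease similarity
#' by left-multiplication — each with restart mass `1 - alpha` on the seed
#' matrix, and averages the two results. The averaged matrix is the single
#' state both walks restart from at the next step.
#'
#' @param rt_prev Current score matrix (diseases x lncRNAs).
#' @param ll Normalized lncRNA matrix (see [normalize_lncrna()]).
#' @param ld Normalized disease matrix (see [normalize_disease()]).
#' @param rt0 Seed matrix (see [init_scores()]).
#' @param alpha Walk-continuation probability in `[0, 1]`.
#' @return The next score matrix.
#' @export
birw_step <- function(rt_prev, ll, ld, rt0, alpha) {
  stopifnot(alpha >= 0, alpha <= 1)
  if (!identical(dim(rt_prev), dim(rt0)) ||
      ncol(rt_prev) != nrow(ll) || nrow(ll) != ncol(ll) ||
      nrow(rt_prev) != nrow(ld) || nrow(ld) != ncol(ld)) {
    abort("inconsistent matrix dimensions in walk step")
  }
  rt_l <- alpha * rt_prev %*% ll + (1 - alpha) * rt0
  rt_d <- alpha * ld %*% rt_prev + (1 - alpha) * rt0
  (rt_l + rt_d) / 2
}

#' Run the bi-random walk to its fixed point
#'
#' Iterates [birw_step()] from the seed matrix until the maximum absolute
#' elementwise change between successive score matrices falls below `tol`,
#' or `max_iter` steps have been taken. With `alpha < 1` and the
#' sub-stochastic transition matrices produced by the normalization step the
#' map is a contraction and the iteration converges to the unique solution
#' of `RT = (alpha/2) (RT LL + LD RT) + (1 - alpha) Rt0`. Non-convergence
#' (possible at `alpha = 1`, where the restart anchor vanishes) is reported
#' through the `converged` flag, not as an error.
#'
#' @param assoc Association matrix (seeds the walk).
#' @param ll,ld Normalized similarity matrices.
#' @param config An [lnc_config()].
#' @return An object of class `lnc_walk`: list with `scores` (the steady
#'   score matrix, `scores[i, j]` being the predicted association strength
#'   of disease i and lncRNA j), `iterations`, `converged`, `final_delta`.
#' @export
run_birw <- function(assoc, ll, ld, config = lnc_config()) {
  a <- as_assoc_matrix(assoc)
  rt0 <- init_scores(a)
  rt <- rt0
  delta <- Inf
  iter <- 0L
  while (iter < config$max_iter) {
    iter <- iter + 1L
    rt_next <- birw_step(rt, ll, ld, rt0, config$alpha)
    if (!all(is.finite(rt_next))) {
      abort(paste0("walk diverged to non-finite values at iteration ", iter))
    }
    delta <- max(abs(rt_next - rt))
    rt <- rt_next
    if (delta < config$tol) break
  }
  structure(list(scores = rt, iterations = iter,
                 converged = delta < config$tol, final_delta = delta),
            class = "lnc_walk")
}

#' @export
print.lnc_walk <- function(x, ...) {
  cat("Bi-random walk:", nrow(x$scores), "diseases x", ncol(x$scores),
      "lncRNAs;", x$iterations, "iterations;",
      if (x$converged) "converged" else "NOT converged",
      sprintf("(final delta %.3g)\n", x$final_delta))
  invisible(x)
}

# Build every similarity and transition matrix of the heterogeneous network
# from an association matrix and (optional) expression profiles.
build_network <- function(a, expr = NULL, config = lnc_config()) {
  kl <- gip_kernel(a, "lncrna", config$gamma_l_prime)
  kd <- gip_kernel(a, "disease", config$gamma_d_prime)
  l1 <- if (is.null(expr) || nrow(expr) == 0) {
    rep(FALSE, ncol(a))
  } else {
    colnames(a) %in% rownames(expr)
  }
  spc <- spearman_similarity(expr, colnames(a))
  sl <- combine_lncrna_similarity(spc, kl, l1, config$ew)
  sd <- logistic_disease_similarity(kd, config$c, config$d)
  list(kl = kl, kd = kd, spc = spc, sl = sl, sd = sd,
       ll = normalize_lncrna(sl), ld = normalize_disease(sd))
}

#' Score all lncRNA-disease pairs by network propagation
#'
#' The full pipeline: interaction-profile kernels for both node types,
#' fusion with Spearman expression similarity on the lncRNA side, logistic
#' transform on the disease side, two-step Laplacian normalization of both,
#' then the bi-random walk with restart. The result ranks every pair, known
#' and unknown; unknown pairs with high scores are the candidate
#' associations.
#'
#' @param associations Edge-list data frame or binary association matrix
#'   (see [as_assoc_matrix()]).
#' @param expression Optional expression matrix (lncRNAs x tissues, with
#'   rownames) or a data frame whose first column is the lncRNA identifier.
#' @param config An [lnc_config()]; individual parameters can also be
#'   overridden through `...`.
#' @param ... Overrides forwarded to [lnc_config()] (e.g. `alpha = 0.5`).
#' @return A tibble of class `lnc_scores` with columns `disease`, `lncrna`,
#'   `score`, `known`, sorted by disease then descending score. Walk
#'   metadata is attached as attributes and reported by [glance()].
#' @export
#' @examples
#' edges <- data.frame(disease = c("D1", "D1", "D2"),
#'                     lncrna  = c("L1", "L2", "L2"))
#' lnc_predict(edges, alpha = 0.5)
lnc_predict <- function(associations, expression = NULL,
                        config = lnc_config(), ...) {
  dots <- list(...)
  if (length(dots) > 0) config <- do.call(lnc_config, utils::modifyList(
    unclass(config)[names(formals(lnc_config))], dots))
  a <- as_assoc_matrix(associations)
  expr <- as_expression_matrix(expression)
  net <- build_network(a, expr, config)
  walk <- run_birw(a, net$ll, net$ld, config)
  out <- tibble(disease = rep(rownames(a), times = ncol(a)),
                lncrna = rep(colnames(a), each = nrow(a)),
                score = c(walk$scores),
                known = as.integer(c(a)))
  out <- out[order(out$disease, -out$score, out$lncrna, method = "radix"), ]
  structure(out, class = c("lnc_scores", class(tibble())),
            iterations = walk$iterations, converged = walk$converged,
            final_delta = walk$final_delta, alpha = config$alpha)
}

# Accept NULL, a matrix with rownames, or a data frame with id first column.
as_expression_matrix <- function(expression) {
  if (is.null(expression)) return(NULL)
  if (is.matrix(expression)) {
    stopifnot(is.numeric(expression))
    if (nrow(expression) > 0 && is.null(rownames(expression))) {
      abort("expression matrix needs lncRNA rownames")
    }
    return(expression)
  }
  if (is.data.frame(expression)) {
    m <- as.matrix(expression[, -1, drop = FALSE])
    if (nrow(m) > 0 && !is.numeric(m)) abort("expression values must be numeric")
    rownames(m) <- as.character(expression[[1]])
    return(m)
  }
  abort("expression must be NULL, a matrix, or a data frame")
}

#' @exportS3Method generics::glance
glance.lnc_scores <- function(x, ...) {
  tibble(alpha = attr(x, "alpha"),
         iterations = attr(x, "iterations"),
         converged = attr(x, "converged"),
         final_delta = attr(x, "final_delta"),
         n_diseases = length(unique(x$disease)),
         n_lncrnas = length(unique(x$lncrna)))
}

#' @exportS3Method generics::tidy
tidy.lnc_scores <- function(x, ...) {
  as_tibble(x)[, c("disease", "lncrna", "score", "known")]
}
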