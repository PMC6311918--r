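#' ROC curve and AUC from positive and negative score sets
#'
#' Sweeps a threshold over every distinct observed score, records
#' `(FPR, TPR)` at each, and integrates by the trapezoidal rule. Ties
#' between a positive and a negative score contribute half credit, so the
#' AUC equals the normalized Mann-Whitney U statistic.
#'
#' @param positive_scores,negative_scores Nonempty numeric vectors.
#' @return A list with `roc_points` (tibble of `threshold`, `fpr`, `tpr`,
#'   including the (0, 0) anchor) and `auc`.
#' @export
#' @examples
#' roc_auc(c(3, 1), c(2, 0))$auc  # 0.75
roc_auc <- function(positive_scores, negative_scores) {
  if (length(positive_scores) == 0 || length(negative_scores) == 0) {
    abort("both score sets must be nonempty")
  }
  stopifnot(all(is.finite(positive_scores)), all(is.finite(negative_scores)))
  th <- sort(unique(c(positive_scores, negative_scores)), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(positive_scores >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(negative_scores >= t), numeric(1))
  roc <- tibble(threshold = c(Inf, th), fpr = c(0, fpr), tpr = c(0, tpr))
  list(roc_points = roc, auc = trapezoid(roc$fpr, roc$tpr))
}

trapezoid <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Leave-one-out cross-validation of the prediction pipeline
#'
#' Withholds each known association in turn, rebuilds every
#' association-derived similarity (the interaction-profile kernels change
#' when an edge is removed; expression similarity does not), reruns the
#' walk, and records the rank of the withheld pair's score among all
#' candidate pairs — the pairs unknown in the modified matrix, pooled over
#' all diseases. Ranks use the midrank convention for ties. The ROC sweeps
#' the rank threshold: sensitivity is the fraction of withheld associations
#' ranked at or above the threshold, the false-positive rate the fraction
#' of candidates ranked above it; AUC is the trapezoid over that curve.
#'
#' @param associations Edge list or association matrix with at least 2
#'   known associations.
#' @param expression Optional expression matrix or data frame.
#' @param config An [lnc_config()]; `...` forwards overrides.
#' @param ... Parameter overrides, as in [lnc_predict()].
#' @param scorer Optional replacement scoring function taking the modified
#'   association matrix and returning a score matrix (or `lnc_walk`); used
#'   for null-model experiments. Default: the full pipeline.
#' @return An object of class `lnc_loocv`: list with `folds` (per-fold
#'   tibble of `disease`, `lncrna`, `score`, `rank`, `n_candidates`,
#'   `iterations`, `converged`), `roc` (tibble of `rank_threshold`, `fpr`,
#'   `tpr`), `auc`, `n_folds`. Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @export
lnc_loocv <- function(associations, expression = NULL,
                      config = lnc_config(), ..., scorer = NULL) {
  dots <- list(...)
  if (length(dots) > 0) config <- do.call(lnc_config, utils::modifyList(
    unclass(config)[names(formals(lnc_config))], dots))
  a <- as_assoc_matrix(associations)
  if (sum(a) < 2) abort("LOOCV needs at least 2 known associations")
  expr <- as_expression_matrix(expression)
  expr <- if (is.null(expr)) NULL else {
    expr[rownames(expr) %in% colnames(a), , drop = FALSE]
  }

  # expression similarity is independent of A: compute once
  spc <- spearman_similarity(expr, colnames(a))
  l1 <- if (is.null(expr)) rep(FALSE, ncol(a)) else colnames(a) %in% rownames(expr)
  if (is.null(scorer)) {
    scorer <- function(a_mod) {
      kl <- gip_kernel(a_mod, "lncrna", config$gamma_l_prime)
      kd <- gip_kernel(a_mod, "disease", config$gamma_d_prime)
      sl <- combine_lncrna_similarity(spc, kl, l1, config$ew)
      sd <- logistic_disease_similarity(kd, config$c, config$d)
      run_birw(a_mod, normalize_lncrna(sl), normalize_disease(sd), config)
    }
  }

  known <- which(a == 1, arr.ind = TRUE)
  folds <- purrr::map(seq_len(nrow(known)), function(f) {
    i <- known[f, 1]; j <- known[f, 2]
    a_mod <- a
    a_mod[i, j] <- 0
    if (sum(a_mod) == 0) {
      warn(paste0("skipping fold ", f, ": no training associations remain"))
      return(NULL)
    }
    res <- scorer(a_mod)
    iters <- NA_integer_; conv <- NA
    if (inherits(res, "lnc_walk")) {
      iters <- res$iterations; conv <- res$converged
      if (!conv) warn(paste0("walk did not converge in fold ", f))
      res <- res$scores
    }
    cand <- a_mod == 0
    s_pos <- res[i, j]
    neg <- res[cand]
    neg <- neg[-match(s_pos, neg)]  # remove one copy: the withheld pair itself
    tibble(disease = rownames(a)[i], lncrna = colnames(a)[j],
           score = s_pos,
           rank = 1 + sum(neg > s_pos) + 0.5 * sum(neg == s_pos),
           n_candidates = sum(cand), iterations = iters, converged = conv)
  })
  folds <- dplyr::bind_rows(folds)
  if (nrow(folds) == 0) abort("no usable LOOCV folds")

  n_cand <- max(folds$n_candidates)
  ks <- sort(unique(c(0, folds$rank, n_cand)))
  tpr <- vapply(ks, function(k) mean(folds$rank <= k), numeric(1))
  fpr <- vapply(ks, function(k) {
    mean(pmin(pmax(k - (folds$rank <= k), 0), n_cand - 1)) / (n_cand - 1)
  }, numeric(1))
  roc <- tibble(rank_threshold = ks, fpr = fpr, tpr = tpr)
  structure(list(folds = folds, roc = roc,
                 auc = trapezoid(roc$fpr, roc$tpr),
                 n_folds = nrow(folds), alpha = config$alpha),
            class = "lnc_loocv")
}

#' @export
print.lnc_loocv <- function(x, ...) {
  cat(sprintf("LOOCV over %d associations: AUC = %.4f (alpha = %g)\n",
              x$n_folds, x$auc, x$alpha))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.lnc_loocv <- function(x, ...) x$folds

#' @exportS3Method generics::glance
glance.lnc_loocv <- function(x, ...) {
  tibble(auc = x$auc, n_folds = x$n_folds,
         mean_rank = mean(x$folds$rank),
         median_rank = stats::median(x$folds$rank),
         prop_converged = mean(x$folds$converged),
         alpha = x$alpha)
}

#' Top unobserved candidates for one disease
#'
#' Ranks the lncRNAs not yet known to associate with a disease by predicted
#' score (the operation behind per-disease candidate tables). Ties are
#' broken by lncRNA identifier so the output is fully deterministic.
#'
#' @param scores A prediction tibble from [lnc_predict()] (columns
#'   `disease`, `lncrna`, `score`, `known`).
#' @param disease Disease identifier.
#' @param k Number of candidates to return; if larger than the candidate
#'   pool the full pool is returned with a warning.
#' @return A tibble of `disease`, `lncrna`, `score`, `rank`.
#' @export
top_candidates <- function(scores, disease, k = 10) {
  stopifnot(is.data.frame(scores),
            all(c("disease", "lncrna", "score", "known") %in% names(scores)),
            k >= 1)
  if (!disease %in% scores$disease) {
    abort(paste0("unknown disease identifier: ", disease))
  }
  cand <- scores[scores$disease == disease & scores$known == 0, ]
  cand <- cand[order(-cand$score, cand$lncrna, method = "radix"), ]
  if (k > nrow(cand)) {
    warn(paste0("only ", nrow(cand), " candidate(s) available for ", disease))
    k <- nrow(cand)
  }
  out <- utils::head(cand[, c("disease", "lncrna", "score")], k)
  out$rank <- seq_len(nrow(out))
  as_tibble(out)
}

#' LOOCV AUC as a function of the walk parameter alpha
#'
#' Reruns the full leave-one-out evaluation for each value of `alpha` and
#' tabulates the AUC, the standard way of choosing the restart weight.
#'
#' @param associations,expression,config As in [lnc_loocv()].
#' @param alphas Numeric vector of alpha values in `[0, 1]`.
#' @return A tibble of class `lnc_sweep` with columns `alpha`, `auc`; the
#'   best alpha is attached as attribute `best_alpha`.
#' @export
lnc_alpha_sweep <- function(associations, expression = NULL,
                            alphas = seq(0.1, 0.9, by = 0.1),
                            config = lnc_config()) {
  stopifnot(length(alphas) >= 1, all(alphas >= 0 & alphas <= 1))
  auc <- vapply(alphas, function(al) {
    lnc_loocv(associations, expression, config, alpha = al)$auc
  }, numeric(1))
  out <- tibble(alpha = alphas, auc = auc)
  structure(out, class = c("lnc_sweep", class(tibble())),
            best_alpha = alphas[which.max(auc)])
}
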