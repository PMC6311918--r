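# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# Normalized Mann-Whitney U by explicit pairwise counting (half credit for
# ties); the reference for every ROC/AUC computation.
mw_auc <- function(pos, neg) {
  wins <- 0
  for (p in pos) wins <- wins + sum(p > neg) + 0.5 * sum(p == neg)
  wins / (length(pos) * length(neg))
}

# Direct linear solve of the walk's fixed point
#   RT = (alpha/2) (RT LL + LD RT) + (1 - alpha) Rt0
# through the vectorized system
#   (I - (alpha/2) (LL' (x) I + I (x) LD)) vec(RT) = (1 - alpha) vec(Rt0).
solve_fixed_point <- function(ll, ld, rt0, alpha) {
  nd <- nrow(rt0)
  nl <- ncol(rt0)
  m <- diag(nd * nl) -
    (alpha / 2) * (kronecker(t(ll), diag(nd)) + kronecker(diag(nl), ld))
  matrix(solve(m, (1 - alpha) * c(rt0)), nd, nl,
         dimnames = dimnames(rt0))
}

# Random strictly positive symmetric similarity with unit diagonal.
random_similarity <- function(n, lo = 0.05) {
  s <- matrix(runif(n * n, lo, 1), n)
  s <- (s + t(s)) / 2
  diag(s) <- 1
  s
}

# Random binary association matrix with at least one association.
random_assoc <- function(nd, nl, p = 0.4) {
  repeat {
    a <- matrix(rbinom(nd * nl, 1, p), nd, nl,
                dimnames = list(paste0("D", seq_len(nd)),
                                paste0("L", seq_len(nl))))
    if (sum(a) >= 1) return(a * 1.0)
  }
}

# Small deterministic toy network shared by several tests: two diseases
# linked to overlapping lncRNA sets.
toy_assoc <- function() {
  as_assoc_matrix(data.frame(
    disease = c("D1", "D1", "D2", "D2", "D3"),
    lncrna = c("L1", "L2", "L2", "L3", "L3")
  ))
}
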