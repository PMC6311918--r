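test_that("roc_auc matches hand-counted examples", {
  expect_equal(roc_auc(0.9, 0.1)$auc, 1)
  expect_equal(roc_auc(0.5, 0.5)$auc, 0.5)
  # pairwise wins 3>2, 3>0, 1>0; loss 1<2 -> 3/4
  expect_equal(roc_auc(c(3, 1), c(2, 0))$auc, 0.75)
  expect_error(roc_auc(numeric(0), 1), "nonempty")

  r <- roc_auc(c(3, 1), c(2, 0))$roc_points
  expect_equal(r$fpr[1], 0)
  expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[nrow(r)], 1)
  expect_equal(r$tpr[nrow(r)], 1)
  expect_false(is.unsorted(r$fpr))
})

test_that("roc_auc equals brute-force Mann-Whitney counting with ties", {
  withr::with_seed(12, {
    for (r in 1:200) {
      np <- sample(1:25, 1); nn <- sample(1:25, 1)
      # coarse grid forces plenty of exact ties
      pos <- sample(seq(0, 1, by = 0.2), np, replace = TRUE)
      neg <- sample(seq(0, 1, by = 0.2), nn, replace = TRUE)
      expect_equal(roc_auc(pos, neg)$auc, mw_auc(pos, neg), tolerance = 1e-12)
    }
  })
})

test_that("LOOCV recovers a held-out association backed by a profile twin", {
  # L1 and L2 share an identical interaction profile on every other disease,
  # and L2 is known to associate with D1: after withholding (D1, L1) the
  # kernel sees the twins at similarity 1 and the walk must rank the held-out
  # pair first among all candidates.
  a <- as_assoc_matrix(data.frame(
    disease = c("D1", "D1", "D2", "D2", "D3", "D3", "D4"),
    lncrna = c("L1", "L2", "L1", "L2", "L1", "L2", "L3")
  ))
  a_mod <- a; a_mod["D1", "L1"] <- 0
  kl_mod <- gip_kernel(a_mod, "lncrna")
  expect_lt(kl_mod["L1", "L2"], 1)   # twin-ness is broken during the fold...
  cv <- lnc_loocv(a)
  fold <- cv$folds[cv$folds$disease == "D1" & cv$folds$lncrna == "L1", ]
  expect_equal(fold$rank, 1)         # ...but the walk still ranks it first
  expect_equal(cv$n_folds, sum(a))
})

test_that("per-fold similarities are rebuilt from the modified matrix", {
  a <- toy_assoc()
  kl_full <- gip_kernel(a, "lncrna")
  seen <- list()
  probe <- function(a_mod) {
    seen[[length(seen) + 1]] <<- gip_kernel(a_mod, "lncrna")
    run_birw(a_mod, normalize_lncrna(gip_kernel(a_mod, "lncrna")),
             normalize_disease(logistic_disease_similarity(gip_kernel(a_mod, "disease"))),
             lnc_config())
  }
  lnc_loocv(a, scorer = probe)
  for (k in seen) expect_gt(max(abs(k - kl_full)), 0)
})

test_that("random scores give chance-level AUC, a perfect scorer gives 1", {
  sim <- simulate_lnc_network(nd = 30, nl = 24, n_blocks = 2, p_in = 0.6,
                              p_out = 0.05, expr_coverage = 0, seed = 13)
  rng <- new.env(); rng$i <- 0
  random_scorer <- function(a_mod) {
    rng$i <- rng$i + 1
    withr::with_seed(1000 + rng$i, matrix(runif(length(a_mod)), nrow(a_mod)))
  }
  cv_rand <- lnc_loocv(sim$associations, scorer = random_scorer)
  expect_gte(cv_rand$n_folds, 200)
  expect_lt(abs(cv_rand$auc - 0.5), 0.05)

  perfect_scorer <- function(a_mod) {
    s <- matrix(0, nrow(a_mod), ncol(a_mod), dimnames = dimnames(a_mod))
    s[sim$associations == 1] <- 1   # held-out pair always at the max score
    s
  }
  cv_perf <- lnc_loocv(sim$associations, scorer = perfect_scorer)
  expect_equal(cv_perf$auc, 1, tolerance = 1e-9)
})

test_that("LOOCV AUC is invariant under identifier relabeling", {
  withr::with_seed(14, a <- random_assoc(6, 5, p = 0.4))
  cv1 <- lnc_loocv(a)
  b <- a
  rownames(b) <- paste0("dis-", rownames(a))
  colnames(b) <- paste0("rna-", colnames(a))
  cv2 <- lnc_loocv(b)
  expect_equal(cv2$auc, cv1$auc, tolerance = 1e-12)
  expect_equal(cv2$folds$rank, cv1$folds$rank, tolerance = 1e-12)
})

test_that("top candidate ranking excludes known pairs and breaks ties by id", {
  scores <- tibble::tibble(
    disease = rep("D1", 4),
    lncrna = c("Lb", "La", "Lc", "Ld"),
    score = c(0.2, 0.2, 0.9, 0.5),
    known = c(0L, 0L, 1L, 0L)
  )
  top <- top_candidates(scores, "D1", k = 2)
  expect_equal(top$lncrna, c("Ld", "La"))   # Lc is known; La beats Lb by id
  expect_equal(top$rank, 1:2)
  expect_warning(full <- top_candidates(scores, "D1", k = 10), "3 candidate")
  expect_equal(nrow(full), 3L)
  expect_error(top_candidates(scores, "D9"), "unknown disease")

  ties <- tibble::tibble(disease = "D1", lncrna = c("Lz", "La"),
                         score = c(0.5, 0.5), known = c(0L, 0L))
  expect_equal(top_candidates(ties, "D1", k = 2)$lncrna, c("La", "Lz"))
})

test_that("alpha sweep tabulates one AUC per alpha, deterministically", {
  sim <- simulate_lnc_network(nd = 10, nl = 8, n_blocks = 2, p_in = 0.7,
                              p_out = 0.05, expr_coverage = 0.5, seed = 15)
  sw <- lnc_alpha_sweep(sim$associations, sim$expression, alphas = c(0.2, 0.8))
  expect_equal(nrow(sw), 2L)
  expect_true(all(sw$auc >= 0 & sw$auc <= 1))
  expect_true(attr(sw, "best_alpha") %in% sw$alpha)
  sw2 <- lnc_alpha_sweep(sim$associations, sim$expression, alphas = c(0.2, 0.8))
  expect_identical(as.data.frame(sw), as.data.frame(sw2))

  # restart-only scoring ranks by the seed matrix alone
  sw0 <- lnc_alpha_sweep(sim$associations, alphas = 0)
  rt0_scorer <- function(a_mod) init_scores(a_mod)
  cv0 <- lnc_loocv(sim$associations, scorer = rt0_scorer)
  expect_equal(sw0$auc, cv0$auc, tolerance = 1e-12)
})
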