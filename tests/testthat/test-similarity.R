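test_that("interaction-profile kernel matches hand evaluation", {
  a <- as_assoc_matrix(diag(2))
  kl <- gip_kernel(a, "lncrna")
  # mean squared column norm is 1, so the bandwidth is 1 and the two
  # orthogonal unit profiles sit at squared distance 2
  expect_equal(kl[1, 2], exp(-2), tolerance = 1e-12)
  expect_equal(diag(kl), c(L1 = 1, L2 = 1))
  kd <- gip_kernel(a, "disease")
  expect_equal(kd[1, 2], exp(-2), tolerance = 1e-12)

  expect_error(gip_kernel(matrix(0, 2, 2)), "bandwidth")

  # bandwidth scaling: doubling gamma_prime squares each off-diagonal entry
  withr::with_seed(1, a2 <- random_assoc(4, 5))
  k1 <- gip_kernel(a2, "lncrna", gamma_prime = 1)
  k2 <- gip_kernel(a2, "lncrna", gamma_prime = 2)
  off <- upper.tri(k1)
  expect_equal(k2[off], k1[off]^2, tolerance = 1e-12)
})

test_that("kernel entries decrease with Hamming distance between profiles", {
  # all 2^4 binary profiles of length 4 as lncRNA columns; a single shared
  # bandwidth, so ordering by kernel must invert ordering by distance
  profs <- as.matrix(expand.grid(rep(list(0:1), 4)))
  a <- t(profs)
  dimnames(a) <- list(paste0("D", 1:4), paste0("L", seq_len(nrow(profs))))
  k <- gip_kernel(a, "lncrna")
  ham <- as.matrix(stats::dist(profs, method = "manhattan"))
  for (h in 1:3) {
    hi <- k[ham == h]
    lo <- k[ham == h + 1]
    expect_true(min(hi) > max(lo))
  }
})

test_that("kernel is unchanged by permutation of the non-profile axis", {
  withr::with_seed(2, a <- random_assoc(5, 4))
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(gip_kernel(a[perm, ], "lncrna"), gip_kernel(a, "lncrna"),
               tolerance = 1e-14)
})

test_that("Spearman similarity uses average ranks, zeroes outside L1", {
  ex <- rbind(L1 = c(1, 2, 3), L2 = c(3, 2, 1))
  s <- spearman_similarity(ex, c("L1", "L2", "L3"))
  expect_equal(s["L1", "L2"], -1)
  expect_equal(diag(s), c(L1 = 1, L2 = 1, L3 = 0))
  expect_equal(s["L1", "L3"], 0)
  expect_equal(s, t(s))

  # explicit rank-difference formula: 1 - 6*4/(4*15) = 0.6
  ex2 <- rbind(La = c(1, 2, 3, 4), Lb = c(2, 1, 4, 3))
  s2 <- spearman_similarity(ex2, c("La", "Lb"))
  expect_equal(s2["La", "Lb"], 0.6, tolerance = 1e-12)

  # constant profile carries no rank information
  ex3 <- rbind(La = c(1, 1, 1), Lb = c(1, 2, 3))
  s3 <- spearman_similarity(ex3, c("La", "Lb"))
  expect_equal(s3["La", "Lb"], 0)
  expect_equal(s3["La", "La"], 1)

  # no expression at all is legal
  expect_equal(spearman_similarity(NULL, c("L1", "L2")),
               matrix(0, 2, 2, dimnames = list(c("L1", "L2"), c("L1", "L2"))))
})

test_that("similarity fusion weights expression only inside L1", {
  spc <- matrix(c(1, 0.6, 0.6, 1), 2, dimnames = list(c("L1", "L2"), c("L1", "L2")))
  kl <- matrix(c(1, 0.4, 0.4, 1), 2, dimnames = dimnames(spc))
  sl <- combine_lncrna_similarity(spc, kl, c(TRUE, TRUE), ew = 0.5)
  expect_equal(sl[1, 2], 0.5)

  sl2 <- combine_lncrna_similarity(spc, kl, c(TRUE, FALSE), ew = 0.5)
  expect_equal(sl2[1, 2], 0.4)  # pair leaves L1: kernel only

  expect_identical(combine_lncrna_similarity(spc, kl, c(TRUE, TRUE), ew = 0), kl)
  expect_equal(combine_lncrna_similarity(spc, kl, c(TRUE, TRUE), ew = 1), spc)
  expect_error(combine_lncrna_similarity(spc, kl[1, 1, drop = FALSE],
                                         TRUE, 0.5), "dimensions")
})

test_that("logistic disease transform matches direct evaluation and is monotone", {
  sd0 <- logistic_disease_similarity(matrix(0, 1, 1))
  expect_equal(sd0[1, 1], 1e-4, tolerance = 1e-12)
  sd1 <- logistic_disease_similarity(matrix(1, 1, 1))
  expect_equal(sd1[1, 1], 1 / (1 + 9999 * exp(-15)), tolerance = 1e-12)
  expect_equal(round(sd1[1, 1], 5), 0.99695)

  grid <- seq(0, 1, by = 0.01)
  vals <- logistic_disease_similarity(matrix(grid, 1))
  expect_true(all(diff(c(vals)) > 0))
  expect_true(all(vals > 1e-4 - 1e-15 & vals < 1))
})

test_that("all similarity constructions are symmetric", {
  withr::with_seed(3, {
    a <- random_assoc(6, 7)
    expr <- matrix(rnorm(4 * 5), 4, dimnames = list(colnames(a)[1:4], NULL))
  })
  kl <- gip_kernel(a, "lncrna")
  kd <- gip_kernel(a, "disease")
  spc <- spearman_similarity(expr, colnames(a))
  sl <- combine_lncrna_similarity(spc, kl, colnames(a) %in% rownames(expr))
  sd <- logistic_disease_similarity(kd)
  for (m in list(kl, kd, spc, sl, sd)) {
    expect_lt(max(abs(m - t(m))), 1e-12)
  }
  expect_true(all(kl > 0 & kl <= 1))
  expect_true(all(sd > 0 & sd < 1))
})
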