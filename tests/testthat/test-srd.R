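test_that("consensus fusion takes row maxima for actives, minima for inactives", {
  expect_equal(fuse_reference(rbind(c(0.2, 0.8, 0.5)), TRUE), 0.8)
  expect_equal(fuse_reference(rbind(c(0.3, 0.6)), FALSE), 0.3)
  M <- cbind(only = c(0.1, 0.9, 0.4))
  expect_equal(fuse_reference(M, c(TRUE, FALSE, TRUE)), M[, 1],
               ignore_attr = TRUE)
  sm <- data.frame(ligand_id = c("a", "b"), active = c(TRUE, FALSE),
                   SM = c(0.2, 0.7), JT = c(0.5, 0.1))
  expect_equal(fuse_reference(sm), c(0.5, 0.1))
  expect_error(fuse_reference(M, c(TRUE, NA, FALSE)), "complete")
})

test_that("ranking is ascending with averaged ties", {
  expect_equal(rank_vector(c(10, 30, 20)), c(1, 3, 2))
  expect_equal(rank_vector(c(1, 1)), c(1.5, 1.5))
  expect_equal(rank_vector(sort(runif(8))), 1:8, ignore_attr = TRUE)
  expect_error(rank_vector(numeric(0)), "empty")
})

test_that("SRD values and their maximum match exhaustive-permutation oracles", {
  expect_equal(srd_value(1:4, 1:4), 0)
  expect_equal(srd_value(4:1, 1:4), 8)
  expect_equal(srd_value(c(2, 1, 4, 3), 1:4), 4)
  expect_error(srd_value(1:3, 1:4), "length")

  # exhaustive check for all n <= 7: brute-force footrule over all
  # permutations reproduces srd_value, and its maximum equals max_srd(n)
  for (n in 2:7) {
    P <- perms_recursive(n)
    ref <- seq_len(n)
    vals <- apply(P, 1L, function(pp) srd_value(pp, ref))
    oracle <- apply(P, 1L, function(pp) brute_srd(pp, ref))
    expect_equal(vals, oracle)
    expect_equal(max(oracle), max_srd(n))
  }
  expect_equal(max_srd(4), 8)
  expect_equal(max_srd(5), 12)
  expect_equal(max_srd(1), 0)
  expect_error(max_srd(0), "positive")
})

test_that("normalization maps SRD onto [0, 100] percent", {
  expect_equal(normalize_srd(4, 4), 50)
  expect_equal(normalize_srd(0, 9), 0)
  expect_equal(normalize_srd(max_srd(11), 11), 100)
  expect_equal(normalize_srd(0, 1), 0)
  expect_error(normalize_srd(9, 4), "exceeds")
})

test_that("SRD is symmetric and rank-invariant", {
  set.seed(89)
  for (i in 1:30) {
    n <- sample(3:40, 1)
    x <- rank_vector(runif(n)); y <- rank_vector(runif(n))
    expect_equal(srd_value(x, y), srd_value(y, x))
  }
  # adding a constant to a column leaves its SRD unchanged
  M <- matrix(runif(40), 10, 4, dimnames = list(NULL, paste0("m", 1:4)))
  act <- rep(c(TRUE, FALSE), 5)
  base <- srd(M, act, pretreatment = "none", folds = 2, perm_reps = 100, seed = 1)
  M2 <- M; M2[, 2] <- M2[, 2] + 5
  ref <- fuse_reference(M, act); ref2 <- fuse_reference(M2, act)
  # fusion itself may change, so compare at fixed reference
  expect_equal(srd_value(rank_vector(M2[, 2]), rank_vector(ref)),
               srd_value(rank_vector(M[, 2]), rank_vector(ref)))
  # a column equal to the reference after a strictly monotone transform
  # has SRD 0 (tie-free case)
  M3 <- cbind(M, refcol = exp(fuse_reference(M, act)))
  ref3 <- fuse_reference(M3, act)
  expect_equal(srd_value(rank_vector(M3[, "refcol"]), rank_vector(ref3)), 0)
})

test_that("the permutation null distribution is exact for small n", {
  pt <- permutation_test(4)
  expect_equal(pt$type, "exact")
  expect_equal(pt$mean, 5)              # (n^2 - 1)/3
  # support contains even values only
  P <- perms_recursive(4)
  vals <- apply(P, 1L, function(pp) brute_srd(pp, 1:4))
  expect_true(all(vals %% 2 == 0))
  expect_equal(sort(unique(vals)), c(0, 2, 4, 6, 8))
  expect_equal(pt$pvalue(0), 1 / 24)
  expect_equal(pt$pvalue(8), 1)

  pt8 <- permutation_test(8)
  expect_equal(pt8$pvalue(0), 1 / 40320)  # exactly one permutation attains 0
  expect_equal(pt8$mean, (64 - 1) / 3)
  expect_error(permutation_test(1), "at least 2")
})

test_that("the Monte-Carlo null mean converges to (n^2 - 1)/3", {
  n <- 50L; reps <- 10000L
  pt <- permutation_test(n, reps = reps, seed = 7)
  expect_equal(pt$type, "monte-carlo")
  # standard error of the footrule null at n = 50, estimated by resampling
  set.seed(1)
  draws <- replicate(2000, sum(abs(sample.int(n) - seq_len(n))))
  se <- sd(draws) / sqrt(reps)
  expect_lt(abs(pt$mean - (n^2 - 1) / 3), 3 * se)
  expect_error(permutation_test(50, reps = 50), "reps >= 100")
  # determinism under a fixed seed
  pt2 <- permutation_test(n, reps = 500L, seed = 11)
  pt3 <- permutation_test(n, reps = 500L, seed = 11)
  expect_equal(pt2$mean, pt3$mean)
})

test_that("cross-validation yields k+1 self-contained SRD rounds", {
  set.seed(97)
  M <- matrix(runif(200), 20, 10, dimnames = list(NULL, paste0("m", 1:10)))
  act <- rep(c(TRUE, FALSE), 10)
  cv <- crossvalidate_srd(M, act, k = 5, seed = 3)
  expect_equal(dim(cv), c(10L, 6L))
  expect_equal(colnames(cv), c("1", "2", "3", "4", "5", "All"))
  # same seed -> identical folds and values
  cv2 <- crossvalidate_srd(M, act, k = 5, seed = 3)
  expect_identical(cv, cv2)
  # identical columns -> all rounds 0 for both
  M2 <- cbind(a = M[, 1], b = M[, 1])
  cv3 <- crossvalidate_srd(M2, act, k = 5, seed = 3)
  expect_equal(unname(as.vector(cv3)), rep(0, 12))
  expect_error(crossvalidate_srd(M, act, k = 1), "fold count")
  expect_error(crossvalidate_srd(M, act, k = 21), "fold count")
  # each fold round really drops that fold's rows
  folds <- attr(cv, "folds")
  expect_equal(sort(unique(folds)), 1:5)
  expect_true(max(table(folds)) - min(table(folds)) <= 1)
})

test_that("the srd() fit returns a classed object with working methods", {
  set.seed(101)
  g <- generate_dataset(synth_config(n_residues = 8, n_actives = 15,
                                     n_decoys = 15, seed = 6))
  sm <- suppressMessages(similarity_matrix(g$dataset, g$reference,
                                           c("SM", "JT", "BUB", "RR", "Phi")))
  fit <- srd(sm, pretreatment = "auto", folds = 5, perm_reps = 2000, seed = 4)
  expect_s3_class(fit, "srd")
  expect_named(coef(fit), c("SM", "JT", "BUB", "RR", "Phi"))
  expect_true(all(coef(fit) >= 0 & coef(fit) <= 100))
  s <- summary(fit)
  expect_s3_class(s, "summary.srd")
  expect_equal(nrow(s$table), 5L)
  expect_true(all(s$table$p_random >= 0 & s$table$p_random <= 1))
  expect_output(print(fit), "Sum of ranking differences")
  expect_output(print(s), "Random-ranking null")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
  expect_error(srd(sm[sm$active, ]), "at least one active")
})
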