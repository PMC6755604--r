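test_that("confusion counts match direct counting", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(cc[c("a", "b", "c", "d", "p")],
               list(a = 1, b = 1, c = 1, d = 1, p = 4), ignore_attr = TRUE)
  x <- c(1, 0, 1)
  cc2 <- confusion_counts(x, x)
  expect_equal(cc2$b + cc2$c, 0)
  cc3 <- confusion_counts(c(0, 0, 0), c(0, 0, 0))
  expect_equal(c(cc3$a, cc3$d, cc3$p), c(0, 3, 3))
  expect_error(confusion_counts(c(1, 0), c(1, 0, 1)), "length mismatch")
  expect_error(confusion_counts(numeric(0), numeric(0)), "empty")
  expect_error(confusion_counts(c(1, 2), c(1, 0)), "0 or 1")
  # random vectors against an independent loop-based recount
  set.seed(31)
  for (i in 1:25) {
    p <- sample(1:64, 1)
    x <- rbinom(p, 1, 0.5); y <- rbinom(p, 1, 0.5)
    expect_equal(unclass(confusion_counts(x, y))[1:5], brute_counts(x, y))
  }
})

test_that("worked examples of the defining formulas hold", {
  expect_equal(raw_similarity("SM", list(a = 2, b = 1, c = 0, d = 1, p = 4)), 0.75)
  expect_equal(raw_similarity("JT", list(a = 2, b = 1, c = 1, d = 0, p = 4)), 0.5)
  expect_equal(raw_similarity("BUB", list(a = 4, b = 2, c = 1, d = 1, p = 8)),
               6 / 9)
})

test_that("affine rescaling maps measure ranges onto [0, 1]", {
  # correlation-type endpoint mapping with alpha = 1, beta = 2
  expect_equal(scale_similarity(-1, "Phi"), 0)
  expect_equal(scale_similarity(1, "Phi"), 1)
  # identity scaling for measures already in [0, 1]
  expect_equal(scale_similarity(0.5, "JT"), 0.5)
  # values outside [0, 1] beyond tolerance are an internal error
  expect_error(scale_similarity(1.5, "JT"), "outside")
  # within-tolerance overshoot is clamped
  expect_equal(scale_similarity(1 + 1e-12, "JT"), 1)
})

test_that("the catalog has 44 measures with the documented classes", {
  lm <- list_measures()
  expect_equal(nrow(lm), 44L)
  expect_equal(anyDuplicated(lm$abbrev), 0L)
  named <- c("SM", "JT", "BUB", "RT", "SS2", "SS4", "CT1", "CT2", "CT3",
             "AC", "RR", "Mic", "Mou", "Yu1", "HD", "Den", "dis", "Phi",
             "Coh", "Pe1", "Pe2", "MP", "HL")
  expect_true(all(named %in% lm$abbrev))
  expect_true(all(lm$symmetricity %in% c("S", "I", "A", "Q")))
  expect_true(all(lm$metricity %in% c("M", "N")))
  expect_equal(get_measure("JT")$symmetricity, "A")
  expect_equal(get_measure("JT")$metricity, "M")
  expect_equal(get_measure("SM")$symmetricity, "S")
  # the coefficients the study singles out as symmetric or correlation-based
  sq <- lm$symmetricity[match(c("Mic", "HD", "Den", "dis", "SS4", "Phi",
                                "Coh", "Pe1", "Pe2", "MP", "HL"), lm$abbrev)]
  expect_true(all(sq %in% c("S", "Q")))
  expect_error(get_measure("XYZ"), "unknown")
})

test_that("every scaled measure stays in [0, 1] on randomized confusion tables", {
  set.seed(4711)
  abbrevs <- list_measures()$abbrev
  n <- 10000L
  p <- sample(1:512, n, replace = TRUE)
  w <- matrix(runif(4 * n), 4L)
  counts <- vapply(seq_len(n), function(i)
    as.vector(stats::rmultinom(1L, p[i], w[, i])), numeric(4L))
  # group by p so alpha/beta (which may depend on p) are evaluated per table
  for (ab in abbrevs) {
    vals <- vapply(seq_len(n), function(i)
      similarity(ab, list(a = counts[1L, i], b = counts[2L, i],
                          c = counts[3L, i], d = counts[4L, i], p = p[i])),
      numeric(1L))
    expect_true(all(vals >= 0 & vals <= 1), label = paste(ab, "in [0,1]"))
  }
})

test_that("symmetricity classes obey their defining invariances", {
  lm <- list_measures()
  set.seed(53)
  for (i in 1:100) {
    p <- sample(4:128, 1)
    x <- rbinom(p, 1, runif(1, 0.1, 0.9))
    y <- rbinom(p, 1, runif(1, 0.1, 0.9))
    cc <- confusion_counts(x, y)
    cc_compl <- confusion_counts(1 - x, 1 - y)  # a<->d, b<->c
    cc_swap <- confusion_counts(y, x)           # b<->c
    for (k in seq_len(nrow(lm))) {
      ab <- lm$abbrev[k]
      v <- similarity(ab, cc)
      if (lm$symmetricity[k] == "S") {
        expect_equal(similarity(ab, cc_compl), v, tolerance = 1e-9)
      }
      if (lm$exchange_symmetric[k]) {
        expect_equal(similarity(ab, cc_swap), v, tolerance = 1e-9)
      }
      if (lm$symmetricity[k] == "A") {
        # changing d alone leaves the raw value untouched
        s0 <- raw_similarity(ab, cc)
        s1 <- raw_similarity(ab, list(a = cc$a, b = cc$b, c = cc$c,
                                      d = cc$d + 11, p = cc$p + 11))
        if (!is.nan(s0)) expect_equal(s1, s0, tolerance = 1e-12)
      }
    }
  }
  # the directional Peirce/Cole pairs map onto each other under exchange
  cc <- list(a = 5, b = 3, c = 1, d = 7, p = 16)
  ccx <- list(a = 5, b = 1, c = 3, d = 7, p = 16)
  expect_equal(similarity("Pe1", ccx), similarity("Pe2", cc))
  expect_equal(similarity("Co1", ccx), similarity("Co2", cc))
})

test_that("1 - s' is a metric for JT, SM and RT on random triples", {
  set.seed(59)
  for (i in 1:1000) {
    p <- sample(5:64, 1)
    x <- rbinom(p, 1, 0.4); y <- rbinom(p, 1, 0.4); z <- rbinom(p, 1, 0.4)
    for (ab in c("JT", "SM", "RT")) {
      dxy <- 1 - similarity(ab, confusion_counts(x, y))
      dxz <- 1 - similarity(ab, confusion_counts(x, z))
      dzy <- 1 - similarity(ab, confusion_counts(z, y))
      if (dxy > dxz + dzy + 1e-9) {
        fail(sprintf("triangle inequality violated for %s", ab))
      }
    }
  }
  succeed()
})

test_that("similarity_matrix has one scaled value per ligand and measure", {
  set.seed(61)
  g <- generate_dataset(synth_config(n_residues = 8, n_actives = 6,
                                     n_decoys = 6, seed = 8))
  sm <- suppressMessages(similarity_matrix(g$dataset, g$reference))
  expect_equal(dim(sm), c(12L, 46L))
  expect_equal(names(sm)[1:2], c("ligand_id", "active"))
  vals <- as.matrix(sm[, -(1:2)])
  expect_true(all(vals >= 0 & vals <= 1))

  # a query identical to the reference scores 1 on every measure whose
  # formula attains its maximum at identity
  d2 <- g$dataset
  d2$bits[1L, ] <- g$reference$bits
  sm2 <- suppressMessages(similarity_matrix(d2, g$reference))
  lm <- list_measures()
  for (ab in lm$abbrev[lm$max_at_identity]) {
    expect_equal(sm2[[ab]][1L], 1, tolerance = 1e-12)
  }

  # JT column equals a brute-force per-ligand recount
  jt <- vapply(seq_len(nrow(d2$bits)), function(i) {
    cnt <- brute_counts(d2$bits[i, ], g$reference$bits)
    if (cnt$b + cnt$c == 0) 1 else cnt$a / (cnt$a + cnt$b + cnt$c)
  }, numeric(1L))
  expect_equal(sm2$JT, jt, tolerance = 1e-12)

  # layout mismatch is an error
  expect_error(similarity_matrix(g$dataset, g$reference$bits[-1]), "layout")
})
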