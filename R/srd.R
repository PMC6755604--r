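#' Consensus reference fusion for SRD
#'
#' In a virtual-screening setting the ideal similarity measure scores every
#' active ligand as high as possible and every decoy as low as possible.
#' The hypothetical ideal reference column is therefore fused from the
#' (pretreated) similarity matrix row-wise: for an active ligand the row
#' maximum across measures, for an inactive one the row minimum.
#'
#' @param sim similarity matrix: data.frame from
#'   \code{\link{similarity_matrix}} (pretreated) or a numeric matrix.
#' @param active logical activity per row; taken from the data.frame's
#'   \code{active} column when omitted.
#' @return Numeric reference vector, one fused value per ligand.
#' @examples
#' fuse_reference(rbind(c(0.2, 0.8, 0.5)), active = TRUE)   # 0.8
#' fuse_reference(rbind(c(0.3, 0.6)), active = FALSE)       # 0.3
#' @export
fuse_reference <- function(sim, active = NULL) {
  if (is.data.frame(sim)) {
    if (is.null(active)) active <- sim$active
    sim <- as.matrix(sim[, measure_columns(sim), drop = FALSE])
  }
  if (is.null(active)) stop("activity labels are required for reference fusion")
  active <- as.logical(active)
  if (length(active) != nrow(sim) || anyNA(active)) {
    stop("'active' must be a complete logical vector, one entry per row")
  }
  if (nrow(sim) == 0L) stop("empty similarity matrix")
  hi <- do.call(pmax, as.data.frame(sim))
  lo <- do.call(pmin, as.data.frame(sim))
  ifelse(active, hi, lo)
}

#' Rank a vector ascending with averaged ties
#'
#' Objects are ranked in increasing order of magnitude; tied values receive
#' the average of the ranks they span, as in the rank-transformation
#' pretreatment.
#'
#' @param values numeric vector.
#' @return Numeric rank vector.
#' @export
rank_vector <- function(values) {
  if (length(values) == 0L) stop("cannot rank an empty vector")
  rank(values, ties.method = "average")
}

#' Sum of ranking differences
#'
#' The SRD value of a method against a reference is the Manhattan distance
#' between the two rank vectors: the sum over objects of the absolute
#' difference between the method's rank and the reference rank (the
#' Spearman footrule when there are no ties). \code{max_srd} gives the
#' theoretical maximum of this sum for n objects (attained by the reversed
#' ranking): n^2/2 for even n, (n^2 - 1)/2 for odd n. \code{normalize_srd}
#' expresses an SRD value as a percentage of that maximum.
#'
#' @param column_ranks,reference_ranks rank vectors of equal length.
#' @param n number of ranked objects.
#' @param srd_raw raw SRD value.
#' @return \code{srd_value}: non-negative raw SRD; \code{max_srd}: the
#'   maximum; \code{normalize_srd}: percentage in [0, 100] (0 for n = 1).
#' @examples
#' srd_value(c(4, 3, 2, 1), c(1, 2, 3, 4))  # 8 = max_srd(4)
#' normalize_srd(4, 4)                      # 50
#' @export
srd_value <- function(column_ranks, reference_ranks) {
  if (length(column_ranks) != length(reference_ranks)) {
    stop("rank vectors differ in length")
  }
  sum(abs(column_ranks - reference_ranks))
}

#' @rdname srd_value
#' @export
max_srd <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 1) stop("n must be a positive count")
  n <- as.integer(n)
  if (n %% 2L == 0L) n^2 / 2 else (n^2 - 1) / 2
}

#' @rdname srd_value
#' @export
normalize_srd <- function(srd_raw, n) {
  if (n == 1L) return(0)
  mx <- max_srd(n)
  if (srd_raw > mx + 1e-9) {
    stop(sprintf("SRD value %g exceeds the theoretical maximum %g for n = %d",
                 srd_raw, mx, n))
  }
  100 * srd_raw / mx
}

# all permutations of 1..n as an (n! x n) matrix, built iteratively
permutations_matrix <- function(n) {
  P <- matrix(1L, 1L, 1L)
  if (n == 1L) return(P)
  for (k in 2L:n) {
    P <- do.call(rbind, lapply(seq_len(k), function(pos) {
      # insert k at position pos of each length-(k-1) permutation
      left <- P[, seq_len(pos - 1L), drop = FALSE]
      right <- if (pos <= k - 1L) P[, pos:(k - 1L), drop = FALSE]
               else P[, 0L, drop = FALSE]
      cbind(left, k, right, deparse.level = 0L)
    }))
  }
  P
}

#' Permutation (randomization) test for SRD
#'
#' Validates SRD values against the null hypothesis of random ranking: the
#' distribution of the SRD between a random permutation of n objects and a
#' fixed reference ranking. For n <= \code{exact_limit} (default 8) the
#' distribution is exact, enumerating all n! permutations; for larger n a
#' seeded Monte-Carlo sample of \code{reps} random permutations is used.
#' The null mean is (n^2 - 1)/3.
#'
#' @param n number of ranked objects (>= 2).
#' @param reps Monte-Carlo sample size (>= 100; ignored for exact n).
#' @param seed optional integer seed for the Monte-Carlo draw.
#' @param exact_limit largest n for which the full enumeration is used.
#' @return Object of class \code{"srd_perm"}: list with \code{n},
#'   \code{type} ("exact" or "monte-carlo"), \code{mean}, \code{q5},
#'   \code{q95} (5th/95th percentiles of the null SRD distribution, raw
#'   scale), and \code{pvalue(observed)} giving P(SRD <= observed) under
#'   the null — the probability that a random ranking comes at least this
#'   close to the reference.
#' @examples
#' pt <- permutation_test(4)
#' pt$mean           # 5 = (16 - 1)/3
#' pt$pvalue(0)      # 1/24
#' @export
permutation_test <- function(n, reps = 10000L, seed = NULL, exact_limit = 8L) {
  if (length(n) != 1L || is.na(n) || n < 2) stop("n must be at least 2")
  n <- as.integer(n)
  ref <- seq_len(n)
  if (n <= exact_limit) {
    P <- permutations_matrix(n)
    vals <- rowSums(abs(P - rep(ref, each = nrow(P))))
    type <- "exact"
  } else {
    if (reps < 100L) stop("Monte-Carlo permutation test needs reps >= 100")
    if (!is.null(seed)) {
      old <- get_rng_state()
      on.exit(restore_rng_state(old))
      set.seed(seed)
    }
    vals <- vapply(seq_len(reps), function(i) sum(abs(sample.int(n) - ref)),
                   numeric(1L))
    type <- "monte-carlo"
  }
  vals <- sort(vals)
  structure(list(
    n = n, type = type, reps = if (type == "monte-carlo") reps else length(vals),
    mean = mean(vals),
    q5 = unname(stats::quantile(vals, 0.05, type = 1L)),
    q95 = unname(stats::quantile(vals, 0.95, type = 1L)),
    pvalue = function(observed) {
      vapply(observed, function(o) mean(vals <= o + 1e-9), numeric(1L))
    }
  ), class = "srd_perm")
}

#' @export
print.srd_perm <- function(x, ...) {
  cat(sprintf("SRD randomization test (%s, n = %d): null mean %.3f, 5th pct %g, 95th pct %g\n",
              x$type, x$n, x$mean, x$q5, x$q95))
  invisible(x)
}

srd_for_matrix <- function(M, active) {
  ref <- fuse_reference(M, active)
  ref_ranks <- rank_vector(ref)
  n <- nrow(M)
  vapply(colnames(M), function(cl) {
    normalize_srd(srd_value(rank_vector(M[, cl]), ref_ranks), n)
  }, numeric(1L))
}

#' Cross-validated SRD
#'
#' Splits the ligands into k random folds (seeded) and performs one
#' complete, self-contained SRD analysis per round with that fold's rows
#' removed — consensus fusion, ranking and normalization are all recomputed
#' on the reduced matrix — plus a final round ("All") on the full matrix,
#' giving k + 1 normalized SRD values per measure.
#'
#' @param sim pretreated similarity matrix (data.frame or numeric matrix).
#' @param active logical activity per row (taken from the data.frame when
#'   omitted).
#' @param k number of folds (default 5).
#' @param seed optional integer seed for the fold assignment.
#' @return Numeric matrix (measures x rounds) with columns
#'   \code{"1"..."k"} and \code{"All"}; the fold assignment is attached as
#'   attribute \code{"folds"}.
#' @export
crossvalidate_srd <- function(sim, active = NULL, k = 5L, seed = NULL) {
  if (is.data.frame(sim)) {
    if (is.null(active)) active <- sim$active
    M <- as.matrix(sim[, measure_columns(sim), drop = FALSE])
  } else M <- as.matrix(sim)
  n <- nrow(M)
  if (k < 2L || k > n) stop("fold count k must satisfy 2 <= k <= number of rows")
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  perm <- sample.int(n)
  fold_sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  fold_of <- integer(n)
  fold_of[perm] <- rep(seq_len(k), fold_sizes)
  rounds <- c(as.character(seq_len(k)), "All")
  out <- matrix(NA_real_, ncol(M), k + 1L,
                dimnames = list(colnames(M), rounds))
  for (j in seq_len(k)) {
    keep <- fold_of != j
    out[, j] <- srd_for_matrix(M[keep, , drop = FALSE], active[keep])
  }
  out[, k + 1L] <- srd_for_matrix(M, active)
  attr(out, "folds") <- fold_of
  out
}

#' Sum of ranking differences analysis of a similarity matrix
#'
#' Fits the full SRD comparison to a similarity matrix: column-wise
#' pretreatment, consensus reference fusion (row maximum for actives, row
#' minimum for inactives), tie-aware ranking, Manhattan rank distance per
#' measure, normalization to [0, 100] percent, k-fold cross-validation and
#' a permutation (randomization) test of the null hypothesis of random
#' ranking.
#'
#' @param sim similarity matrix: data.frame with \code{ligand_id},
#'   \code{active} and one column per measure (see
#'   \code{\link{similarity_matrix}}), or a numeric matrix plus
#'   \code{active}.
#' @param active logical activity per row (taken from the data.frame when
#'   omitted).
#' @param pretreatment one of \code{"auto"}, \code{"rgs"}, \code{"rank"},
#'   \code{"none"}.
#' @param folds number of cross-validation folds.
#' @param perm_reps Monte-Carlo sample size for the randomization test.
#' @param seed optional integer seed (fold assignment and Monte-Carlo).
#' @return Object of class \code{"srd"}: list with \code{srd_raw} and
#'   \code{srd_norm} (named per measure), \code{cv} (measures x rounds
#'   matrix), \code{perm} (\code{\link{permutation_test}} result),
#'   \code{reference} (fused values), \code{n}, \code{pretreatment},
#'   \code{call}. Methods: \code{print}, \code{summary}, \code{coef}
#'   (normalized SRD values), \code{plot}.
#' @examples
#' g <- generate_dataset(synth_config(n_residues = 8, n_actives = 10,
#'                                    n_decoys = 10, seed = 3))
#' sm <- similarity_matrix(g$dataset, g$reference, c("SM", "JT", "RR"))
#' fit <- srd(sm, pretreatment = "auto", seed = 1)
#' coef(fit)
#' @export
srd <- function(sim, active = NULL, pretreatment = c("auto", "rgs", "rank", "none"),
                folds = 5L, perm_reps = 10000L, seed = NULL) {
  cl <- match.call()
  pretreatment <- match.arg(pretreatment)
  if (is.data.frame(sim)) {
    if (is.null(active)) active <- sim$active
    M <- as.matrix(sim[, measure_columns(sim), drop = FALSE])
  } else M <- as.matrix(sim)
  if (is.null(active)) stop("activity labels are required")
  active <- as.logical(active)
  n <- nrow(M)
  if (!any(active) || all(active)) {
    stop("SRD reference fusion needs at least one active and one inactive ligand")
  }
  Mp <- pretreat(M, pretreatment)
  ref <- fuse_reference(Mp, active)
  ref_ranks <- rank_vector(ref)
  srd_raw <- vapply(colnames(Mp), function(c2)
    srd_value(rank_vector(Mp[, c2]), ref_ranks), numeric(1L))
  srd_norm <- vapply(srd_raw, normalize_srd, numeric(1L), n = n)
  cv <- crossvalidate_srd(Mp, active, k = folds, seed = seed)
  perm <- permutation_test(n, reps = perm_reps, seed = seed)
  structure(list(call = cl, n = n, pretreatment = pretreatment,
                 measures = colnames(Mp), srd_raw = srd_raw,
                 srd_norm = srd_norm, cv = cv, perm = perm,
                 reference = ref, active = active),
            class = "srd")
}

#' @export
print.srd <- function(x, ...) {
  cat("Sum of ranking differences analysis\n")
  cat("  ", x$n, " ligands, ", length(x$measures), " similarity measures, pretreatment: ",
      x$pretreatment, "\n", sep = "")
  ord <- order(x$srd_norm)
  top <- utils::head(ord, 5L)
  cat("  closest to the consensus reference:\n")
  for (i in top) {
    cat(sprintf("    %-4s SRD = %5.2f%%\n", x$measures[i], x$srd_norm[i]))
  }
  cat(sprintf("  random-ranking null mean: %.2f%%\n",
              100 * x$perm$mean / max_srd(x$n)))
  invisible(x)
}

#' @export
coef.srd <- function(object, ...) object$srd_norm

#' @export
summary.srd <- function(object, ...) {
  norm_factor <- max_srd(object$n)
  tab <- data.frame(
    measure = object$measures,
    srd_raw = unname(object$srd_raw),
    srd_norm = unname(object$srd_norm),
    cv_mean = rowMeans(object$cv[, seq_len(ncol(object$cv) - 1L), drop = FALSE]),
    cv_sd = apply(object$cv[, seq_len(ncol(object$cv) - 1L), drop = FALSE], 1L,
                  stats::sd),
    p_random = object$perm$pvalue(unname(object$srd_raw)),
    row.names = NULL
  )
  tab <- tab[order(tab$srd_norm), ]
  structure(list(table = tab, n = object$n,
                 perm_norm = c(mean = 100 * object$perm$mean / norm_factor,
                               q5 = 100 * object$perm$q5 / norm_factor,
                               q95 = 100 * object$perm$q95 / norm_factor),
                 pretreatment = object$pretreatment),
            class = "summary.srd")
}

#' @export
print.summary.srd <- function(x, ...) {
  cat("SRD analysis (", x$n, " ligands, pretreatment: ", x$pretreatment,
      ")\n\n", sep = "")
  print(x$table, digits = 4, row.names = FALSE)
  cat(sprintf("\nRandom-ranking null (normalized): mean %.2f%%, 5th pct %.2f%%, 95th pct %.2f%%\n",
              x$perm_norm["mean"], x$perm_norm["q5"], x$perm_norm["q95"]))
  invisible(x)
}

#' @export
plot.srd <- function(x, ...) {
  ord <- order(x$srd_norm)
  norm_factor <- max_srd(x$n)
  graphics::barplot(x$srd_norm[ord], names.arg = x$measures[ord],
                    las = 2, cex.names = 0.6,
                    ylab = "Normalized SRD [%]",
                    main = "Similarity measures vs. consensus reference", ...)
  graphics::abline(h = 100 * x$perm$mean / norm_factor, lty = 2, col = "red")
  graphics::abline(h = 100 * c(x$perm$q5, x$perm$q95) / norm_factor,
                   lty = 3, col = "red")
  invisible(x)
}
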