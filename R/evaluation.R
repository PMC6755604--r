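#' ROC AUC via the Mann-Whitney statistic
#'
#' The area under the ROC curve equals the probability that a randomly
#' chosen active ligand is scored higher than a randomly chosen inactive
#' one (ties counted half), i.e. the normalized Mann-Whitney U statistic
#' computed from midranks. 0.5 corresponds to random ranking.
#'
#' @param scores numeric score per ligand (higher = more active-like).
#' @param labels logical (or 0/1) activity per ligand; both classes must be
#'   present.
#' @return AUC value in [0, 1].
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.1), c(TRUE, TRUE, FALSE, FALSE))  # 1
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(labels) || anyNA(scores)) {
    stop("scores and labels must be complete vectors of equal length")
  }
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC needs at least one active and one inactive ligand")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

subset_reference <- function(reference, dataset) {
  bits <- if (inherits(reference, "interaction_fp")) reference$bits else reference
  keep <- colnames(dataset$bits)
  missing <- setdiff(keep, names(bits))
  if (length(missing)) {
    stop("reference fingerprint lacks column(s): ",
         paste(utils::head(missing, 3L), collapse = ", "))
  }
  interaction_fp(bits[keep],
                 if (inherits(reference, "interaction_fp")) reference$ligand_id else "ref",
                 if (inherits(reference, "interaction_fp")) reference$active else NA)
}

#' Full factorial evaluation grid
#'
#' Runs the complete comparison protocol over every combination of dataset,
#' bit-selection scheme (ALL/WO1/WO3) and filtering rule (NO/RES/INTS):
#' each combination yields one SRD input matrix (ligands x measures), which
#' is pretreated and analysed by cross-validated SRD, contributing
#' folds + 1 rows per measure to the long result table. With 10 datasets
#' the grid comprises 90 SRD input variants; with all 44 measures and
#' fivefold cross-validation that is 23,760 result rows. ROC AUC is
#' computed per variant and measure on the raw scaled similarities
#' (pretreatment is column-monotone, so AUC is unaffected by it).
#'
#' @param datasets list of \code{\link{fp_dataset}} objects.
#' @param references list of reference fingerprints (full, unfiltered
#'   layout), one per dataset.
#' @param measures measure abbreviations (default: all 44).
#' @param selections bit-selection schemes to include.
#' @param filterings filtering rules to include.
#' @param pretreatment pretreatment method for SRD.
#' @param folds cross-validation folds.
#' @param seed integer seed (fold assignments).
#' @return Object of class \code{"srd_grid"}: list with \code{srd} (long
#'   data.frame: dataset, bit_selection, filtering, measure, symmetricity,
#'   metricity, round, srd_norm), \code{auc} (dataset, bit_selection,
#'   filtering, measure, auc), \code{skipped} (variants emptied by
#'   filtering, normally none), and the configuration.
#' @export
run_grid <- function(datasets, references, measures = NULL,
                     selections = c("ALL", "WO1", "WO3"),
                     filterings = c("NO", "RES", "INTS"),
                     pretreatment = "auto", folds = 5L, seed = 1L) {
  if (inherits(datasets, "fp_dataset")) datasets <- list(datasets)
  if (inherits(references, "interaction_fp")) references <- list(references)
  if (length(datasets) != length(references)) {
    stop("one reference fingerprint per dataset required")
  }
  if (is.null(measures)) measures <- list_measures()$abbrev
  catalog <- list_measures()
  sym <- stats::setNames(catalog$symmetricity, catalog$abbrev)
  met <- stats::setNames(catalog$metricity, catalog$abbrev)

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)

  srd_rows <- list()
  auc_rows <- list()
  skipped <- character(0)
  for (di in seq_along(datasets)) {
    ds <- datasets[[di]]
    for (sel in selections) {
      ds_sel <- select_bits(ds, sel)
      for (flt in filterings) {
        tag <- paste(ds$name, sel, flt, sep = "/")
        ds_v <- tryCatch(apply_filtering(ds_sel, flt), error = function(e) NULL)
        if (is.null(ds_v) || ncol(ds_v$bits) == 0L) {
          warning("variant ", tag, " emptied by filtering; skipped")
          skipped <- c(skipped, tag)
          next
        }
        ref_v <- subset_reference(references[[di]], ds_v)
        sm <- suppressMessages(similarity_matrix(ds_v, ref_v, measures))
        M <- as.matrix(sm[, measures, drop = FALSE])
        cv <- crossvalidate_srd(pretreat(M, pretreatment), sm$active, k = folds)
        srd_rows[[tag]] <- data.frame(
          dataset = ds$name, bit_selection = sel, filtering = flt,
          measure = rep(rownames(cv), ncol(cv)),
          symmetricity = rep(sym[rownames(cv)], ncol(cv)),
          metricity = rep(met[rownames(cv)], ncol(cv)),
          round = rep(colnames(cv), each = nrow(cv)),
          srd_norm = as.vector(cv),
          row.names = NULL, stringsAsFactors = FALSE
        )
        auc_rows[[tag]] <- data.frame(
          dataset = ds$name, bit_selection = sel, filtering = flt,
          measure = measures,
          auc = vapply(measures, function(mm) roc_auc(sm[[mm]], sm$active),
                       numeric(1L)),
          row.names = NULL, stringsAsFactors = FALSE
        )
      }
    }
  }
  structure(list(srd = do.call(rbind, c(srd_rows, list(make.row.names = FALSE))),
                 auc = do.call(rbind, c(auc_rows, list(make.row.names = FALSE))),
                 skipped = skipped,
                 config = list(measures = measures, selections = selections,
                               filterings = filterings, folds = folds,
                               pretreatment = pretreatment, seed = seed)),
            class = "srd_grid")
}

#' @export
print.srd_grid <- function(x, ...) {
  nv <- nrow(unique(x$srd[, c("dataset", "bit_selection", "filtering")]))
  cat("SRD evaluation grid: ", nv, " input variants, ",
      nrow(x$srd), " SRD rows, ", nrow(x$auc), " AUC values\n", sep = "")
  if (length(x$skipped)) {
    cat("  skipped variants:", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Factorial ANOVA on normalized SRD values
#'
#' Fixed-effects analysis of variance of the grid's normalized SRD values
#' over grouping factors such as measure, bit selection, filtering rule,
#' symmetricity or metricity. Sums of squares are sequential (type I); on
#' the balanced full-factorial grid all SS types coincide. Per-level means
#' carry 95\% t-based confidence half-widths. When the between-group sum of
#' squares is zero the F statistic is reported as 0.
#'
#' @param table data.frame with an \code{srd_norm} column (e.g.
#'   \code{run_grid(...)$srd}), or an \code{srd_grid}.
#' @param factors character vector of factor column names; with
#'   \code{interactions = TRUE} all interaction terms are included.
#' @param response response column name.
#' @param interactions include interaction terms.
#' @return Object of class \code{"factor_anova"}: list with \code{anova}
#'   (term, df, sum_sq, mean_sq, F, p) and \code{effects} (one data.frame
#'   per factor: level, n, mean, ci_half, lower, upper).
#' @examples
#' df <- data.frame(g = rep(c("A", "B"), each = 3),
#'                  srd_norm = c(1, 2, 3, 2, 3, 4))
#' factor_anova(df, "g")$anova$F  # 1.5
#' @export
factor_anova <- function(table, factors, response = "srd_norm",
                         interactions = FALSE) {
  if (inherits(table, "srd_grid")) table <- table$srd
  if (!response %in% names(table)) stop("no '", response, "' column in table")
  missing <- setdiff(factors, names(table))
  if (length(missing)) stop("unknown factor(s): ", paste(missing, collapse = ", "))
  for (f in factors) {
    table[[f]] <- factor(table[[f]])
    if (nlevels(table[[f]]) < 2L) {
      stop("factor '", f, "' has fewer than 2 levels")
    }
  }
  if (interactions && length(factors) > 1L) {
    cells <- interaction(table[factors], drop = FALSE)
    empty <- levels(cells)[tabulate(cells, nlevels(cells)) == 0L]
    if (length(empty)) {
      stop("empty cell(s) in requested interaction: ",
           paste(utils::head(empty, 3L), collapse = ", "))
    }
  }
  op <- if (interactions) " * " else " + "
  fml <- stats::as.formula(paste(response, "~", paste(factors, collapse = op)))
  fit <- stats::aov(fml, data = table)
  # a perfect fit (zero residual variance) is handled by the F = 0 / p = 1
  # convention below, so the F-test reliability warning is moot
  at <- withCallingHandlers(stats::anova(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  terms <- rownames(at)
  res_row <- terms == "Residuals"
  atab <- data.frame(term = terms[!res_row],
                     df = at$Df[!res_row],
                     sum_sq = at$`Sum Sq`[!res_row],
                     mean_sq = at$`Mean Sq`[!res_row],
                     df_resid = at$Df[res_row],
                     F = at$`F value`[!res_row],
                     p = at$`Pr(>F)`[!res_row],
                     row.names = NULL, stringsAsFactors = FALSE)
  zero_between <- !is.na(atab$sum_sq) & atab$sum_sq <= 1e-12
  atab$F[zero_between] <- 0
  atab$p[zero_between] <- 1
  effects <- lapply(stats::setNames(factors, factors), function(f) {
    sp <- split(table[[response]], table[[f]])
    lv <- names(sp)
    n <- lengths(sp)
    mu <- vapply(sp, mean, numeric(1L))
    sdv <- vapply(sp, stats::sd, numeric(1L))
    half <- ifelse(n > 1L, stats::qt(0.975, n - 1L) * sdv / sqrt(n), NA_real_)
    data.frame(level = lv, n = as.integer(n), mean = unname(mu),
               ci_half = unname(half), lower = unname(mu - half),
               upper = unname(mu + half), row.names = NULL,
               stringsAsFactors = FALSE)
  })
  structure(list(anova = atab, effects = effects, alpha = 0.05,
                 formula = fml), class = "factor_anova")
}

#' @export
print.factor_anova <- function(x, ...) {
  cat("Factorial ANOVA:", deparse(x$formula), "\n\n")
  print(x$anova, digits = 4, row.names = FALSE)
  sig <- x$anova$term[!is.na(x$anova$p) & x$anova$p < x$alpha]
  if (length(sig)) {
    cat("\nSignificant at alpha = 0.05:", paste(sig, collapse = ", "), "\n")
  }
  for (f in names(x$effects)) {
    cat("\nLevel means (", f, "):\n", sep = "")
    print(x$effects[[f]], digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.factor_anova <- function(x, factor = names(x$effects)[1L], ...) {
  eff <- x$effects[[factor]]
  if (is.null(eff)) stop("no such factor in the fit: ", factor)
  n <- nrow(eff)
  ylim <- range(c(eff$lower, eff$upper), na.rm = TRUE)
  graphics::plot(seq_len(n), eff$mean, xaxt = "n", pch = 19, ylim = ylim,
                 xlab = factor, ylab = "Mean normalized SRD [%]",
                 main = paste("Factor means with 95% CI:", factor), ...)
  graphics::axis(1, at = seq_len(n), labels = eff$level, las = 2, cex.axis = 0.7)
  graphics::arrows(seq_len(n), eff$lower, seq_len(n), eff$upper,
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}
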