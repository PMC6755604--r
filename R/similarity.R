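#' Confusion counts for a pair of binary fingerprints
#'
#' For two equal-length 0/1 vectors, counts the four co-occurrence events:
#' \code{a} common on-bits (1-1), \code{b} on in the first only (1-0),
#' \code{c} on in the second only (0-1), \code{d} common off-bits (0-0),
#' with total length \code{p = a + b + c + d}. All binary similarity
#' coefficients in the catalog are functions of these five counts.
#'
#' @param fp1,fp2 0/1 vectors of equal length, or \code{interaction_fp}
#'   objects.
#' @return Object of class \code{"confusion_counts"}: list with elements
#'   \code{a}, \code{b}, \code{c}, \code{d}, \code{p}.
#' @examples
#' confusion_counts(c(1, 1, 0, 0), c(1, 0, 1, 0))  # a=b=c=d=1
#' @export
confusion_counts <- function(fp1, fp2) {
  if (inherits(fp1, "interaction_fp")) fp1 <- fp1$bits
  if (inherits(fp2, "interaction_fp")) fp2 <- fp2$bits
  fp1 <- as.numeric(fp1); fp2 <- as.numeric(fp2)
  if (length(fp1) == 0L || length(fp2) == 0L) stop("empty fingerprint vector")
  if (length(fp1) != length(fp2)) {
    stop(sprintf("fingerprint length mismatch: %d vs %d",
                 length(fp1), length(fp2)))
  }
  if (anyNA(fp1) || anyNA(fp2) || !all(fp1 %in% c(0, 1)) || !all(fp2 %in% c(0, 1))) {
    stop("fingerprint bits must be 0 or 1")
  }
  a <- sum(fp1 * fp2)
  b <- sum(fp1) - a
  c <- sum(fp2) - a
  d <- length(fp1) - a - b - c
  structure(list(a = a, b = b, c = c, d = d, p = length(fp1)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion counts: a=%g b=%g c=%g d=%g (p=%g)\n",
              x$a, x$b, x$c, x$d, x$p))
  invisible(x)
}

# One catalog entry. alpha/beta may depend on the fingerprint length p, so
# they are stored as functions of p; most measures are already in [0, 1]
# (alpha = 0, beta = 1) and measures on [-1, 1] use alpha = 1, beta = 2.
measure_def <- function(abbrev, name, f, sym, met,
                        alpha = function(p) 0, beta = function(p) 1,
                        exchange_symmetric = TRUE, max_at_identity = TRUE) {
  list(abbrev = abbrev, name = name, f = f,
       alpha = alpha, beta = beta,
       symmetricity = sym, metricity = met,
       exchange_symmetric = exchange_symmetric,
       max_at_identity = max_at_identity)
}

make_catalog <- function() {
  m <- list()
  add <- function(...) m[[length(m) + 1L]] <<- measure_def(...)

  ## -- symmetric (S): d weighted like a ------------------------------------
  add("SM",  "Sokal-Michener (simple matching)",
      function(a, b, c, d, p) (a + d) / p, "S", "M")
  add("RT",  "Rogers-Tanimoto",
      function(a, b, c, d, p) (a + d) / (p + b + c), "S", "M")
  add("SS2", "Sokal-Sneath 2",
      function(a, b, c, d, p) 2 * (a + d) / (p + a + d), "S", "N")
  add("SS3", "Sokal-Sneath 3",
      function(a, b, c, d, p)
        0.25 * (a / (a + b) + a / (a + c) + d / (b + d) + d / (c + d)),
      "S", "N")
  add("SS4", "Sokal-Sneath 4",
      function(a, b, c, d, p) a * d / sqrt((a + b) * (a + c) * (b + d) * (c + d)),
      "S", "N")
  add("Mic", "Michael",
      function(a, b, c, d, p) 4 * (a * d - b * c) / ((a + d)^2 + (b + c)^2),
      "S", "N", alpha = function(p) 1, beta = function(p) 2,
      max_at_identity = FALSE)
  add("RG",  "Rogot-Goldberg",
      function(a, b, c, d, p) a / (2 * a + b + c) + d / (2 * d + b + c),
      "S", "N")
  add("HD",  "Hawkins-Dotson",
      function(a, b, c, d, p) 0.5 * (a / (a + b + c) + d / (b + c + d)),
      "S", "N")
  add("GK",  "Goodman-Kruskal",
      function(a, b, c, d, p) {
        m2 <- 2 * pmin(a, d)
        (m2 - b - c) / (m2 + b + c)
      }, "S", "N", alpha = function(p) 1, beta = function(p) 2)
  add("HL",  "Harris-Lahey",
      function(a, b, c, d, p)
        a * (2 * d + b + c) / (2 * (a + b + c)) +
        d * (2 * a + b + c) / (2 * (b + c + d)),
      "S", "N", beta = function(p) p)
  add("CT1", "Consonni-Todeschini 1",
      function(a, b, c, d, p) log1p(a + d) / log1p(p), "S", "M")
  add("CT2", "Consonni-Todeschini 2",
      function(a, b, c, d, p) (log1p(p) - log1p(b + c)) / log1p(p), "S", "M")
  add("AC",  "Austin-Colwell",
      function(a, b, c, d, p) (2 / pi) * asin(sqrt((a + d) / p)), "S", "M")
  add("Sco", "Scott",
      function(a, b, c, d, p)
        (4 * a * d - (b + c)^2) / ((2 * a + b + c) * (2 * d + b + c)),
      "S", "N", alpha = function(p) 1, beta = function(p) 2)

  ## -- intermediate (I): d underweighted -----------------------------------
  add("BUB", "Baroni-Urbani-Buser",
      function(a, b, c, d, p) {
        s <- sqrt(a * d)
        (s + a) / (s + a + b + c)
      }, "I", "M")
  add("Fai", "Faith",
      function(a, b, c, d, p) (a + 0.5 * d) / p, "I", "N",
      max_at_identity = FALSE)
  add("RR",  "Russell-Rao",
      function(a, b, c, d, p) a / p, "I", "M", max_at_identity = FALSE)
  add("For", "Forbes",
      function(a, b, c, d, p) a * p / ((a + b) * (a + c)), "I", "N",
      beta = function(p) p, max_at_identity = FALSE)
  add("Fos", "Fossum",
      function(a, b, c, d, p) p * (a - 0.5)^2 / ((a + b) * (a + c)), "I", "N",
      beta = function(p) (p - 0.5)^2 / p, max_at_identity = FALSE)
  add("CT3", "Consonni-Todeschini 3",
      function(a, b, c, d, p) log1p(a) / log1p(p), "I", "M",
      max_at_identity = FALSE)

  ## -- asymmetric (A): d not considered at all -----------------------------
  add("JT",  "Jaccard-Tanimoto",
      function(a, b, c, d, p) a / (a + b + c), "A", "M")
  add("Gle", "Gleason (Dice-Sorensen)",
      function(a, b, c, d, p) 2 * a / (2 * a + b + c), "A", "N")
  add("SS1", "Sokal-Sneath 1",
      function(a, b, c, d, p) a / (a + 2 * (b + c)), "A", "M")
  add("Sim", "Simpson",
      function(a, b, c, d, p) a / pmin(a + b, a + c), "A", "N")
  add("BB",  "Braun-Blanquet",
      function(a, b, c, d, p) a / pmax(a + b, a + c), "A", "N")
  add("DK",  "Driver-Kroeber (Ochiai)",
      function(a, b, c, d, p) a / sqrt((a + b) * (a + c)), "A", "N")
  add("Kul", "Kulczynski",
      function(a, b, c, d, p) 0.5 * (a / (a + b) + a / (a + c)), "A", "N")
  add("Ja",  "Jaccard (weighted)",
      function(a, b, c, d, p) 3 * a / (3 * a + b + c), "A", "N")
  add("Mou", "Mountford",
      function(a, b, c, d, p) 2 * a / (a * b + a * c + 2 * b * c), "A", "N",
      beta = function(p) 2)
  add("CT4", "Consonni-Todeschini 4",
      function(a, b, c, d, p) log1p(a) / log1p(a + b + c), "A", "M")
  add("Sor", "Sorgenfrei",
      function(a, b, c, d, p) a^2 / ((a + b) * (a + c)), "A", "N")

  ## -- correlation-based (Q) ------------------------------------------------
  add("Yu1", "Yule 1 (Q)",
      function(a, b, c, d, p) (a * d - b * c) / (a * d + b * c),
      "Q", "N", alpha = function(p) 1, beta = function(p) 2)
  add("Yu2", "Yule 2 (Y)",
      function(a, b, c, d, p) {
        u <- sqrt(a * d); v <- sqrt(b * c)
        (u - v) / (u + v)
      }, "Q", "N", alpha = function(p) 1, beta = function(p) 2)
  add("Den", "Dennis",
      function(a, b, c, d, p) (a * d - b * c) / sqrt(p * (a + b) * (a + c)),
      "Q", "N", alpha = function(p) sqrt(p), beta = function(p) 2 * sqrt(p),
      max_at_identity = FALSE)
  add("Co1", "Cole 1",
      function(a, b, c, d, p) (a * d - b * c) / ((a + c) * (c + d)),
      "Q", "N", alpha = function(p) p - 1, beta = function(p) p,
      exchange_symmetric = FALSE)
  add("Co2", "Cole 2",
      function(a, b, c, d, p) (a * d - b * c) / ((a + b) * (b + d)),
      "Q", "N", alpha = function(p) p - 1, beta = function(p) p,
      exchange_symmetric = FALSE)
  add("dis", "Dispersion",
      function(a, b, c, d, p) (a * d - b * c) / p^2,
      "Q", "N", alpha = function(p) 0.25, beta = function(p) 0.5,
      max_at_identity = FALSE)
  add("Phi", "Pearson-Heron 1 (phi)",
      function(a, b, c, d, p)
        (a * d - b * c) / sqrt((a + b) * (a + c) * (b + d) * (c + d)),
      "Q", "N", alpha = function(p) 1, beta = function(p) 2)
  add("PH2", "Pearson-Heron 2",
      function(a, b, c, d, p) {
        u <- sqrt(a * d); v <- sqrt(b * c)
        cos(pi * v / (u + v))
      }, "Q", "N", alpha = function(p) 1, beta = function(p) 2)
  add("Coh", "Cohen",
      function(a, b, c, d, p)
        2 * (a * d - b * c) / ((a + b) * (b + d) + (a + c) * (c + d)),
      "Q", "N", alpha = function(p) 1, beta = function(p) 2)
  add("Pe1", "Peirce 1",
      function(a, b, c, d, p) (a * d - b * c) / ((a + b) * (c + d)),
      "Q", "N", alpha = function(p) 1, beta = function(p) 2,
      exchange_symmetric = FALSE)
  add("Pe2", "Peirce 2",
      function(a, b, c, d, p) (a * d - b * c) / ((a + c) * (b + d)),
      "Q", "N", alpha = function(p) 1, beta = function(p) 2,
      exchange_symmetric = FALSE)
  add("MP",  "Maxwell-Pilliner",
      function(a, b, c, d, p)
        2 * (a * d - b * c) / ((a + b) * (c + d) + (a + c) * (b + d)),
      "Q", "N", alpha = function(p) 1, beta = function(p) 2)
  add("CT5", "Consonni-Todeschini 5",
      function(a, b, c, d, p)
        (log1p(a * d) - log1p(b * c)) / log1p(p^2 / 4),
      "Q", "N", alpha = function(p) 1, beta = function(p) 2,
      max_at_identity = FALSE)

  names(m) <- vapply(m, `[[`, "", "abbrev")
  m
}

.MEASURES <- make_catalog()

#' The catalog of 44 binary similarity measures
#'
#' \code{list_measures} summarises the catalog of 44 binary similarity
#' coefficients (Sokal-Michener, Jaccard-Tanimoto, Baroni-Urbani-Buser,
#' the Consonni-Todeschini family, correlation-based coefficients, ...).
#' Each measure carries rescaling constants alpha/beta mapping its raw range
#' into [0, 1], a symmetricity class — \code{S} (common off-bits \code{d}
#' weighted like common on-bits \code{a}), \code{I} (\code{d}
#' underweighted), \code{A} (\code{d} ignored), \code{Q}
#' (correlation-based) — and a metricity flag (\code{M} if 1 - s' is a
#' metric distance, else \code{N}). Two boolean columns document formula
#' idiosyncrasies: \code{exchange_symmetric} is FALSE for the directional
#' Peirce and Cole coefficients (swapping the two fingerprints maps Pe1 to
#' Pe2 and Co1 to Co2), and \code{max_at_identity} is FALSE for
#' absolute-type measures (e.g. Russell-Rao a/p) that do not reach 1 for
#' identical fingerprints.
#'
#' @return \code{list_measures}: data.frame with one row per measure.
#' @examples
#' nrow(list_measures())           # 44
#' get_measure("JT")$symmetricity  # "A"
#' @export
list_measures <- function() {
  data.frame(
    abbrev = vapply(.MEASURES, `[[`, "", "abbrev"),
    name = vapply(.MEASURES, `[[`, "", "name"),
    symmetricity = vapply(.MEASURES, `[[`, "", "symmetricity"),
    metricity = vapply(.MEASURES, `[[`, "", "metricity"),
    exchange_symmetric = vapply(.MEASURES, `[[`, TRUE, "exchange_symmetric"),
    max_at_identity = vapply(.MEASURES, `[[`, TRUE, "max_at_identity"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' @rdname list_measures
#' @param abbrev measure abbreviation, e.g. \code{"JT"}.
#' @return \code{get_measure}: the full catalog entry (list with the raw
#'   formula function \code{f}, \code{alpha}, \code{beta} and class flags).
#' @export
get_measure <- function(abbrev) {
  if (!abbrev %in% names(.MEASURES)) stop("unknown similarity measure: ", abbrev)
  .MEASURES[[abbrev]]
}

resolve_measure <- function(measure) {
  if (is.character(measure)) get_measure(measure) else measure
}

#' Raw and rescaled similarity values
#'
#' \code{raw_similarity} evaluates a measure's defining formula on confusion
#' counts; for degenerate counts (a zero denominator) it returns \code{NaN},
#' which \code{similarity} resolves by convention. \code{scale_similarity}
#' applies the affine rescaling s' = (s + alpha) / beta onto [0, 1]; values
#' outside [0, 1] by more than 1e-9 signal an internal scaling error, and
#' values within tolerance are clamped. \code{similarity} combines the two
#' and applies the degenerate-denominator convention: identical fingerprints
#' (b = c = 0) score the maximum s' = 1, any other degeneracy scores the
#' minimum s' = 0 — preserving the ranking semantics that an identical
#' interaction pattern is the most similar one.
#'
#' @param measure abbreviation or catalog entry from \code{\link{get_measure}}.
#' @param counts a \code{\link{confusion_counts}} object (or list with
#'   numeric a, b, c, d, p, possibly vectorised).
#' @param s raw similarity value(s).
#' @param p fingerprint length, required for the measures whose scaling
#'   constants depend on it.
#' @return Numeric value(s); \code{similarity} always lies in [0, 1].
#' @examples
#' raw_similarity("SM", confusion_counts(c(1, 1, 0, 1), c(1, 1, 1, 0)))
#' similarity("JT", confusion_counts(c(1, 1, 0, 0), c(1, 1, 0, 0)))  # 1
#' @export
raw_similarity <- function(measure, counts) {
  m <- resolve_measure(measure)
  s <- m$f(as.numeric(counts$a), as.numeric(counts$b), as.numeric(counts$c),
           as.numeric(counts$d), as.numeric(counts$p))
  s[!is.finite(s)] <- NaN
  s
}

#' @rdname raw_similarity
#' @export
scale_similarity <- function(s, measure, p = NULL) {
  m <- resolve_measure(measure)
  if (is.null(p)) {
    # constant-scaling measures do not need p; probe with a placeholder
    p <- 1
  }
  sp <- (s + m$alpha(p)) / m$beta(p)
  tol <- 1e-9
  bad <- is.finite(sp) & (sp < -tol | sp > 1 + tol)
  if (any(bad)) {
    stop(sprintf("internal scaling error for %s: scaled value %.6g outside [0,1]",
                 m$abbrev, sp[which(bad)[1L]]))
  }
  pmin(pmax(sp, 0), 1)
}

#' @rdname raw_similarity
#' @export
similarity <- function(measure, counts) {
  m <- resolve_measure(measure)
  s <- raw_similarity(m, counts)
  sp <- scale_similarity(s, m, p = as.numeric(counts$p))
  deg <- is.nan(s)
  if (any(deg)) {
    sp[deg] <- ifelse(counts$b[deg] + counts$c[deg] == 0, 1, 0)
  }
  sp
}

# Vectorised catalog evaluation over n ligand pairs sharing length p.
# Returns the n x m scaled similarity matrix plus a degeneracy count.
eval_measures <- function(a, b, c, d, p, measures) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c)
  d <- as.numeric(d); p <- as.numeric(p)
  n_deg <- 0L
  vals <- vapply(measures, function(ab) {
    m <- .MEASURES[[ab]]
    s <- m$f(a, b, c, d, p)
    sp <- scale_similarity(s, m, p = p[1L])
    deg <- !is.finite(s)
    if (any(deg)) {
      n_deg <<- n_deg + sum(deg)
      sp[deg] <- ifelse(b[deg] + c[deg] == 0, 1, 0)
    }
    sp
  }, numeric(length(a)))
  vals <- matrix(vals, nrow = length(a),
                 dimnames = list(NULL, measures))
  attr(vals, "n_degenerate") <- n_deg
  vals
}

#' Similarity matrix of a ligand set against a reference fingerprint
#'
#' Computes, for every ligand in the dataset, the rescaled similarity of its
#' fingerprint to a reference fingerprint under each requested measure —
#' the input matrix of the SRD analysis: one row per query ligand, one
#' column per similarity measure.
#'
#' @param dataset a \code{\link{fp_dataset}} (after any bit selection and
#'   filtering).
#' @param reference an \code{\link{interaction_fp}} or named 0/1 vector
#'   whose names match the dataset's bit columns exactly.
#' @param measures character vector of measure abbreviations
#'   (default: all 44).
#' @return data.frame with columns \code{ligand_id}, \code{active} and one
#'   scaled similarity column per measure. The number of
#'   degenerate-denominator events resolved by convention is attached as
#'   attribute \code{"n_degenerate"} and reported via a single
#'   \code{message} when non-zero.
#' @examples
#' g <- generate_dataset(synth_config(n_residues = 6, n_actives = 5,
#'                                    n_decoys = 5, seed = 7))
#' sm <- similarity_matrix(g$dataset, g$reference, c("SM", "JT"))
#' head(sm)
#' @export
similarity_matrix <- function(dataset, reference, measures = NULL) {
  stopifnot(inherits(dataset, "fp_dataset"))
  if (inherits(reference, "interaction_fp")) reference <- reference$bits
  if (is.null(names(reference)) ||
      !identical(names(reference), colnames(dataset$bits))) {
    stop("reference fingerprint layout does not match the dataset columns")
  }
  if (is.null(measures)) measures <- list_measures()$abbrev
  unknown <- setdiff(measures, names(.MEASURES))
  if (length(unknown)) stop("unknown measure(s): ", paste(unknown, collapse = ", "))
  r <- as.numeric(reference)
  X <- dataset$bits
  a <- as.numeric(X %*% r)
  b <- rowSums(X) - a
  c <- sum(r) - a
  d <- ncol(X) - a - b - c
  vals <- eval_measures(a, b, c, d, rep(ncol(X), nrow(X)), measures)
  if (attr(vals, "n_degenerate") > 0L) {
    message(sprintf("similarity_matrix: %d degenerate denominator(s) resolved by convention",
                    attr(vals, "n_degenerate")))
  }
  out <- data.frame(ligand_id = rownames(X), active = dataset$active,
                    vals, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_degenerate") <- attr(vals, "n_degenerate")
  out
}

#' Write a similarity matrix to CSV
#'
#' Emits \code{ligand_id,active,SM,JT,...} with similarity values printed to
#' six decimal places.
#'
#' @param sim data.frame from \code{\link{similarity_matrix}}.
#' @param path output file path.
#' @export
write_similarity <- function(sim, path) {
  out <- sim
  meas <- setdiff(names(out), c("ligand_id", "active"))
  out$active <- as.integer(out$active)
  for (mcol in meas) out[[mcol]] <- sprintf("%.6f", out[[mcol]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_similarity
#' @return \code{read_similarity} returns the data.frame with
#'   \code{active} as logical.
#' @export
read_similarity <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  df$active <- df$active == 1
  df
}
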