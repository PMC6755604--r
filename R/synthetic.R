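#' Configuration for the synthetic fingerprint generator
#'
#' Describes a synthetic virtual-screening dataset with the statistical
#' structure of docked active/decoy interaction-fingerprint sets: a
#' reference interaction pattern, actives whose fingerprints are mildly
#' corrupted copies of it, decoys corrupted much more strongly, plus the
#' sparsity structure that makes the filtering rules meaningful —
#' whole residues that never interact (silent residue blocks) and
#' individual interactions inside interacting residues that cannot be
#' established (e.g. an aromatic bit on a residue without an aromatic
#' ring).
#'
#' Defaults describe one study condition: a 40-residue binding-site
#' neighbourhood (360 bits), 200 actives vs. 200 decoys, reference bit
#' density 0.2, per-bit flip probability 0.05 for actives and 0.4 for
#' decoys, 30\% silent residues and 15\% additional impossible bits.
#'
#' @param n_residues number of residues in the layout.
#' @param n_actives,n_decoys number of active / decoy ligands.
#' @param p_ref probability that a reference bit is on.
#' @param flip_active,flip_decoy per-bit Bernoulli flip probability of an
#'   active / decoy fingerprint relative to the reference
#'   (\code{flip_decoy >= flip_active}).
#' @param frac_silent_residues fraction of residues forced all-zero across
#'   the whole dataset (and the reference).
#' @param frac_impossible_bits fraction of the remaining (non-silent)
#'   columns additionally forced all-zero.
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return Object of class \code{"synth_config"}.
#' @export
synth_config <- function(n_residues = 40L, n_actives = 200L, n_decoys = 200L,
                         p_ref = 0.2, flip_active = 0.05, flip_decoy = 0.4,
                         frac_silent_residues = 0.3,
                         frac_impossible_bits = 0.15, seed = 1L) {
  cfg <- list(n_residues = as.integer(n_residues),
              n_actives = as.integer(n_actives),
              n_decoys = as.integer(n_decoys),
              p_ref = p_ref, flip_active = flip_active,
              flip_decoy = flip_decoy,
              frac_silent_residues = frac_silent_residues,
              frac_impossible_bits = frac_impossible_bits,
              seed = as.integer(seed))
  probs <- c(cfg$p_ref, cfg$flip_active, cfg$flip_decoy,
             cfg$frac_silent_residues, cfg$frac_impossible_bits)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("probabilities and fractions must lie in [0, 1]")
  }
  if (cfg$flip_decoy < cfg$flip_active) {
    stop("flip_decoy must be >= flip_active (decoys are less similar to the reference)")
  }
  if (cfg$n_residues < 1L || cfg$n_actives < 1L || cfg$n_decoys < 1L) {
    stop("counts must be at least 1")
  }
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(paste0("Synthetic fingerprint config: %d residues x 9 types, ",
                     "%d actives (flip %.2f) + %d decoys (flip %.2f), ",
                     "p_ref %.2f, %.0f%% silent residues, %.0f%% impossible bits, seed %d\n"),
              x$n_residues, x$n_actives, x$flip_active, x$n_decoys,
              x$flip_decoy, x$p_ref, 100 * x$frac_silent_residues,
              100 * x$frac_impossible_bits, x$seed))
  invisible(x)
}

#' Generate a synthetic fingerprint dataset
#'
#' Draws a reference fingerprint bitwise Bernoulli(p_ref) over the full
#' n_residues x 9 layout, then each active as the reference with
#' independent per-bit flips at \code{flip_active} and each decoy likewise
#' at \code{flip_decoy}. A seeded choice of silent residues (whole 9-bit
#' blocks) and of additional impossible bits (single columns inside
#' non-silent residues, never a residue's full block) is forced to zero in
#' the reference and every ligand. Deterministic given the config seed.
#'
#' @param config a \code{\link{synth_config}}.
#' @return List with elements \code{dataset} (a \code{\link{fp_dataset}}),
#'   \code{reference} (an \code{\link{interaction_fp}}) and
#'   \code{zeroed_columns} (names of the forced-zero columns).
#' @examples
#' g <- generate_dataset(synth_config(n_residues = 10, n_actives = 5,
#'                                    n_decoys = 5, seed = 42))
#' dim(g$dataset$bits)  # 10 ligands x 90 bits
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)

  n_types <- length(INTERACTION_TYPES)
  residues <- sprintf("RES%d", seq_len(config$n_residues))
  layout <- bit_layout(residues)
  p <- config$n_residues * n_types

  n_silent <- round(config$frac_silent_residues * config$n_residues)
  if (n_silent >= config$n_residues) {
    stop("configuration leaves no non-silent residue")
  }
  silent <- sort(sample.int(config$n_residues, n_silent))
  live_cols <- which(!rep(seq_len(config$n_residues) %in% silent, each = n_types))

  n_imposs <- round(config$frac_impossible_bits * length(live_cols))
  impossible <- integer(0)
  if (n_imposs > 0L) {
    impossible <- sort(sample(live_cols, n_imposs))
    # never silence a whole residue through impossible bits alone
    res_of <- rep(seq_len(config$n_residues), each = n_types)
    for (r in unique(res_of[impossible])) {
      block <- which(res_of == r)
      if (all(block %in% impossible)) {
        impossible <- setdiff(impossible, block[1L])
      }
    }
  }
  zero_cols <- sort(union(which(rep(seq_len(config$n_residues) %in% silent,
                                    each = n_types)), impossible))
  if (length(zero_cols) >= p) stop("configuration leaves no live bit column")

  ref <- stats::rbinom(p, 1L, config$p_ref)
  n <- config$n_actives + config$n_decoys
  flips <- matrix(0L, n, p)
  flips[seq_len(config$n_actives), ] <-
    stats::rbinom(config$n_actives * p, 1L, config$flip_active)
  flips[config$n_actives + seq_len(config$n_decoys), ] <-
    stats::rbinom(config$n_decoys * p, 1L, config$flip_decoy)
  bits <- (matrix(ref, n, p, byrow = TRUE) + flips) %% 2L

  ref[zero_cols] <- 0L
  bits[, zero_cols] <- 0L

  ids <- c(sprintf("act%03d", seq_len(config$n_actives)),
           sprintf("dec%03d", seq_len(config$n_decoys)))
  nms <- layout_names(layout)
  colnames(bits) <- nms
  dataset <- fp_dataset(bits,
                        active = rep(c(TRUE, FALSE),
                                     c(config$n_actives, config$n_decoys)),
                        ligand_id = ids, name = sprintf("synth%d", config$seed),
                        layout = layout)
  list(dataset = dataset,
       reference = interaction_fp(stats::setNames(ref, nms), "reference", TRUE),
       zeroed_columns = nms[zero_cols])
}
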