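subset_columns <- function(dataset, keep) {
  out <- dataset
  out$bits <- dataset$bits[, keep, drop = FALSE]
  out$columns <- dataset$columns[keep, , drop = FALSE]
  rownames(out$columns) <- NULL
  out
}

#' Bit-selection schemes ALL / WO1 / WO3
#'
#' Interaction fingerprints carry, besides the specific interaction bits,
#' very general contact definitions. The three bit-selection schemes studied
#' here keep all nine interaction types (\code{ALL}), drop the "Any contact"
#' bit (\code{WO1}), or drop "Any contact" plus the backbone and sidechain
#' contact bits (\code{WO3}). Residue order and the order of the remaining
#' interaction types are preserved. Removing an interaction type that is
#' absent from the layout is a no-op.
#'
#' @param dataset a \code{\link{fp_dataset}}.
#' @param scheme one of \code{"ALL"}, \code{"WO1"}, \code{"WO3"}.
#' @return The selected \code{fp_dataset}.
#' @examples
#' d <- generate_dataset(synth_config(n_residues = 2, n_actives = 2,
#'                                    n_decoys = 2, seed = 1))$dataset
#' ncol(select_bits(d, "WO3")$bits)  # 2 residues x 6 types
#' @export
select_bits <- function(dataset, scheme = c("ALL", "WO1", "WO3")) {
  stopifnot(inherits(dataset, "fp_dataset"))
  if (length(scheme) != 1L || !scheme %in% c("ALL", "WO1", "WO3")) {
    stop("unknown bit-selection scheme: ", paste(scheme, collapse = ", "))
  }
  drop_types <- switch(scheme, ALL = character(), WO1 = "Any",
                       WO3 = c("Any", "BB", "SC"))
  if (length(drop_types) == 0L) return(dataset)
  subset_columns(dataset, !dataset$columns$interaction %in% drop_types)
}

#' Fingerprint filtering rules RES and INTS
#'
#' Docked ligand sets leave many residues consistently non-interacting, so
#' unfiltered fingerprints are dominated by shared zero bits.
#' Residue-based filtering (\code{filter_residues}, RES) removes every
#' residue whose entire bit block is zero across all ligands in the dataset.
#' Interaction-based filtering (\code{filter_interactions}, INTS)
#' additionally removes every individual bit column that is never set across
#' the dataset — a superset of the RES removals, since it also catches
#' interactions a retained residue cannot establish (e.g. the aromatic bit
#' of a residue without an aromatic ring). Retained bit values, ligand order
#' and activity labels are untouched.
#'
#' @param dataset a \code{\link{fp_dataset}}.
#' @return The filtered \code{fp_dataset}.
#' @examples
#' d <- generate_dataset(synth_config(seed = 1))$dataset
#' ncol(filter_interactions(d)$bits) <= ncol(filter_residues(d)$bits)
#' @export
filter_residues <- function(dataset) {
  stopifnot(inherits(dataset, "fp_dataset"))
  if (nrow(dataset$bits) == 0L) stop("empty dataset")
  col_on <- colSums(dataset$bits) > 0L
  residue_on <- tapply(col_on, dataset$columns$residue, any)
  keep <- residue_on[dataset$columns$residue]
  if (!any(keep)) stop("all residues are silent; nothing left after RES filtering")
  subset_columns(dataset, as.vector(keep))
}

#' @rdname filter_residues
#' @export
filter_interactions <- function(dataset) {
  stopifnot(inherits(dataset, "fp_dataset"))
  if (nrow(dataset$bits) == 0L) stop("empty dataset")
  keep <- colSums(dataset$bits) > 0L
  if (!any(keep)) stop("all bit columns are zero; nothing left after INTS filtering")
  subset_columns(dataset, keep)
}

#' @rdname filter_residues
#' @param rule one of \code{"NO"} (identity), \code{"RES"}, \code{"INTS"}.
#' @export
apply_filtering <- function(dataset, rule = c("NO", "RES", "INTS")) {
  rule <- match.arg(rule)
  switch(rule, NO = dataset, RES = filter_residues(dataset),
         INTS = filter_interactions(dataset))
}
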