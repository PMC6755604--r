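#' Canonical SIFt interaction types
#'
#' The nine per-residue interaction bits of the modified structural
#' interaction fingerprint (SIFt), in canonical order: any contact (Any),
#' backbone contact (BB), sidechain contact (SC), polar residue (Pol),
#' hydrophobic residue (Hyd), hydrogen-bond acceptor (HBA), hydrogen-bond
#' donor (HBD), aromatic residue (Aro) and charged residue (Chg).
#'
#' @format Character vector of length 9.
#' @export
INTERACTION_TYPES <- c("Any", "BB", "SC", "Pol", "Hyd", "HBA", "HBD", "Aro", "Chg")

#' Construct a fingerprint bit layout
#'
#' A bit layout is the cross product of an ordered residue list and an
#' ordered list of interaction types: bit (i, j) of the fingerprint encodes
#' whether residue i forms interaction type j with the ligand. Bits are
#' ordered residue-major, i.e. the bit index of (residue i, interaction j)
#' is \code{(i - 1) * n_types + j}.
#'
#' @param residues character vector of residue identifiers (e.g. "ASP86").
#' @param interaction_types character vector, a subset of
#'   \code{\link{INTERACTION_TYPES}} kept in canonical order.
#' @return An object of class \code{"bit_layout"} with elements
#'   \code{residues} and \code{interaction_types}.
#' @examples
#' lay <- bit_layout(c("ASP86", "LYS89"))
#' layout_names(lay)[1:3]
#' @export
bit_layout <- function(residues, interaction_types = INTERACTION_TYPES) {
  residues <- as.character(residues)
  interaction_types <- as.character(interaction_types)
  if (length(residues) < 1L) stop("layout needs at least one residue")
  if (anyDuplicated(residues)) stop("duplicated residue identifiers in layout")
  if (!all(interaction_types %in% INTERACTION_TYPES)) {
    stop("unknown interaction type(s): ",
         paste(setdiff(interaction_types, INTERACTION_TYPES), collapse = ", "))
  }
  # keep canonical order regardless of input order
  interaction_types <- INTERACTION_TYPES[INTERACTION_TYPES %in% interaction_types]
  structure(list(residues = residues, interaction_types = interaction_types),
            class = "bit_layout")
}

#' @rdname bit_layout
#' @param layout a \code{bit_layout}.
#' @return \code{layout_names} returns the "RESIDUE:INTERACTION" column names
#'   in bit order.
#' @export
layout_names <- function(layout) {
  stopifnot(inherits(layout, "bit_layout"))
  as.vector(t(outer(layout$residues, layout$interaction_types, paste, sep = ":")))
}

#' @export
print.bit_layout <- function(x, ...) {
  cat("Fingerprint bit layout:", length(x$residues), "residues x",
      length(x$interaction_types), "interaction types =",
      length(x$residues) * length(x$interaction_types), "bits\n")
  cat("Interaction types:", paste(x$interaction_types, collapse = ", "), "\n")
  invisible(x)
}

parse_bit_columns <- function(nms) {
  parts <- strsplit(nms, ":", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop("malformed fingerprint column name(s) (expected RESIDUE:INTERACTION): ",
         paste(utils::head(nms[bad], 3L), collapse = ", "))
  }
  residue <- vapply(parts, `[`, "", 1L)
  interaction <- vapply(parts, `[`, "", 2L)
  unknown <- !interaction %in% INTERACTION_TYPES
  if (any(unknown)) {
    stop("unknown interaction type in column(s): ",
         paste(utils::head(nms[unknown], 3L), collapse = ", "))
  }
  data.frame(residue = residue, interaction = interaction,
             stringsAsFactors = FALSE)
}

#' Construct a fingerprint dataset
#'
#' A fingerprint dataset holds one binary interaction fingerprint per ligand
#' together with an activity label (active vs. decoy/inactive). Bits are
#' stored as a 0/1 integer matrix with one row per ligand; column names
#' follow the "RESIDUE:INTERACTION" dialect so the layout round-trips
#' through plain CSV.
#'
#' @param bits 0/1 matrix (ligands x bits) with "RESIDUE:INTERACTION"
#'   column names, or a \code{bit_layout} to derive the names from.
#' @param active logical vector of activity labels, one per ligand.
#' @param ligand_id character vector of ligand identifiers.
#' @param name dataset name.
#' @param layout optional \code{bit_layout}; when given, its column names
#'   must match \code{colnames(bits)}.
#' @return Object of class \code{"fp_dataset"}: a list with elements
#'   \code{name}, \code{bits}, \code{active}, \code{columns} (parsed
#'   residue/interaction per bit column).
#' @export
fp_dataset <- function(bits, active, ligand_id = rownames(bits),
                       name = "dataset", layout = NULL) {
  bits <- as.matrix(bits)
  if (!is.null(layout)) {
    if (is.null(colnames(bits))) colnames(bits) <- layout_names(layout)
    else if (!identical(colnames(bits), layout_names(layout)))
      stop("bit column names do not match the supplied layout")
  }
  if (is.null(colnames(bits))) stop("bit matrix must carry RESIDUE:INTERACTION column names")
  storage.mode(bits) <- "integer"
  if (any(is.na(bits)) || !all(bits == 0L | bits == 1L)) {
    bad <- which(is.na(bits) | !(bits == 0L | bits == 1L), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-binary bit value at row %d, column '%s'",
                 bad[1L], colnames(bits)[bad[2L]]))
  }
  if (is.null(ligand_id)) ligand_id <- paste0("lig", seq_len(nrow(bits)))
  active <- as.logical(active)
  if (length(active) != nrow(bits) || anyNA(active)) {
    stop("'active' must be a complete logical vector with one entry per ligand")
  }
  if (length(ligand_id) != nrow(bits)) stop("one ligand id per row required")
  rownames(bits) <- ligand_id
  structure(list(name = name, bits = bits, active = active,
                 columns = parse_bit_columns(colnames(bits))),
            class = "fp_dataset")
}

#' @export
print.fp_dataset <- function(x, ...) {
  cat("Interaction fingerprint dataset '", x$name, "': ", nrow(x$bits),
      " ligands (", sum(x$active), " active, ", sum(!x$active),
      " inactive), ", ncol(x$bits), " bits over ",
      length(unique(x$columns$residue)), " residues\n", sep = "")
  invisible(x)
}

#' @export
dim.fp_dataset <- function(x) dim(x$bits)

#' Extract one ligand's fingerprint
#'
#' @param dataset a \code{fp_dataset}.
#' @param i ligand index or ligand id.
#' @return Object of class \code{"interaction_fp"}: list with
#'   \code{ligand_id}, named 0/1 \code{bits} vector and \code{active} flag.
#' @export
fingerprint <- function(dataset, i) {
  stopifnot(inherits(dataset, "fp_dataset"))
  if (is.character(i)) i <- match(i, rownames(dataset$bits))
  if (is.na(i) || i < 1L || i > nrow(dataset$bits)) stop("no such ligand")
  interaction_fp(dataset$bits[i, ], rownames(dataset$bits)[i], dataset$active[i])
}

#' @rdname fingerprint
#' @param bits named 0/1 vector ("RESIDUE:INTERACTION" names).
#' @param ligand_id ligand identifier.
#' @param active logical activity label.
#' @export
interaction_fp <- function(bits, ligand_id = "ref", active = NA) {
  nm <- names(bits)
  if (is.null(nm)) stop("fingerprint bits must be named")
  bits <- stats::setNames(as.integer(bits), nm)
  if (!all(bits %in% 0:1)) stop("fingerprint bits must be 0/1")
  parse_bit_columns(names(bits))  # validates the naming dialect
  structure(list(ligand_id = as.character(ligand_id), bits = bits,
                 active = as.logical(active)),
            class = "interaction_fp")
}

#' @export
print.interaction_fp <- function(x, ...) {
  cat("Interaction fingerprint '", x$ligand_id, "': ", sum(x$bits), "/",
      length(x$bits), " bits on",
      if (!is.na(x$active)) paste0(", ", if (x$active) "active" else "inactive"),
      "\n", sep = "")
  invisible(x)
}

sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path)
  if (grepl("\t", header)) "\t" else ","
}

#' Read and write fingerprint datasets
#'
#' The on-disk format is a delimited text table with header
#' \code{ligand_id,active,RES:INT,...}; \code{active} and all bit cells are
#' 0/1. The reader sniffs comma vs. tab delimiters; the writer emits comma.
#'
#' @param path file path.
#' @param name dataset name (defaults to the file base name).
#' @return \code{read_fingerprints} returns a \code{\link{fp_dataset}}.
#' @examples
#' d <- generate_dataset(synth_config(n_residues = 4, n_actives = 3,
#'                                    n_decoys = 3, seed = 1))$dataset
#' f <- tempfile(fileext = ".csv")
#' write_fingerprints(d, f)
#' identical(read_fingerprints(f)$bits, d$bits)
#' @export
read_fingerprints <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path)
  delim <- sniff_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  if (ncol(df) < 3L || names(df)[1L] != "ligand_id" || names(df)[2L] != "active") {
    stop("malformed header: expected 'ligand_id,active,<RESIDUE:INTERACTION>,...'")
  }
  bitnames <- names(df)[-(1:2)]
  parse_bit_columns(bitnames)
  if (!all(df$active %in% c("0", "1"))) {
    stop("activity labels must be 0 or 1")
  }
  cells <- as.matrix(df[, -(1:2), drop = FALSE])
  bad <- !(cells == "0" | cells == "1")
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-binary bit value '%s' at row %d, column '%s'",
                 cells[idx[1L], idx[2L]], idx[1L], bitnames[idx[2L]]))
  }
  bits <- matrix(as.integer(cells), nrow = nrow(df),
                 dimnames = list(df$ligand_id, bitnames))
  fp_dataset(bits, active = df$active == "1", ligand_id = df$ligand_id,
             name = name)
}

#' @rdname read_fingerprints
#' @param dataset a \code{fp_dataset} to write.
#' @export
write_fingerprints <- function(dataset, path) {
  stopifnot(inherits(dataset, "fp_dataset"))
  df <- data.frame(ligand_id = rownames(dataset$bits),
                   active = as.integer(dataset$active),
                   dataset$bits, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
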