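measure_columns <- function(sim) setdiff(names(sim), c("ligand_id", "active"))

apply_columnwise <- function(sim, f) {
  is_df <- is.data.frame(sim)
  if (is_df) {
    cols <- measure_columns(sim)
    for (cl in cols) sim[[cl]] <- f(sim[[cl]], cl)
    sim
  } else {
    out <- apply(sim, 2L, f, "column")
    dimnames(out) <- dimnames(sim)
    out
  }
}

#' Column-wise data pretreatment of similarity matrices
#'
#' Even after rescaling to [0, 1], different similarity measures occupy very
#' different sub-ranges (e.g. Mountford values near 0, Yule values near 1),
#' which would bias the row-min/max consensus fusion of the SRD reference.
#' These transforms put the measure columns on a common footing before SRD:
#' \code{autoscale} (standardization: column mean 0, sample standard
#' deviation 1), \code{range_scale} (column min 0, max 1, linear in
#' between) and \code{rank_transform} (ascending ranks 1..n, ties averaged).
#' A constant column cannot be scaled; it is set to all-zero with a
#' warning (\code{rank_transform} handles constants naturally via ties).
#'
#' @param sim similarity matrix: data.frame from
#'   \code{\link{similarity_matrix}} (columns \code{ligand_id} and
#'   \code{active} are passed through) or a plain numeric matrix.
#' @param method for \code{pretreat}: one of \code{"auto"}, \code{"rgs"},
#'   \code{"rank"}, \code{"none"}.
#' @return The transformed object, same shape as the input.
#' @examples
#' autoscale(cbind(x = c(1, 2, 3)))        # -1, 0, 1
#' range_scale(cbind(x = c(1, 2, 3)))      # 0, 0.5, 1
#' rank_transform(cbind(x = c(0.3, 0.1, 0.2)))
#' @export
autoscale <- function(sim) {
  apply_columnwise(sim, function(x, nm) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      warning("constant column '", nm, "' set to zero in autoscaling")
      return(rep(0, length(x)))
    }
    (x - mean(x)) / s
  })
}

#' @rdname autoscale
#' @export
range_scale <- function(sim) {
  apply_columnwise(sim, function(x, nm) {
    r <- range(x)
    if (r[1L] == r[2L]) {
      warning("constant column '", nm, "' set to zero in range scaling")
      return(rep(0, length(x)))
    }
    (x - r[1L]) / (r[2L] - r[1L])
  })
}

#' @rdname autoscale
#' @export
rank_transform <- function(sim) {
  apply_columnwise(sim, function(x, nm) rank(x, ties.method = "average"))
}

#' @rdname autoscale
#' @export
pretreat <- function(sim, method = c("auto", "rgs", "rank", "none")) {
  method <- match.arg(method)
  switch(method,
         auto = autoscale(sim),
         rgs = range_scale(sim),
         rank = rank_transform(sim),
         none = sim)
}
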