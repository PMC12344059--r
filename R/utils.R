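# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg, call. = FALSE) {
  if (!isTRUE(cond)) stop(msg, call. = call.)
}

# Stage seeds are derived additively from a master seed; offsets are small so
# the result stays a valid 32-bit integer for any master seed below 2^31 - 64.
.stage_seed <- function(master, offset) {
  as.integer((as.numeric(master) + offset) %% .Machine$integer.max)
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0 && x == round(x)

# rbind a list of data.frames; empty list gives a 0-row prototype (or an
# empty data.frame when no prototype is supplied)
.rbind_all <- function(rows, prototype = NULL) {
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(prototype %||% data.frame())
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control. Inputs are validated to lie in
#' \[0, 1\]; adjusted values are monotone in the p-value ranks and never
#' smaller than the raw p-values.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Numeric vector of BH-adjusted p-values, same length as `pvals`.
#' @export
benjamini_hochberg <- function(pvals) {
  .assert(is.numeric(pvals), "pvals must be numeric")
  ok <- !is.na(pvals)
  .assert(all(pvals[ok] >= 0 & pvals[ok] <= 1), "p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}
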