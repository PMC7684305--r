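# Needleman-Wunsch global alignment with the package's identity convention.

#' Alignment scoring parameters
#'
#' Classical linear-gap global-alignment scoring. End gaps are penalized like
#' internal gaps (no free end gaps).
#'
#' @param match match score (default +1).
#' @param mismatch mismatch score (default -1).
#' @param gap per-base gap penalty (default -2).
#' @return a named list of class `nw_scoring`.
#' @export
nw_scoring <- function(match = 1, mismatch = -1, gap = -2) {
  stopifnot(is.numeric(match), is.numeric(mismatch), is.numeric(gap))
  structure(list(match = match, mismatch = mismatch, gap = gap),
            class = "nw_scoring")
}

#' Global pairwise alignment of two sequences
#'
#' Needleman-Wunsch alignment under [nw_scoring()]. Identity is defined as
#' matches / alignment columns, where gap columns count in the denominator.
#' Among score-tied traceback moves the convention is diagonal, then gap in
#' `b`, then gap in `a`, making the reported identity deterministic.
#'
#' @param a,b non-empty DNA sequences (single strings).
#' @param scoring an [nw_scoring()] object.
#' @return list with `score`, `matches`, `columns`, `identity`.
#' @export
nw_align <- function(a, b, scoring = nw_scoring()) {
  if (!is.character(a) || !is.character(b) || length(a) != 1 || length(b) != 1)
    stop("'a' and 'b' must be single character strings")
  if (nchar(a) == 0 || nchar(b) == 0)
    stop("sequences must be non-empty")
  nw_align_cpp(a, b, scoring$match, scoring$mismatch, scoring$gap)
}

#' Global-alignment identity fraction
#'
#' @inheritParams nw_align
#' @return identity in `[0, 1]`.
#' @export
nw_identity <- function(a, b, scoring = nw_scoring()) {
  nw_align(a, b, scoring)$identity
}

#' Pairwise identity matrix
#'
#' Computes NW identities between every sequence in `x` and every sequence in
#' `y`; with `y = NULL` the symmetric within-`x` matrix is returned.
#'
#' @param x,y character vectors of non-empty sequences.
#' @param scoring an [nw_scoring()] object.
#' @return numeric matrix of identities.
#' @export
nw_identity_matrix <- function(x, y = NULL, scoring = nw_scoring()) {
  if (any(nchar(x) == 0)) stop("sequences must be non-empty")
  if (is.null(y)) {
    m <- nw_identity_self_cpp(x, scoring$match, scoring$mismatch, scoring$gap)
    dimnames(m) <- list(names(x), names(x))
  } else {
    if (any(nchar(y) == 0)) stop("sequences must be non-empty")
    m <- nw_identity_cross_cpp(x, y, scoring$match, scoring$mismatch,
                               scoring$gap)
    dimnames(m) <- list(names(x), names(y))
  }
  m
}
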