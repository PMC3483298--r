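#' TSS-relative coordinates
#'
#' All genomic positions in this package are expressed relative to the
#' transcription start site (TSS) with no position zero: +1 is the first
#' transcribed base and -1 the base immediately upstream. Internally,
#' coordinates are mapped onto consecutive integer offsets so that interval
#' arithmetic is ordinary subtraction.
#'
#' `tss_offset()` maps a TSS coordinate onto that consecutive integer scale
#' (..., -2, -1, +1, +2, ... become ..., -2, -1, 0, 1, ...);
#' `offset_to_tss()` is its inverse.
#'
#' @param pos integer vector of TSS-relative coordinates; zero is forbidden.
#' @return `tss_offset()`: integer vector of consecutive offsets.
#' @examples
#' tss_offset(c(-1, 1))       # -1, 0
#' offset_to_tss(tss_offset(-480))  # round trip
#' @export
tss_offset <- function(pos) {
  pos <- validate_tss(pos)
  ifelse(pos < 0L, pos, pos - 1L)
}

#' @rdname tss_offset
#' @param off integer vector of consecutive offsets.
#' @return `offset_to_tss()`: integer vector of TSS coordinates (never zero).
#' @export
offset_to_tss <- function(off) {
  off <- as.integer(off)
  ifelse(off < 0L, off, off + 1L)
}

validate_tss <- function(pos) {
  if (!is.numeric(pos) || any(is.na(pos)) || any(pos != as.integer(pos))) {
    stop("TSS coordinates must be non-missing integers", call. = FALSE)
  }
  pos <- as.integer(pos)
  if (any(pos == 0L)) {
    stop("TSS coordinate 0 does not exist (+1 is the first transcribed base, -1 the base upstream)",
         call. = FALSE)
  }
  pos
}

#' Inclusive length of a TSS-relative interval
#'
#' Span in base pairs from coordinate `a` to coordinate `b` (both included)
#' under the no-position-zero convention. The cloned insulin-gene interval
#' from -480 to +362 is 842 bp.
#'
#' @param a,b TSS-relative coordinates; `a` must not lie after `b`.
#' @return positive integer, length in bp.
#' @examples
#' interval_length(-480, 362)  # 842
#' interval_length(-1, 1)      # 2
#' @export
interval_length <- function(a, b) {
  ua <- tss_offset(a)
  ub <- tss_offset(b)
  if (any(ua > ub)) stop("interval start lies after its end", call. = FALSE)
  as.integer(ub - ua + 1L)
}
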