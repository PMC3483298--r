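#' Gene fragments anchored to the TSS
#'
#' A fragment is a fully specified A/C/G/T sequence whose first base sits at
#' a known TSS-relative coordinate. Ambiguity codes are rejected: the
#' templates this toolkit models are cloned, fully known sequences.
#'
#' @param name identifier for the fragment.
#' @param seq nucleotide string, upper- or lower-case A/C/G/T only.
#' @param tss_anchor TSS-relative coordinate of the first base (e.g. -480).
#' @return an object of class `msp_fragment` with elements `name`, `seq`
#'   (uppercase) and `tss_anchor`.
#' @examples
#' frag <- fragment("toy", "ACGTCGA", tss_anchor = -3)
#' fragment_end(frag)
#' @export
fragment <- function(name, seq, tss_anchor) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (!grepl("^[ACGT]+$", seq)) {
    stop("fragment sequence must contain only A/C/G/T (ambiguity codes rejected)",
         call. = FALSE)
  }
  tss_anchor <- validate_tss(tss_anchor)
  structure(list(name = name, seq = seq, tss_anchor = tss_anchor),
            class = "msp_fragment")
}

#' @export
print.msp_fragment <- function(x, ...) {
  cat(sprintf("<msp_fragment> %s: %d bp, anchored at %+d (ends %+d), %d CpG site(s)\n",
              x$name, nchar(x$seq), x$tss_anchor, fragment_end(x),
              nrow(find_cpg_sites(x))))
  invisible(x)
}

#' @rdname fragment
#' @param frag an `msp_fragment`.
#' @return `fragment_end()`: TSS coordinate of the last base.
#' @export
fragment_end <- function(frag) {
  stopifnot(inherits(frag, "msp_fragment"))
  offset_to_tss(tss_offset(frag$tss_anchor) + nchar(frag$seq) - 1L)
}

#' Convert between fragment-local offsets and TSS coordinates
#'
#' Fragment-local offsets are 0-based; TSS coordinates skip zero. The two
#' maps are exact inverses over the fragment.
#'
#' @param frag an `msp_fragment`.
#' @param pos TSS-relative coordinate(s) inside the fragment.
#' @param local 0-based offset(s) inside the fragment.
#' @return integer vector.
#' @export
fragment_local <- function(frag, pos) {
  stopifnot(inherits(frag, "msp_fragment"))
  loc <- tss_offset(pos) - tss_offset(frag$tss_anchor)
  if (any(loc < 0L) || any(loc >= nchar(frag$seq))) {
    stop("coordinate outside fragment", call. = FALSE)
  }
  loc
}

#' @rdname fragment_local
#' @export
fragment_tss <- function(frag, local) {
  stopifnot(inherits(frag, "msp_fragment"))
  local <- as.integer(local)
  if (any(local < 0L) || any(local >= nchar(frag$seq))) {
    stop("offset outside fragment", call. = FALSE)
  }
  offset_to_tss(tss_offset(frag$tss_anchor) + local)
}

#' Locate CpG dinucleotides on the top strand
#'
#' Every position i with base C followed by G yields one site. Sites are
#' returned 5' to 3'; overlap is impossible by construction. CHH/CHG
#' (non-CpG) methylation is not modelled.
#'
#' @param frag an `msp_fragment`.
#' @return a tibble with columns `index` (0-based ordinal), `local`
#'   (0-based offset of the C) and `tss` (TSS coordinate of the C).
#' @examples
#' find_cpg_sites(fragment("toy", "ACGTCGA", -3))
#' @export
find_cpg_sites <- function(frag) {
  stopifnot(inherits(frag, "msp_fragment"))
  loc <- as.integer(gregexpr("CG", frag$seq, fixed = TRUE)[[1]])
  if (length(loc) == 1L && loc[1] == -1L) {
    return(tibble::tibble(index = integer(), local = integer(), tss = integer()))
  }
  loc <- loc - 1L  # 0-based offset of the C
  tibble::tibble(index = seq_along(loc) - 1L,
                 local = loc,
                 tss = fragment_tss(frag, loc))
}

#' Read fragments from FASTA
#'
#' Record ids become fragment names; a `tss_anchor=<int>` token in the
#' description supplies the anchor (default +1 when absent).
#'
#' @param path FASTA file.
#' @return list of `msp_fragment` objects.
#' @export
read_fragments <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(set), function(i) {
    full <- names(set)[i]
    name <- strsplit(full, "[ |]")[[1]][1]
    anchor <- 1L
    m <- regmatches(full, regexpr("tss_anchor=-?[0-9]+", full))
    if (length(m) == 1L) anchor <- as.integer(sub("tss_anchor=", "", m))
    fragment(name, as.character(set[[i]]), anchor)
  })
}

#' Write fragments or converted sequences to FASTA
#'
#' Converted sequences carry `|converted|<strand>|<profile>` appended to the
#' record id; fragments carry their `tss_anchor` in the description.
#'
#' @param x a list of `msp_fragment` or `converted_sequence` objects (or a
#'   single one).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, c("msp_fragment", "converted_sequence"))) x <- list(x)
  ids <- vapply(x, function(el) {
    if (inherits(el, "msp_fragment")) {
      sprintf("%s tss_anchor=%d", el$name, el$tss_anchor)
    } else {
      sprintf("%s|converted|%s|%s", el$source, el$strand, el$profile_id)
    }
  }, character(1))
  seqs <- vapply(x, function(el) el$seq, character(1))
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
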