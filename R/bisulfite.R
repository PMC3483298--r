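#' Reverse complement
#'
#' Standard Watson-Crick reverse complement of an A/C/G/T string (an
#' involution). Thin wrapper over Biostrings.
#'
#' @param seq character vector of nucleotide strings.
#' @return character vector of the same length.
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq))
  if (!all(grepl("^[ACGT]+$", seq))) {
    stop("reverse_complement: sequences must contain only A/C/G/T", call. = FALSE)
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Per-CpG methylation profiles
#'
#' A profile assigns methylated/unmethylated to each CpG site of one
#' fragment -- no extras, no gaps. One profile applies to both strands
#' (CpG methylation is symmetric; hemimethylation is not modelled).
#' `state = "methylated"` mirrors an M.SssI-treated template,
#' `"unmethylated"` a mock-treated one.
#'
#' @param frag an `msp_fragment`.
#' @param state either a single string `"methylated"`/`"unmethylated"`, or a
#'   logical vector (TRUE = methylated) with one element per CpG site.
#' @return object of class `methylation_profile`: fields `fragment`,
#'   `site_tss`, `methylated` (logical), `label`.
#' @examples
#' frag <- fragment("toy", "ACGCGA", -3)
#' methylation_profile(frag, "unmethylated")
#' @export
methylation_profile <- function(frag, state) {
  stopifnot(inherits(frag, "msp_fragment"))
  sites <- find_cpg_sites(frag)
  if (is.character(state) && length(state) == 1L) {
    state <- match.arg(state, c("methylated", "unmethylated"))
    meth <- rep(state == "methylated", nrow(sites))
    label <- state
  } else {
    if (!is.logical(state) || length(state) != nrow(sites) || anyNA(state)) {
      stop("profile must cover exactly the fragment's ", nrow(sites),
           " CpG site(s)", call. = FALSE)
    }
    meth <- state
    label <- if (all(meth)) "methylated" else if (!any(meth)) "unmethylated" else "mixed"
  }
  structure(list(fragment = frag$name, site_tss = sites$tss,
                 site_local = sites$local, methylated = meth, label = label),
            class = "methylation_profile")
}

#' @export
print.methylation_profile <- function(x, ...) {
  cat(sprintf("<methylation_profile> %s on %s: %d site(s), %d methylated\n",
              x$label, x$fragment, length(x$methylated), sum(x$methylated)))
  invisible(x)
}

#' In-silico bisulfite conversion
#'
#' Bisulfite treatment deaminates unmethylated cytosine to uracil (read as
#' thymine after PCR) while 5-methylcytosine is protected. On the selected
#' strand every C outside CpG context becomes T; a CpG-context C becomes C
#' or T according to the profile. The bottom strand is the conversion of the
#' reverse complement under the symmetric CpG rule, reported 5' to 3' of
#' that strand.
#'
#' @param frag an `msp_fragment`.
#' @param profile a `methylation_profile` for the same fragment.
#' @param strand `"top"` or `"bottom"`.
#' @return object of class `converted_sequence`: `seq`, `strand`,
#'   `profile_id`, `source`, plus bookkeeping used by primer evaluation:
#'   `cpg_local` (0-based offsets of CpG Cs on this strand), `meth`
#'   (their states), `source_c_local` (offsets that were C on this strand
#'   before conversion) and `frag_tss` of the top-strand C of each site.
#' @examples
#' frag <- fragment("toy", "ACGCGA", -3)
#' bisulfite_convert(frag, methylation_profile(frag, "unmethylated"))$seq  # "ATGTGA"
#' @export
bisulfite_convert <- function(frag, profile, strand = c("top", "bottom")) {
  stopifnot(inherits(frag, "msp_fragment"), inherits(profile, "methylation_profile"))
  strand <- match.arg(strand)
  if (!identical(profile$fragment, frag$name) ||
      !identical(profile$site_local, find_cpg_sites(frag)$local)) {
    stop("profile does not match fragment", call. = FALSE)
  }
  src <- if (strand == "top") frag$seq else reverse_complement(frag$seq)
  n <- nchar(src)
  chars <- strsplit(src, "", fixed = TRUE)[[1]]

  # CpG C offsets on the working strand; CG is its own reverse complement,
  # so bottom-strand sites are the mirror images of the top-strand sites.
  top_c <- profile$site_local                      # 0-based C offsets, top
  if (strand == "top") {
    c_here <- top_c
    meth <- profile$methylated
  } else {
    c_here <- n - 2L - rev(top_c)
    meth <- rev(profile$methylated)
  }
  is_c <- which(chars == "C") - 1L                  # all C offsets, 0-based
  keep <- c_here[meth]                              # protected Cs
  to_t <- setdiff(is_c, keep)
  chars[to_t + 1L] <- "T"

  structure(list(seq = paste(chars, collapse = ""),
                 strand = strand,
                 profile_id = profile$label,
                 source = frag$name,
                 cpg_local = c_here,
                 meth = meth,
                 source_c_local = is_c,
                 site_tss = if (strand == "top") profile$site_tss else rev(profile$site_tss)),
            class = "converted_sequence")
}

#' @export
print.converted_sequence <- function(x, ...) {
  cat(sprintf("<converted_sequence> %s|converted|%s|%s (%d bp)\n",
              x$source, x$strand, x$profile_id, nchar(x$seq)))
  invisible(x)
}
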