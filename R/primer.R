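#' MSP/BSP primers
#'
#' A primer is a template-complementary core plus an optional untemplated
#' GC-rich 5' clamp; the synthesised oligo is `clamp + core`. Clamps are
#' excluded from template matching (they are untemplated by construction)
#' but included in melting temperature and product length.
#'
#' @param name identifier.
#' @param core template-complementary region, A/C/G/T.
#' @param clamp untemplated 5' addition, possibly empty; at most 20 nt.
#' @param orientation `"forward"` (same sense as the converted template the
#'   assay was designed on) or `"reverse"`.
#' @return object of class `msp_primer` with fields `name`, `core`, `clamp`,
#'   `orientation` and `full` (clamp + core).
#' @examples
#' primer("P12", "TTTTTATTTTTGAGAGAGAGTTGGGGATTT", clamp = "GCAGG")
#' @export
primer <- function(name, core, clamp = "", orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  stopifnot(is.character(core), length(core) == 1L,
            is.character(clamp), length(clamp) == 1L)
  core <- toupper(core); clamp <- toupper(clamp)
  if (!grepl("^[ACGT]+$", core)) stop("primer core must be A/C/G/T", call. = FALSE)
  if (nchar(clamp) > 0L && !grepl("^[ACGT]+$", clamp)) {
    stop("primer clamp must be A/C/G/T", call. = FALSE)
  }
  if (nchar(clamp) > 20L) stop("clamp longer than 20 nt", call. = FALSE)
  full <- paste0(clamp, core)
  if (nchar(full) < 15L) stop("primer shorter than 15 nt", call. = FALSE)
  structure(list(name = name, core = core, clamp = clamp,
                 orientation = orientation, full = full),
            class = "msp_primer")
}

#' @export
print.msp_primer <- function(x, ...) {
  cat(sprintf("<msp_primer> %s (%s): 5'-%s%s-3' (%d nt%s)\n",
              x$name, x$orientation,
              if (nzchar(x$clamp)) paste0("[", x$clamp, "]") else "",
              x$core, nchar(x$full),
              if (nzchar(x$clamp)) paste0(", clamp ", nchar(x$clamp), " nt") else ""))
  invisible(x)
}

#' Attach an explicit 5' clamp
#'
#' @param p an `msp_primer`.
#' @param clamp clamp sequence to prepend (replaces any existing clamp).
#' @param name optional new name.
#' @return clamped `msp_primer`; the core (and so the 3' terminus) is
#'   untouched.
#' @export
add_clamp <- function(p, clamp, name = p$name) {
  stopifnot(inherits(p, "msp_primer"))
  primer(name, p$core, clamp = clamp, orientation = p$orientation)
}

#' Design a GC clamp to raise and match melting temperatures
#'
#' Grows an untemplated GC-rich 5' addition (letters drawn with the given GC
#' fraction, seeded) of minimal length such that the full-oligo Tm reaches
#' `target_tm` and, when a partner primer is supplied, the two Tms agree
#' within `tm_tolerance`. The core's 3' terminus is never altered, so
#' methylation specificity is untouched. If the target cannot be reached
#' within `max_clamp` nucleotides, an error of class
#' `mspkit_design_failure` reports the best achievable Tm.
#'
#' @param p an `msp_primer`.
#' @param target_tm desired Tm, degrees Celsius; must be at least the
#'   primer's current Tm.
#' @param partner optional `msp_primer` whose (post-clamp) Tm must be
#'   matched within `tm_tolerance`.
#' @param tm_tolerance allowed |Tm difference| versus the partner, degrees
#'   Celsius.
#' @param gc_fraction GC weight of the clamp alphabet.
#' @param max_clamp maximum clamp length, nt.
#' @param seed integer seed for the clamp-letter draws.
#' @param ... passed to [melting_temperature()].
#' @return clamped `msp_primer`.
#' @export
design_clamp <- function(p, target_tm, partner = NULL, tm_tolerance = 2,
                         gc_fraction = 0.8, max_clamp = 20L, seed = 1L, ...) {
  stopifnot(inherits(p, "msp_primer"))
  tm_now <- melting_temperature(p$full, ...)
  if (target_tm < tm_now) {
    stop("target_tm below the primer's current Tm (", round(tm_now, 1), " C)",
         call. = FALSE)
  }
  ok <- function(tm) {
    tm >= target_tm &&
      (is.null(partner) || abs(tm - melting_temperature(partner$full, ...)) <= tm_tolerance)
  }
  if (ok(tm_now)) return(p)
  probs <- c(G = gc_fraction / 2, C = gc_fraction / 2,
             A = (1 - gc_fraction) / 2, T = (1 - gc_fraction) / 2)
  letters_drawn <- withr::with_seed(seed,
    sample(names(probs), max_clamp, replace = TRUE, prob = probs))
  best_tm <- tm_now
  clamp <- p$clamp
  for (ltr in letters_drawn) {
    if (nchar(clamp) >= max_clamp) break
    clamp <- paste0(ltr, clamp)
    cand <- primer(p$name, p$core, clamp = clamp, orientation = p$orientation)
    tm <- melting_temperature(cand$full, ...)
    best_tm <- max(best_tm, tm)
    if (ok(tm)) return(cand)
  }
  stop(structure(class = c("mspkit_design_failure", "error", "condition"),
                 list(message = sprintf(
                        "could not reach Tm %.1f C within a %d-nt clamp (best achievable %.1f C)",
                        target_tm, max_clamp, best_tm),
                      call = NULL, best_tm = best_tm)))
}
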