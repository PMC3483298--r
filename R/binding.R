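#' Scan a converted template for primer binding sites
#'
#' Exhaustive scan of both orientations: "sense" sites are positions where
#' the primer core equals a template substring (the primer reads like the
#' template strand); "antisense" sites are positions where the reverse
#' complement of the core matches (the primer anneals to the template strand
#' directly, priming leftward). Clamp bases are excluded from mismatch
#' counting, as are 5'-terminal bases overhanging a template end (both are
#' untemplated); the 3' end must always lie on the template. A site is
#' extendable when no mismatch falls within the 3'-terminal window and the
#' total mismatch count is within tolerance -- the all-or-nothing mechanism
#' by which an MSP primer rejects the methylated template.
#'
#' @param p an `msp_primer`.
#' @param template a `converted_sequence`, an `msp_fragment` (matched
#'   unconverted), or a plain character string.
#' @param max_mismatches maximum on-template core mismatches for a site to
#'   be reported.
#' @param three_prime_window number of 3'-terminal bases that must match
#'   perfectly for extension.
#' @param max_overhang maximum number of 5' core bases allowed to overhang a
#'   template end.
#' @return tibble with one row per site: `orientation`, `start`, `end`
#'   (0-based template offsets of the core footprint; `start` may be
#'   negative / `end` beyond the template under a 5' overhang),
#'   `three_prime_local` (template offset paired with the primer's 3' base),
#'   `mismatch_count`, `three_prime_window_mismatches`, `overhang`,
#'   `extendable`. Empty tibble when nothing binds.
#' @export
find_binding_sites <- function(p, template, max_mismatches = 2L,
                               three_prime_window = 2L, max_overhang = 5L) {
  stopifnot(inherits(p, "msp_primer"))
  tpl <- template_string(template)
  tch <- strsplit(tpl, "", fixed = TRUE)[[1]]
  L <- length(tch)
  if (L == 0L) stop("empty template", call. = FALSE)
  core <- strsplit(p$core, "", fixed = TRUE)[[1]]
  n <- length(core)
  rows <- list()

  scan <- function(query, orientation) {
    # query is aligned 5'->3' along the template for both orientations
    # (antisense uses the reverse complement of the core).
    if (orientation == "sense") {
      starts <- seq.int(-min(max_overhang, n - three_prime_window), L - n)
    } else {
      starts <- seq.int(0L, (L - n) + min(max_overhang, n - three_prime_window))
    }
    out <- list()
    for (s in starts) {
      idx <- s + seq_len(n) - 1L          # template offsets of core positions
      on <- idx >= 0L & idx <= L - 1L
      if (orientation == "sense") {
        d3 <- n - seq_len(n) + 1L          # 3'-distance of each core position
      } else {
        d3 <- seq_len(n)
      }
      if (any(d3 <= three_prime_window & !on)) next  # 3' end must be templated
      mm <- on & (query != tch[pmax(idx, 0L) + 1L])
      mmc <- sum(mm)
      if (mmc > max_mismatches) next
      w_mm <- sum(mm & d3 <= three_prime_window)
      out[[length(out) + 1L]] <- tibble::tibble(
        orientation = orientation,
        start = s, end = s + n - 1L,
        three_prime_local = if (orientation == "sense") s + n - 1L else s,
        mismatch_count = mmc,
        three_prime_window_mismatches = w_mm,
        overhang = sum(!on),
        extendable = w_mm == 0L && mmc <= max_mismatches)
    }
    out
  }

  rows <- c(scan(core, "sense"),
            scan(strsplit(reverse_complement(p$core), "", fixed = TRUE)[[1]],
                 "antisense"))
  if (length(rows) == 0L) {
    return(tibble::tibble(orientation = character(), start = integer(),
                          end = integer(), three_prime_local = integer(),
                          mismatch_count = integer(),
                          three_prime_window_mismatches = integer(),
                          overhang = integer(), extendable = logical()))
  }
  out <- do.call(rbind, rows)
  out[order(out$mismatch_count, out$three_prime_window_mismatches, out$start), ]
}

template_string <- function(template) {
  if (inherits(template, "converted_sequence")) template$seq
  else if (inherits(template, "msp_fragment")) template$seq
  else if (is.character(template) && length(template) == 1L) toupper(template)
  else stop("template must be a converted_sequence, msp_fragment or string",
            call. = FALSE)
}

# CpG C offsets of a converted_sequence lying inside [start, end] on-template
covered_cpg <- function(conv, start, end) {
  keep <- conv$cpg_local >= max(start, 0L) &
    conv$cpg_local <= min(end, nchar(conv$seq) - 1L)
  list(local = conv$cpg_local[keep], tss = conv$site_tss[keep])
}

#' Classify a primer as methylation-specific, bisulfite-specific or neither
#'
#' The primer core is aligned against all four converted references
#' (top/bottom strand x all-methylated/all-unmethylated) and against the
#' unconverted fragment. It is methylation-specific (MSP) when it extends
#' from exactly one methylation state with the discriminating CpG read by
#' its 3'-terminal window; bisulfite-specific (BSP) when it extends from
#' both states; and non-bisulfite when it matches the unconverted sequence
#' strictly better than any conversion.
#'
#' @inheritParams find_binding_sites
#' @param frag an `msp_fragment` (its CpG sites define the discrimination).
#' @return object of class `primer_classification`: `klass` (`"MSP"`,
#'   `"BSP"`, `"non-bisulfite"` or `"no-binding"`), `target_state` (for MSP),
#'   `interrogated_sites` (TSS coordinates of CpG sites under the core),
#'   `three_prime_site` (CpG at the exact 3' terminus, or NA),
#'   `n_discriminating`, `binds_unmethylated`, `binds_methylated`, `strand`
#'   of the best site, and the per-reference best-site table `sites`.
#' @export
classify_primer <- function(p, frag, max_mismatches = 2L,
                            three_prime_window = 2L, max_overhang = 5L) {
  stopifnot(inherits(p, "msp_primer"), inherits(frag, "msp_fragment"))
  pu <- methylation_profile(frag, "unmethylated")
  pm <- methylation_profile(frag, "methylated")
  refs <- list(
    unmethylated_top = bisulfite_convert(frag, pu, "top"),
    unmethylated_bottom = bisulfite_convert(frag, pu, "bottom"),
    methylated_top = bisulfite_convert(frag, pm, "top"),
    methylated_bottom = bisulfite_convert(frag, pm, "bottom"))

  best <- lapply(refs, function(r) {
    s <- find_binding_sites(p, r, max_mismatches, three_prime_window, max_overhang)
    if (nrow(s) == 0L) NULL else s[1L, ]
  })
  raw_sites <- find_binding_sites(p, frag, max_mismatches, three_prime_window,
                                  max_overhang)
  raw_best <- if (nrow(raw_sites) > 0L) raw_sites[1L, ] else NULL

  ext <- function(b) !is.null(b) && b$extendable
  ext_u <- ext(best$unmethylated_top) || ext(best$unmethylated_bottom)
  ext_m <- ext(best$methylated_top) || ext(best$methylated_bottom)
  conv_mm <- suppressWarnings(min(vapply(
    Filter(function(b) !is.null(b) && b$extendable, best),
    function(b) b$mismatch_count, integer(1))))

  klass <- "no-binding"; target <- NA_character_
  if (ext(raw_best) && is.finite(conv_mm) == FALSE) {
    klass <- "non-bisulfite"
  } else if (ext(raw_best) && raw_best$mismatch_count < conv_mm) {
    klass <- "non-bisulfite"
  } else if (ext_u && !ext_m) {
    klass <- "MSP"; target <- "unmethylated"
  } else if (ext_m && !ext_u) {
    klass <- "MSP"; target <- "methylated"
  } else if (ext_u && ext_m) {
    klass <- "BSP"
  }

  # interrogated CpG sites from the best unmethylated-reference site
  pick <- if (ext(best$unmethylated_top)) list(best$unmethylated_top, refs$unmethylated_top)
          else if (ext(best$unmethylated_bottom)) list(best$unmethylated_bottom, refs$unmethylated_bottom)
          else if (ext(best$methylated_top)) list(best$methylated_top, refs$methylated_top)
          else if (ext(best$methylated_bottom)) list(best$methylated_bottom, refs$methylated_bottom)
          else NULL
  interrogated <- integer(0); tp_site <- NA_integer_; strand <- NA_character_
  if (!is.null(pick)) {
    cov <- covered_cpg(pick[[2]], pick[[1]]$start, pick[[1]]$end)
    interrogated <- cov$tss
    strand <- pick[[2]]$strand
    hit3 <- cov$local == pick[[1]]$three_prime_local
    if (any(hit3)) tp_site <- cov$tss[hit3]
  }

  site_tbl <- do.call(rbind, lapply(names(best), function(nm) {
    b <- best[[nm]]
    if (is.null(b)) return(NULL)
    cbind(tibble::tibble(reference = nm), b)
  }))

  structure(list(name = p$name, klass = klass, target_state = target,
                 interrogated_sites = interrogated,
                 three_prime_site = tp_site,
                 n_discriminating = length(interrogated),
                 binds_unmethylated = ext_u, binds_methylated = ext_m,
                 strand = strand, sites = site_tbl),
            class = "primer_classification")
}

#' @export
print.primer_classification <- function(x, ...) {
  cat(sprintf("<primer_classification> %s: %s%s\n", x$name, x$klass,
              if (x$klass == "MSP") paste0(" (targets ", x$target_state, " template)") else ""))
  if (length(x$interrogated_sites)) {
    cat("  interrogated CpG site(s):",
        paste(sprintf("%+d", x$interrogated_sites), collapse = ", "),
        if (!is.na(x$three_prime_site))
          sprintf("(3' terminus on %+d)", x$three_prime_site) else "", "\n")
  }
  invisible(x)
}

#' Classify a primer pair
#'
#' A pair is MSP when both primers are methylation-specific, BSP when both
#' are bisulfite-specific, and `mixed` when one of each is combined --
#' mixed pairs interrogate fewer CpG sites and carry only moderate
#' methylation specificity, so they are reported with a warning.
#'
#' @inheritParams classify_primer
#' @param fwd,rev the two `msp_primer`s.
#' @return list with `pair_class`, `forward` and `reverse`
#'   classifications, and `interrogated_sites` (union).
#' @export
classify_pair <- function(fwd, rev, frag, ...) {
  cf <- classify_primer(fwd, frag, ...)
  cr <- classify_primer(rev, frag, ...)
  kk <- sort(c(cf$klass, cr$klass))
  pair_class <- if (all(kk == "MSP")) "MSP"
  else if (all(kk == "BSP")) "BSP"
  else if (setequal(kk, c("BSP", "MSP"))) "mixed"
  else "other"
  if (pair_class == "mixed") {
    warning("mixed MSP/BSP pair: only moderate methylation specificity ",
            "(a single interrogated CpG cannot give fully methylation-specific PCR)",
            call. = FALSE)
  }
  list(pair_class = pair_class, forward = cf, reverse = cr,
       interrogated_sites = sort(union(cf$interrogated_sites,
                                       cr$interrogated_sites)))
}

#' In-silico PCR on a bisulfite-converted template
#'
#' Converts the fragment under the given profile (both strands), finds
#' extendable binding sites for the two primers in convergent orientation,
#' and returns every predicted product within the length limit. Product
#' lengths are clamp-inclusive (untemplated 5' additions are synthesised
#' into the amplicon). An empty result is the in-silico "no band".
#'
#' @inheritParams classify_pair
#' @param profile a `methylation_profile`, or `"methylated"` /
#'   `"unmethylated"` to use the corresponding uniform profile.
#' @param max_product maximum product length, bp.
#' @param max_mismatches,three_prime_window,max_overhang see
#'   [find_binding_sites()].
#' @return tibble with `strand`, `forward`, `reverse`, `start`, `end`
#'   (0-based footprint offsets on that strand), `product_length`, `profile`.
#' @export
insilico_pcr <- function(fwd, rev, frag, profile = "unmethylated",
                         max_product = 2000L, max_mismatches = 2L,
                         three_prime_window = 2L, max_overhang = 5L) {
  stopifnot(inherits(fwd, "msp_primer"), inherits(rev, "msp_primer"),
            inherits(frag, "msp_fragment"))
  if (is.character(profile)) profile <- methylation_profile(frag, profile)
  out <- list()
  for (strand in c("top", "bottom")) {
    conv <- bisulfite_convert(frag, profile, strand)
    for (pair in list(list(fwd, rev), list(rev, fwd))) {
      a <- pair[[1]]; b <- pair[[2]]
      sa <- find_binding_sites(a, conv, max_mismatches, three_prime_window, max_overhang)
      sb <- find_binding_sites(b, conv, max_mismatches, three_prime_window, max_overhang)
      sa <- sa[sa$extendable & sa$orientation == "sense", , drop = FALSE]
      sb <- sb[sb$extendable & sb$orientation == "antisense", , drop = FALSE]
      if (nrow(sa) == 0L || nrow(sb) == 0L) next
      for (i in seq_len(nrow(sa))) for (j in seq_len(nrow(sb))) {
        if (sa$start[i] > sb$start[j] || sa$end[i] > sb$end[j]) next
        len <- (sb$end[j] - sa$start[i] + 1L) +
          nchar(a$clamp) + nchar(b$clamp)
        if (len > max_product || len < max(nchar(a$full), nchar(b$full))) next
        out[[length(out) + 1L]] <- tibble::tibble(
          strand = strand, forward = a$name, reverse = b$name,
          start = sa$start[i], end = sb$end[j],
          product_length = len, profile = profile$label)
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(strand = character(), forward = character(),
                          reverse = character(), start = integer(),
                          end = integer(), product_length = integer(),
                          profile = character()))
  }
  unique(do.call(rbind, out))
}

#' Methylation-specificity report for a primer pair
#'
#' Runs in-silico PCR under the all-methylated and all-unmethylated
#' profiles, classifies both primers, and -- when experimental detection
#' limits are supplied -- computes the analytical specificity ratio
#' LOD(methylated) / LOD(unmethylated), i.e. how many more copies of the
#' wrong template are needed before it is detected.
#'
#' @inheritParams insilico_pcr
#' @param lod_unmethylated,lod_methylated optional detection limits in
#'   template copies; when either is missing the ratio is omitted.
#' @return object of class `specificity_report`.
#' @export
specificity_report <- function(fwd, rev, frag, lod_unmethylated = NULL,
                               lod_methylated = NULL, ...) {
  cls <- suppressWarnings(classify_pair(fwd, rev, frag, ...))
  amp_u <- insilico_pcr(fwd, rev, frag, "unmethylated", ...)
  amp_m <- insilico_pcr(fwd, rev, frag, "methylated", ...)
  ratio <- NULL
  if (!is.null(lod_unmethylated) && !is.null(lod_methylated)) {
    ratio <- lod_methylated / lod_unmethylated
  }
  per_primer <- tibble::tibble(
    primer = c(cls$forward$name, cls$reverse$name),
    klass = c(cls$forward$klass, cls$reverse$klass),
    n_discriminating = c(cls$forward$n_discriminating,
                         cls$reverse$n_discriminating))
  structure(list(
    pair_class = cls$pair_class,
    amplifies_unmethylated = nrow(amp_u) > 0L,
    amplifies_methylated = nrow(amp_m) > 0L,
    methylation_specific = nrow(amp_u) > 0L && nrow(amp_m) == 0L,
    interrogated_sites = cls$interrogated_sites,
    per_primer = per_primer,
    n_discriminating = sum(per_primer$n_discriminating),
    products_unmethylated = amp_u,
    products_methylated = amp_m,
    analytical_specificity = ratio,
    exceeds_1e5 = if (is.null(ratio)) NA else ratio > 1e5),
    class = "specificity_report")
}

#' @export
print.specificity_report <- function(x, ...) {
  cat("<specificity_report>\n")
  cat("  pair class:        ", x$pair_class, "\n")
  cat("  amplifies unmethylated:", x$amplifies_unmethylated,
      " methylated:", x$amplifies_methylated, "\n")
  cat("  verdict:           ",
      if (x$methylation_specific) "methylation-specific"
      else "not methylation-specific", "\n")
  if (length(x$interrogated_sites)) {
    cat("  interrogated CpGs: ",
        paste(sprintf("%+d", x$interrogated_sites), collapse = ", "), "\n")
  }
  if (!is.null(x$analytical_specificity)) {
    cat(sprintf("  analytical specificity: %.3g%s\n", x$analytical_specificity,
                if (isTRUE(x$exceeds_1e5)) " (exceeds 1e5)" else ""))
  }
  invisible(x)
}

#' Whole-blood sensitivity equivalence
#'
#' Scales a per-reaction detection limit to whole-animal terms: with a
#' diploid genome (two target copies per cell), `copies_per_reaction`
#' detected against a background of `background_cells` non-target cells
#' corresponds to `copies_per_reaction / copies_per_cell *
#' total_nucleated_cells / background_cells` target cells distributed in
#' the whole blood volume. Defaults reproduce the mouse arithmetic: 10
#' copies against 1e5 cells, 2e7 circulating nucleated cells per mouse,
#' giving 1000 beta cells (about one islet).
#'
#' @param copies_per_reaction detection limit, template copies per reaction.
#' @param background_cells non-target cell equivalents per reaction.
#' @param total_nucleated_cells circulating nucleated cells in the animal.
#' @param copies_per_cell genome copies per cell (2 for diploid).
#' @return list with `cells_per_reaction` and `whole_blood_cells`.
#' @export
blood_sensitivity_equivalent <- function(copies_per_reaction = 10,
                                         background_cells = 1e5,
                                         total_nucleated_cells = 2e7,
                                         copies_per_cell = 2) {
  cells <- copies_per_reaction / copies_per_cell
  list(cells_per_reaction = cells,
       whole_blood_cells = cells * total_nucleated_cells / background_cells)
}
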