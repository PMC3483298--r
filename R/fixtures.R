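#' Packaged oligonucleotide table
#'
#' The published primer set for the mouse insulin-gene (Ins2) assays:
#' cloning and exon-2 mapping primers, the first-generation bisulfite
#' primers P1-P6, and the clamped redesigns P12/P13 (qMSP) and P16/P17
#' (qBSP). The `clamp` column marks the untemplated 5' additions.
#'
#' @return tibble with `id`, `name`, `sequence` (full oligo), `clamp`,
#'   `core` (sequence minus clamp), `orientation`, `role`.
#' @export
ins2_primers <- function() {
  path <- system.file("extdata", "ins2_primers.csv", package = "mspkit",
                      mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$clamp[is.na(d$clamp)] <- ""
  d$core <- substring(d$sequence, nchar(d$clamp) + 1L)
  tibble::as_tibble(d)
}

#' Build an `msp_primer` from the packaged table
#'
#' @param id primer id (e.g. `"P12"`).
#' @return an `msp_primer` with the clamp annotated.
#' @export
ins2_primer <- function(id) {
  d <- ins2_primers()
  row <- d[d$id == id, ]
  if (nrow(row) != 1L) stop("unknown primer id: ", id, call. = FALSE)
  primer(row$id, row$core, clamp = row$clamp, orientation = row$orientation)
}

#' Packaged qMSP standard-curve variation table
#'
#' Per-dilution-level mean Cq and SD for the qMSP standard curve (eleven
#' 3-fold levels, n = 12 replicates each), with the CV column as printed.
#'
#' @return tibble with `log_copies`, `mean_cq`, `sd`, `cv_printed`.
#' @export
qmsp_curve_levels <- function() {
  tibble::as_tibble(utils::read.csv(
    system.file("extdata", "qmsp_curve_levels.csv", package = "mspkit",
                mustWork = TRUE)))
}

#' Packaged inter-assay reproducibility replicates
#'
#' Three replicate assays (run on separate days) of the Relative Expression
#' Ratio and Demethylation Index at four post-treatment days, with the
#' printed summary columns.
#'
#' @return tibble with `method`, `day`, `assay1..assay3`, `mean_printed`,
#'   `sd_printed`, `cv_printed`.
#' @export
interassay_replicates <- function() {
  tibble::as_tibble(utils::read.csv(
    system.file("extdata", "interassay_replicates.csv", package = "mspkit",
                mustWork = TRUE)))
}

#' Packaged exon-2 clone counts
#'
#' Per-CpG unmethylated-clone counts for the beta-cell-enriched fraction
#' (17 clones) and pooled non-beta tissues (23 clones) at the four exon-2
#' CpG sites.
#'
#' @return tibble with `site`, `group`, `n_unmethylated`, `n_clones`.
#' @export
exon2_clone_counts <- function() {
  tibble::as_tibble(utils::read.csv(
    system.file("extdata", "exon2_clone_counts.csv", package = "mspkit",
                mustWork = TRUE), check.names = FALSE,
    colClasses = c(site = "character")))
}

#' Clone-call matrix reconstructed from the exon-2 counts
#'
#' A synthetic clone-by-CpG matrix whose per-site marginals equal the
#' published counts (per-clone joint patterns are not published, so within
#' each group the unmethylated calls at each site are assigned to the
#' lowest-numbered clones). Site frequencies and per-site exact tests
#' depend only on these marginals.
#'
#' @return a `clone_call_matrix`.
#' @export
exon2_clone_matrix <- function() {
  counts <- exon2_clone_counts()
  sites <- unique(counts$site)
  groups <- unique(counts$group)
  rows <- list()
  for (g in groups) {
    n <- unique(counts$n_clones[counts$group == g])
    for (i in seq_len(n)) {
      calls <- vapply(sites, function(s) {
        u <- counts$n_unmethylated[counts$group == g & counts$site == s]
        if (i <= u) "U" else "M"
      }, character(1))
      rows[[length(rows) + 1L]] <- c(
        list(clone = sprintf("%s_%02d", g, i), group = g,
             conversion_rate = 1, qc_pass = TRUE),
        as.list(stats::setNames(calls, sites)))
    }
  }
  out <- do.call(rbind, lapply(rows, tibble::as_tibble))
  attr(out, "site_labels") <- sites
  class(out) <- c("clone_call_matrix", class(out))
  out
}
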