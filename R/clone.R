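#' Call per-CpG methylation on one bisulfite-sequenced clone
#'
#' A clone is a single bisulfite-converted molecule (a Sanger-sequenced
#' plasmid insert). The read is mapped by exact position against the
#' fragment's converted coordinate frame: at every position that was C on
#' the unconverted top strand the read may carry C or T, every other
#' position must match exactly; indel-containing or otherwise unmappable
#' reads are rejected. At each CpG C the call is C = methylated,
#' T = unmethylated; the bisulfite conversion rate is the fraction of
#' covered non-CpG C positions read as T (unconverted non-CpG cytosines
#' betray incomplete chemistry).
#'
#' @param read nucleotide string (one clone, 5'->3' of the top strand).
#' @param frag the `msp_fragment` the amplicon derives from.
#' @return list with `offset` (0-based mapping position), `calls` (named
#'   character vector, `"M"`/`"U"`/`NA` per covered CpG, names = TSS
#'   coordinates), `conversion_rate`, `n_nonCpG_C`. Unmappable reads raise
#'   an error of class `mspkit_unmappable`.
#' @export
call_clone <- function(read, frag) {
  stopifnot(inherits(frag, "msp_fragment"))
  read <- toupper(read)
  if (!grepl("^[ACGT]+$", read)) stop("clone read must be A/C/G/T", call. = FALSE)
  och <- strsplit(frag$seq, "", fixed = TRUE)[[1]]
  rch <- strsplit(read, "", fixed = TRUE)[[1]]
  L <- length(och); n <- length(rch)
  if (n > L) {
    stop(structure(class = c("mspkit_unmappable", "error", "condition"),
                   list(message = "read longer than fragment", call = NULL)))
  }
  sites <- find_cpg_sites(frag)
  is_cpg_c <- rep(FALSE, L); is_cpg_c[sites$local + 1L] <- TRUE

  hits <- integer(0)
  for (s in 0:(L - n)) {
    idx <- s + seq_len(n)
    tmpl <- och[idx]
    okpos <- ifelse(tmpl == "C", rch %in% c("C", "T"), rch == tmpl)
    if (all(okpos)) hits <- c(hits, s)
    if (length(hits) > 1L) break
  }
  if (length(hits) == 0L) {
    stop(structure(class = c("mspkit_unmappable", "error", "condition"),
                   list(message = "read does not map to the fragment's converted frame",
                        call = NULL)))
  }
  if (length(hits) > 1L) {
    stop(structure(class = c("mspkit_unmappable", "error", "condition"),
                   list(message = "ambiguous mapping (multiple compatible offsets)",
                        call = NULL)))
  }
  s <- hits[1L]
  covered <- sites[sites$local >= s & sites$local <= s + n - 1L, ]
  read_at <- function(local) rch[local - s + 1L]
  calls <- vapply(covered$local, function(l) {
    b <- read_at(l)
    if (b == "C") "M" else if (b == "T") "U" else NA_character_
  }, character(1))
  names(calls) <- sprintf("%+d", covered$tss)

  nonc <- which(och == "C") - 1L
  nonc <- setdiff(nonc, sites$local)
  nonc <- nonc[nonc >= s & nonc <= s + n - 1L]
  rate <- if (length(nonc) == 0L) NA_real_ else {
    mean(vapply(nonc, function(l) read_at(l) == "T", logical(1)))
  }
  list(offset = s, calls = calls, conversion_rate = rate,
       n_nonCpG_C = length(nonc))
}

#' Call a set of clone reads into a clone-by-CpG matrix
#'
#' Clones whose conversion rate falls below `qc_threshold` are flagged
#' (`qc_pass = FALSE`) and excluded from downstream frequencies; unmappable
#' reads are dropped and reported in the `rejected` attribute.
#'
#' @param reads tibble/data.frame with columns `id`, `group`, `seq` (as
#'   produced by [simulate_clone_reads()] or read from FASTA with
#'   `group=<label>` descriptions).
#' @param frag the `msp_fragment`.
#' @param qc_threshold minimum bisulfite conversion rate (default 0.95,
#'   standard bisulfite QC practice).
#' @return a `clone_call_matrix`: tibble with `clone`, `group`,
#'   `conversion_rate`, `qc_pass`, then one `"M"`/`"U"`/NA column per CpG
#'   site labelled by its signed TSS coordinate. Attribute `rejected` lists
#'   unmappable clone ids.
#' @export
call_clones <- function(reads, frag, qc_threshold = 0.95) {
  stopifnot(all(c("id", "group", "seq") %in% names(reads)))
  sites <- find_cpg_sites(frag)
  labels <- sprintf("%+d", sites$tss)
  rows <- list(); rejected <- character(0)
  for (i in seq_len(nrow(reads))) {
    res <- tryCatch(call_clone(reads$seq[i], frag),
                    mspkit_unmappable = function(e) NULL)
    if (is.null(res)) { rejected <- c(rejected, reads$id[i]); next }
    calls <- stats::setNames(rep(NA_character_, length(labels)), labels)
    calls[names(res$calls)] <- res$calls
    rate <- res$conversion_rate
    rows[[length(rows) + 1L]] <- c(
      list(clone = reads$id[i], group = reads$group[i],
           conversion_rate = rate,
           qc_pass = is.na(rate) || rate >= qc_threshold),
      as.list(calls))
  }
  out <- do.call(rbind, lapply(rows, function(r) tibble::as_tibble(r)))
  if (is.null(out)) {
    out <- tibble::as_tibble(c(list(clone = character(), group = character(),
                                    conversion_rate = numeric(),
                                    qc_pass = logical()),
                               stats::setNames(rep(list(character()),
                                                   length(labels)), labels)))
  }
  out <- out[order(out$clone), ]
  attr(out, "rejected") <- rejected
  attr(out, "site_labels") <- labels
  class(out) <- c("clone_call_matrix", class(out))
  out
}

site_columns <- function(mat) {
  lab <- attr(mat, "site_labels")
  if (is.null(lab)) lab <- grep("^[+-][0-9]+$", names(mat), value = TRUE)
  lab
}

round_half_up <- function(x, digits = 0) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Per-site unmethylated fractions
#'
#' Fraction unmethylated = U / (U + M) over QC-passing clones, missing calls
#' excluded; `percent` is rounded half-up for display, matching how clone
#' counts are conventionally reported (13 of 17 -> 76 percent).
#'
#' @param mat a `clone_call_matrix`.
#' @param group optional group label to restrict to.
#' @return tibble with `site`, `n_unmethylated`, `n_methylated`, `fraction`
#'   (NA when no informative clone) and `percent`.
#' @export
site_frequencies <- function(mat, group = NULL) {
  labs <- site_columns(mat)
  dat <- mat[mat$qc_pass, , drop = FALSE]
  if (!is.null(group)) dat <- dat[dat$group %in% group, , drop = FALSE]
  if (nrow(dat) == 0L) stop("no QC-passing clones in the requested group", call. = FALSE)
  res <- lapply(labs, function(lb) {
    v <- dat[[lb]]
    u <- sum(v == "U", na.rm = TRUE); m <- sum(v == "M", na.rm = TRUE)
    frac <- if (u + m == 0L) NA_real_ else u / (u + m)
    tibble::tibble(site = lb, n_unmethylated = u, n_methylated = m,
                   fraction = frac,
                   percent = if (is.na(frac)) NA_real_ else round_half_up(100 * frac))
  })
  do.call(rbind, res)
}

#' Two-sided Fisher exact test on one CpG site's 2x2 table
#'
#' Unmethylated/methylated counts in two groups; two-sided by summation of
#' all tables with point probability not exceeding the observed one (the
#' QUMA convention, identical to [stats::fisher.test()]). A degenerate
#' table (a zero margin) returns p = 1 by convention.
#'
#' @param a_unmethylated,a_methylated counts in group A.
#' @param b_unmethylated,b_methylated counts in group B.
#' @return list with `p_value` and `degenerate`.
#' @export
site_fisher_test <- function(a_unmethylated, a_methylated,
                             b_unmethylated, b_methylated) {
  tab <- matrix(c(a_unmethylated, a_methylated,
                  b_unmethylated, b_methylated), nrow = 2, byrow = TRUE)
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  p <- if (degenerate) 1 else stats::fisher.test(tab, alternative = "two.sided")$p.value
  list(p_value = min(p, 1), degenerate = degenerate)
}

#' Compare per-site methylation between two clone groups
#'
#' Builds the per-site 2x2 tables (missing calls excluded) and applies the
#' two-sided Fisher exact test; no multiple-testing correction is applied.
#'
#' @param mat a `clone_call_matrix`.
#' @param group_a,group_b group labels (each may name several groups, e.g.
#'   pooling all non-beta tissues).
#' @return tibble: `site`, counts for both groups, `p_value`, `degenerate`.
#' @export
compare_sites <- function(mat, group_a, group_b) {
  fa <- site_frequencies(mat, group_a)
  fb <- site_frequencies(mat, group_b)
  res <- lapply(seq_len(nrow(fa)), function(i) {
    ft <- site_fisher_test(fa$n_unmethylated[i], fa$n_methylated[i],
                           fb$n_unmethylated[i], fb$n_methylated[i])
    tibble::tibble(site = fa$site[i],
                   a_unmethylated = fa$n_unmethylated[i],
                   a_methylated = fa$n_methylated[i],
                   b_unmethylated = fb$n_unmethylated[i],
                   b_methylated = fb$n_methylated[i],
                   p_value = ft$p_value, degenerate = ft$degenerate)
  })
  do.call(rbind, res)
}

#' Text lollipop rendering of a clone-call matrix
#'
#' One row per clone (stable ordering by clone id within group), one column
#' per CpG site: `*` methylated, `o` unmethylated, `.` missing. Totals per
#' site and group accompany the grid.
#'
#' @param mat a `clone_call_matrix`.
#' @return object of class `lollipop_summary`: `grids` (named character
#'   vectors of rows per group), `counts` (per group x site totals tibble),
#'   `sites`.
#' @export
lollipop_summary <- function(mat) {
  labs <- site_columns(mat)
  if (nrow(mat) == 0L) {
    return(structure(list(grids = list(),
                          counts = tibble::tibble(group = character(),
                                                  site = character()),
                          sites = labs),
                     class = "lollipop_summary"))
  }
  groups <- unique(mat$group)
  sym <- c(M = "*", U = "o")
  grids <- lapply(groups, function(g) {
    d <- mat[mat$group == g, , drop = FALSE]
    d <- d[order(d$clone), , drop = FALSE]
    vapply(seq_len(nrow(d)), function(i) {
      ch <- vapply(labs, function(lb) {
        v <- d[[lb]][i]
        if (is.na(v)) "." else sym[[v]]
      }, character(1))
      paste(ch, collapse = "")
    }, character(1)) |> stats::setNames(d$clone)
  })
  names(grids) <- groups
  counts <- do.call(rbind, lapply(groups, function(g) {
    f <- tryCatch(site_frequencies(mat, group = g), error = function(e) NULL)
    if (is.null(f)) NULL else cbind(tibble::tibble(group = g), f)
  }))
  structure(list(grids = grids, counts = counts, sites = labs),
            class = "lollipop_summary")
}

#' @export
print.lollipop_summary <- function(x, ...) {
  cat("CpG sites:", paste(x$sites, collapse = " "), "\n")
  for (g in names(x$grids)) {
    cat(sprintf("-- %s (%d clones) --\n", g, length(x$grids[[g]])))
    for (nm in names(x$grids[[g]])) cat(sprintf("  %-12s %s\n", nm, x$grids[[g]][[nm]]))
  }
  invisible(x)
}
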