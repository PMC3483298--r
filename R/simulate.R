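#' Specification of a synthetic fragment
#'
#' Describes a fragment to be generated: total length, TSS anchor, CpG
#' positions, primer footprints to embed, and the approximate GC content of
#' the remainder. Embedded sites are given as the primer core plus the TSS
#' coordinate of the template base paired with the primer's 3' terminus
#' (`tss3`); reverse-orientation sites are written as the reverse
#' complement of the core extending rightward from `tss3`.
#'
#' The generator works on the bisulfite-converted unmethylated top strand
#' and then "unconverts" it: declared CpG positions become C, and decoy
#' non-CpG cytosines are sprinkled onto eligible T positions (so that
#' conversion-rate accounting and non-bisulfite classification have
#' something to chew on) while guaranteeing that no CpG other than the
#' declared ones can arise.
#'
#' @param length fragment length, bp.
#' @param tss_anchor TSS coordinate of the first base.
#' @param cpg_tss TSS coordinates of the CpG cytosines.
#' @param sites list of embedded sites, each
#'   `list(seq =, tss3 =, orientation = "sense"|"antisense")`.
#' @param gc_fraction approximate GC fraction of the unconstrained
#'   remainder.
#' @param name fragment name.
#' @return object of class `fragment_spec`.
#' @export
fragment_spec <- function(length, tss_anchor, cpg_tss, sites = list(),
                          gc_fraction = 0.5, name = "synthetic") {
  stopifnot(length > 0, gc_fraction >= 0, gc_fraction <= 1)
  structure(list(length = as.integer(length),
                 tss_anchor = validate_tss(tss_anchor),
                 cpg_tss = validate_tss(cpg_tss),
                 sites = sites, gc_fraction = gc_fraction, name = name),
            class = "fragment_spec")
}

#' Synthetic insulin-gene fragment specification
#'
#' The packaged default: an 842 bp fragment anchored at -480 carrying nine
#' CpG sites at -414, -182 and -171 (promoter), +14 (exon 1), +121
#' (intron 1) and +190, +310, +337, +340 (exon 2), with the published
#' bisulfite primer footprints embedded so that the printed MSP primers
#' amplify only the unmethylated conversion and the BSP primers amplify
#' both. It is a synthetic stand-in for the cloned fragment, not the real
#' genomic sequence.
#'
#' @return a `fragment_spec`.
#' @export
ins2_fragment_spec <- function() {
  pr <- ins2_primers()
  core <- function(id) {
    row <- pr[pr$id == id, ]
    substring(row$sequence, nchar(row$clamp) + 1L)
  }
  # sites are written in order; later writes may conflict with earlier ones
  # at up to 2 positions outside their 3' window (the published primers are
  # mutually inconsistent at single bases -- see the P6/P13 footprints).
  sites <- list(
    list(seq = core("P1"), tss3 = -452L, orientation = "sense"),      # BSP For
    list(seq = core("P6"), tss3 = -171L, orientation = "antisense"),  # MSP Rev
    list(seq = core("P12"), tss3 = -414L, orientation = "sense"),     # MSP For
    list(seq = core("P13"), tss3 = -171L, orientation = "antisense"),
    list(seq = core("P17"), tss3 = -166L, orientation = "antisense"), # BSP Rev
    list(seq = core("P5"), tss3 = -182L, orientation = "sense"),      # MSP For
    list(seq = core("P2"), tss3 = -80L, orientation = "antisense"),   # BSP Rev
    list(seq = core("P3"), tss3 = 337L, orientation = "antisense"))   # MSP Rev
  fragment_spec(842L, -480L,
                cpg_tss = c(-414L, -182L, -171L, 14L, 121L, 190L, 310L,
                            337L, 340L),
                sites = sites, gc_fraction = 0.5, name = "Ins2-synthetic")
}

#' Generate a fragment from a specification
#'
#' Deterministic in `(spec, seed)`. Construction and its guarantees:
#' declared CpG cytosines appear exactly at the requested positions and
#' nowhere else; embedded primer cores match the unmethylated top-strand
#' conversion at every position the construction can honour, with
#' unresolvable single-base conflicts (and core bases that would require a
#' non-CpG C on a converted strand) left as mismatches, which must stay out
#' of the site's 3' window and within the default binding tolerance;
#' remaining positions are filled from A/G/T and decoy non-CpG cytosines
#' are added where they cannot create a CpG.
#'
#' @param spec a `fragment_spec`.
#' @param seed integer seed.
#' @return an `msp_fragment`.
#' @export
make_fragment <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "fragment_spec"))
  L <- spec$length
  anchor_off <- tss_offset(spec$tss_anchor)
  loc_of <- function(tss) tss_offset(tss) - anchor_off
  cpg <- sort(loc_of(spec$cpg_tss))
  if (any(cpg < 0L) || any(cpg + 1L > L - 1L)) {
    stop("CpG position outside fragment", call. = FALSE)
  }
  if (any(diff(cpg) < 2L)) stop("overlapping CpG sites", call. = FALSE)

  conv <- rep(NA_character_, L)        # unmethylated top-strand conversion
  conv[cpg + 1L] <- "T"                # CpG C reads T when unmethylated
  conv[cpg + 2L] <- "G"
  is_cpg_c <- rep(FALSE, L); is_cpg_c[cpg + 1L] <- TRUE

  for (site in spec$sites) {
    q <- toupper(site$seq)
    n <- nchar(q)
    ori <- match.arg(site$orientation, c("sense", "antisense"))
    if (ori == "antisense") q <- reverse_complement(q)
    qch <- strsplit(q, "", fixed = TRUE)[[1]]
    s <- if (ori == "sense") loc_of(site$tss3) - n + 1L else loc_of(site$tss3)
    idx <- s + seq_len(n) - 1L
    on <- idx >= 0L & idx <= L - 1L
    if (sum(!on) > 10L) stop("embedded site mostly outside fragment", call. = FALSE)
    d3 <- if (ori == "sense") n - seq_len(n) + 1L else seq_len(n)
    mism <- 0L
    for (k in seq_len(n)) {
      if (!on[k]) next
      pos <- idx[k] + 1L
      want <- qch[k]
      writable <- !(want == "C" && !is_cpg_c[idx[k]])  # no non-CpG C on a converted strand
      if (is.na(conv[pos]) && writable) {
        conv[pos] <- want
      } else if (is.na(conv[pos]) || conv[pos] != want) {
        if (d3[k] <= 2L) {
          stop("embedded-site conflict inside a 3' window (infeasible spec)",
               call. = FALSE)
        }
        mism <- mism + 1L
      }
    }
    if (mism > 2L) {
      stop("embedded site accumulates more than 2 mismatches (infeasible spec)",
           call. = FALSE)
    }
  }

  withr::with_seed(seed, {
    todo <- which(is.na(conv))
    if (length(todo)) {
      gw <- spec$gc_fraction / 2
      conv[todo] <- sample(c("A", "T", "G"), length(todo), replace = TRUE,
                           prob = c((1 - gw) / 2, (1 - gw) / 2, gw))
    }
    # decoy non-CpG cytosines: original C at T positions not followed by G
    orig <- conv
    orig[cpg + 1L] <- "C"
    eligible <- which(orig == "T")
    eligible <- eligible[eligible < L]            # keep last base simple
    eligible <- eligible[orig[eligible + 1L] != "G"]
    n_decoy <- round(length(eligible) * spec$gc_fraction / 2)
    if (n_decoy > 0L) {
      orig[sample(eligible, n_decoy)] <- "C"
    }
  })

  frag <- fragment(spec$name, paste(orig, collapse = ""), spec$tss_anchor)
  found <- find_cpg_sites(frag)
  if (!identical(found$local, cpg)) {
    stop("internal error: generated fragment has unexpected CpG sites", call. = FALSE)
  }
  conv_check <- bisulfite_convert(frag,
                                  methylation_profile(frag, "unmethylated"),
                                  "top")$seq
  if (!identical(conv_check, paste(conv, collapse = ""))) {
    stop("internal error: conversion of the generated fragment drifted", call. = FALSE)
  }
  frag
}

#' Cq-simulation configuration
#'
#' Generative model for quantification cycles: the effective template of an
#' MSP reaction is `copies_unmethylated + leakage x copies_methylated`
#' (imperfect specificity enters as a copy-number attenuation, default
#' 1e-5 from the observed analytical specificity), while BSP sees the total.
#' Then Cq = intercept - log_A(N) + Gaussian noise, censored at the
#' no-detect ceiling of 40 cycles. Default amplification factors correspond
#' to the measured efficiencies (93.34 percent MSP, 91.47 percent BSP); the
#' intercept places 1e6 copies near Cq 18 as on the printed curve.
#'
#' @param intercept Cq at a single template copy.
#' @param a_msp,a_bsp per-cycle amplification factors of the two assays.
#' @param noise_sd Gaussian Cq noise, cycles.
#' @param leakage probability-scale amplification of methylated template by
#'   the MSP assay.
#' @param ceiling no-detect Cq ceiling.
#' @return list of class `cq_sim_config`.
#' @export
cq_sim_config <- function(intercept = 38.7, a_msp = 1.9334, a_bsp = 1.9147,
                          noise_sd = 0.3, leakage = 1e-5, ceiling = 40) {
  stopifnot(leakage >= 0, leakage <= 1, noise_sd >= 0, a_msp > 1, a_bsp > 1)
  structure(list(intercept = intercept, a_msp = a_msp, a_bsp = a_bsp,
                 noise_sd = noise_sd, leakage = leakage, ceiling = ceiling),
            class = "cq_sim_config")
}

#' Simulate quantification cycles
#'
#' @param copies_unmethylated,copies_methylated template copies (>= 0);
#'   vectors recycle.
#' @param assay `"MSP"` or `"BSP"`.
#' @param cfg a [cq_sim_config()].
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return numeric vector of Cq values (NA = no detection).
#' @examples
#' cfg <- cq_sim_config(noise_sd = 0)
#' simulate_cq(1e6, 0, "MSP", cfg)
#' @export
simulate_cq <- function(copies_unmethylated, copies_methylated = 0,
                        assay = c("MSP", "BSP"), cfg = cq_sim_config(),
                        seed = NULL) {
  assay <- match.arg(assay)
  stopifnot(all(copies_unmethylated >= 0), all(copies_methylated >= 0))
  k <- max(length(copies_unmethylated), length(copies_methylated))
  cu <- rep_len(copies_unmethylated, k)
  cm <- rep_len(copies_methylated, k)
  n_eff <- if (assay == "MSP") cu + cfg$leakage * cm else cu + cm
  a <- if (assay == "MSP") cfg$a_msp else cfg$a_bsp
  run <- function() {
    cq <- cfg$intercept - log(n_eff) / log(a) +
      stats::rnorm(k, 0, cfg$noise_sd)
    cq[n_eff == 0] <- NA_real_
    pmin(cq, cfg$ceiling)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a serial-dilution standard curve
#'
#' Default grid mirrors the printed qMSP curve design: eleven 3-fold steps
#' of unmethylated plasmid from 1e6 down to 17 copies, 12 replicates per
#' level.
#'
#' @param cfg a [cq_sim_config()].
#' @param levels number of dilution levels (>= 3).
#' @param reps replicates per level.
#' @param top_copies copies at the highest level.
#' @param fold dilution factor per step.
#' @param assay assay simulated.
#' @param seed integer seed.
#' @return tibble with `level`, `copies`, `log_copies`, `replicate`, `cq`.
#' @export
simulate_dilution_series <- function(cfg = cq_sim_config(), levels = 11L,
                                     reps = 12L, top_copies = 1e6, fold = 3,
                                     assay = "MSP", seed = 1L) {
  stopifnot(levels >= 3L)
  copies <- top_copies / fold^(seq_len(levels) - 1L)
  grid <- expand.grid(replicate = seq_len(reps), level = seq_len(levels))
  cp <- copies[grid$level]
  cq <- simulate_cq(cp, 0, assay, cfg, seed = seed)
  tibble::tibble(level = grid$level, copies = cp, log_copies = log10(cp),
                 replicate = grid$replicate, cq = cq)
}

#' Time-course specification for the diabetic-mouse blood simulator
#'
#' Defaults reproduce the published study design: blood sampled before
#' treatment (day 0) and on days 1, 2, 5, 6, 7, 14 and 35 after the
#' beta-cell toxin; the default unmethylated-fraction trajectory follows
#' the printed per-day Relative Expression Ratio means (baseline 0.459,
#' excursion peaking around days 2-7, return toward baseline by day 14).
#' Total amplifiable copies are held constant across days (total-DNA
#' dynamics after beta-cell injury are not well characterised; the
#' simplest assumption is used).
#'
#' @param days sampling days.
#' @param unmeth_fraction unmethylated fraction per day, in (0,1).
#' @param animals_per_day animals sampled per day.
#' @param total_copies total amplifiable template copies per sample.
#' @param animal_sd between-animal SD of the unmethylated fraction.
#' @param tech_reps technical replicates per assay.
#' @return list of class `timecourse_spec`.
#' @export
timecourse_spec <- function(days = c(0, 1, 2, 5, 6, 7, 14, 35),
                            unmeth_fraction = c(0.459, 0.571, 0.649, 0.566,
                                                0.579, 0.650, 0.523, 0.506),
                            animals_per_day = 8L, total_copies = 1e4,
                            animal_sd = 0.10, tech_reps = 3L) {
  stopifnot(length(days) == length(unmeth_fraction),
            all(unmeth_fraction > 0), all(unmeth_fraction < 1))
  structure(list(days = days, unmeth_fraction = unmeth_fraction,
                 animals_per_day = as.integer(animals_per_day),
                 total_copies = total_copies, animal_sd = animal_sd,
                 tech_reps = as.integer(tech_reps)),
            class = "timecourse_spec")
}

#' Simulate a blood time course with ground truth
#'
#' Per animal and day, MSP and BSP Cq triples are drawn from the
#' [cq_sim_config()] model with that animal's unmethylated fraction;
#' unmethylated-plasmid reference reactions are emitted alongside, plus the
#' generating truth for recovery tests.
#'
#' @param spec a [timecourse_spec()].
#' @param cfg a [cq_sim_config()].
#' @param seed integer seed.
#' @return list with `records` (sample_id, day, assay, replicate, cq),
#'   `reference` (assay, replicate, cq) and `truth` (sample_id, day,
#'   unmeth_fraction, total_copies).
#' @export
simulate_timecourse <- function(spec = timecourse_spec(),
                                cfg = cq_sim_config(), seed = 1L) {
  stopifnot(inherits(spec, "timecourse_spec"))
  withr::with_seed(seed, {
    recs <- list(); truth <- list()
    for (di in seq_along(spec$days)) {
      day <- spec$days[di]
      for (an in seq_len(spec$animals_per_day)) {
        id <- sprintf("d%g_m%02d", day, an)
        f <- min(max(stats::rnorm(1, spec$unmeth_fraction[di], spec$animal_sd),
                     0.01), 0.99)
        cu <- f * spec$total_copies
        cm <- (1 - f) * spec$total_copies
        for (assay in c("MSP", "BSP")) {
          cq <- simulate_cq(rep(cu, spec$tech_reps), cm, assay, cfg)
          recs[[length(recs) + 1L]] <- tibble::tibble(
            sample_id = id, day = day, assay = assay,
            replicate = seq_len(spec$tech_reps), cq = cq)
        }
        truth[[length(truth) + 1L]] <- tibble::tibble(
          sample_id = id, day = day, unmeth_fraction = f,
          total_copies = spec$total_copies)
      }
    }
    reference <- do.call(rbind, lapply(c("MSP", "BSP"), function(assay) {
      ref_cq <- simulate_cq(rep(spec$total_copies, spec$tech_reps), 0, assay, cfg)
      tibble::tibble(assay = assay, replicate = seq_len(spec$tech_reps),
                     cq = ref_cq)
    }))
    list(records = do.call(rbind, recs), reference = reference,
         truth = do.call(rbind, truth))
  })
}

#' Simulate bisulfite clone reads
#'
#' Each clone draws per-site methylation independently from the given
#' probabilities, is converted on the top strand, and then suffers
#' conversion failures (non-CpG cytosines left unconverted) at the given
#' rate.
#'
#' @param frag an `msp_fragment`.
#' @param p_methylated per-CpG methylation probabilities (recycled to the
#'   number of sites).
#' @param n_clones number of clones.
#' @param conversion_failure_rate per-C probability of escaping conversion.
#' @param group group label attached to the reads.
#' @param seed integer seed.
#' @return tibble with `id`, `group`, `seq`; attribute `truth` holds the
#'   drawn methylation states (clones x sites matrix).
#' @export
simulate_clone_reads <- function(frag, p_methylated, n_clones,
                                 conversion_failure_rate = 0,
                                 group = "sim", seed = 1L) {
  stopifnot(inherits(frag, "msp_fragment"),
            conversion_failure_rate >= 0, conversion_failure_rate <= 1)
  sites <- find_cpg_sites(frag)
  k <- nrow(sites)
  p <- rep_len(p_methylated, k)
  och <- strsplit(frag$seq, "", fixed = TRUE)[[1]]
  nonc <- setdiff(which(och == "C") - 1L, sites$local)
  withr::with_seed(seed, {
    states <- matrix(stats::runif(n_clones * k) < rep(p, each = n_clones),
                     nrow = n_clones)
    seqs <- vapply(seq_len(n_clones), function(i) {
      prof <- methylation_profile(frag, as.logical(states[i, ]))
      ch <- strsplit(bisulfite_convert(frag, prof, "top")$seq, "",
                     fixed = TRUE)[[1]]
      if (conversion_failure_rate > 0 && length(nonc)) {
        fail <- nonc[stats::runif(length(nonc)) < conversion_failure_rate]
        ch[fail + 1L] <- "C"
      }
      paste(ch, collapse = "")
    }, character(1))
  })
  out <- tibble::tibble(id = sprintf("%s_clone%03d", group, seq_len(n_clones)),
                        group = group, seq = seqs)
  colnames(states) <- sprintf("%+d", sites$tss)
  attr(out, "truth") <- states
  out
}
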