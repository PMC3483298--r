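#' Standard-curve fit for a qPCR dilution series
#'
#' Ordinary least squares of Cq on log10(input copies). The slope gives the
#' per-cycle amplification factor A = 10^(-1/slope) and the efficiency
#' (A - 1) x 100; perfect doubling corresponds to slope -3.3219 and 100
#' percent efficiency. A curve is flagged `accepted` when the slope is
#' negative and 1 < A <= 2.2.
#'
#' @param copies input copy numbers (> 0), one per reaction.
#' @param cq quantification cycles.
#' @return object of class `standard_curve`: `slope` (cycles per log10
#'   copies), `intercept`, `r2`, `amplification_factor`, `efficiency_pct`,
#'   `n`, `accepted`.
#' @examples
#' n <- 10^(1:5)
#' fit_standard_curve(n, 35 - log2(n))  # slope -3.3219, efficiency 100
#' @export
fit_standard_curve <- function(copies, cq) {
  stopifnot(is.numeric(copies), is.numeric(cq), length(copies) == length(cq))
  keep <- !is.na(cq)
  copies <- copies[keep]; cq <- cq[keep]
  if (any(copies <= 0)) stop("copies must be positive", call. = FALSE)
  lx <- log10(copies)
  if (length(unique(lx)) < 3L) {
    stop("need at least 3 distinct copy levels", call. = FALSE)
  }
  fit <- stats::lm(cq ~ lx)
  slope <- unname(stats::coef(fit)[2])
  if (slope == 0) stop("zero slope: no dilution response", call. = FALSE)
  a <- 10^(-1 / slope)
  sst <- sum((cq - mean(cq))^2)
  r2 <- if (sst == 0) NA_real_ else 1 - sum(stats::residuals(fit)^2) / sst
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = r2,
                 amplification_factor = a,
                 efficiency_pct = (a - 1) * 100,
                 n = length(cq),
                 accepted = slope < 0 && a > 1 && a <= 2.2),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(paste0("<standard_curve> slope %.4f, intercept %.2f, R2 %.4f, ",
                     "A %.4f, efficiency %.2f%%%s\n"),
              x$slope, x$intercept, x$r2, x$amplification_factor,
              x$efficiency_pct, if (x$accepted) "" else " [not accepted]"))
  invisible(x)
}

#' Convert between standard-curve slope and efficiency
#'
#' `slope_to_efficiency()` returns (10^(-1/slope) - 1) x 100;
#' `efficiency_to_slope()` is its exact inverse, -1/log10(1 + eff/100).
#'
#' @param slope standard-curve slope, cycles per log10 copies (negative).
#' @param efficiency_pct efficiency in percent.
#' @return numeric.
#' @export
slope_to_efficiency <- function(slope) (10^(-1 / slope) - 1) * 100

#' @rdname slope_to_efficiency
#' @export
efficiency_to_slope <- function(efficiency_pct) -1 / log10(1 + efficiency_pct / 100)

mean_cq <- function(x, what) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("missing ", what, " Cq", call. = FALSE)
  mean(x)
}

#' Delta-delta-Cq unmethylated-DNA ratio
#'
#' Classical relative quantification assuming 100 percent efficiency of
#' both reactions: dCq = Cq(MSP) - Cq(BSP) per specimen, ddCq =
#' dCq(sample) - dCq(reference), ratio = 2^-ddCq. The fully unmethylated
#' cloned plasmid serves as the reference, so it maps to ratio 1 and blood
#' samples fall below 1. Technical replicates are averaged on the Cq scale
#' before any ratio is formed.
#'
#' @param sample_msp,sample_bsp sample Cq replicates for the MSP and BSP
#'   assays.
#' @param ref_msp,ref_bsp reference (plasmid) Cq replicates.
#' @return object of class `sample_quant` with `method`, `ratio` and the
#'   `components` used.
#' @examples
#' ddcq_ratio(30, 28, 20, 20)$ratio  # 0.25
#' @export
ddcq_ratio <- function(sample_msp, sample_bsp, ref_msp, ref_bsp) {
  dcq_s <- mean_cq(sample_msp, "sample MSP") - mean_cq(sample_bsp, "sample BSP")
  dcq_r <- mean_cq(ref_msp, "reference MSP") - mean_cq(ref_bsp, "reference BSP")
  ddcq <- dcq_s - dcq_r
  structure(list(method = "ddCq", ratio = 2^(-ddcq),
                 components = list(dcq_sample = dcq_s, dcq_reference = dcq_r,
                                   ddcq = ddcq)),
            class = "sample_quant")
}

#' Relative Expression Ratio (efficiency-corrected)
#'
#' Efficiency-corrected relative quantification: each assay's fitted
#' amplification factor A replaces the assumed 2, giving
#' ratio = A_MSP^(Cq_MSP,ref - Cq_MSP,sample) /
#'         A_BSP^(Cq_BSP,ref - Cq_BSP,sample).
#' With A_MSP = A_BSP = 2 this reduces exactly to [ddcq_ratio()].
#'
#' @inheritParams ddcq_ratio
#' @param a_msp,a_bsp amplification factors (not percent) from the fitted
#'   MSP and BSP standard curves; must exceed 1.
#' @return a `sample_quant` (method `"RER"`).
#' @examples
#' rer_ratio(30, 28, 20, 20, 2, 2)$ratio  # 0.25
#' @export
rer_ratio <- function(sample_msp, sample_bsp, ref_msp, ref_bsp, a_msp, a_bsp) {
  if (a_msp <= 1 || a_bsp <= 1) {
    stop("amplification factors must exceed 1", call. = FALSE)
  }
  e_m <- mean_cq(ref_msp, "reference MSP") - mean_cq(sample_msp, "sample MSP")
  e_b <- mean_cq(ref_bsp, "reference BSP") - mean_cq(sample_bsp, "sample BSP")
  structure(list(method = "RER", ratio = a_msp^e_m / a_bsp^e_b,
                 components = list(dcq_msp = e_m, dcq_bsp = e_b,
                                   a_msp = a_msp, a_bsp = a_bsp)),
            class = "sample_quant")
}

#' Demethylation Index
#'
#' Reference-free unmethylated-DNA index from the MSP-BSP Cq difference at
#' assumed 100 percent efficiency: DI = 2^(Cq_BSP - Cq_MSP). More
#' unmethylated template lowers Cq_MSP and raises DI. Because no external
#' reference enters, DI cannot absorb day-to-day shifts -- the practical
#' weakness the inter-assay statistics expose.
#'
#' @inheritParams ddcq_ratio
#' @return a `sample_quant` (method `"DI"`).
#' @examples
#' demethylation_index(30, 28)$ratio  # 0.25
#' @export
demethylation_index <- function(sample_msp, sample_bsp) {
  d <- mean_cq(sample_bsp, "sample BSP") - mean_cq(sample_msp, "sample MSP")
  structure(list(method = "DI", ratio = 2^d,
                 components = list(dcq = d)),
            class = "sample_quant")
}

#' @export
print.sample_quant <- function(x, ...) {
  cat(sprintf("<sample_quant> %s ratio = %.4g\n", x$method, x$ratio))
  invisible(x)
}

#' Replicate summary statistics
#'
#' Mean, sample standard deviation (n - 1) and percent coefficient of
#' variation (100 x SD / mean) at full precision.
#'
#' @param values numeric vector, length >= 2.
#' @return list with `n`, `mean`, `sd`, `cv_pct` (NA with a warning when
#'   the mean is zero).
#' @examples
#' replicate_stats(c(0.610, 0.541, 1.068))$cv_pct  # 38.72...
#' @export
replicate_stats <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least 2 replicates", call. = FALSE)
  m <- mean(values); s <- stats::sd(values)
  cv <- if (m == 0) { warning("mean is zero: CV undefined", call. = FALSE); NA_real_ }
        else 100 * s / m
  list(n = length(values), mean = m, sd = s, cv_pct = cv)
}

#' Per-level and mean coefficient of variation of a standard curve
#'
#' Accepts either per-level summaries (`mean_cq` and `sd` columns) or raw
#' replicates (`cq` column, several rows per level); returns the percent CV
#' per dilution level and the unweighted mean and SD of those CVs.
#'
#' @param data data frame with a `log_copies` (or `copies`) column plus
#'   either `mean_cq` and `sd`, or raw `cq`.
#' @return list with `per_level` (tibble: `log_copies`, `mean_cq`, `sd`,
#'   `cv_pct`), `mean_cv`, `sd_cv`, `range`.
#' @export
curve_cv_profile <- function(data) {
  data <- as.data.frame(data)
  if (!"log_copies" %in% names(data)) {
    if (!"copies" %in% names(data)) stop("need log_copies or copies column", call. = FALSE)
    data$log_copies <- log10(data$copies)
  }
  if (all(c("mean_cq", "sd") %in% names(data))) {
    lev <- tibble::tibble(log_copies = data$log_copies,
                          mean_cq = data$mean_cq, sd = data$sd)
  } else if ("cq" %in% names(data)) {
    sp <- split(data$cq[!is.na(data$cq)], data$log_copies[!is.na(data$cq)])
    lev <- tibble::tibble(log_copies = as.numeric(names(sp)),
                          mean_cq = vapply(sp, mean, numeric(1)),
                          sd = vapply(sp, stats::sd, numeric(1)))
  } else stop("need either (mean_cq, sd) or cq columns", call. = FALSE)
  if (nrow(lev) == 0L) stop("empty curve table", call. = FALSE)
  lev$cv_pct <- 100 * lev$sd / lev$mean_cq
  list(per_level = lev,
       mean_cv = mean(lev$cv_pct),
       sd_cv = if (nrow(lev) > 1L) stats::sd(lev$cv_pct) else 0,
       range = range(lev$cv_pct))
}

#' Two-sample t-test (pooled Student by default)
#'
#' Two-tailed unpaired test; the classical pooled-variance form is the
#' default (matching the usual Prism setting), Welch by flag.
#'
#' @param a,b numeric vectors, each n >= 2.
#' @param var_equal pooled variance (TRUE, Student) or Welch (FALSE).
#' @return list with `t`, `df`, `p_value`.
#' @export
ttest_unpaired <- function(a, b, var_equal = TRUE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) stop("need n >= 2 per group", call. = FALSE)
  if (stats::var(a) + stats::var(b) == 0) {
    stop("degenerate variance: all values identical", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Quantify a blood time course under all three calculation methods
#'
#' For each sample, technical-replicate Cq means feed the delta-delta-Cq,
#' Relative Expression Ratio and Demethylation Index calculations with the
#' unmethylated plasmid as reference; per-day summaries then carry n, mean,
#' SD and a two-tailed unpaired t-test against the pre-treatment day.
#' When the reference is missing, ddCq and RER are skipped with a warning
#' and the reference-free DI is still computed.
#'
#' @param records data frame of sample reactions: columns `sample_id`,
#'   `day`, `assay` (`"MSP"`/`"BSP"`), `replicate`, `cq`.
#' @param reference data frame of plasmid-reference reactions: columns
#'   `assay`, `replicate`, `cq`; or NULL.
#' @param a_msp,a_bsp amplification factors for RER (default 2 = 100
#'   percent efficiency, under which RER equals ddCq exactly).
#' @param baseline_day day used as the pre-treatment comparator.
#' @return list with `samples` (per-sample ratios, one row per sample and
#'   method) and `summary` (per day: `n`, mean/sd/p for each method,
#'   p = NA on the baseline day).
#' @export
timecourse_analysis <- function(records, reference, a_msp = 2, a_bsp = 2,
                                baseline_day = 0) {
  stopifnot(all(c("sample_id", "day", "assay", "cq") %in% names(records)))
  have_ref <- !is.null(reference) && nrow(reference) > 0L
  if (!have_ref) {
    warning("no reference sample: ddCq and RER skipped, DI still computed",
            call. = FALSE)
  }
  ref_m <- if (have_ref) reference$cq[reference$assay == "MSP"] else NULL
  ref_b <- if (have_ref) reference$cq[reference$assay == "BSP"] else NULL

  ids <- unique(records$sample_id)
  rows <- lapply(ids, function(id) {
    d <- records[records$sample_id == id, ]
    msp <- d$cq[d$assay == "MSP"]; bsp <- d$cq[d$assay == "BSP"]
    day <- d$day[1]
    out <- list(tibble::tibble(sample_id = id, day = day, method = "DI",
                               ratio = demethylation_index(msp, bsp)$ratio))
    if (have_ref) {
      out <- c(out, list(
        tibble::tibble(sample_id = id, day = day, method = "ddCq",
                       ratio = ddcq_ratio(msp, bsp, ref_m, ref_b)$ratio),
        tibble::tibble(sample_id = id, day = day, method = "RER",
                       ratio = rer_ratio(msp, bsp, ref_m, ref_b,
                                         a_msp, a_bsp)$ratio)))
    }
    do.call(rbind, out)
  })
  samples <- do.call(rbind, rows)

  days <- sort(unique(samples$day))
  methods <- unique(samples$method)
  summ <- lapply(days, function(dd) {
    row <- tibble::tibble(day = dd,
                          n = length(unique(samples$sample_id[samples$day == dd])))
    for (m in methods) {
      v <- samples$ratio[samples$day == dd & samples$method == m]
      v0 <- samples$ratio[samples$day == baseline_day & samples$method == m]
      p <- if (dd == baseline_day || length(v) < 2L || length(v0) < 2L) NA_real_
           else ttest_unpaired(v, v0)$p_value
      row[[paste0(tolower(m), "_mean")]] <- mean(v)
      row[[paste0(tolower(m), "_sd")]] <- stats::sd(v)
      row[[paste0(tolower(m), "_p")]] <- p
    }
    row
  })
  list(samples = samples, summary = do.call(rbind, summ))
}
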