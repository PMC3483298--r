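test_that("melting temperature behaves like a nearest-neighbor model", {
  expect_gt(melting_temperature("GCGCGCGCGC"), melting_temperature("ATATATATAT"))
  set.seed(11)
  for (i in 1:10) {
    s <- random_seq(sample(8:40, 1))
    expect_equal(melting_temperature(s),
                 melting_temperature(reverse_complement(s)), tolerance = 1e-10)
  }
  # monotone in length for homopolymer extensions of a GC-rich seed
  seed_seq <- "GCGGCCGC"
  tms <- melting_temperature(vapply(0:8, function(k) {
    paste0(seed_seq, strrep("G", k))
  }, character(1)))
  expect_true(all(diff(tms) > 0))
  expect_error(melting_temperature("ACGTACG"), "short")
})

test_that("the clamped redesign raises Tm over the original primer", {
  expect_gt(melting_temperature(ins2_primer("P12")$full),
            melting_temperature(ins2_primer("P4")$full))
})

test_that("primer construction enforces the length and clamp contracts", {
  expect_error(primer("x", "ACGTACGTACGT"), "15")
  expect_error(primer("x", "ACGTACGTACGTACG", clamp = strrep("G", 21)), "clamp")
  p <- primer("P12", "TTTTTATTTTTGAGAGAGAGTTGGGGATTT", clamp = "GCAGG")
  expect_identical(p$full, "GCAGGTTTTTATTTTTGAGAGAGAGTTGGGGATTT")
  expect_identical(p$full, ins2_primers()$sequence[ins2_primers()$id == "P12"])
})

test_that("binding-site scan reports mismatches relative to the 3' end", {
  tpl <- "AAAATTTGGGATTAGGTTAGGATTTTAAGG"
  p <- primer("exact", substr(tpl, 5, 24))
  s <- find_binding_sites(p, tpl)
  s <- s[s$orientation == "sense", ]
  expect_identical(nrow(s), 1L)
  expect_identical(s$start, 4L)
  expect_identical(s$mismatch_count, 0L)
  expect_true(s$extendable)
  # a 3'-terminal mismatch is reported but kills extension
  core <- substr(tpl, 5, 24)
  core3 <- paste0(substr(core, 1, 19), "C")  # template has T/G there, not C
  s3 <- find_binding_sites(primer("mm3", core3), tpl)
  s3 <- s3[s3$orientation == "sense" & s3$start == 4L, ]
  expect_identical(nrow(s3), 1L)
  expect_identical(s3$three_prime_window_mismatches, 1L)
  expect_false(s3$extendable)
})

test_that("MSP discrimination: P12 extends only on the unmethylated conversion", {
  frag <- ins2_test_fragment()
  pu <- bisulfite_convert(frag, methylation_profile(frag, "unmethylated"))
  pm <- bisulfite_convert(frag, methylation_profile(frag, "methylated"))
  p12 <- ins2_primer("P12")
  su <- find_binding_sites(p12, pu)
  sm <- find_binding_sites(p12, pm)
  expect_identical(sum(su$extendable), 1L)
  expect_identical(sum(sm$extendable), 0L)
  # the methylated site is still seen, blocked at the 3' terminus
  expect_true(nrow(sm) >= 1L && all(sm$three_prime_window_mismatches > 0L))
})

test_that("classification recovers the published primer roles", {
  frag <- ins2_test_fragment()
  c1 <- classify_primer(ins2_primer("P1"), frag)
  expect_identical(c1$klass, "BSP")
  expect_identical(length(c1$interrogated_sites), 0L)
  c12 <- classify_primer(ins2_primer("P12"), frag)
  expect_identical(c12$klass, "MSP")
  expect_identical(c12$target_state, "unmethylated")
  expect_identical(c12$interrogated_sites, -414L)
  c13 <- classify_primer(ins2_primer("P13"), frag)
  expect_identical(c13$klass, "MSP")
  expect_identical(c13$interrogated_sites, -171L)
  # a primer copied from a CpG-free stretch of the unmethylated conversion
  conv <- bisulfite_convert(frag, methylation_profile(frag, "unmethylated"))
  free <- substr(conv$seq, 401, 425)  # no CpG between -80 and -56
  cf <- classify_primer(primer("free", free), frag)
  expect_identical(cf$klass, "BSP")
  expect_identical(cf$n_discriminating, 0L)
  # a primer matching the unconverted sequence (with its non-CpG Cs) is
  # recognised as non-bisulfite
  raw <- classify_primer(primer("raw", substr(frag$seq, 150, 180)), frag)
  expect_identical(raw$klass, "non-bisulfite")
})

test_that("pair classification flags mixed MSP/BSP combinations", {
  frag <- ins2_test_fragment()
  expect_warning(cl <- classify_pair(ins2_primer("P4"), ins2_primer("P2"), frag),
                 "moderate")
  expect_identical(cl$pair_class, "mixed")
  cl2 <- classify_pair(ins2_primer("P12"), ins2_primer("P13"), frag)
  expect_identical(cl2$pair_class, "MSP")
  cl3 <- classify_pair(ins2_primer("P16"), ins2_primer("P17"), frag)
  expect_identical(cl3$pair_class, "BSP")
})

test_that("explicit clamping reproduces the printed redesigned primer", {
  p12core <- primer("P4-extended", sub("^GCAGG", "", ins2_primer("P12")$full))
  clamped <- add_clamp(p12core, "GCAGG", name = "P12")
  expect_identical(clamped$full, ins2_primer("P12")$full)
})

test_that("clamp design reaches the target Tm without touching the 3' end", {
  p <- primer("at", "TTTATTTATTATTTAATTAT")
  expect_identical(design_clamp(p, melting_temperature(p$full)), p)
  set.seed(99)
  for (i in 1:30) {
    core <- paste(sample(c("A", "T", "G"), 22, replace = TRUE,
                         prob = c(0.45, 0.45, 0.1)), collapse = "")
    p <- primer(paste0("r", i), core)
    target <- melting_temperature(p$full) + sample(3:10, 1)
    out <- design_clamp(p, target, seed = i)
    expect_gte(melting_temperature(out$full), target)
    expect_identical(out$core, p$core)
    expect_identical(substr(out$full, nchar(out$full) - 9, nchar(out$full)),
                     substr(p$full, nchar(p$full) - 9, nchar(p$full)))
  }
  expect_error(design_clamp(primer("cold", "TTTATTTATTATTTAATTAT"), 95),
               class = "mspkit_design_failure")
})

test_that("clamping never alters classification", {
  frag <- ins2_test_fragment()
  p12core <- primer("p", sub("^GCAGG", "", ins2_primer("P12")$full))
  before <- classify_primer(p12core, frag)
  clamped <- design_clamp(p12core, melting_temperature(p12core$full) + 5,
                          seed = 4)
  after <- classify_primer(clamped, frag)
  expect_identical(after$klass, before$klass)
  expect_identical(after$interrogated_sites, before$interrogated_sites)
  expect_identical(after$three_prime_site, before$three_prime_site)
})

test_that("in-silico PCR reproduces the band pattern of the cloned template", {
  frag <- ins2_test_fragment()
  msp_m <- insilico_pcr(ins2_primer("P12"), ins2_primer("P13"), frag, "methylated")
  msp_u <- insilico_pcr(ins2_primer("P12"), ins2_primer("P13"), frag, "unmethylated")
  expect_identical(nrow(msp_m), 0L)   # no band from methylated template
  expect_identical(nrow(msp_u), 1L)
  bsp_u <- insilico_pcr(ins2_primer("P1"), ins2_primer("P2"), frag, "unmethylated")
  bsp_m <- insilico_pcr(ins2_primer("P1"), ins2_primer("P2"), frag, "methylated")
  expect_identical(nrow(bsp_u), 1L)
  expect_identical(nrow(bsp_m), 1L)
  expect_identical(bsp_u$product_length, bsp_m$product_length)
  # two same-sense primers cannot make a product
  none <- insilico_pcr(ins2_primer("P12"), ins2_primer("P5"), frag, "unmethylated")
  expect_identical(nrow(none), 0L)
})

test_that("product length equals brute-force substring arithmetic", {
  set.seed(5)
  for (i in 1:10) {
    n <- 300
    tpl_chars <- sample(c("A", "G", "T"), n, replace = TRUE)
    f_start <- sample(5:60, 1); f_len <- sample(18:24, 1)
    r_end <- sample(180:260, 1); r_len <- sample(18:24, 1)
    tpl <- paste(tpl_chars, collapse = "")
    fwd_seq <- substr(tpl, f_start, f_start + f_len - 1)
    rev_seq <- reverse_complement(substr(tpl, r_end - r_len + 1, r_end))
    frag <- fragment("bf", tpl, 1)
    fwd <- primer("F", fwd_seq, clamp = "GGCC")
    rev <- primer("R", rev_seq)
    prod <- insilico_pcr(fwd, rev, frag, "unmethylated")
    prod <- prod[prod$strand == "top" & prod$forward == "F", ]
    expect_true(nrow(prod) >= 1L)
    expected <- (r_end - f_start + 1) + nchar(fwd$clamp)
    expect_true(expected %in% prod$product_length)
  }
})

test_that("specificity report carries the analytical-specificity arithmetic", {
  frag <- ins2_test_fragment()
  rep1 <- specificity_report(ins2_primer("P4"), ins2_primer("P6"), frag,
                             lod_unmethylated = 2, lod_methylated = 1e6)
  expect_true(rep1$methylation_specific)
  expect_equal(rep1$analytical_specificity, 5e5)
  expect_true(rep1$exceeds_1e5)
  # ratio invariant to swapping primer order within the pair
  rep2 <- specificity_report(ins2_primer("P6"), ins2_primer("P4"), frag,
                             lod_unmethylated = 2, lod_methylated = 1e6)
  expect_equal(rep2$analytical_specificity, rep1$analytical_specificity)
  expect_identical(rep2$methylation_specific, rep1$methylation_specific)
  # missing LODs: ratio omitted, no error
  rep3 <- specificity_report(ins2_primer("P4"), ins2_primer("P6"), frag)
  expect_null(rep3$analytical_specificity)
  # a pair amplifying both profiles is flagged not methylation-specific
  rep4 <- specificity_report(ins2_primer("P16"), ins2_primer("P17"), frag)
  expect_false(rep4$methylation_specific)
  expect_true(rep4$amplifies_methylated)
  # two interrogated sites outrank a mixed pair's single site
  rep5 <- suppressWarnings(
    specificity_report(ins2_primer("P4"), ins2_primer("P2"), frag))
  expect_gt(rep1$n_discriminating, rep5$n_discriminating)
})

test_that("whole-blood equivalence arithmetic gives 1000 beta cells", {
  eq <- blood_sensitivity_equivalent(copies_per_reaction = 10,
                                     background_cells = 1e5,
                                     total_nucleated_cells = 2e7)
  expect_equal(eq$cells_per_reaction, 5)
  expect_equal(eq$whole_blood_cells, 1000)
})
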