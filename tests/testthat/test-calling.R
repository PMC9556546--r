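test_that("window allele frequencies aggregate reads, flag empty windows", {
  markers <- data.frame(
    sample = "s1", chromosome = "Chr1",
    position = c(10000, 30000, 120000),
    col_reads = c(10, 5, 0), ler_reads = c(0, 5, 4),
    stringsAsFactors = FALSE)
  wa <- window_allele_freq(markers, c(Chr1 = 200000))
  w1 <- wa[wa$start == 0, ]          # covers both first markers
  expect_equal(w1$af, 15 / 20)
  w2 <- wa[wa$start == 100000, ]     # only the pure-Ler marker
  expect_equal(w2$af, 0)
  gap <- wa[wa$start == 50000, ]     # no markers at all
  expect_true(is.na(gap$af))
  expect_false(gap$informative)
  expect_error(window_allele_freq(markers, c(Chr1 = 2e5), window = 0),
               "positive")
})

test_that("a single planted transition yields one call containing it", {
  set.seed(20)
  kar <- karyotype("Chr1", 24, 10)
  pop <- planted_population(list(list(Chr1 = 1.0)), kar,
                            marker_density = 0.2, mean_depth = 10)
  wa <- window_allele_freq(pop$markers, kar)
  calls <- call_crossovers(wa)
  expect_equal(nrow(calls), 1L)
  expect_lte(calls$interval_start, 1e6)
  expect_gte(calls$interval_end, 1e6)
  expect_true(calls$point >= calls$interval_start &
              calls$point <= calls$interval_end)
  expect_true(calls$type %in% c("col_to_het", "het_to_col"))
})

test_that("no transition yields no calls; two transitions yield two ordered calls", {
  set.seed(21)
  kar <- karyotype("Chr1", 24, 25)
  pop <- planted_population(list(list(Chr1 = numeric(0)),
                                 list(Chr1 = c(5, 15))), kar,
                            marker_density = 0.2, mean_depth = 10)
  wa <- window_allele_freq(pop$markers, kar)
  calls <- call_crossovers(wa)
  expect_true(all(calls$sample == "bc1_0002"))
  expect_equal(nrow(calls), 2L)
  expect_lt(calls$interval_end[1], calls$interval_start[2])
  expect_lte(calls$interval_start[1], 5e6); expect_gte(calls$interval_end[1], 5e6)
  expect_lte(calls$interval_start[2], 15e6); expect_gte(calls$interval_end[2], 15e6)
})

test_that("error-free planted crossovers are fully recovered; 1% error nearly so", {
  set.seed(22)
  kar <- small_karyotype()
  gt <- genotype_spec("z", zyp1 = TRUE, poisson_total = 3)
  # explicit well-separated truth: up to 3 crossovers per chromosome, at
  # least 1 Mb apart and 1 Mb from the ends
  ids <- sprintf("bc1_%04d", 1:25)
  rows <- list()
  for (sm in ids) for (k in 1:2) {
    len <- kar$genomic_length_mb[k]
    nco <- sample(0:3, 1)
    pos <- numeric(0)
    while (length(pos) < nco) {
      cand <- runif(1, 1, len - 1)
      if (all(abs(cand - pos) >= 1)) pos <- c(pos, cand)
    }
    if (nco > 0)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sm, chromosome = kar$chromosome[k], position_mb = sort(pos))
  }
  rows <- do.call(rbind, rows)
  truth0 <- crossover_table(rows$sample, rows$chromosome, rows$position_mb,
                            karyotype = kar)
  spec0 <- synthetic_population_spec(25, gt, kar, marker_density = 0.1,
                                     mean_depth = 5, error_rate = 0)
  pop0 <- generate_population_markers(spec0, co_source = truth0)
  wa0 <- window_allele_freq(pop0$markers, kar)
  calls0 <- call_crossovers(wa0)
  # every truth breakpoint has a call whose interval contains it
  hit <- vapply(seq_len(nrow(truth0)), function(i) {
    b <- truth0$position_mb[i] * 1e6
    any(calls0$sample == truth0$sample[i] &
        calls0$chromosome == truth0$chromosome[i] &
        calls0$interval_start <= b & calls0$interval_end >= b)
  }, logical(1))
  expect_true(all(hit))
  expect_equal(nrow(calls0), nrow(truth0))   # no spurious calls either

  set.seed(23)
  # model-drawn truth, ends masked so every block has enough windows
  masks <- data.frame(chromosome = rep(kar$chromosome, 2),
                      start = c(0, 0, 29.5e6, 19.5e6),
                      end = c(5e5, 5e5, 30e6, 20e6))
  spec1 <- synthetic_population_spec(25, gt, kar, marker_density = 0.1,
                                     mean_depth = 5, error_rate = 0.01,
                                     masks = masks)
  pop1 <- generate_population_markers(spec1)
  calls1 <- call_crossovers(window_allele_freq(pop1$markers, kar))
  truth1 <- pop1$truth
  hit1 <- vapply(seq_len(nrow(truth1)), function(i) {
    b <- truth1$position_mb[i] * 1e6
    any(calls1$sample == truth1$sample[i] &
        calls1$chromosome == truth1$chromosome[i] &
        calls1$interval_start <= b & calls1$interval_end >= b)
  }, logical(1))
  expect_gte(mean(hit1), 0.95)
  # no spurious calls: every call lies within one window (documented
  # tolerance: 100 kb) of a true breakpoint
  spurious <- vapply(seq_len(nrow(calls1)), function(j) {
    tp <- truth1$position_mb[truth1$sample == calls1$sample[j] &
                             truth1$chromosome == calls1$chromosome[j]] * 1e6
    !length(tp) || min(abs(c(tp - calls1$interval_start[j],
                             tp - calls1$interval_end[j]))) > 1e5
  }, logical(1))
  expect_equal(sum(spurious), 0L)
})

test_that("calls are invariant to marker row shuffling", {
  set.seed(24)
  kar <- karyotype("Chr1", 24, 10)
  pop <- planted_population(list(list(Chr1 = 4)), kar,
                            marker_density = 0.2, mean_depth = 10)
  wa1 <- window_allele_freq(pop$markers, kar)
  shuf <- pop$markers[sample(nrow(pop$markers)), ]
  shuf <- shuf[order(shuf$sample, shuf$chromosome, shuf$position), ]
  wa2 <- window_allele_freq(shuf, kar)
  expect_equal(wa2$af, wa1$af)
  set.seed(1); c1 <- call_crossovers(wa1)
  set.seed(1); c2 <- call_crossovers(wa2)
  expect_equal(c1, c2)
})

test_that("QC rejects low coverage and contamination, passes clean samples", {
  af_clean <- data.frame(sample = "s", af = c(rep(0.5, 50), rep(1, 50)),
                         informative = TRUE)
  af_contam <- data.frame(sample = "s", af = c(rep(0.5, 45), rep(0.85, 10),
                                               rep(1, 45)),
                          informative = TRUE)
  expect_equal(qc_samples(af_clean, c(s = 0.05))$reason, "low_coverage")
  expect_equal(qc_samples(af_contam, c(s = 1))$reason, "contamination")
  qc <- qc_samples(af_clean, c(s = 1))
  expect_true(qc$pass)
  expect_equal(qc$reason, "pass")
})

test_that("aneuploidy screen flags a planted 1.5x chromosome and only it", {
  set.seed(25)
  kar <- arabidopsis_karyotype("female")
  gt <- genotype_spec("z", zyp1 = TRUE, poisson_total = 5)
  spec <- synthetic_population_spec(3, gt, kar, mean_depth = 1,
                                    trisomy = list(fraction = 1 / 3,
                                                   chromosome = "Chr3",
                                                   het_centromere = TRUE))
  depth <- generate_depth_profile(spec)
  scr <- aneuploidy_screen(depth)
  expect_equal(nrow(scr$calls), 1L)
  expect_equal(scr$calls$sample, "bc1_0001")
  expect_equal(scr$calls$chromosome, "Chr3")
  expect_equal(scr$calls$direction, "gain")
  expect_gt(scr$calls$median_fold, 1.2)
})

test_that("fold change 1.15 is never flagged no matter how small p is", {
  # deterministic-depth construction: separation is perfect (p ~ 0) but the
  # fold stays below the 1.2 threshold
  mkchrom <- function(sm, ch, n, d)
    data.frame(sample = sm, chromosome = ch,
               start = (0:(n - 1)) * 1e5, end = (1:n) * 1e5,
               depth = d + rep(c(-0.001, 0.001), length.out = n))
  dep <- rbind(mkchrom("s", "Chr1", 500, 1.15), mkchrom("s", "Chr2", 500, 1),
               mkchrom("s", "Chr3", 500, 1))
  scr <- aneuploidy_screen(dep)
  expect_lt(min(scr$pairs$p_adj), 1e-20)   # the pairs are wildly significant
  expect_equal(nrow(scr$calls), 0L)        # but no fold passes 1.2
})

test_that("screens with too few windows are marked unreliable", {
  dep <- data.frame(sample = "s", chromosome = rep(c("a", "b"), each = 5),
                    start = 0, end = 1e5, depth = 1)
  scr <- aneuploidy_screen(dep)
  expect_equal(scr$unreliable, "s")
  expect_equal(nrow(scr$calls), 0L)
})

test_that("called crossovers convert to a crossover table", {
  set.seed(26)
  kar <- karyotype("Chr1", 24, 10)
  pop <- planted_population(list(list(Chr1 = 2)), kar,
                            marker_density = 0.2, mean_depth = 10)
  calls <- call_crossovers(window_allele_freq(pop$markers, kar))
  tab <- calls_to_crossover_table(calls, kar)
  expect_s3_class(tab, "crossover_table")
  expect_equal(tab$position_mb, calls$point / 1e6)
})
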