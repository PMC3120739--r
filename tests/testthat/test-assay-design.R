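assays <- read_assays(system.file("extdata", "assays.yml",
                                  package = "methylightr"))

test_that("published oligos parse with the expected annotation", {
  f1 <- parse_oligo("tggag ttttC ggttg attgg tt", "forward", "ML-Primer-F1")
  expect_identical(nchar(f1$sequence), 22L)
  expect_identical(oligo_cpg_count(f1), 1L)
  f2 <- parse_oligo("CgCgg tCgtg gttag ttagt", "forward", "ML-Primer-F2")
  expect_identical(nchar(f2$sequence), 20L)
  expect_identical(oligo_cpg_count(f2), 3L)
  col_r <- parse_oligo("gggaa gatgg gatag aaggg aatat", "reverse", "COL2A1-R")
  expect_identical(nchar(col_r$sequence), 25L)
  expect_identical(oligo_cpg_count(col_r), 0L)
  # 5'/3' decorations and labels strip cleanly
  p <- parse_oligo("5'-acc Cg accc Cg aac Cg Cg-3'", "probe", "ML-Probe-1")
  expect_identical(nchar(p$sequence), 18L)
  expect_identical(oligo_cpg_count(p), 4L)
  expect_error(parse_oligo("ACGX", "forward"), "non-base")
})

test_that("shipped assay config carries the printed discriminating counts", {
  counts <- lapply(assays, function(a)
    c(oligo_cpg_count(a$forward), oligo_cpg_count(a$reverse),
      oligo_cpg_count(a$probe)))
  expect_identical(counts[["ML-70bp-classic"]], c(1L, 2L, 4L))
  expect_identical(counts[["ML-115bp-novel"]], c(3L, 4L, 3L))
  expect_identical(counts[["COL2A1-reference"]], c(0L, 0L, 0L))
  expect_identical(assays[["ML-70bp-classic"]]$target_strand, "antisense")
  expect_true(assays[["COL2A1-reference"]]$reference)
})

test_that("explicit-index annotation substitutes for case marking", {
  o <- parse_oligo("acgtacgt", "forward", discriminating = c(2, 6))
  expect_identical(oligo_cpg_count(o), 2L)
  expect_error(parse_oligo("acgt", "forward", discriminating = 9),
               "outside")
})

test_that("oligo location distinguishes methylated from unmethylated templates", {
  a115 <- assays[["ML-115bp-novel"]]
  fx <- build_assay_fixture(a115, seed = 7)
  tpl <- bisulfite_templates(fx)
  hit_m <- locate_oligo(a115$forward, tpl$sense_methylated)
  expect_identical(nrow(hit_m), 1L)
  expect_identical(hit_m$mismatches, 0L)
  best_u <- best_oligo_hit(a115$forward, tpl$sense_unmethylated)
  expect_gte(best_u$mismatch_at_cpg, 1L)
  # oligo longer than template: empty with warning
  expect_warning(none <- locate_oligo(a115$forward, tpl_short <- local({
    r <- genomic_region("tiny", "ACGTACG", 1L)
    bisulfite_templates(r)$sense_methylated
  })), "longer")
  expect_identical(nrow(none), 0L)
})

test_that("amplicon intervals follow primer geometry", {
  fx <- make_neutral_fixture(seed = 5)
  tpl <- bisulfite_templates(fx$region)
  iv_m <- amplicon_of(fx$assay, tpl$sense_methylated)
  expect_identical(interval_length(iv_m), fx$expected_len)
  expect_identical(attr(iv_m, "template_start"), fx$f_pos)
  expect_identical(attr(iv_m, "template_end"), fx$r5_pos)
  expect_true(attr(iv_m, "probe_inside"))
  # a conversion-insensitive assay lands identically on the M and U templates
  iv_u <- amplicon_of(fx$assay, tpl$sense_unmethylated)
  expect_identical(unclass(iv_m)[c("start_tss", "end_tss")],
                   unclass(iv_u)[c("start_tss", "end_tss")])
})

test_that("amplicon geometry is recovered over 200 random fixtures", {
  set.seed(55)
  for (i in 1:200) {
    fx <- make_neutral_fixture(seed = 10000 + i,
                               flank = sample(5:30, 1),
                               f_len = sample(16:24, 1),
                               gap1 = sample(0:15, 1),
                               p_len = sample(15:22, 1),
                               gap2 = sample(0:15, 1),
                               r_len = sample(16:24, 1))
    tpl <- bisulfite_templates(fx$region)
    iv <- suppressWarnings(amplicon_of(fx$assay, tpl$sense_methylated))
    # direct index arithmetic oracle
    expect_identical(interval_length(iv), fx$r5_pos - fx$f_pos + 1L)
  }
})

test_that("TSS coordinate arithmetic matches the published amplicon lengths", {
  expect_identical(interval_length(amplicon_interval(238, 307)), 70L)
  expect_identical(interval_length(amplicon_interval(133, 283)), 151L)
  # computes to 116 bp inclusive though the assay is named "115-bp"
  expect_identical(interval_length(amplicon_interval(157, 272)), 116L)
  # spans crossing the TSS skip position 0
  expect_identical(interval_length(amplicon_interval(-5, 5)), 10L)
  expect_error(amplicon_interval(0, 10), "position 0")
})

test_that("interval overlap is genomic, symmetric and bounded", {
  a <- amplicon_interval(157, 272, "sense")
  b <- amplicon_interval(133, 283, "antisense")
  c70 <- amplicon_interval(238, 307, "antisense")
  expect_identical(interval_overlap(a, b), 116L)   # full containment
  expect_identical(interval_overlap(c70, b), 46L)  # partial
  expect_identical(interval_overlap(amplicon_interval(1, 10),
                                    amplicon_interval(20, 30)), 0L)
  set.seed(66)
  for (i in 1:100) {
    x <- sort(sample(setdiff(-50:200, 0), 2))
    y <- sort(sample(setdiff(-50:200, 0), 2))
    ia <- amplicon_interval(x[1], x[2]); ib <- amplicon_interval(y[1], y[2])
    expect_identical(interval_overlap(ia, ib), interval_overlap(ib, ia))
    expect_lte(interval_overlap(ia, ib),
               min(interval_length(ia), interval_length(ib)))
    expect_identical(interval_overlap(ia, ia), interval_length(ia))
  }
})

test_that("TSS conversion round-trips for 1000 seeded positions", {
  set.seed(77)
  for (i in 1:1000) {
    tss_offset <- sample(1:500, 1)
    pos <- sample(1:1000, 1)
    expect_identical(tss_to_offset(offset_to_tss(pos, tss_offset), tss_offset),
                     pos)
    t <- sample(setdiff(-500:500, 0), 1)
    expect_identical(offset_to_tss(tss_to_offset(t, tss_offset), tss_offset),
                     t)
  }
  expect_error(tss_to_offset(0, 10), "position 0")
})

test_that("specificity verdicts separate specific, neutral and undiscriminating designs", {
  for (nm in c("ML-115bp-novel", "ML-70bp-classic")) {
    a <- assays[[nm]]
    fx <- build_assay_fixture(a, seed = 7)
    rep <- specificity_report(a, bisulfite_templates(fx))
    expect_identical(rep$verdict, "methylation-specific")
    expect_identical(rep$target_strand, a$target_strand)
    # every discriminating base fails on the unmethylated template
    u <- rep$hits[rep$hits$template == paste0(a$target_strand, "_unmethylated"), ]
    m <- rep$hits[rep$hits$template == paste0(a$target_strand, "_methylated"), ]
    expect_true(all(m$mismatches == 0L))
    expect_true(all(u$mismatch_at_cpg >= 1L))
  }
  # reference assay: methylation-neutral
  fx0 <- make_neutral_fixture(seed = 9)
  rep0 <- specificity_report(fx0$assay, bisulfite_templates(fx0$region))
  expect_identical(rep0$verdict, "methylation-neutral")
  # an undiscriminating non-reference assay warns
  bad <- suppressWarnings(assay("nodisc", fx0$assay$forward,
                                fx0$assay$reverse, fx0$assay$probe,
                                target_strand = "sense", reference = FALSE))
  repb <- specificity_report(bad, bisulfite_templates(fx0$region))
  expect_true("no methylation discrimination" %in% repb$warnings)
  expect_false(repb$verdict == "methylation-specific")
})

test_that("constructed discriminating bases all fail on the unmethylated template", {
  # fixture-built methylation-specific forward oligos: mismatch_at_cpg on the
  # unmethylated template equals the discriminating count
  set.seed(88)
  for (i in 1:50) {
    fx <- build_assay_fixture(assays[["ML-115bp-novel"]], seed = i)
    tpl <- bisulfite_templates(fx)
    for (o in list(assays[["ML-115bp-novel"]]$forward,
                   assays[["ML-115bp-novel"]]$probe)) {
      h_m <- best_oligo_hit(o, tpl$sense_methylated)
      sc <- locate_oligo(o, tpl$sense_unmethylated,
                         max_mismatch = nchar(o$sequence),
                         orientation = h_m$orientation)
      at <- sc[sc$position == h_m$position, ]
      expect_identical(at$mismatch_at_cpg, oligo_cpg_count(o))
    }
  }
})
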