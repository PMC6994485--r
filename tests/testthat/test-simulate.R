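test_that("read simulation is seed-deterministic down to the FASTQ bytes", {
  d <- demo_reference()
  spec <- read_sim_spec(d$ref, d$guide, c(`-18` = 0.3, `-16` = 0.05),
                        sequencing_error_rate = 0.001, indel_rate = 0.02,
                        n_reads = 300L, seed = 51)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  sim1 <- simulate_reads(spec, fastq_path = f1)
  sim2 <- simulate_reads(spec, fastq_path = f2)
  expect_identical(sim1$reads, sim2$reads)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(sim1$truth, sim2$truth)
})

test_that("zero rates and zero noise reproduce the reference exactly", {
  d <- demo_reference()
  spec <- read_sim_spec(d$ref, d$guide, c(`-18` = 0, `-16` = 0),
                        sequencing_error_rate = 0, indel_rate = 0,
                        n_reads = 50L, seed = 52)
  sim <- simulate_reads(spec)
  expect_true(all(sim$reads == d$ref))
})

test_that("conversion truth rates behave binomially", {
  d <- demo_reference()
  spec <- read_sim_spec(d$ref, d$guide, c(`-18` = 0.3),
                        sequencing_error_rate = 0, n_reads = 10000L,
                        seed = 53)
  sim <- simulate_reads(spec)
  frac <- mean(sim$truth$converted[, "-18"])
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(frac - 0.3), 3 * se)
})

test_that("linked co-editing confines conversions to edited reads", {
  d <- demo_reference()
  spec <- read_sim_spec(d$ref, d$guide, c(`-18` = 0.3, `-16` = 0.2),
                        sequencing_error_rate = 0, n_reads = 5000L,
                        seed = 54, co_editing_mode = "linked",
                        linked_edit_probability = 0.4)
  sim <- simulate_reads(spec)
  conv <- sim$truth$converted
  expect_true(all(!conv[!sim$truth$edited, ]))
  # marginal rates are preserved
  se <- sqrt(0.3 * 0.7 / 5000)
  expect_lt(abs(mean(conv[, "-18"]) - 0.3), 4 * se)
  # co-editing is positively linked: both-converted exceeds independence
  expect_gt(mean(conv[, "-18"] & conv[, "-16"]), 0.3 * 0.2)
})

test_that("rates at non-C positions are rejected", {
  d <- demo_reference()
  expect_error(read_sim_spec(d$ref, d$guide, c(`-17` = 0.2)),
               "non-C position")
  expect_error(read_sim_spec(d$ref, d$guide, c(`-18` = 1.2)), "\\[0, 1\\]")
})

test_that("simulated variant tables carry truth the scanner agrees with", {
  vt <- simulate_variant_table(100, flank_length = 30,
                               fraction_targetable = 0.5, seed = 55)
  expect_identical(nrow(vt$variants), 100L)
  expect_identical(sum(vt$truth$targetable), 50L)
  sc <- scan_variants(vt$variants, builtin_catalog())
  agree <- (sc$verdict == "precisely-correctable") == vt$truth$targetable
  expect_gte(sum(agree), 98L)
  # non-targetable constructions are verifiably PAM-free
  expect_true(all(sc$verdict[!vt$truth$targetable] == "not-targetable"))
  # determinism
  vt2 <- simulate_variant_table(100, flank_length = 30,
                                fraction_targetable = 0.5, seed = 55)
  expect_identical(vt, vt2)
})

test_that("fraction_targetable = 0 yields only not-targetable verdicts", {
  vt <- simulate_variant_table(20, fraction_targetable = 0, seed = 56)
  sc <- scan_variants(vt$variants, builtin_catalog())
  expect_true(all(sc$verdict == "not-targetable"))
})

test_that("variant-call simulation is exact and reproducible", {
  calls <- simulate_variant_calls(c(`C>T/G>A` = 10, `T>C/A>G` = 4),
                                  n_indel = 3, seed = 57)
  s <- tally_variants(calls)
  expect_identical(s$n_snvs, 14L)
  expect_identical(s$n_indels, 3L)
  sp <- s$spectrum
  expect_identical(sp$count[sp$class == "C>T/G>A"], 10L)
  expect_identical(sp$count[sp$class == "T>C/A>G"], 4L)
  expect_equal(sum(sp$frequency), 1)
  expect_identical(calls,
                   simulate_variant_calls(c(`C>T/G>A` = 10, `T>C/A>G` = 4),
                                          n_indel = 3, seed = 57))
  # empty composition -> empty set
  expect_identical(nrow(simulate_variant_calls(seed = 58)), 0L)
  expect_error(simulate_variant_calls(c(`C>U/G>A` = 1), seed = 59),
               "unknown substitution class")
})

test_that("random genomes respect the GC dial and the seed", {
  g1 <- random_genome(2000, seed = 60, gc = 0.5)
  g2 <- random_genome(2000, seed = 60, gc = 0.5)
  expect_identical(g1, g2)
  gc_frac <- function(s) {
    ch <- strsplit(s, "")[[1]]; mean(ch %in% c("G", "C"))
  }
  expect_lt(abs(gc_frac(g1) - 0.5), 0.05)
  expect_lt(abs(gc_frac(random_genome(2000, seed = 61, gc = 0.2)) - 0.2),
            0.05)
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(1000)
  before <- .Random.seed
  invisible(random_genome(100, seed = 62))
  invisible(simulate_variant_calls(c(`C>T/G>A` = 2), seed = 63))
  expect_identical(.Random.seed, before)
})
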