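test_that("read anchoring classifies reference, indel and junk reads", {
  d <- demo_reference()
  # a read identical to the reference is usable
  an <- anchor_reads(d$ref, d$ref, d$guide)
  expect_identical(an$usable_reads, 1L)
  # a 1-nt deletion inside the protospacer is discarded as an indel
  del <- paste0(substr(d$ref, 1, 29), substr(d$ref, 31, nchar(d$ref)))
  an2 <- anchor_reads(del, d$ref, d$guide)
  expect_identical(an2$usable_reads, 0L)
  expect_identical(unname(an2$discarded["indel"]), 1L)
  # too-short and unrelated reads get their own reasons
  an3 <- anchor_reads(c("ACGT", strrep("G", 60)), d$ref, d$guide)
  expect_identical(unname(an3$discarded["short"]), 1L)
  expect_identical(unname(an3$discarded["unanchored"]), 1L)
  # a reverse-complemented reference read is still usable
  an4 <- anchor_reads(reverse_complement(d$ref), d$ref, d$guide)
  expect_identical(an4$usable_reads, 1L)
  expect_error(anchor_reads(d$ref, "ACGTACGT", d$guide))
})

test_that("anchoring agrees with simulator ground truth on indels", {
  d <- demo_reference()
  spec <- read_sim_spec(d$ref, d$guide, c(`-18` = 0),
                        sequencing_error_rate = 0, indel_rate = 0.05,
                        n_reads = 1000L, seed = 21)
  sim <- simulate_reads(spec)
  an <- anchor_reads(sim$reads, d$ref, d$guide)
  expect_identical(an$usable_reads, sum(!sim$truth$has_indel))
  expect_identical(unname(an$discarded["indel"]),
                   sum(sim$truth$has_indel))
  # conservation of reads
  expect_identical(an$usable_reads + sum(an$discarded), an$total_reads)
})

test_that("conversion percentages match a hand count", {
  d <- demo_reference()
  # 10 reads; 4 carry T at -18 (protospacer offset 2 = reference offset 22)
  reads <- rep(d$ref, 10)
  substr(reads[1:4], 23, 23) <- "T"
  et <- quantify_conversions(anchor_reads(reads, d$ref, d$guide))
  pp <- et$per_position
  expect_identical(pp$conversion_percent[pp$position == -18], 40)
  expect_true(all(pp$conversion_percent[pp$position != -18] == 0))
  expect_identical(pp$c_to_t[pp$position == -18], 4L)
  # C-to-other tallied separately
  reads2 <- rep(d$ref, 10)
  substr(reads2[1:3], 23, 23) <- "A"
  et2 <- quantify_conversions(anchor_reads(reads2, d$ref, d$guide))
  expect_identical(et2$per_position$c_to_other[pp$position == -18], 3L)
  expect_identical(et2$per_position$conversion_percent[pp$position == -18],
                   0)
})

test_that("all-reference reads give 0% and zero usable reads stay defined", {
  d <- demo_reference()
  et <- quantify_conversions(anchor_reads(rep(d$ref, 5), d$ref, d$guide))
  expect_true(all(et$per_position$conversion_percent == 0))
  empty <- quantify_conversions(anchor_reads(character(0), d$ref, d$guide))
  expect_identical(empty$usable_reads, 0L)
  expect_true(all(empty$per_position$conversion_percent == 0))
})

test_that("editing tables are orientation-invariant", {
  d <- demo_reference()
  spec <- read_sim_spec(d$ref, d$guide, c(`-18` = 0.4, `-16` = 0.1),
                        sequencing_error_rate = 0.001, n_reads = 500L,
                        seed = 22)
  sim <- simulate_reads(spec)
  et <- quantify_conversions(anchor_reads(sim$reads, d$ref, d$guide))
  et_rc <- quantify_conversions(
    anchor_reads(reverse_complement(sim$reads), d$ref, d$guide))
  expect_identical(et$per_position, et_rc$per_position)
})

test_that("window summaries follow the threshold/tie rules", {
  fake <- structure(list(per_position = data.frame(
    position = c(-18L, -17L, -16L),
    c_to_t = c(40L, 20L, 2L), c_to_other = c(0L, 0L, 0L),
    conversion_percent = c(40, 20, 2)),
    usable_reads = 100L, total_reads = 100L,
    discarded = c(short = 0L, indel = 0L, unanchored = 0L), guide = NULL),
    class = "editing_table")
  ws <- summarize_window(fake, 10)
  expect_identical(ws$window_bounds, c(-18L, -17L))
  expect_identical(ws$predominant_position, -18L)
  expect_identical(ws$predominance_ratio, 2)
  # all zeros -> empty window
  fake0 <- fake
  fake0$per_position$conversion_percent <- c(0, 0, 0)
  expect_null(summarize_window(fake0, 10)$window_bounds)
  # single edited position -> infinite predominance sentinel
  fake1 <- fake
  fake1$per_position$conversion_percent <- c(30, 0, 0)
  expect_identical(summarize_window(fake1, 10)$predominance_ratio, Inf)
  # monotone in threshold: a higher threshold never widens the window
  width <- function(t) {
    b <- summarize_window(fake, t)$window_bounds
    if (is.null(b)) 0L else b[2] - b[1] + 1L
  }
  ws_widths <- vapply(c(1, 10, 25, 50), width, integer(1))
  expect_true(all(diff(ws_widths) <= 0))
})

test_that("canavanine frequency is the plated-colony ratio", {
  expect_identical(canavanine_frequency(0, 500), 0)
  expect_identical(canavanine_frequency(25, 500), 0.05)
  expect_identical(canavanine_frequency(500, 500), 1)
  expect_error(canavanine_frequency(5, 0), "must be > 0")
  expect_warning(out <- canavanine_frequency(600, 500), "exceeds")
  expect_identical(out, 1.2)
})

test_that("FASTQ round-trips through the Biostrings wrappers", {
  reads <- c(r1 = "ACGTACGTAC", r2 = "TTTTGGGGCC")
  f <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, f)
  expect_identical(read_fastq(f), reads)
})
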