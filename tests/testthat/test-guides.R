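test_that("PAM-relative indexing is the stated bijection", {
  expect_identical(pam_relative_index(19L), -1L)
  expect_identical(pam_relative_index(2L), -18L)
  # bijection round trip over all offsets
  expect_identical(protospacer_offset(pam_relative_index(0:19)), 0:19)
  expect_identical(sort(pam_relative_index(0:19)), -20:-1)
  expect_error(pam_relative_index(20L), "0..19")
  expect_error(pam_relative_index(-1L), "0..19")
  expect_error(protospacer_offset(0L), "-20")
})

test_that("constructed 23-mer yields the expected NGG site", {
  s <- paste0(strrep("C", 20), "TGG")
  sites <- find_guide_sites(s, builtin_pam_specs()["SpCas9"])
  plus <- sites[sites$strand == "+", ]
  expect_identical(nrow(plus), 1L)
  expect_identical(plus$pam_start, 20L)
  expect_identical(plus$pam_end, 23L)
  expect_identical(plus$pam_seq, "TGG")
  expect_identical(plus$protospacer, strrep("C", 20))
  expect_identical(plus$proto_start, 0L)
  expect_identical(plus$proto_end, 20L)
})

test_that("NG sites on the 23-mer match the brute-force oracle", {
  s <- paste0(strrep("C", 20), "TGG")
  spec <- builtin_pam_specs()["SpCas9-NG"]
  sites <- find_guide_sites(s, spec)
  # the qualifying + strand site with the PAM at [20, 22)
  expect_true(any(sites$strand == "+" & sites$pam_start == 20L &
                  sites$pam_end == 22L))
  orc <- oracle_sites(s, spec)
  expect_identical(plain_sites(sites), `rownames<-`(orc, NULL))
})

test_that("scanner equals the every-offset oracle on random sequences", {
  specs <- builtin_pam_specs()
  set.seed(202)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
    sites <- find_guide_sites(s, specs)
    orc <- oracle_sites(s, specs)
    expect_identical(plain_sites(sites), `rownames<-`(orc, NULL))
  }
})

test_that("site set is strand-symmetric under reverse complementation", {
  specs <- builtin_pam_specs()
  set.seed(303)
  for (i in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 250, replace = TRUE),
               collapse = "")
    n <- nchar(s)
    a <- find_guide_sites(s, specs)
    b <- find_guide_sites(reverse_complement(s), specs)
    # mirror: strands swap, coordinates reflect; protospacers identical
    key <- function(d, flip) {
      strand <- if (flip) chartr("+-", "-+", d$strand) else d$strand
      pam_start <- if (flip) n - d$pam_end else d$pam_start
      sort(paste(strand, pam_start, d$cas_variant, d$pam_matched,
                 d$protospacer))
    }
    expect_identical(key(b, TRUE), key(a, FALSE))
  }
})

test_that("N bases, duplicate motifs and short input are handled", {
  # N only matches pattern-N: an N inside the PAM's G positions kills it
  s <- paste0(strrep("A", 20), "TNG")
  expect_identical(nrow(find_guide_sites(s, builtin_pam_specs()["SpCas9"])),
                   0L)
  # NG is reported once per variant (xCas9 and SpCas9-NG)
  s2 <- paste0(strrep("A", 20), "TGT")
  hits <- find_guide_sites(s2, builtin_pam_specs()[c("xCas9", "SpCas9-NG")])
  ng <- hits[hits$strand == "+" & hits$pam_start == 20L, ]
  expect_setequal(ng$cas_variant, c("xCas9", "SpCas9-NG"))
  # too-short sequence: empty result, not an error
  expect_identical(nrow(find_guide_sites("ACGTACGT")), 0L)
})

test_that("guide sites export as TSV and BED", {
  s <- paste0(strrep("C", 20), "TGGA")
  sites <- find_guide_sites(s, builtin_pam_specs()["SpCas9"])
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_guide_sites_tsv(sites, tsv)
  back <- utils::read.delim(tsv)
  expect_identical(back$pam_start, sites$pam_start)
  write_guide_sites_bed(sites, bed)
  bedback <- utils::read.delim(bed, header = FALSE)
  expect_identical(bedback$V2, sites$proto_start)
  expect_identical(bedback$V3, sites$proto_end)
  expect_identical(bedback$V6, sites$strand)
})
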