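# Variant-call tallies: indel and SNV counts and the strand-collapsed
# substitution spectrum, for comparing whole-genome off-target burdens
# between editor treatments. Variant calling itself is upstream.

.SPECTRUM6 <- c("C>T/G>A", "C>A/G>T", "C>G/G>C",
                "T>A/A>T", "T>C/A>G", "T>G/A>C")
.COMP <- c(A = "T", C = "G", G = "C", T = "A")

# Collapse an SNV to its pyrimidine-reference representation.
.collapse_class <- function(ref, alt) {
  flip <- ref %in% c("G", "A")
  r <- ifelse(flip, .COMP[ref], ref)
  a <- ifelse(flip, .COMP[alt], alt)
  key <- paste0(r, ">", a)
  c(`C>T` = "C>T/G>A", `C>A` = "C>A/G>T", `C>G` = "C>G/G>C",
    `T>A` = "T>A/A>T", `T>C` = "T>C/A>G", `T>G` = "T>G/A>C")[key]
}

#' Tally indels, SNVs and the substitution spectrum of a call set
#'
#' Multi-allelic records are split per alternate allele before
#' classification. A split record is an SNV iff ref and alt are both single
#' A/C/G/T bases; it is an indel when ref and alt are plain base strings of
#' different lengths. Same-length multi-base substitutions (MNVs) and
#' symbolic or breakend alleles go to an `other` bucket that is excluded
#' from the spectrum; malformed allele strings are skipped with a warning
#' tally. The spectrum is collapsed to the 6 complementary substitution
#' classes by default; `collapse = FALSE` keeps all 12 directional classes.
#'
#' @param records data.frame with character columns `ref` and `alt`
#'   (`alt` may hold comma-separated alternates), e.g. from
#'   [read_vcf_calls()] or [simulate_variant_calls()].
#' @param collapse collapse complementary classes (default `TRUE`).
#' @return object of class `variant_call_summary`: list with `n_indels`,
#'   `n_snvs`, `n_other`, `n_malformed`, and `spectrum` (data.frame:
#'   `class`, `count`, `frequency`; frequencies sum to 1 when
#'   `n_snvs > 0`).
#' @export
tally_variants <- function(records, collapse = TRUE) {
  stopifnot(is.data.frame(records), all(c("ref", "alt") %in% names(records)))
  ref <- toupper(as.character(records$ref))
  alt <- toupper(as.character(records$alt))
  # split multi-allelic records, one row per alternate
  alts <- strsplit(alt, ",", fixed = TRUE)
  ref <- rep(ref, lengths(alts))
  alt <- unlist(alts, use.names = FALSE)

  classes <- if (collapse) .SPECTRUM6
             else as.vector(outer(c("C", "T", "G", "A"), c("A", "C", "G", "T"),
                                  function(r, a) paste0(r, ">", a)))
  if (!collapse) classes <- classes[substr(classes, 1, 1) !=
                                    substr(classes, 3, 3)]
  counts <- stats::setNames(integer(length(classes)), classes)
  n_indel <- 0L; n_snv <- 0L; n_other <- 0L; n_bad <- 0L

  plain <- function(x) nchar(x) >= 1L &
    !grepl("[^ACGT]", x)
  for (i in seq_along(ref)) {
    r <- ref[i]; a <- alt[i]
    if (is.na(r) || is.na(a) || !nzchar(r) || !nzchar(a)) {
      n_bad <- n_bad + 1L; next
    }
    if (!plain(r) || !plain(a)) {
      # symbolic (<DEL>, *, breakends) or otherwise non-base alleles
      if (grepl("^<.*>$", a) || a == "*" || grepl("[][]", a)) {
        n_other <- n_other + 1L
      } else n_bad <- n_bad + 1L
      next
    }
    if (nchar(r) == 1L && nchar(a) == 1L) {
      if (r == a) { n_bad <- n_bad + 1L; next }
      n_snv <- n_snv + 1L
      key <- if (collapse) .collapse_class(r, a) else paste0(r, ">", a)
      counts[key] <- counts[key] + 1L
    } else if (nchar(r) != nchar(a)) {
      n_indel <- n_indel + 1L
    } else {
      n_other <- n_other + 1L  # MNV
    }
  }
  if (n_bad > 0L)
    warning(n_bad, " malformed record(s) skipped", call. = FALSE)
  spectrum <- data.frame(
    class = classes, count = as.integer(counts),
    frequency = if (n_snv > 0L) as.numeric(counts) / n_snv
                else rep(0, length(counts)),
    stringsAsFactors = FALSE)
  structure(list(n_indels = n_indel, n_snvs = n_snv, n_other = n_other,
                 n_malformed = n_bad, collapse = collapse,
                 spectrum = spectrum),
            class = "variant_call_summary")
}

#' @export
print.variant_call_summary <- function(x, ...) {
  cat("<variant_call_summary>", x$n_snvs, "SNVs,", x$n_indels, "indels",
      if (x$n_other) paste0("(", x$n_other, " other)"), "\n")
  sp <- x$spectrum[x$spectrum$count > 0, ]
  for (i in seq_len(nrow(sp)))
    cat(sprintf("  %-9s %6d  %5.1f%%\n", sp$class[i], sp$count[i],
                100 * sp$frequency[i]))
  invisible(x)
}

#' Compare labelled variant-call summaries
#'
#' Side-by-side counts and spectrum frequencies for two or more summaries,
#' plus pairwise differences in indel and SNV counts. No significance
#' testing is performed.
#'
#' @param summaries named list of [tally_variants()] results (>= 2); names
#'   label the treatments, in input order.
#' @return list with `table` (one row per summary: label, n_indels,
#'   n_snvs, one frequency column per spectrum class) and `differences`
#'   (pairwise rows: label_a, label_b, metric, difference = a - b).
#' @export
compare_summaries <- function(summaries) {
  stopifnot(is.list(summaries), length(summaries) >= 2L)
  if (is.null(names(summaries)))
    names(summaries) <- paste0("sample", seq_along(summaries))
  stopifnot(all(vapply(summaries, inherits, logical(1),
                       "variant_call_summary")))
  classes <- summaries[[1]]$spectrum$class
  tab <- do.call(rbind, lapply(names(summaries), function(nm) {
    s <- summaries[[nm]]
    row <- data.frame(label = nm, n_indels = s$n_indels, n_snvs = s$n_snvs,
                      stringsAsFactors = FALSE)
    freqs <- as.list(stats::setNames(s$spectrum$frequency, classes))
    cbind(row, as.data.frame(freqs, check.names = FALSE))
  }))
  pairs <- utils::combn(names(summaries), 2L, simplify = FALSE)
  differences <- do.call(rbind, lapply(pairs, function(p) {
    a <- summaries[[p[1]]]; b <- summaries[[p[2]]]
    data.frame(label_a = p[1], label_b = p[2],
               metric = c("n_indels", "n_snvs"),
               difference = c(a$n_indels - b$n_indels,
                              a$n_snvs - b$n_snvs),
               stringsAsFactors = FALSE)
  }))
  list(table = tab, differences = differences)
}

#' Read variant calls from a VCF file
#'
#' Wraps `vcfR::read.vcfR()` (plain or gzipped VCF v4.x) and returns the
#' columns [tally_variants()] consumes.
#'
#' @param path VCF file path.
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @export
read_vcf_calls <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
             ref = fix[, "REF"], alt = fix[, "ALT"],
             stringsAsFactors = FALSE)
}

#' Write a summary as TSV or JSON
#'
#' @param summary a [tally_variants()] result.
#' @param path output path.
#' @export
write_summary_tsv <- function(summary, path) {
  head <- data.frame(class = c("n_indels", "n_snvs", "n_other"),
                     count = c(summary$n_indels, summary$n_snvs,
                               summary$n_other),
                     frequency = NA_real_, stringsAsFactors = FALSE)
  utils::write.table(rbind(head, summary$spectrum), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary_tsv
#' @export
write_summary_json <- function(summary, path) {
  obj <- list(n_indels = summary$n_indels, n_snvs = summary$n_snvs,
              n_other = summary$n_other,
              spectrum = summary$spectrum)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
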