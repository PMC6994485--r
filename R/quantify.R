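# Amplicon quantification: anchor reads on the reference flanks of a
# protospacer, count per-position C-to-T conversion, summarise the editing
# window, and the canavanine-selection mutation frequency.

# Reference in protospacer-strand orientation plus protospacer coordinates.
.proto_frame <- function(reference, guide) {
  ref <- as_dna(reference, what = "reference")
  stopifnot(is.data.frame(guide), nrow(guide) == 1L)
  L <- guide$proto_end - guide$proto_start
  if (guide$strand == "+") {
    list(ref = ref, proto_start = guide$proto_start, L = L)
  } else {
    n <- nchar(ref)
    list(ref = reverse_complement(ref),
         proto_start = n - guide$proto_end, L = L)
  }
}

#' Anchor amplicon reads on the protospacer flanks
#'
#' A read is usable iff it contains exact matches to both `flank_length`-nt
#' reference flanks of the protospacer, in the same orientation, separated
#' by exactly the protospacer length (i.e. indel-free across the
#' protospacer). Each read is checked as given and reverse-complemented.
#' Non-usable reads are tallied by reason: `"short"` (shorter than
#' flanks + protospacer), `"indel"` (both flanks found but never at the
#' reference spacing) or `"unanchored"` (a flank missing).
#'
#' @param reads character vector of read sequences (e.g. from
#'   [read_fastq()]).
#' @param reference amplicon reference sequence containing the
#'   protospacer + PAM.
#' @param guide one row of [find_guide_sites()] output locating the
#'   protospacer on `reference`.
#' @param flank_length exact-match anchor length on each side (default 10).
#' @return object of class `anchored_reads`: list with `segments`
#'   (protospacer-length segments of the usable reads, protospacer-strand
#'   orientation), `usable_reads`, `total_reads`, `discarded` (named reason
#'   tally) and `guide`.
#' @export
anchor_reads <- function(reads, reference, guide, flank_length = 10L) {
  fr <- .proto_frame(reference, guide)
  L <- fr$L
  fl <- as.integer(flank_length)
  if (fr$proto_start < fl || fr$proto_start + L + fl > nchar(fr$ref))
    stop("reference lacks ", fl, " nt of flank on both sides of the ",
         "protospacer", call. = FALSE)
  flankL <- substr(fr$ref, fr$proto_start - fl + 1L, fr$proto_start)
  flankR <- substr(fr$ref, fr$proto_start + L + 1L, fr$proto_start + L + fl)
  reads <- toupper(reads)
  n <- length(reads)
  segments <- character(0)
  reasons <- c(short = 0L, indel = 0L, unanchored = 0L)
  min_len <- 2L * fl + L
  too_short <- nchar(reads) < min_len
  reasons["short"] <- sum(too_short)
  pending <- reads[!too_short]
  seg <- rep(NA_character_, length(pending))
  # Vectorised fast path: first flankL occurrence with flankR at the exact
  # reference spacing. Covers all indel-free reads whose flanks are unique.
  fast <- function(rds) {
    p <- as.integer(regexpr(flankL, rds, fixed = TRUE))
    ok <- p > 0L &
      substr(rds, p + fl + L, p + 2L * fl + L - 1L) == flankR
    list(ok = ok, seg = substr(rds, p + fl, p + fl + L - 1L))
  }
  f1 <- fast(pending)
  seg[f1$ok] <- f1$seg[f1$ok]
  todo <- which(is.na(seg))
  if (length(todo)) {
    rc <- reverse_complement(pending[todo])
    f2 <- fast(rc)
    seg[todo[f2$ok]] <- f2$seg[f2$ok]
    todo <- todo[!f2$ok]
  }
  if (length(todo)) {
    # Thorough scan over every flankL occurrence, both orientations.
    seg_of <- function(rd) {
      p <- 1L
      repeat {
        hit <- regexpr(flankL, substr(rd, p, nchar(rd)), fixed = TRUE)
        if (hit == -1L) return(NULL)
        pos <- p + as.integer(hit) - 1L
        if (substr(rd, pos + fl + L, pos + fl + L + fl - 1L) == flankR)
          return(substr(rd, pos + fl, pos + fl + L - 1L))
        p <- pos + 1L
      }
    }
    for (j in todo) {
      rd <- pending[j]
      sj <- seg_of(rd)
      if (is.null(sj)) sj <- seg_of(reverse_complement(rd))
      if (!is.null(sj)) {
        seg[j] <- sj
      } else {
        both <- function(x) grepl(flankL, x, fixed = TRUE) &&
          grepl(flankR, x, fixed = TRUE)
        if (both(rd) || both(reverse_complement(rd)))
          reasons["indel"] <- reasons["indel"] + 1L
        else reasons["unanchored"] <- reasons["unanchored"] + 1L
      }
    }
  }
  segments <- seg[!is.na(seg)]
  structure(list(segments = segments, usable_reads = length(segments),
                 total_reads = n, discarded = reasons, guide = guide,
                 protospacer = substr(fr$ref, fr$proto_start + 1L,
                                      fr$proto_start + L)),
            class = "anchored_reads")
}

#' Per-position C-to-T conversion table
#'
#' For every reference-C position of the protospacer, the conversion percent
#' is 100 x (usable reads carrying T there) / (usable reads); C-to-A and
#' C-to-G reads are tallied separately as `c_to_other`. Positions are keyed
#' by PAM-relative index. With zero usable reads a defined empty table is
#' returned (no division).
#'
#' @param anchored an [anchor_reads()] result.
#' @return object of class `editing_table`: list with `per_position`
#'   (data.frame: `position`, `c_to_t`, `c_to_other`, `conversion_percent`),
#'   `usable_reads`, `total_reads`, `discarded`, `guide`.
#' @export
quantify_conversions <- function(anchored) {
  stopifnot(inherits(anchored, "anchored_reads"))
  proto <- anchored$protospacer
  L <- nchar(proto)
  ref_chars <- strsplit(proto, "", fixed = TRUE)[[1]]
  c_offsets <- which(ref_chars == "C")          # 1-based
  nuse <- anchored$usable_reads
  if (length(c_offsets)) {
    seg <- anchored$segments
    c_to_t <- integer(length(c_offsets))
    c_to_other <- integer(length(c_offsets))
    for (k in seq_along(c_offsets)) {
      b <- substr(seg, c_offsets[k], c_offsets[k])
      c_to_t[k] <- sum(b == "T")
      c_to_other[k] <- sum(b == "A" | b == "G")
    }
    pct <- if (nuse > 0L) 100 * c_to_t / nuse else rep(0, length(c_to_t))
    per_position <- data.frame(
      position = c_offsets - 1L - L,
      c_to_t = c_to_t, c_to_other = c_to_other,
      conversion_percent = pct)
  } else {
    per_position <- data.frame(position = integer(0), c_to_t = integer(0),
                               c_to_other = integer(0),
                               conversion_percent = numeric(0))
  }
  structure(list(per_position = per_position, usable_reads = nuse,
                 total_reads = anchored$total_reads,
                 discarded = anchored$discarded, guide = anchored$guide),
            class = "editing_table")
}

#' @export
print.editing_table <- function(x, digits = 1, ...) {
  cat("<editing_table>", x$usable_reads, "usable /", x$total_reads,
      "total reads\n")
  pp <- x$per_position
  for (i in seq_len(nrow(pp))) {
    bars <- strrep("#", round(pp$conversion_percent[i] / 2))
    cat(sprintf("  C%4d %6.*f%% %s\n", pp$position[i], digits,
                pp$conversion_percent[i], bars))
  }
  invisible(x)
}

#' Write an editing table as TSV
#'
#' @param table an [quantify_conversions()] result.
#' @param path output path.
#' @export
write_editing_tsv <- function(table, path) {
  utils::write.table(table$per_position, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Summarise the editing window of an editing table
#'
#' The window spans the most PAM-distal to the most PAM-proximal position
#' whose conversion reaches `threshold_percent`. The predominant position is
#' the argmax conversion; ties go to the position closest to -18, then the
#' more PAM-distal one. The predominance ratio is top conversion / runner-up
#' conversion (`Inf` when the runner-up is zero or absent).
#'
#' @param table an [quantify_conversions()] result.
#' @param threshold_percent window inclusion threshold (default 10).
#' @return object of class `window_summary`: list with `threshold_percent`,
#'   `window_bounds` (length-2 integer or `NULL` when empty),
#'   `predominant_position` (`NA` when empty) and `predominance_ratio`.
#' @export
summarize_window <- function(table, threshold_percent = 10) {
  stopifnot(inherits(table, "editing_table"))
  pp <- table$per_position
  hot <- pp$position[pp$conversion_percent >= threshold_percent]
  if (!length(hot)) {
    return(structure(list(threshold_percent = threshold_percent,
                          window_bounds = NULL,
                          predominant_position = NA_integer_,
                          predominance_ratio = NA_real_),
                     class = "window_summary"))
  }
  bounds <- c(min(hot), max(hot))
  ord <- order(-pp$conversion_percent, abs(pp$position + 18L), pp$position)
  top <- pp[ord[1L], ]
  ratio <- if (nrow(pp) < 2L || pp$conversion_percent[ord[2L]] == 0) Inf
           else top$conversion_percent / pp$conversion_percent[ord[2L]]
  structure(list(threshold_percent = threshold_percent,
                 window_bounds = bounds,
                 predominant_position = top$position,
                 predominance_ratio = ratio),
            class = "window_summary")
}

#' @export
print.window_summary <- function(x, ...) {
  if (is.null(x$window_bounds)) {
    cat("<window_summary> empty window at threshold",
        x$threshold_percent, "%\n")
  } else {
    cat("<window_summary> window [", x$window_bounds[1], ",",
        x$window_bounds[2], "], predominant C at",
        x$predominant_position, "(ratio",
        format(x$predominance_ratio, digits = 3), ")\n")
  }
  invisible(x)
}

#' Canavanine-selection mutation frequency
#'
#' The induced mutation frequency estimated from a canavanine selection:
#' the ratio of the colony count on canavanine plates to the colony count
#' on drug-free plates.
#'
#' @param colonies_selective colonies on canavanine-supplemented plates.
#' @param colonies_nonselective colonies on drug-free plates (must be > 0).
#' @return the frequency as a fraction. A selective count exceeding the
#'   non-selective count gives a warning but the ratio is still returned.
#' @export
canavanine_frequency <- function(colonies_selective, colonies_nonselective) {
  s <- colonies_selective; t <- colonies_nonselective
  if (!is.numeric(s) || !is.numeric(t) || length(s) != 1L ||
      length(t) != 1L || is.na(s) || is.na(t) || s < 0 || t < 0)
    stop("colony counts must be single non-negative numbers", call. = FALSE)
  if (t == 0) stop("non-selective colony count must be > 0", call. = FALSE)
  if (s > t)
    warning("selective colony count exceeds non-selective count",
            call. = FALSE)
  s / t
}

#' Read / write FASTQ
#'
#' `read_fastq` wraps [Biostrings::readDNAStringSet()] (qualities are not
#' used by the quantifier); `write_fastq` writes constant-quality records.
#'
#' @param path file path.
#' @return `read_fastq`: named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- names(x)
  out
}

#' @rdname read_fastq
#' @param reads named character vector of read sequences.
#' @param quality_char constant per-base quality character (default `"I"`,
#'   Phred 40).
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  qs <- Biostrings::BStringSet(vapply(nchar(reads),
                                      function(k) strrep(quality_char, k),
                                      character(1)))
  x <- Biostrings::DNAStringSet(unname(reads))
  names(x) <- ids
  Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                              qualities = qs)
  invisible(path)
}
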