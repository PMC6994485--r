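# Protospacer/PAM discovery on both strands and the PAM-relative coordinate
# convention used throughout the toolkit.
#
# Coordinates are 0-based, half-open intervals on the + strand of the source
# sequence. PAM-relative positions are negative integers: -1 is the base
# immediately 5'-adjacent to the first PAM base on the protospacer strand,
# so in a 20-mer protospacer the PAM-distal end is -20 and "C-18" is
# protospacer offset 2 (third base).

#' Convert a protospacer offset to a PAM-relative position
#'
#' @param offset 0-based offset(s) within the protospacer (`0..L-1`).
#' @param protospacer_length protospacer length (default 20).
#' @return integer vector of PAM-relative positions in `-L..-1`; offset
#'   `L-1` (PAM-adjacent) maps to `-1`.
#' @examples
#' pam_relative_index(19)  # -1
#' pam_relative_index(2)   # -18
#' @export
pam_relative_index <- function(offset, protospacer_length = 20L) {
  offset <- as.integer(offset)
  if (any(is.na(offset)) || any(offset < 0L) ||
      any(offset >= protospacer_length))
    stop("offset must be in 0..", protospacer_length - 1L, call. = FALSE)
  offset - as.integer(protospacer_length)
}

#' @rdname pam_relative_index
#' @param index PAM-relative position(s) in `-L..-1`.
#' @export
protospacer_offset <- function(index, protospacer_length = 20L) {
  index <- as.integer(index)
  if (any(is.na(index)) || any(index < -protospacer_length) ||
      any(index > -1L))
    stop("PAM-relative index must be in -", protospacer_length, "..-1",
         call. = FALSE)
  index + as.integer(protospacer_length)
}

.empty_guide_sites <- function() {
  structure(
    data.frame(
      sequence_name = character(0), strand = character(0),
      pam_start = integer(0), pam_end = integer(0),
      cas_variant = character(0), pam_matched = character(0),
      pam_seq = character(0), protospacer = character(0),
      proto_start = integer(0), proto_end = integer(0),
      stringsAsFactors = FALSE),
    class = c("guide_sites", "data.frame"))
}

#' Find protospacer/PAM guide sites on both strands
#'
#' Scans a sequence for every occurrence of every PAM motif of every supplied
#' Cas9 variant, on both strands, that has a full-length protospacer directly
#' 5' of it on the protospacer strand. Overlapping and nested motifs (e.g. NG
#' inside NGG) are each reported under their own variant, and a motif shared
#' by two variants (NG for xCas9 and SpCas9-NG) is reported once per variant.
#'
#' Coordinates (`pam_start`/`pam_end`, `proto_start`/`proto_end`) are 0-based
#' half-open intervals on the + strand. For a site on the `-` strand the
#' protospacer column still reads 5'->3' on the protospacer (minus) strand,
#' and its + strand interval lies 3' of the PAM interval.
#'
#' @param seq character scalar (optionally named) or `DNAString`; `N` bases
#'   are allowed and match pattern-N only.
#' @param pam_specs a [pam_spec] or list of them (default: the built-in Cas9
#'   variant panel, [builtin_pam_specs()]).
#' @param protospacer_length protospacer length (default 20).
#' @return data.frame of class `guide_sites`, sorted by + strand PAM start,
#'   then strand (+ before -), then variant, then motif. A sequence too
#'   short to host any site yields zero rows (not an error).
#' @export
find_guide_sites <- function(seq, pam_specs = builtin_pam_specs(),
                             protospacer_length = 20L) {
  seq_name <- if (!is.null(names(seq)) && nzchar(names(seq)[1]))
    names(seq)[1] else "seq"
  s <- as_dna(seq[[1]])
  if (inherits(pam_specs, "pam_spec")) pam_specs <- list(pam_specs)
  if (!length(pam_specs) || !all(vapply(pam_specs, inherits, logical(1),
                                        "pam_spec")))
    stop("pam_specs must be pam_spec objects", call. = FALSE)
  L <- as.integer(protospacer_length)
  n <- nchar(s)
  strands <- list(`+` = s, `-` = reverse_complement(s))
  rows <- list()
  for (strand in names(strands)) {
    sseq <- strands[[strand]]
    chars <- strsplit(sseq, "", fixed = TRUE)[[1]]
    for (spec in pam_specs) {
      for (motif in spec$motifs) {
        m <- nchar(motif)
        if (n < L + m) next
        pchars <- .check_pattern(motif)
        starts0 <- L:(n - m)  # 0-based PAM starts with full protospacer 5'
        hits <- starts0[.iupac_scan(chars, starts0, pchars)]
        for (p0 in hits) {
          proto <- substr(sseq, p0 - L + 1L, p0)
          pamseq <- substr(sseq, p0 + 1L, p0 + m)
          if (strand == "+") {
            pam_start <- p0; pam_end <- p0 + m
            proto_start <- p0 - L; proto_end <- p0
          } else {
            pam_start <- n - (p0 + m); pam_end <- n - p0
            proto_start <- n - p0; proto_end <- n - p0 + L
          }
          rows[[length(rows) + 1L]] <- data.frame(
            sequence_name = seq_name, strand = strand,
            pam_start = pam_start, pam_end = pam_end,
            cas_variant = spec$cas_variant_name, pam_matched = motif,
            pam_seq = pamseq, protospacer = proto,
            proto_start = proto_start, proto_end = proto_end,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) return(.empty_guide_sites())
  out <- do.call(rbind, rows)
  out <- out[order(out$pam_start, out$strand, out$cas_variant,
                   out$pam_matched), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("guide_sites", "data.frame")
  attr(out, "source_sequence") <- s
  attr(out, "protospacer_length") <- L
  out
}

#' Write guide sites as TSV or BED
#'
#' The BED intervals cover the protospacer (0-based half-open), with the
#' name column `cas_variant|pam_matched` and the strand column set.
#'
#' @param sites a `guide_sites` data.frame from [find_guide_sites()].
#' @param path output file path.
#' @export
write_guide_sites_tsv <- function(sites, path) {
  utils::write.table(as.data.frame(sites), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_guide_sites_tsv
#' @export
write_guide_sites_bed <- function(sites, path) {
  bed <- data.frame(
    chrom = sites$sequence_name,
    start = sites$proto_start,
    end = sites$proto_end,
    name = paste(sites$cas_variant, sites$pam_matched, sep = "|"),
    score = 0L,
    strand = sites$strand,
    stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
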