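# Nucleotide sequence utilities: validation, reverse complement, IUPAC
# matching with the degenerate codes used by the editor rule table.

# Degenerate-code expansions. Subject N is deliberately absent from every
# expansion: an ambiguous base never satisfies a literal or D/R/Y code and
# is matched by pattern-N only (conservative site calling).
.IUPAC_EXPAND <- list(
  A = "A", C = "C", G = "G", T = "T",
  N = c("A", "C", "G", "T"),
  D = c("A", "G", "T"),
  R = c("A", "G"),
  Y = c("C", "T")
)

.SEQ_ALPHABET <- c("A", "C", "G", "T", "N")

#' Normalize and validate a nucleotide sequence
#'
#' Accepts a character scalar (or a [Biostrings::DNAString]), upper-cases it
#' and checks that it only contains A/C/G/T/N.
#'
#' @param x character scalar or `DNAString`.
#' @param allow_n logical; permit ambiguous `N` bases (default `TRUE`).
#' @param what label used in error messages.
#' @return upper-case character scalar.
#' @export
as_dna <- function(x, allow_n = TRUE, what = "sequence") {
  if (inherits(x, "XString")) x <- as.character(x)
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single character string", call. = FALSE)
  x <- toupper(x)
  if (nchar(x) < 1L) stop(what, " must have length >= 1", call. = FALSE)
  alphabet <- if (allow_n) .SEQ_ALPHABET else .SEQ_ALPHABET[1:4]
  bad <- setdiff(unique(strsplit(x, "", fixed = TRUE)[[1]]), alphabet)
  if (length(bad))
    stop(what, " contains illegal character(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  x
}

#' Reverse complement of a DNA sequence
#'
#' Watson-Crick complement, reversed; `N` maps to `N`. Vectorised over `x`.
#'
#' @param x character vector of sequences over A/C/G/T/N (case-insensitive).
#' @return character vector of reverse complements (upper case).
#' @examples
#' reverse_complement("ACGT")  # palindrome -> "ACGT"
#' reverse_complement("AAA")   # "TTT"
#' @export
reverse_complement <- function(x) {
  vapply(x, function(s) {
    s <- as_dna(s)
    comp <- chartr("ACGTN", "TGCAN", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.check_pattern <- function(pattern) {
  pchars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(pchars), names(.IUPAC_EXPAND))
  if (length(bad))
    stop("unsupported IUPAC code(s) in pattern: ",
         paste(bad, collapse = ", "), call. = FALSE)
  pchars
}

#' Match a degenerate IUPAC pattern against a same-length window
#'
#' Supported codes are the ones the editor rule table uses: the literals
#' A/C/G/T plus N (any base), D (not C), R (A or G) and Y (C or T). Any other
#' code is rejected rather than silently accepted. An `N` in the *subject*
#' window matches pattern-N only.
#'
#' @param pattern IUPAC pattern (character scalar).
#' @param window subject sequence of the same length.
#' @return `TRUE` iff every position of `window` satisfies its pattern code.
#' @examples
#' iupac_match("NGA", "TGA")  # TRUE
#' iupac_match("D", "C")      # FALSE: D = A, G or T
#' iupac_match("TCR", "TCA")  # TRUE
#' iupac_match("TCR", "TCC")  # FALSE
#' @export
iupac_match <- function(pattern, window) {
  pchars <- .check_pattern(pattern)
  window <- as_dna(window, what = "window")
  wchars <- strsplit(window, "", fixed = TRUE)[[1]]
  if (length(pchars) != length(wchars))
    stop("pattern and window must have the same length", call. = FALSE)
  all(mapply(function(p, w) p == "N" || w %in% .IUPAC_EXPAND[[p]],
             pchars, wchars))
}

# Vectorised core used by the scanner: ok[i] says whether the window of
# length(pchars) starting at 0-based offset starts0[i] in chars matches.
.iupac_scan <- function(chars, starts0, pchars) {
  ok <- rep(TRUE, length(starts0))
  for (j in seq_along(pchars)) {
    if (pchars[j] == "N") next   # pattern-N takes any base, including N
    w <- chars[starts0 + j]
    ok <- ok & (w %in% .IUPAC_EXPAND[[pchars[j]]])
  }
  ok
}

#' PAM specification for one Cas9 variant
#'
#' @param cas_variant_name label, e.g. `"SpCas9"`, `"VQR-Cas9"`.
#' @param motifs character vector of IUPAC PAM motifs, each 2-4 nt, over
#'   the supported codes (A/C/G/T/N/R/Y/D).
#' @return object of class `pam_spec`.
#' @export
pam_spec <- function(cas_variant_name, motifs) {
  stopifnot(is.character(cas_variant_name), length(cas_variant_name) == 1L)
  if (!is.character(motifs) || length(motifs) < 1L)
    stop("motif list must be non-empty", call. = FALSE)
  motifs <- toupper(motifs)
  for (m in motifs) {
    if (nchar(m) < 2L || nchar(m) > 4L)
      stop("PAM motif must be 2-4 characters: ", m, call. = FALSE)
    .check_pattern(m)
  }
  structure(list(cas_variant_name = cas_variant_name, motifs = motifs),
            class = "pam_spec")
}

#' @export
print.pam_spec <- function(x, ...) {
  cat("<pam_spec>", x$cas_variant_name, ":",
      paste(x$motifs, collapse = ", "), "\n")
  invisible(x)
}

#' Built-in PAM specifications of the Cas9 variant panel
#'
#' Wild-type SpCas9 (NGG) and the four altered-PAM variants used to extend
#' the targeting scope of narrow-window BEs: VQR-Cas9 (NGA), VRER-Cas9
#' (NGCG), xCas9 (NG, GAA, GAT) and SpCas9-NG (NG).
#'
#' @return named list of [pam_spec] objects.
#' @export
builtin_pam_specs <- function() {
  list(
    `SpCas9`    = pam_spec("SpCas9", "NGG"),
    `VQR-Cas9`  = pam_spec("VQR-Cas9", "NGA"),
    `VRER-Cas9` = pam_spec("VRER-Cas9", "NGCG"),
    `xCas9`     = pam_spec("xCas9", c("NG", "GAA", "GAT")),
    `SpCas9-NG` = pam_spec("SpCas9-NG", "NG")
  )
}

#' Read / write FASTA
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] and
#' [Biostrings::writeXStringSet()] returning plain named character vectors,
#' which is what the rest of the toolkit consumes.
#'
#' @param path file path.
#' @return `read_fasta`: named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(vapply(seqs, as_dna, character(1)))
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}
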