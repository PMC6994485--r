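# Shared fixtures and independent oracles, built in code at test time.

# A 20-mer protospacer that is all A except the assigned PAM-relative
# positions, e.g. mk_proto(c(`-18` = "C")).
mk_proto <- function(assign) {
  p <- rep("A", 20)
  for (nm in names(assign)) p[as.integer(nm) + 21L] <- assign[[nm]]
  paste(p, collapse = "")
}

# Random A/T-only background (no G/C, hence no PAM motif can match).
at_background <- function(k) {
  paste(sample(c("A", "T"), k, replace = TRUE), collapse = "")
}

# Independent brute-force guide-site oracle: tests every window of every
# motif at every offset on both strands, using its own degenerate-code
# table and naive per-window checks.
oracle_sites <- function(seq, pam_specs, L = 20L) {
  codes <- list(A = "A", C = "C", G = "G", T = "T",
                N = c("A", "C", "G", "T"), D = c("A", "G", "T"),
                R = c("A", "G"), Y = c("C", "T"))
  match1 <- function(motif, window) {
    pc <- strsplit(motif, "")[[1]]; wc <- strsplit(window, "")[[1]]
    all(vapply(seq_along(pc),
               function(j) wc[j] %in% codes[[pc[j]]], logical(1)))
  }
  rc <- function(x) paste(rev(strsplit(chartr("ACGTN", "TGCAN", x),
                                       "")[[1]]), collapse = "")
  n <- nchar(seq)
  rows <- list()
  for (strand in c("+", "-")) {
    sseq <- if (strand == "+") seq else rc(seq)
    for (spec in pam_specs) {
      for (motif in spec$motifs) {
        m <- nchar(motif)
        for (p0 in seq_len(max(0L, n - m + 1L)) - 1L) {
          if (p0 < L) next
          if (!match1(motif, substr(sseq, p0 + 1L, p0 + m))) next
          if (strand == "+") {
            pam_start <- p0
          } else {
            pam_start <- n - (p0 + m)
          }
          rows[[length(rows) + 1L]] <- data.frame(
            strand = strand, pam_start = pam_start,
            cas_variant = spec$cas_variant_name, pam_matched = motif,
            protospacer = substr(sseq, p0 - L + 1L, p0),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) return(data.frame(strand = character(0),
                                       pam_start = integer(0),
                                       cas_variant = character(0),
                                       pam_matched = character(0),
                                       protospacer = character(0)))
  out <- do.call(rbind, rows)
  out[order(out$pam_start, out$strand, out$cas_variant, out$pam_matched), ,
      drop = FALSE]
}

# Strip class/attributes from a guide_sites frame down to the oracle's
# comparison columns.
plain_sites <- function(x) {
  d <- as.data.frame(x)[, c("strand", "pam_start", "cas_variant",
                            "pam_matched", "protospacer")]
  d <- data.frame(d, stringsAsFactors = FALSE)
  rownames(d) <- NULL
  d
}

# Reference amplicon with an embedded protospacer + PAM at offset 20, and
# its guide row. Protospacer Cs at -18, -16, -11, -10.
demo_reference <- function(proto = "ATCACGTTACCAGTAATGAT", pam = "TGG",
                           seed = 11) {
  bg <- random_genome(80, seed = seed)
  ref <- paste0(substr(bg, 1, 20), proto, pam, substr(bg, 44, 80))
  g <- find_guide_sites(ref, builtin_pam_specs()["SpCas9"])
  g <- g[g$strand == "+" & g$proto_start == 20L, , drop = FALSE]
  stopifnot(nrow(g) == 1L)
  list(ref = ref, guide = g)
}

# Variant record built around a given protospacer + PAM in an A/T
# background; focal position is PAM-relative (the protospacer base there
# must be C and is carried as the record's focal base).
mk_variant <- function(id, proto, pam, focal_pos, flank = 28L) {
  off <- focal_pos + 20L              # 0-based offset of focal C
  pc <- strsplit(proto, "")[[1]]
  stopifnot(pc[off + 1L] == "C")
  f5 <- paste0(at_background(flank), paste(pc[seq_len(off)], collapse = ""))
  f3 <- paste0(paste(pc[(off + 2L):20L], collapse = ""), pam,
               at_background(flank))
  variant_records(id, f5, f3, "C")
}

# The 19 rule-table rows with a protospacer construction that matches
# exactly that row (and, by design of the constructions, no other row).
conformance_cases <- function() {
  list(
    list(row = "<-19 no", target = -20L, proto = mk_proto(c(`-20` = "C")),
         bes = c("nCDA1-BE3", "nCDA1d198-BE3", "A3A-NL-BE3")),
    list(row = "-19 no", target = -19L, proto = mk_proto(c(`-19` = "C")),
         bes = c("nCDA1-BE3", "nCDA1d198-BE3", "A3A-NL-BE3")),
    list(row = "-19 CCDDD", target = -19L,
         proto = mk_proto(c(`-20` = "C", `-19` = "C")),
         bes = "cCDA1-BE3"),
    list(row = "-18 no", target = -18L, proto = mk_proto(c(`-18` = "C")),
         bes = c("nCDA1d198-BE3", "nCDA1-BE3", "cCDA1-BE3", "A3A-NL-BE3")),
    list(row = "-18 NCN", target = -18L,
         proto = mk_proto(c(`-18` = "C", `-17` = "C")),
         bes = "nCDA1d(194-188)-BE3"),
    list(row = "-17 no", target = -17L, proto = mk_proto(c(`-17` = "C")),
         bes = c("nCDA1d198-BE3", "cCDA1-BE3", "A3A-BE3", "nCDA1-BE3",
                 "BE3")),
    list(row = "-17 DCN", target = -17L,
         proto = mk_proto(c(`-17` = "C", `-16` = "C")),
         bes = "nCDA1d(194-188)-BE3"),
    list(row = "-17 CCDDDD", target = -17L,
         proto = mk_proto(c(`-18` = "C", `-17` = "C")),
         bes = "BE3"),
    list(row = "-16 no", target = -16L, proto = mk_proto(c(`-16` = "C")),
         bes = c("BE3", "nCDA1d198-BE3", "A3A-BE3")),
    list(row = "-16 DDDCC", target = -16L,
         proto = mk_proto(c(`-16` = "C", `-15` = "C")),
         bes = "cCDA1-BE3"),
    list(row = "-16 TCC", target = -16L,
         proto = mk_proto(c(`-17` = "T", `-16` = "C", `-15` = "C")),
         bes = c("cCDA1-BE3", "YEE-BE3", "BE-PAPAPAP")),
    list(row = "-16 NCD", target = -16L,
         proto = mk_proto(c(`-17` = "C", `-16` = "C")),
         bes = c("A3Ad182-BE3", "A3A(Y130F)d186-BE3")),
    list(row = "-15 no", target = -15L, proto = mk_proto(c(`-15` = "C")),
         bes = c("BE3", "nCDA1d198-BE3", "A3A-BE3")),
    list(row = "-15 CDCD", target = -15L,
         proto = mk_proto(c(`-17` = "C", `-15` = "C")),
         bes = c("BE-PAPAPAP", "A3Ad182-BE3", "A3A(Y130F)d186-BE3",
                 "YEE-BE3")),
    list(row = "-15 DCN", target = -15L,
         proto = mk_proto(c(`-17` = "C", `-15` = "C", `-14` = "C")),
         bes = c("A3Ad182-BE3", "A3A(Y130F)d186-BE3")),
    list(row = "-15 RCCD", target = -15L,
         proto = mk_proto(c(`-17` = "G", `-16` = "C", `-15` = "C")),
         bes = "BE-PAPAPAP"),
    list(row = "-14 no", target = -14L, proto = mk_proto(c(`-14` = "C")),
         bes = c("BE3", "A3A-BE3", "nCDA1-BE3")),
    list(row = "-14 DDCC", target = -14L,
         proto = mk_proto(c(`-20` = "C", `-14` = "C", `-13` = "C")),
         bes = "BE-PAPAPAP"),
    list(row = ">-14 no", target = -10L, proto = mk_proto(c(`-10` = "C")),
         bes = c("A3A-BE3", "nCDA1-BE3", "BE3"))
  )
}
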