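# ClinVar-style scan: which candidate pathogenic T->C (A->G) variants can a
# narrow-window cytosine editor revert precisely?
#
# A correctable variant is one whose disease allele carries a C (on one
# strand) that some guide places inside a cataloged editor window. Both
# strand representations are evaluated; candidates are ranked by a priority
# ranking of target positions (default C-18 > C-17 > C-19, extended by the
# A3A positions -16 and -15), then by whether a rule matched precisely, then
# by fewest high-risk bystanders, with deterministic tie-breaks.

#' Build a variant record table
#'
#' @param id character vector of record identifiers.
#' @param flank5,flank3 character vectors of 5' / 3' flanking sequence
#'   around the focal base, on the reported strand (>= 25 nt each for
#'   scanning).
#' @param disease_base the focal base of the disease allele on the reported
#'   strand: `"C"` for a T-to-C variant, `"G"` when the C lies on the
#'   complementary strand (an A-to-G variant as reported).
#' @return data.frame of class `variant_records`.
#' @export
variant_records <- function(id, flank5, flank3, disease_base = "C") {
  out <- data.frame(id = as.character(id),
                    flank5 = toupper(flank5), flank3 = toupper(flank3),
                    disease_base = toupper(disease_base),
                    stringsAsFactors = FALSE)
  stopifnot(all(out$disease_base %in% c("A", "C", "G", "T")))
  class(out) <- c("variant_records", "data.frame")
  out
}

# PAM motifs through which an editor can be deployed. CDA1-derived fusions
# were built for the whole Cas9 variant panel and tolerate Cas9 replacement,
# so they are available behind every paneled PAM; every other editor is tied
# to the PAMs of its own profile (NGG for the A3A/APOBEC1 editors).
.editor_pam_motifs <- function(name, catalog) {
  p <- catalog$profiles[[name]]
  if (identical(p$deaminase_family, "CDA1"))
    return(unique(unlist(lapply(catalog$pam_specs, `[[`, "motifs"))))
  unique(unlist(lapply(p$compatible_pams, `[[`, "motifs")))
}

# Can this editor be used at a site whose PAM region starts at 0-based
# position pam_start0 of sequence s (protospacer-strand orientation)?
.editor_pam_ok <- function(name, s, pam_start0, catalog) {
  for (m in .editor_pam_motifs(name, catalog)) {
    len <- nchar(m)
    if (pam_start0 + len > nchar(s)) next
    if (iupac_match(m, substr(s, pam_start0 + 1L, pam_start0 + len)))
      return(TRUE)
  }
  FALSE
}

# Enumerate guide candidates that place a focal C (0-based position `focal`
# of sequence `s`, which must read C there) inside a cataloged window.
# Recommended editors are restricted to those deployable at the site's PAM;
# `precise` requires a matched rule with at least one deployable editor.
# Returns a data.frame of candidates (possibly empty).
.scan_one_strand <- function(s, focal, strand_label, catalog) {
  if (substr(s, focal + 1L, focal + 1L) != "C") return(NULL)
  sites <- find_guide_sites(s, catalog$pam_specs)
  sites <- sites[sites$strand == "+" &
                 sites$proto_start <= focal & focal < sites$proto_end, ,
                 drop = FALSE]
  # one candidate per distinct protospacer placement
  sites <- sites[!duplicated(sites$proto_start), , drop = FALSE]
  if (!nrow(sites)) return(NULL)
  wins <- Filter(function(p) !is.null(p$window) && is.null(p$members),
                 catalog$profiles)
  win_lo <- min(vapply(wins, function(p) p$window[1], integer(1)))
  win_hi <- max(vapply(wins, function(p) p$window[2], integer(1)))
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    pos <- pam_relative_index(focal - sites$proto_start[i])
    if (pos < win_lo || pos > win_hi) next
    rec <- recommend(sites$protospacer[i], pos, catalog)
    effective <- Filter(function(nm)
      .editor_pam_ok(nm, s, sites$proto_end[i], catalog), rec$bes)
    profiled <- Filter(function(nm) {
      p <- catalog$profiles[[nm]]
      !is.null(p$window) && is.null(p$members)
    }, effective)
    n_high <- if (length(profiled)) {
      min(vapply(profiled, function(nm) {
        rep <- bystander_report(sites$protospacer[i], pos, nm, catalog)
        sum(rep$tier == "high")
      }, integer(1)))
    } else NA_integer_
    rows[[length(rows) + 1L]] <- data.frame(
      strand = strand_label, position = pos,
      cas_variant = sites$cas_variant[i], pam_matched = sites$pam_matched[i],
      pam_seq = sites$pam_seq[i], protospacer = sites$protospacer[i],
      proto_start = sites$proto_start[i],
      precise = rec$precise && length(effective) > 0L,
      recommended_bes = paste(effective, collapse = ","),
      n_high_risk_bystanders = n_high,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Scan variant records for precise correctability
#'
#' For every record, both strand representations are examined (the reported
#' strand and its reverse complement; only representations where the focal
#' disease base reads C can host a cytosine editor). Every guide site of
#' every cataloged Cas9 PAM variant that places the focal C inside a
#' cataloged editor window is a candidate. Candidates are ranked by:
#' position under `catalog$ranking` (earlier is better; unranked positions
#' last), then a matched precise rule, then fewest high-risk bystanders,
#' then smallest distance to the PAM, then the reported strand before its
#' complement. The verdict is `"precisely-correctable"` when the best
#' candidate matched a rule, `"bystander-prone"` when candidates exist but
#' none matched, and `"not-targetable"` when no candidate exists.
#'
#' Records with flanks shorter than `min_flank` are skipped with a warning
#' (verdict `NA`), not an error.
#'
#' @param variants a [variant_records()] data.frame (or one with the same
#'   columns).
#' @param catalog a [builtin_catalog()] object (its `ranking` supplies the
#'   position priority).
#' @param min_flank minimum flank length in nt (default 25).
#' @return the input with columns `verdict`, `best_strand`,
#'   `best_position`, `best_cas_variant`, `best_pam`, `best_protospacer`,
#'   `recommended_bes`, `n_high_risk_bystanders`, `n_candidates` appended.
#' @export
scan_variants <- function(variants, catalog = builtin_catalog(),
                          min_flank = 25L) {
  stopifnot(all(c("id", "flank5", "flank3", "disease_base") %in%
                names(variants)))
  n <- nrow(variants)
  out <- as.data.frame(variants)
  out$verdict <- NA_character_
  out$best_strand <- NA_character_
  out$best_position <- NA_integer_
  out$best_cas_variant <- NA_character_
  out$best_pam <- NA_character_
  out$best_protospacer <- NA_character_
  out$recommended_bes <- NA_character_
  out$n_high_risk_bystanders <- NA_integer_
  out$n_candidates <- 0L
  for (i in seq_len(n)) {
    if (nchar(out$flank5[i]) < min_flank || nchar(out$flank3[i]) < min_flank) {
      warning("record ", out$id[i], " skipped: flanks shorter than ",
              min_flank, " nt", call. = FALSE)
      next
    }
    s <- as_dna(paste0(out$flank5[i], out$disease_base[i], out$flank3[i]),
                what = paste0("record ", out$id[i]))
    focal <- nchar(out$flank5[i])                 # 0-based focal index
    cands <- rbind(
      .scan_one_strand(s, focal, "+", catalog),
      .scan_one_strand(reverse_complement(s), nchar(s) - 1L - focal, "-",
                       catalog))
    out$n_candidates[i] <- if (is.null(cands)) 0L else nrow(cands)
    if (is.null(cands)) {
      out$verdict[i] <- "not-targetable"
      next
    }
    rank_pos <- match(cands$position, catalog$ranking)
    rank_pos[is.na(rank_pos)] <- length(catalog$ranking) + 1L
    n_high <- cands$n_high_risk_bystanders
    n_high[is.na(n_high)] <- .Machine$integer.max
    # a precisely-addressable candidate always beats an imprecise one;
    # among precise candidates the position priority ranking decides
    ord <- order(!cands$precise, rank_pos, n_high, abs(cands$position),
                 cands$strand, cands$proto_start)
    best <- cands[ord[1L], ]
    out$verdict[i] <- if (best$precise) "precisely-correctable"
                      else "bystander-prone"
    out$best_strand[i] <- best$strand
    out$best_position[i] <- best$position
    out$best_cas_variant[i] <- best$cas_variant
    out$best_pam[i] <- best$pam_seq
    out$best_protospacer[i] <- best$protospacer
    out$recommended_bes[i] <- best$recommended_bes
    out$n_high_risk_bystanders[i] <- best$n_high_risk_bystanders
  }
  class(out) <- c("variant_scan", "data.frame")
  out
}

#' Read / write variant record tables as TSV
#'
#' Columns: `id`, `flank5`, `flank3`, `disease_base` (scan output columns
#' are preserved on write when present).
#'
#' @param path file path.
#' @return `read_variant_tsv`: a [variant_records()] data.frame.
#' @export
read_variant_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character")
  variant_records(df$id, df$flank5, df$flank3, df$disease_base)
}

#' @rdname read_variant_tsv
#' @param variants a variant table (scanned or not).
#' @export
write_variant_tsv <- function(variants, path) {
  utils::write.table(as.data.frame(variants), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
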