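# Seed-deterministic generators: amplicon reads with controlled per-position
# C-to-T conversion, variant tables with flanks and ground-truth labels,
# random genomes, and variant-call sets. Every generator emits
# machine-readable truth alongside the data.

# Run code under a given seed without disturbing the caller's RNG stream.
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Random genome / amplicon sequence
#'
#' Bases drawn i.i.d.; at the default `gc = 0.5` the composition is uniform
#' over A/C/G/T.
#'
#' @param length sequence length in nt.
#' @param seed integer seed (generation is fully reproducible).
#' @param gc GC content in `[0, 1]`.
#' @return character scalar.
#' @export
random_genome <- function(length, seed = 1L, gc = 0.5) {
  stopifnot(length >= 1, gc >= 0, gc <= 1)
  .with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
  })
}

#' Specification for an amplicon read simulation
#'
#' @param reference amplicon reference sequence (character).
#' @param guide one row of [find_guide_sites()] on `reference` locating the
#'   protospacer.
#' @param per_position_rates named numeric vector: names are PAM-relative
#'   positions (which must be reference Cs of the protospacer), values are
#'   per-read C-to-T conversion probabilities.
#' @param sequencing_error_rate uniform per-base substitution error
#'   probability (default 0.001).
#' @param indel_rate per-read probability of an injected 1-nt indel inside
#'   the protospacer (default 0).
#' @param n_reads number of reads.
#' @param seed integer seed.
#' @param co_editing_mode `"independent"` (each listed C converts
#'   independently, the default measurement model) or `"linked"` (a read is
#'   edited with `linked_edit_probability` and, if edited, converts each
#'   listed C with `rate / linked_edit_probability` capped at 1 -
#'   processive co-editing).
#' @param linked_edit_probability per-read editing probability for linked
#'   mode.
#' @return object of class `read_sim_spec`.
#' @export
read_sim_spec <- function(reference, guide, per_position_rates,
                          sequencing_error_rate = 0.001, indel_rate = 0,
                          n_reads = 1000L, seed = 1L,
                          co_editing_mode = c("independent", "linked"),
                          linked_edit_probability = NA_real_) {
  reference <- as_dna(reference, what = "reference")
  co_editing_mode <- match.arg(co_editing_mode)
  probs <- c(per_position_rates, sequencing_error_rate, indel_rate)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  if (co_editing_mode == "linked") {
    if (is.na(linked_edit_probability) || linked_edit_probability <= 0 ||
        linked_edit_probability > 1)
      stop("linked mode needs linked_edit_probability in (0, 1]",
           call. = FALSE)
    if (any(per_position_rates > linked_edit_probability))
      warning("rates above linked_edit_probability are capped",
              call. = FALSE)
  }
  fr <- .proto_frame(reference, guide)
  proto <- substr(fr$ref, fr$proto_start + 1L, fr$proto_start + fr$L)
  pos <- as.integer(names(per_position_rates))
  if (any(is.na(pos)))
    stop("per_position_rates must be named by PAM-relative positions",
         call. = FALSE)
  offs <- protospacer_offset(pos, fr$L)     # 0-based in protospacer
  bases <- substring(proto, offs + 1L, offs + 1L)
  if (any(bases != "C"))
    stop("conversion rate given at non-C position(s): ",
         paste(pos[bases != "C"], collapse = ", "), call. = FALSE)
  structure(list(reference = reference, guide = guide,
                 per_position_rates = per_position_rates,
                 sequencing_error_rate = sequencing_error_rate,
                 indel_rate = indel_rate, n_reads = as.integer(n_reads),
                 seed = as.integer(seed),
                 co_editing_mode = co_editing_mode,
                 linked_edit_probability = linked_edit_probability,
                 frame = fr),
            class = "read_sim_spec")
}

#' Simulate amplicon reads with known conversion rates
#'
#' Reads are full-length copies of the reference (protospacer-strand
#' orientation of the simulation frame is mapped back to the reference
#' orientation), with: C-to-T conversions applied at the listed positions
#' per the co-editing mode, uniform substitution sequencing errors, and a
#' 1-nt insertion or deletion inside the protospacer in a fraction
#' `indel_rate` of reads. Per-read ground truth is returned, and the same
#' spec + seed reproduces byte-identical output.
#'
#' @param spec a [read_sim_spec()].
#' @param fastq_path optional path; when given the reads are also written
#'   as FASTQ (constant qualities).
#' @return list with `reads` (named character vector), `truth` (list:
#'   `converted` logical matrix reads x positions, `edited` per-read flag,
#'   `n_errors`, `has_indel`) and `spec`.
#' @export
simulate_reads <- function(spec, fastq_path = NULL) {
  stopifnot(inherits(spec, "read_sim_spec"))
  fr <- spec$frame
  n <- spec$n_reads
  rates <- spec$per_position_rates
  pos <- as.integer(names(rates))
  offs_abs <- fr$proto_start + protospacer_offset(pos, fr$L) + 1L  # 1-based
  out <- .with_seed(spec$seed, {
    reads <- rep(fr$ref, n)
    converted <- matrix(FALSE, nrow = n, ncol = length(rates),
                        dimnames = list(NULL, names(rates)))
    if (spec$co_editing_mode == "independent") {
      edited <- rep(NA, n)
      for (k in seq_along(rates))
        converted[, k] <- stats::runif(n) < rates[k]
    } else {
      edited <- stats::runif(n) < spec$linked_edit_probability
      for (k in seq_along(rates)) {
        cond <- min(1, rates[k] / spec$linked_edit_probability)
        converted[, k] <- edited & (stats::runif(n) < cond)
      }
    }
    for (k in seq_along(rates)) {
      idx <- which(converted[, k])
      if (length(idx))
        substr(reads[idx], offs_abs[k], offs_abs[k]) <- "T"
    }
    # uniform substitution errors
    L_ref <- nchar(fr$ref)
    n_errors <- integer(n)
    if (spec$sequencing_error_rate > 0) {
      hits <- which(stats::runif(n * L_ref) < spec$sequencing_error_rate)
      for (h in hits) {
        i <- (h - 1L) %/% L_ref + 1L
        p <- (h - 1L) %% L_ref + 1L
        cur <- substr(reads[i], p, p)
        substr(reads[i], p, p) <-
          sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
        n_errors[i] <- n_errors[i] + 1L
      }
    }
    # injected 1-nt indels inside the protospacer
    has_indel <- stats::runif(n) < spec$indel_rate
    for (i in which(has_indel)) {
      at <- fr$proto_start + sample.int(fr$L, 1L)   # 1-based
      if (stats::runif(1) < 0.5) {
        reads[i] <- paste0(substr(reads[i], 1L, at - 1L),
                           substr(reads[i], at + 1L, nchar(reads[i])))
      } else {
        reads[i] <- paste0(substr(reads[i], 1L, at),
                           sample(c("A", "C", "G", "T"), 1L),
                           substr(reads[i], at + 1L, nchar(reads[i])))
      }
    }
    list(reads = reads, converted = converted, edited = edited,
         n_errors = n_errors, has_indel = has_indel)
  })
  reads <- out$reads
  if (spec$guide$strand == "-") reads <- reverse_complement(reads)
  names(reads) <- sprintf("read%06d", seq_len(n))
  if (!is.null(fastq_path)) write_fastq(reads, fastq_path)
  list(reads = reads,
       truth = list(converted = out$converted, edited = out$edited,
                    n_errors = out$n_errors, has_indel = out$has_indel),
       spec = spec)
}

# Template contexts used by the variant-table generator. Each embeds a
# protospacer (A/T background) whose focal C sits at `position` with the
# stated local context, followed by the PAM; the surrounding flanks are
# G/C-free so the embedded site is the only PAM-bearing one.
.VARIANT_TEMPLATES <- list(
  list(name = "c18_no_bystander", position = -18L, pam = "TGG",
       context = c(`-18` = "C")),
  list(name = "c18_NCN_bystander", position = -18L, pam = "TGG",
       context = c(`-19` = "C", `-18` = "C")),
  list(name = "c18_NG_pam", position = -18L, pam = "AGT",
       context = c(`-19` = "C", `-18` = "C")),
  list(name = "c17_DCN", position = -17L, pam = "TGA",
       context = c(`-17` = "C", `-16` = "C")),
  list(name = "c15_TCAC_AGG", position = -15L, pam = "AGG",
       context = c(`-18` = "T", `-17` = "C", `-16` = "A", `-15` = "C")),
  list(name = "c16_NCD", position = -16L, pam = "TGG",
       context = c(`-17` = "C", `-16` = "C"))
)

# Build flank5/flank3 for one template: focal base is the template's target
# C; background A/T only (no stray G/C, hence no stray PAM on either strand).
.build_template_record <- function(tpl, flank_length, L = 20L) {
  bg <- function(k) paste(sample(c("A", "T"), k, replace = TRUE),
                          collapse = "")
  proto <- strsplit(bg(L), "", fixed = TRUE)[[1]]
  for (nm in names(tpl$context))
    proto[protospacer_offset(as.integer(nm), L) + 1L] <- tpl$context[[nm]]
  focal_off <- protospacer_offset(tpl$position, L)       # 0-based
  left_in <- paste(proto[seq_len(focal_off)], collapse = "")
  right_in <- paste(proto[(focal_off + 2L):L], collapse = "")
  pad5 <- bg(max(0L, flank_length - nchar(left_in)))
  flank5 <- paste0(pad5, left_in)
  flank3 <- paste0(right_in, tpl$pam, bg(flank_length))
  list(flank5 = flank5, flank3 = flank3)
}

#' Simulate a variant table with ground-truth targetability
#'
#' Targetable records embed a PAM placing the focal C at a known position
#' with a controlled local context drawn from the rule-table patterns, in an
#' A/T-only background (so the embedded site is verifiably the only PAM
#' match on either strand). Non-targetable records are A/T-only apart from
#' the focal C, so no PAM motif of the panel can match at all.
#'
#' @param n number of records.
#' @param flank_length flank length in nt (>= 25; default 30).
#' @param fraction_targetable fraction of records built targetable.
#' @param seed integer seed.
#' @return list with `variants` (a [variant_records()] table) and `truth`
#'   (data.frame: `id`, `targetable`, `template`, `intended_position`).
#' @export
simulate_variant_table <- function(n, flank_length = 30L,
                                   fraction_targetable = 0.5, seed = 1L) {
  stopifnot(flank_length >= 25L, fraction_targetable >= 0,
            fraction_targetable <= 1)
  .with_seed(seed, {
    n_t <- round(n * fraction_targetable)
    targetable <- rep(c(TRUE, FALSE), c(n_t, n - n_t))
    targetable <- sample(targetable)
    ids <- sprintf("var%04d", seq_len(n))
    f5 <- f3 <- character(n)
    template <- rep(NA_character_, n)
    intended <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      if (targetable[i]) {
        tpl <- .VARIANT_TEMPLATES[[sample.int(length(.VARIANT_TEMPLATES),
                                              1L)]]
        rec <- .build_template_record(tpl, flank_length)
        f5[i] <- rec$flank5; f3[i] <- rec$flank3
        template[i] <- tpl$name
        intended[i] <- tpl$position
      } else {
        bg <- function(k) paste(sample(c("A", "T"), k, replace = TRUE),
                                collapse = "")
        f5[i] <- bg(flank_length); f3[i] <- bg(flank_length)
      }
    }
    list(variants = variant_records(ids, f5, f3, "C"),
         truth = data.frame(id = ids, targetable = targetable,
                            template = template,
                            intended_position = intended,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a variant-call set with a known composition
#'
#' Emits exactly the requested number of SNVs per substitution class (each
#' SNV drawn in one of the two complementary orientations at random) and
#' the requested number of 1-nt indels, at distinct positions on a dummy
#' contig, shuffled by seed.
#'
#' @param n_snv_by_class named integer vector over (a subset of) the six
#'   collapsed classes `"C>T/G>A"`, `"C>A/G>T"`, `"C>G/G>C"`, `"T>A/A>T"`,
#'   `"T>C/A>G"`, `"T>G/A>C"`.
#' @param n_indel number of indel records.
#' @param seed integer seed.
#' @return data.frame with `chrom`, `pos`, `ref`, `alt` (a valid input to
#'   [tally_variants()] and [write_vcf_calls()]).
#' @export
simulate_variant_calls <- function(n_snv_by_class = integer(0), n_indel = 0L,
                                   seed = 1L) {
  stopifnot(all(n_snv_by_class >= 0), n_indel >= 0)
  bad <- setdiff(names(n_snv_by_class), .SPECTRUM6)
  if (length(bad))
    stop("unknown substitution class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  .with_seed(seed, {
    rows <- list()
    for (cls in names(n_snv_by_class)) {
      k <- n_snv_by_class[[cls]]
      if (k == 0L) next
      reps <- strsplit(strsplit(cls, "/", fixed = TRUE)[[1]], ">",
                       fixed = TRUE)
      pick <- sample.int(2L, k, replace = TRUE)
      for (j in seq_len(k)) {
        rp <- reps[[pick[j]]]
        rows[[length(rows) + 1L]] <- data.frame(
          ref = rp[1], alt = rp[2], stringsAsFactors = FALSE)
      }
    }
    for (j in seq_len(n_indel)) {
      anchor <- sample(c("A", "C", "G", "T"), 1L)
      extra <- sample(c("A", "C", "G", "T"), 1L)
      if (stats::runif(1) < 0.5) {
        rows[[length(rows) + 1L]] <- data.frame(
          ref = anchor, alt = paste0(anchor, extra),
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          ref = paste0(anchor, extra), alt = anchor,
          stringsAsFactors = FALSE)
      }
    }
    if (!length(rows))
      return(data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        stringsAsFactors = FALSE))
    calls <- do.call(rbind, rows)
    calls <- calls[sample.int(nrow(calls)), , drop = FALSE]
    calls <- data.frame(chrom = "chrS", pos = seq_len(nrow(calls)) * 100L,
                        ref = calls$ref, alt = calls$alt,
                        stringsAsFactors = FALSE)
    rownames(calls) <- NULL
    calls
  })
}

#' Write variant calls as a minimal VCF v4.2 file
#'
#' Plain-text, sites-only VCF (no genotypes). Readable by any VCF v4.x
#' parser.
#'
#' @param calls data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param path output path.
#' @export
write_vcf_calls <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=precisebe",
               paste0("##contig=<ID=",
                      paste(unique(calls$chrom), collapse = ">\n##contig=<ID="),
                      ">"),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(calls))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                       calls$chrom, calls$pos, calls$ref, calls$alt), con)
  invisible(path)
}
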