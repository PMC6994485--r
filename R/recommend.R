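# Context classification and editor recommendation for a target C within a
# protospacer, following the distance/context rule table.

# Accept either a guide_sites row or a plain 20-mer protospacer string.
.get_protospacer <- function(guide) {
  if (is.data.frame(guide)) {
    stopifnot(nrow(guide) == 1L, "protospacer" %in% names(guide))
    proto <- guide$protospacer
  } else proto <- guide
  proto <- as_dna(proto, what = "protospacer")
  proto
}

.distance_bucket <- function(target) {
  if (target < -19L) "<-19" else if (target > -14L) ">-14"
  else as.character(target)
}

# PAM-relative positions of every C in the protospacer.
.c_positions <- function(proto) {
  L <- nchar(proto)
  offs <- which(strsplit(proto, "", fixed = TRUE)[[1]] == "C") - 1L
  offs - L
}

#' Classify the sequence context of a target C
#'
#' Assigns the distance bucket used by the rule table (`"<-19"` for
#' positions 5' of -19, `">-14"` for -13..-1, else the position itself) and
#' lists, for every cataloged editor with a window profile, the bystander
#' Cs: the non-target Cs of the protospacer falling inside *that editor's*
#' activity window. "No bystander" is a per-editor property, not a global
#' one.
#'
#' @param guide a one-row `guide_sites` data.frame or a 20-mer protospacer
#'   (character).
#' @param target PAM-relative position of the target C (integer in
#'   -20..-1; the protospacer base there must be C).
#' @param catalog a [builtin_catalog()] object.
#' @return list with `target`, `bucket`, `protospacer`, `c_positions`
#'   (PAM-relative positions of all Cs) and `bystanders` (named list,
#'   editor -> integer vector of bystander positions in its window).
#' @export
classify_context <- function(guide, target, catalog = builtin_catalog()) {
  proto <- .get_protospacer(guide)
  L <- nchar(proto)
  target <- as.integer(target)
  if (is.na(target) || target < -L || target > -1L)
    stop("target position must be in -", L, "..-1", call. = FALSE)
  base <- substr(proto, target + L + 1L, target + L + 1L)
  if (base != "C")
    stop("protospacer base at position ", target, " is ", base,
         ", not C", call. = FALSE)
  cpos <- .c_positions(proto)
  others <- setdiff(cpos, target)
  bystanders <- list()
  for (p in catalog$profiles) {
    if (is.null(p$window) || !is.null(p$members)) next
    bystanders[[p$name]] <- others[others >= p$window[1] &
                                   others <= p$window[2]]
  }
  list(target = target, bucket = .distance_bucket(target),
       protospacer = proto, c_positions = cpos, bystanders = bystanders)
}

# Does a pattern rule match, with its target_offset anchored at `target`?
# All pattern positions must fall inside the protospacer, and - since these
# rules describe bystander situations - at least one non-target position of
# the aligned pattern must actually read C (for patterns whose only Cs are
# degenerate N positions, e.g. NCN, this is what distinguishes them from
# the bystander-free case handled by the "no-bystander" rules).
.rule_pattern_matches <- function(rule, proto, target) {
  L <- nchar(proto)
  len <- nchar(rule$pattern)
  start <- target - rule$target_offset        # PAM-relative pattern start
  if (start < -L || start + len - 1L > -1L) return(FALSE)
  window <- substr(proto, start + L + 1L, start + L + len)
  if (!iupac_match(rule$pattern, window)) return(FALSE)
  wchars <- strsplit(window, "", fixed = TRUE)[[1]]
  any(wchars[-(rule$target_offset + 1L)] == "C")
}

# Editors of a no-bystander rule whose own window is free of non-target Cs.
# An editor lacking a window profile cannot certify the condition.
.clean_window_bes <- function(bes, ctx, catalog) {
  keep <- vapply(bes, function(nm) {
    p <- catalog$profiles[[nm]]
    if (is.null(p$window)) return(FALSE)
    bys <- ctx$bystanders[[nm]]
    if (is.null(bys)) {  # family label: clean iff all members are clean
      if (!is.null(p$members))
        return(all(vapply(p$members, function(m)
          length(ctx$bystanders[[m]]) == 0L, logical(1))))
      bys <- setdiff(ctx$c_positions, ctx$target)
      bys <- bys[bys >= p$window[1] & bys <= p$window[2]]
    }
    length(bys) == 0L
  }, logical(1))
  bes[keep]
}

.rule_specificity <- function(rule) {
  if (identical(rule$pattern, "no-bystander")) return(0L)
  sum(.check_pattern(rule$pattern) != "N")
}

#' Recommend base editors for a target C
#'
#' Collects every rule of the catalog whose distance bucket matches the
#' target position and whose condition holds: for anchored-pattern rules the
#' pattern (with its target offset aligned to the target C) must match the
#' protospacer; "no-bystander" rules fire per editor, only for editors whose
#' own activity window contains no other C. Matched rules are ordered by
#' specificity (number of non-N pattern positions, descending), then table
#' order; the recommended editor list is the deduplicated concatenation in
#' that order.
#'
#' @inheritParams classify_context
#' @return object of class `be_recommendation`: list with `target`,
#'   `bucket`, `matched_rules` (data.frame), `bes` (character vector,
#'   ordered, deduplicated), `precise` (`TRUE` iff any rule matched) and
#'   `warnings`.
#' @export
recommend <- function(guide, target, catalog = builtin_catalog()) {
  ctx <- classify_context(guide, target, catalog)
  proto <- ctx$protospacer
  matched <- list()
  for (i in seq_along(catalog$rules)) {
    rule <- catalog$rules[[i]]
    if (rule$bucket != ctx$bucket) next
    if (identical(rule$pattern, "no-bystander")) {
      bes <- .clean_window_bes(rule$bes, ctx, catalog)
      if (!length(bes)) next
      matched[[length(matched) + 1L]] <-
        list(rule = rule, bes = bes, order = i,
             specificity = .rule_specificity(rule))
    } else {
      if (!.rule_pattern_matches(rule, proto, ctx$target)) next
      matched[[length(matched) + 1L]] <-
        list(rule = rule, bes = rule$bes, order = i,
             specificity = .rule_specificity(rule))
    }
  }
  warnings <- character(0)
  if (length(matched)) {
    ord <- order(-vapply(matched, `[[`, integer(1), "specificity"),
                 vapply(matched, `[[`, integer(1), "order"))
    matched <- matched[ord]
    bes <- unlist(lapply(matched, `[[`, "bes"), use.names = FALSE)
    bes <- bes[!duplicated(bes)]
  } else {
    bes <- character(0)
    warnings <- paste0(
      "no discriminating editor for a target C at ", ctx$target,
      " in this context; currently available editors cannot resolve it")
  }
  for (nm in bes) {
    p <- catalog$profiles[[nm]]
    if (!is.null(p$sequence_preference)) {
      pref <- p$sequence_preference
      if (!is.na(pref) && !.seq_pref_ok(proto, ctx$target, pref))
        warnings <- c(warnings, paste0(
          nm, ": reduced activity expected at non-", pref, " sites"))
    }
  }
  mr <- if (length(matched)) do.call(rbind, lapply(matched, function(m)
    data.frame(bucket = m$rule$bucket, pattern = m$rule$pattern,
               target_offset = m$rule$target_offset,
               specificity = m$specificity,
               bes = paste(m$bes, collapse = ","),
               stringsAsFactors = FALSE)))
  else data.frame(bucket = character(0), pattern = character(0),
                  target_offset = integer(0), specificity = integer(0),
                  bes = character(0), stringsAsFactors = FALSE)
  structure(list(target = ctx$target, bucket = ctx$bucket,
                 protospacer = proto, matched_rules = mr, bes = bes,
                 precise = length(matched) > 0L, warnings = warnings),
            class = "be_recommendation")
}

# Trinucleotide sequence-context preference (target C at centre position 2
# of e.g. TCR); positions outside the protospacer fail conservatively.
.seq_pref_ok <- function(proto, target, pref) {
  L <- nchar(proto)
  start <- target - 1L
  if (start < -L || target + 1L > -1L) return(FALSE)
  window <- substr(proto, start + L + 1L, start + L + 3L)
  iupac_match(pref, window)
}

#' @export
print.be_recommendation <- function(x, ...) {
  cat("<be_recommendation> target C at", x$target,
      paste0("(bucket ", x$bucket, ")"), "\n")
  if (x$precise) {
    cat("  recommended:", paste(x$bes, collapse = ", "), "\n")
  } else cat("  no rule matched (precise = FALSE)\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Bystander risk report for one editor
#'
#' Lists every non-target C of the protospacer that falls inside the
#' editor's activity window, tiered `"high"` when it sits at one of the
#' editor's preferred positions and `"low"` otherwise.
#'
#' @inheritParams classify_context
#' @param be a [be_profile] or an editor name resolvable in `catalog`.
#' @return data.frame with columns `position` and `tier`; zero rows when
#'   the window holds no other C.
#' @export
bystander_report <- function(guide, target, be,
                             catalog = builtin_catalog()) {
  if (is.character(be)) {
    be <- catalog$profiles[[be]]
    if (is.null(be)) stop("unknown editor name", call. = FALSE)
  }
  stopifnot(inherits(be, "be_profile"))
  if (is.null(be$window))
    stop(be$name, " has no window profile (external-citation editor); ",
         "bystander reporting is not available", call. = FALSE)
  ctx <- classify_context(guide, target, catalog)
  others <- setdiff(ctx$c_positions, ctx$target)
  inside <- others[others >= be$window[1] & others <= be$window[2]]
  inside <- sort(inside, decreasing = TRUE)  # PAM-proximal first
  data.frame(
    position = inside,
    tier = ifelse(inside %in% be$preferred_positions, "high", "low"),
    stringsAsFactors = FALSE)
}
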