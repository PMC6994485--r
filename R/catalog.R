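# The base-editor knowledge base: activity windows, position preferences and
# the distance/context rule table used to recommend an editor for a target C.
#
# Naming: the Greek capital delta of construct names is rendered as a plain
# "d" (nCDA1d198-BE3 == "nCDA1" with CDA1 truncated after residue 198, fused
# to BE3). "nCDA1d(194-188)-BE3" is the family label covering the d194, d193,
# d192, d190 and d188 truncations; it resolves to those members.

#' Construct a base-editor profile
#'
#' @param name editor label.
#' @param deaminase_family one of `"APOBEC1"`, `"CDA1"`, `"A3A"`, or `NA`
#'   for editors known only by citation.
#' @param compatible_pams list of [pam_spec] objects.
#' @param window `NULL`, or length-2 integer vector `c(lo, hi)` of
#'   PAM-relative positions (both negative, `lo <= hi`, within -20..-1)
#'   bounding the activity window.
#' @param preferred_positions integer vector of PAM-relative positions,
#'   most-preferred first; must lie inside `window`.
#' @param sequence_preference optional IUPAC trinucleotide context the
#'   deaminase favours (e.g. `"TCR"` for eA3A), or `NA`.
#' @param provenance one of `"paper-stated"`, `"figure-informed-default"`,
#'   `"external-citation"`; flags how the window was established.
#' @param members for a family label, the member editor names.
#' @return object of class `be_profile`.
#' @export
be_profile <- function(name, deaminase_family = NA_character_,
                       compatible_pams = list(), window = NULL,
                       preferred_positions = integer(0),
                       sequence_preference = NA_character_,
                       provenance = "figure-informed-default",
                       members = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.null(window)) {
    window <- as.integer(window)
    stopifnot(length(window) == 2L, window[1] <= window[2],
              window[1] >= -20L, window[2] <= -1L)
    if (length(preferred_positions) &&
        (any(preferred_positions < window[1]) ||
         any(preferred_positions > window[2])))
      stop("preferred positions must lie inside the window", call. = FALSE)
  }
  structure(list(
    name = name, deaminase_family = deaminase_family,
    compatible_pams = compatible_pams, window = window,
    preferred_positions = as.integer(preferred_positions),
    sequence_preference = sequence_preference,
    provenance = provenance, members = members),
    class = "be_profile")
}

#' @export
print.be_profile <- function(x, ...) {
  win <- if (is.null(x$window)) "no window profile"
         else paste0("window ", x$window[1], "..", x$window[2],
                     if (length(x$preferred_positions))
                       paste0(", preferred ",
                              paste(x$preferred_positions, collapse = " > "))
                     else "")
  cat("<be_profile>", x$name, paste0("[", x$provenance, "]"), win, "\n")
  invisible(x)
}

# One rule of the recommendation table: a distance bucket plus either the
# "no-bystander" sentinel or an anchored IUPAC pattern whose target_offset
# position is the target C.
.context_rule <- function(bucket, pattern, target_offset, bes) {
  if (!identical(pattern, "no-bystander")) {
    pchars <- .check_pattern(pattern)
    stopifnot(pchars[target_offset + 1L] == "C")
  }
  stopifnot(length(bes) >= 1L)
  list(bucket = bucket, pattern = pattern,
       target_offset = if (identical(pattern, "no-bystander")) NA_integer_
                       else as.integer(target_offset),
       bes = bes)
}

#' Built-in editor catalog and recommendation rule table
#'
#' Returns the toolkit's knowledge base: profiles for the CDA1- and
#' A3A-derived narrow-window editors (including the altered-PAM variants),
#' the classical wide-window editors they are compared against, and the
#' 19-row distance/context rule table mapping a target C's distance from
#' the PAM and its local sequence context to the recommended editors.
#'
#' Window extents are encoded with a provenance flag: `"paper-stated"`
#' windows come from explicit range statements, `"figure-informed-default"`
#' windows are defaults consistent with the polyC editing profiles and with
#' the rule table itself (a "no bystander" recommendation at a distance
#' implies activity there; a bystander caveat implies bystander risk there),
#' and `"external-citation"` editors (YEE-BE3, BE-PAPAPAP) are recommendable
#' names without window profiles.
#'
#' @param ranking priority ranking of target-C positions used by
#'   [scan_variants()]: the stated C-18 > C-17 > C-19 triple, extended by
#'   the A3A editor positions -16 and -15 as fallbacks.
#' @return object of class `be_catalog`: list with elements `profiles`
#'   (named list of [be_profile]), `rules` (list of context rules, table
#'   order), `ranking`, and `pam_specs`.
#' @export
builtin_catalog <- function(ranking = c(-18L, -17L, -19L, -16L, -15L)) {
  specs <- builtin_pam_specs()
  ngg <- specs["SpCas9"]

  profiles <- list()
  add <- function(p) profiles[[p$name]] <<- p

  # Classical editors ------------------------------------------------------
  add(be_profile("BE3", "APOBEC1", ngg, c(-17L, -13L), c(-15L, -16L)))
  add(be_profile("nCDA1-BE3", "CDA1", ngg, c(-20L, -14L), c(-18L, -17L),
                 provenance = "paper-stated"))
  add(be_profile("cCDA1-BE3", "CDA1", ngg, c(-19L, -15L), c(-18L, -17L)))
  add(be_profile("nCDA1d198-BE3", "CDA1", ngg, c(-20L, -15L), c(-18L)))

  # CDA1 truncation family (d195..d188), NGG plus the altered-PAM variants.
  trunc_deltas <- c(195L, 194L, 193L, 192L, 190L, 188L)
  cas_tags <- list(`BE3` = specs["SpCas9"], `VQRBE3` = specs["VQR-Cas9"],
                   `VRERBE3` = specs["VRER-Cas9"], `xBE3` = specs["xCas9"],
                   `NGBE3` = specs["SpCas9-NG"])
  for (tag in names(cas_tags)) {
    for (d in trunc_deltas) {
      add(be_profile(sprintf("nCDA1d%d-%s", d, tag), "CDA1",
                     cas_tags[[tag]], c(-19L, -17L), c(-18L, -17L)))
    }
  }
  fam_members <- sprintf("nCDA1d%d-BE3", c(194L, 193L, 192L, 190L, 188L))
  add(be_profile("nCDA1d(194-188)-BE3", "CDA1", ngg, c(-19L, -17L),
                 c(-18L, -17L), members = fam_members))

  # A3A editors -------------------------------------------------------------
  add(be_profile("A3A-BE3", "A3A", ngg, c(-19L, -11L), c(-16L, -15L),
                 provenance = "paper-stated"))
  add(be_profile("A3A-NL-BE3", "A3A", ngg, c(-20L, -12L), c(-17L, -16L)))
  for (nm in c("A3Ad190-BE3", "A3Ad186-BE3", "A3Ad182-BE3",
               "A3A(Y130F)d186-BE3")) {
    add(be_profile(nm, "A3A", ngg, c(-17L, -14L), c(-16L, -15L),
                   provenance = if (nm == "A3Ad182-BE3") "paper-stated"
                                else "figure-informed-default"))
  }
  add(be_profile("eA3A-BE3", "A3A", ngg, c(-17L, -14L), c(-16L, -15L),
                 sequence_preference = "TCR"))

  # Editors recommendable by external citation only (no window profile).
  add(be_profile("YEE-BE3", NA_character_, ngg,
                 provenance = "external-citation"))
  add(be_profile("BE-PAPAPAP", NA_character_, ngg,
                 provenance = "external-citation"))

  fam <- "nCDA1d(194-188)-BE3"
  rules <- list(
    .context_rule("<-19", "no-bystander", NA,
                  c("nCDA1-BE3", "nCDA1d198-BE3", "A3A-NL-BE3")),
    .context_rule("-19", "no-bystander", NA,
                  c("nCDA1-BE3", "nCDA1d198-BE3", "A3A-NL-BE3")),
    .context_rule("-19", "CCDDD", 1L, "cCDA1-BE3"),
    .context_rule("-18", "no-bystander", NA,
                  c("nCDA1d198-BE3", "nCDA1-BE3", "cCDA1-BE3",
                    "A3A-NL-BE3")),
    .context_rule("-18", "NCN", 1L, fam),
    .context_rule("-17", "no-bystander", NA,
                  c("nCDA1d198-BE3", "cCDA1-BE3", "A3A-BE3", "nCDA1-BE3",
                    "BE3")),
    .context_rule("-17", "DCN", 1L, fam),
    .context_rule("-17", "CCDDDD", 1L, "BE3"),
    .context_rule("-16", "no-bystander", NA,
                  c("BE3", "nCDA1d198-BE3", "A3A-BE3")),
    .context_rule("-16", "DDDCC", 3L, "cCDA1-BE3"),
    .context_rule("-16", "TCC", 1L,
                  c("cCDA1-BE3", "YEE-BE3", "BE-PAPAPAP")),
    .context_rule("-16", "NCD", 1L,
                  c("A3Ad182-BE3", "A3A(Y130F)d186-BE3")),
    .context_rule("-15", "no-bystander", NA,
                  c("BE3", "nCDA1d198-BE3", "A3A-BE3")),
    .context_rule("-15", "CDCD", 2L,
                  c("BE-PAPAPAP", "A3Ad182-BE3", "A3A(Y130F)d186-BE3",
                    "YEE-BE3")),
    .context_rule("-15", "DCN", 1L,
                  c("A3Ad182-BE3", "A3A(Y130F)d186-BE3")),
    .context_rule("-15", "RCCD", 2L, "BE-PAPAPAP"),
    .context_rule("-14", "no-bystander", NA,
                  c("BE3", "A3A-BE3", "nCDA1-BE3")),
    .context_rule("-14", "DDCC", 2L, "BE-PAPAPAP"),
    .context_rule(">-14", "no-bystander", NA,
                  c("A3A-BE3", "nCDA1-BE3", "BE3"))
  )

  cat_obj <- structure(list(profiles = profiles, rules = rules,
                            ranking = as.integer(ranking),
                            pam_specs = specs),
                       class = "be_catalog")
  .check_catalog(cat_obj)
  cat_obj
}

# Referential integrity: every name a rule recommends, and every family
# member, must resolve to a profile.
.check_catalog <- function(catalog) {
  known <- names(catalog$profiles)
  for (r in catalog$rules) {
    missing <- setdiff(r$bes, known)
    if (length(missing))
      stop("rule references unknown editor(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  for (p in catalog$profiles) {
    if (!is.null(p$members)) {
      missing <- setdiff(p$members, known)
      if (length(missing))
        stop("family ", p$name, " has unknown member(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.be_catalog <- function(x, ...) {
  cat("<be_catalog>", length(x$profiles), "editor profiles,",
      length(x$rules), "context rules\n")
  cat("  position ranking:", paste(x$ranking, collapse = " > "), "\n")
  invisible(x)
}

#' Rule table as a data.frame
#'
#' @param catalog a [builtin_catalog()] object.
#' @return data.frame with one row per rule: `bucket`, `pattern`,
#'   `target_offset`, `recommended_bes` (comma-joined).
#' @export
rules_table <- function(catalog) {
  do.call(rbind, lapply(catalog$rules, function(r) data.frame(
    bucket = r$bucket, pattern = r$pattern,
    target_offset = r$target_offset,
    recommended_bes = paste(r$bes, collapse = ","),
    stringsAsFactors = FALSE)))
}

# C-terminal truncation arithmetic ------------------------------------------

# Full deaminase lengths (residues) implied by the construct naming: a "dK"
# construct retains residues 1..K, so it removes length - K residues.
.DEAMINASE_LENGTHS <- c(CDA1 = 208L, A3A = 199L)

#' Residues removed by a C-terminal deaminase truncation
#'
#' A truncation construct `dK` retains residues `1..K` of the deaminase, so
#' it removes `full_length - K` C-terminal residues (CDA1: 208 aa; A3A:
#' 199 aa). E.g. CDA1 d188 removes 20 residues and A3A d182 removes 17.
#'
#' @param deaminase `"CDA1"` or `"A3A"`.
#' @param retained last retained residue number (the `K` of `dK`).
#' @return integer count of removed residues.
#' @export
truncation_removed <- function(deaminase, retained) {
  deaminase <- match.arg(deaminase, names(.DEAMINASE_LENGTHS))
  retained <- as.integer(retained)
  full <- .DEAMINASE_LENGTHS[[deaminase]]
  if (is.na(retained) || retained < 1L || retained > full)
    stop("retained residue must be in 1..", full, call. = FALSE)
  full - retained
}

#' @rdname truncation_removed
#' @param name a construct name such as `"nCDA1d188-BE3"` or
#'   `"A3Ad182-BE3"`; the deaminase and `dK` are parsed from it.
#' @export
truncation_removed_from_name <- function(name) {
  m <- regmatches(name, regexec("(CDA1|A3A)[^d]*d(\\d+)", name))[[1]]
  if (length(m) != 3L)
    stop("cannot parse a deaminase truncation from: ", name, call. = FALSE)
  truncation_removed(m[2], as.integer(m[3]))
}
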