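#' Region-delimitation scheme for vNAR domains
#'
#' The scheme anchors every region boundary to the two canonical cysteines
#' of the Ig fold (positions ~22 and ~83 in the reference structures) and
#' to a carboxy-terminal FR4 framework motif, so that the fixed reference
#' coordinates (CDR1 25-33, HV2 44-51, HV4 60-65, CDR3 87-96 on a
#' 112-residue domain) generalize to length-variant clones. All
#' coordinates are 1-based inclusive residue positions.
#'
#' @param cys1_pos,cys1_window first canonical Cys is the cysteine nearest
#'   `cys1_pos` within `cys1_pos` +/- `cys1_window`.
#' @param cys2_pos,cys2_window likewise for the second canonical Cys.
#' @param cdr1_width fixed CDR1 width (9 residues, 25-33 on the reference
#'   frame); indels are pushed into FR2.
#' @param hv2_offset,hv4_offset start/end offsets of HV2 and HV4 from the
#'   first canonical Cys (defaults reproduce 44-51 and 60-65 when the
#'   anchor sits at 22).
#' @param fr4_motif regular expression locating the FR4 framework anchor;
#'   the first match at or after the CDR3 start is taken as the FR4 start.
#' @param cdr3_bounds admissible CDR3 lengths; outside this range the
#'   clone is reported as `atypical_spacing`.
#' @return a named list used by [annotate_regions()] and friends.
#' @export
region_scheme <- function(cys1_pos = 22, cys1_window = 3,
                          cys2_pos = 83, cys2_window = 6,
                          cdr1_width = 9,
                          hv2_offset = c(22, 29),
                          hv4_offset = c(38, 43),
                          fr4_motif = "[YW]G.G",
                          cdr3_bounds = c(4, 34)) {
  list(cys1_pos = cys1_pos, cys1_window = cys1_window,
       cys2_pos = cys2_pos, cys2_window = cys2_window,
       cdr1_width = cdr1_width, hv2_offset = hv2_offset,
       hv4_offset = hv4_offset, fr4_motif = fr4_motif,
       cdr3_bounds = cdr3_bounds)
}

#' Find the canonical cysteine anchors of a vNAR domain
#'
#' The intradomain disulfide of the Ig fold joins two conserved cysteines
#' (Cys22 and Cys83 in the reference numbering). Each anchor is the
#' cysteine nearest its reference position within a configurable window;
#' when two cysteines are equidistant the N-terminal one is chosen.
#'
#' @param aa protein string.
#' @param scheme a [region_scheme()].
#' @return list with `cys1` and `cys2` (1-based residue indices, `NA`
#'   when no cysteine lies in the window).
#' @examples
#' p <- paste0(strrep("A", 21), "C", strrep("A", 60), "C", strrep("A", 20))
#' find_canonical_anchors(p) # cys1 = 22, cys2 = 83
#' @export
find_canonical_anchors <- function(aa, scheme = region_scheme()) {
  stopifnot(is.character(aa), length(aa) == 1, nchar(aa) > 0)
  pos <- gregexpr("C", aa, fixed = TRUE)[[1]]
  pos <- pos[pos > 0]
  nearest <- function(center, window) {
    cand <- pos[abs(pos - center) <= window]
    if (!length(cand)) NA_integer_ else cand[which.min(abs(cand - center))]
  }
  list(cys1 = nearest(scheme$cys1_pos, scheme$cys1_window),
       cys2 = nearest(scheme$cys2_pos, scheme$cys2_window))
}

region_names <- c("fr1", "cdr1", "fr2", "hv2", "fr3a", "hv4", "fr3b",
                  "cdr3", "fr4")

# Annotate a vector of proteins; returns one row per input. Anchors and
# the FR4 motif are located vectorized; the span arithmetic is plain
# integer work on columns.
annotate_aa <- function(clone_id, aa, scheme) {
  n <- length(aa)
  len <- nchar(aa)

  # canonical cysteine anchors, nearest to the reference positions
  cys <- gregexpr("C", aa, fixed = TRUE)
  nearest <- function(pos, center, window) {
    pos <- pos[pos > 0]
    cand <- pos[abs(pos - center) <= window]
    if (!length(cand)) NA_integer_
    else as.integer(cand[which.min(abs(cand - center))])
  }
  c1 <- vapply(cys, nearest, integer(1),
               center = scheme$cys1_pos, window = scheme$cys1_window)
  c2 <- vapply(cys, nearest, integer(1),
               center = scheme$cys2_pos, window = scheme$cys2_window)

  # FR4 anchor: first motif match at or after the CDR3 start (c2 + 4)
  cdr3_start <- c2 + 4L
  fr4_start <- rep(NA_integer_, n)
  srch <- which(!is.na(c1) & !is.na(c2) & cdr3_start <= len)
  if (length(srch)) {
    rel <- regexpr(scheme$fr4_motif,
                   substring(aa[srch], cdr3_start[srch]))
    hit <- as.integer(rel) > 0
    fr4_start[srch[hit]] <- cdr3_start[srch][hit] + as.integer(rel)[hit] - 1L
  }
  cdr3_len <- fr4_start - cdr3_start

  sp <- list(
    fr1_start = rep(1L, n), fr1_end = c1 + 2L,
    cdr1_start = c1 + 3L, cdr1_end = c1 + 2L + scheme$cdr1_width,
    fr2_start = c1 + 3L + scheme$cdr1_width,
    fr2_end = c1 + scheme$hv2_offset[1] - 1L,
    hv2_start = c1 + scheme$hv2_offset[1],
    hv2_end = c1 + scheme$hv2_offset[2],
    fr3a_start = c1 + scheme$hv2_offset[2] + 1L,
    fr3a_end = c1 + scheme$hv4_offset[1] - 1L,
    hv4_start = c1 + scheme$hv4_offset[1],
    hv4_end = c1 + scheme$hv4_offset[2],
    fr3b_start = c1 + scheme$hv4_offset[2] + 1L,
    fr3b_end = c2 + 3L,
    cdr3_start = cdr3_start, cdr3_end = fr4_start - 1L,
    fr4_start = fr4_start, fr4_end = len)

  starts <- sp[seq(1, 17, by = 2)]
  ends <- sp[seq(2, 18, by = 2)]
  # every region except CDR3 non-empty, spans contiguous, CDR3 in bounds
  nonempty <- Reduce(`&`, Map(function(s, e) e >= s,
                              starts[-8], ends[-8]))
  contiguous <- Reduce(`&`, Map(function(s, e) s == e + 1L,
                                starts[-1], ends[-9]))
  spacing_ok <- !is.na(fr4_start) & nonempty & contiguous &
    cdr3_len >= scheme$cdr3_bounds[1] & cdr3_len <= scheme$cdr3_bounds[2]
  spacing_ok[is.na(spacing_ok)] <- FALSE

  status <- ifelse(is.na(c1) | is.na(c2) | is.na(fr4_start), "no_anchor",
                   ifelse(spacing_ok, "ok", "atypical_spacing"))
  ok <- status == "ok"

  out <- tibble::tibble(clone_id = clone_id)
  for (nm in names(sp)) out[[nm]] <- ifelse(ok, sp[[nm]], NA_integer_)
  out$anchor_cys1 <- c1
  out$anchor_cys2 <- c2
  out$cdr3_length <- ifelse(is.na(fr4_start), NA_integer_, cdr3_len)
  out$cdr1_seq <- ifelse(ok, substring(aa, c1 + 3L,
                                       c1 + 2L + scheme$cdr1_width),
                         NA_character_)
  out$cdr3_seq <- ifelse(ok, substring(aa, cdr3_start, fr4_start - 1L),
                         NA_character_)
  out$hv2_seq <- ifelse(ok, substring(aa, c1 + scheme$hv2_offset[1],
                                      c1 + scheme$hv2_offset[2]),
                        NA_character_)
  out$hv4_seq <- ifelse(ok, substring(aa, c1 + scheme$hv4_offset[1],
                                      c1 + scheme$hv4_offset[2]),
                        NA_character_)
  out$leu31_present <- ifelse(ok, substring(aa, c1 + 9L, c1 + 9L) == "L", NA)
  out$annotation_status <- status
  out
}

#' Annotate framework and hypervariable regions of a translated clone
#'
#' Delimits FR1, CDR1, FR2, HV2, FR3a, HV4, FR3b, CDR3 and FR4 on a
#' translated vNAR by anchoring to the canonical cysteines
#' ([find_canonical_anchors()]) and to the FR4 framework motif. On the
#' 112-residue reference frame (anchors at 22/83, FR4 motif at 97) this
#' reproduces CDR1 25-33, HV2 44-51, HV4 60-65 and CDR3 87-96.
#'
#' `annotation_status` is `"no_anchor"` when either canonical cysteine or
#' the FR4 motif is missing, `"atypical_spacing"` when the anchors are
#' found but the implied spans are incoherent (e.g. CDR3 length outside
#' `scheme$cdr3_bounds`), and `"ok"` otherwise; spans are reported only
#' for `"ok"` clones, which then tile positions 1..length exactly.
#'
#' @param record one-row tibble (or list) with `clone_id` and `aa`.
#' @param scheme a [region_scheme()].
#' @return one-row region-map tibble; see [annotate_repertoire()] for the
#'   columns.
#' @export
annotate_regions <- function(record, scheme = region_scheme()) {
  if (is.data.frame(record)) record <- as.list(record[1, ])
  if (is.null(record$aa) || is.na(record$aa))
    stop("clone ", record$clone_id, " has no translated protein")
  annotate_aa(record$clone_id, record$aa, scheme)
}

#' Annotate every translatable clone of a repertoire
#'
#' @param records clone-record tibble from [translate_repertoire()];
#'   rows without a translated protein are dropped with a message.
#' @param scheme a [region_scheme()].
#' @param complete_only drop clones whose cloning flanks were not both
#'   found (default `TRUE`: reads lacking a flank are flagged upstream
#'   and excluded from annotation, classification and diversity
#'   statistics, but remain countable in QC reports).
#' @return region-map tibble with one row per translated clone:
#'   `clone_id`, `<region>_start`/`<region>_end` for the nine regions,
#'   `anchor_cys1`, `anchor_cys2`, `cdr3_length`, `cdr1_seq`, `cdr3_seq`,
#'   `hv2_seq`, `hv4_seq`, `leu31_present`, `annotation_status`.
#' @export
annotate_repertoire <- function(records, scheme = region_scheme(),
                                complete_only = TRUE) {
  keep <- !is.na(records$aa)
  if (complete_only && "is_complete_insert" %in% names(records))
    keep <- keep & records$is_complete_insert
  if (!any(keep)) stop("no translatable clones to annotate")
  if (any(!keep))
    message(sum(!keep), " untranslated or incomplete clone(s) skipped")
  annotate_aa(records$clone_id[keep], records$aa[keep], scheme)
}

#' Fraction of annotated clones with the conserved CDR1 leucine
#'
#' Reports the fraction of clones carrying Leu at scheme position 31 (the
#' 7th CDR1 residue), a conserved feature of type II vNARs. The
#' denominator can be restricted to a subset of types via `calls`.
#'
#' @param maps region-map tibble (`annotation_status == "ok"` rows are
#'   used).
#' @param calls optional type-call tibble from [classify_repertoire()].
#' @param types optional character vector of labels to restrict to, e.g.
#'   `c("IIa", "IIb")`; requires `calls`.
#' @return fraction in `[0, 1]`.
#' @export
leu31_fraction <- function(maps, calls = NULL, types = NULL) {
  ok <- maps[maps$annotation_status == "ok", ]
  if (!is.null(types)) {
    if (is.null(calls)) stop("`types` restriction requires `calls`")
    ids <- calls$clone_id[calls$label %in% types]
    ok <- ok[ok$clone_id %in% ids, ]
  }
  if (nrow(ok) == 0) stop("no annotated clones in the requested subset")
  mean(ok$leu31_present)
}

#' Write a region-map table as TSV
#'
#' Spans are serialized as `"start-end"` strings in 1-based inclusive
#' coordinates.
#'
#' @param maps region-map tibble from [annotate_repertoire()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_region_tsv <- function(maps, path) {
  out <- tibble::tibble(clone_id = maps$clone_id)
  for (r in region_names) {
    s <- maps[[paste0(r, "_start")]]
    e <- maps[[paste0(r, "_end")]]
    out[[r]] <- ifelse(is.na(s), "", paste0(s, "-", e))
  }
  out$cdr3_length <- maps$cdr3_length
  out$leu31_present <- maps$leu31_present
  out$annotation_status <- maps$annotation_status
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Export region spans in BED-like 0-based half-open coordinates
#'
#' A dialect conversion of the 1-based inclusive spans: `start` becomes
#' `start - 1`, `end` stays, so `[start-1, end)` is half-open as in BED.
#'
#' @param maps region-map tibble (only `annotation_status == "ok"` rows
#'   are exported).
#' @return tibble with `clone_id`, `start`, `end`, `region`.
#' @export
region_bed <- function(maps) {
  ok <- maps[maps$annotation_status == "ok", ]
  rows <- lapply(region_names, function(r) {
    tibble::tibble(clone_id = ok$clone_id,
                   start = ok[[paste0(r, "_start")]] - 1L,
                   end = ok[[paste0(r, "_end")]],
                   region = toupper(r))
  })
  out <- do.call(rbind, rows)
  out[out$end > out$start, ]
}
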