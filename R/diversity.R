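#' Deduplicate clone records by translated protein sequence
#'
#' Repertoire uniqueness is defined on the full translated domain (exact
#' amino-acid identity); the first occurrence of each sequence is kept as
#' the representative.
#'
#' @param records clone-record tibble with an `aa` column present on
#'   every row.
#' @return list with `unique` (tibble of representative records, in first
#'   occurrence order) and `multiplicity` (integer vector of per-sequence
#'   counts named by sequence, in the same order).
#' @export
dedupe_sequences <- function(records) {
  if (any(is.na(records$aa)))
    stop("all records must carry a translated protein (aa)")
  first <- !duplicated(records$aa)
  counts <- table(records$aa)
  mult <- as.integer(counts[records$aa[first]])
  names(mult) <- records$aa[first]
  list(unique = records[first, , drop = FALSE], multiplicity = mult)
}

#' Partition unique clones by CDR3 uniqueness
#'
#' Among deduplicated clones, counts how many carry a CDR3 seen in no
#' other unique clone (`n_unique_cdr3`) versus how many share their CDR3
#' with another clone and therefore owe their uniqueness to variability in
#' the framework/CDR1/HV regions (`n_variable_elsewhere`). The two counts
#' sum to the input size.
#'
#' @param maps region-map tibble over deduplicated clones
#'   (`annotation_status == "ok"`).
#' @return list with `n_unique_cdr3` and `n_variable_elsewhere`.
#' @export
unique_cdr3_partition <- function(maps) {
  ok <- maps[maps$annotation_status == "ok", ]
  tab <- table(ok$cdr3_seq)
  n_singleton <- sum(tab == 1)
  list(n_unique_cdr3 = as.integer(n_singleton),
       n_variable_elsewhere = as.integer(nrow(ok) - n_singleton))
}

#' Per-type percentages from per-type counts
#'
#' @param counts named numeric vector of per-type sequence counts.
#' @param digits decimals kept (type percentages are printed at one
#'   decimal).
#' @return named vector of percentages under half-up rounding.
#' @examples
#' percentages <- repertoire_percentages(
#'   c(I = 36256, IIa = 57112, IIb = 98849, III = 8, IV = 46190))
#' @export
repertoire_percentages <- function(counts, digits = 1) {
  percentage(counts, sum(counts), digits)
}

#' Summarize an annotated, classified repertoire
#'
#' Computes the headline diversity statistics of a deduplicated
#' repertoire: per-type counts and percentages (one decimal, half-up),
#' the unique-CDR3 partition and its integer percentage, the CDR3 length
#' histogram, the CDR3 cysteine-count histogram with integer percentages
#' (computed over distinct CDR3 strings), and the CDR1 variability
#' percentage (share of clones whose CDR1 differs from the modal CDR1
#' string).
#'
#' @param calls type-call tibble from [classify_repertoire()].
#' @param maps region-map tibble for the same clones (same id set).
#' @return object of class `vnar_repertoire_summary`: a list with
#'   `n_total_unique`, `per_type_counts`, `per_type_pct`,
#'   `n_unique_cdr3`, `pct_unique_cdr3`, `cdr3_length_hist`,
#'   `cdr3_cys_hist` (`counts`, `pct`, `n_distinct_cdr3`),
#'   `cdr1_variability_pct`.
#' @export
summarize_repertoire <- function(calls, maps) {
  ok <- maps[maps$annotation_status == "ok", ]
  if (nrow(calls) == 0 || nrow(ok) == 0) stop("empty repertoire")
  if (!setequal(calls$clone_id, ok$clone_id) || nrow(calls) != nrow(ok))
    stop("type calls and region maps cover different clone sets")
  m <- ok[match(calls$clone_id, ok$clone_id), ]

  n <- nrow(calls)
  counts <- table(factor(calls$label, levels = vnar_types))
  counts <- stats::setNames(as.integer(counts), vnar_types)
  part <- unique_cdr3_partition(m)

  len_tab <- table(m$cdr3_length)
  len_hist <- stats::setNames(as.integer(len_tab), names(len_tab))

  distinct_cdr3 <- unique(m$cdr3_seq)
  cys_counts <- nchar(distinct_cdr3) -
    nchar(gsub("C", "", distinct_cdr3, fixed = TRUE))
  cys_tab <- table(cys_counts)
  cys_hist <- stats::setNames(as.integer(cys_tab), names(cys_tab))

  modal_cdr1 <- names(which.max(table(m$cdr1_seq)))
  structure(list(
    n_total_unique = n,
    per_type_counts = counts,
    per_type_pct = repertoire_percentages(counts, digits = 1),
    n_unique_cdr3 = part$n_unique_cdr3,
    pct_unique_cdr3 = percentage(part$n_unique_cdr3, n, digits = 0),
    cdr3_length_hist = len_hist,
    cdr3_cys_hist = list(
      counts = cys_hist,
      pct = percentage(cys_hist, length(distinct_cdr3), digits = 0),
      n_distinct_cdr3 = length(distinct_cdr3)),
    cdr1_variability_pct = percentage(sum(m$cdr1_seq != modal_cdr1), n,
                                      digits = 1)),
    class = "vnar_repertoire_summary")
}

#' @export
print.vnar_repertoire_summary <- function(x, ...) {
  cat("vNAR repertoire summary\n")
  cat("  unique sequences:", x$n_total_unique, "\n")
  cat("  per-type counts (pct):\n")
  for (t in names(x$per_type_counts))
    cat(sprintf("    %-4s %8d  (%.1f%%)\n", t, x$per_type_counts[[t]],
                x$per_type_pct[[t]]))
  cat(sprintf("  unique CDR3s: %d (%d%%)\n", x$n_unique_cdr3,
              x$pct_unique_cdr3))
  lens <- as.integer(names(x$cdr3_length_hist))
  cat(sprintf("  CDR3 length: %d-%d\n", min(lens), max(lens)))
  cat("  CDR3 Cys counts over", x$cdr3_cys_hist$n_distinct_cdr3,
      "distinct CDR3s:",
      paste0(names(x$cdr3_cys_hist$counts), "=",
             x$cdr3_cys_hist$pct, "%", collapse = " "), "\n")
  cat(sprintf("  CDR1 variability: %.1f%%\n", x$cdr1_variability_pct))
  invisible(x)
}

#' CDR3 length range and modal-band fraction
#'
#' @param maps region-map tibble (`annotation_status == "ok"` rows used).
#' @param band inclusive length band whose share is reported; the 15-16
#'   band is the repertoire's mode.
#' @return list with `min`, `max` and `band_fraction`.
#' @export
cdr3_length_stats <- function(maps, band = c(15, 16)) {
  ok <- maps[maps$annotation_status == "ok", ]
  if (nrow(ok) == 0) stop("no annotated clones")
  lens <- ok$cdr3_length
  list(min = min(lens), max = max(lens),
       band_fraction = mean(lens >= band[1] & lens <= band[2]))
}

#' Write a repertoire summary as JSON (and histograms as TSV)
#'
#' @param summary a `vnar_repertoire_summary`.
#' @param path output JSON path.
#' @param hist_tsv optional path for a long-format TSV of the two
#'   histograms.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path, hist_tsv = NULL) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(hist_tsv)) {
    h1 <- data.frame(histogram = "cdr3_length",
                     key = names(summary$cdr3_length_hist),
                     count = as.integer(summary$cdr3_length_hist))
    h2 <- data.frame(histogram = "cdr3_cys",
                     key = names(summary$cdr3_cys_hist$counts),
                     count = as.integer(summary$cdr3_cys_hist$counts))
    utils::write.table(rbind(h1, h2), hist_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
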