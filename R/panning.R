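#' Call a phage-ELISA well positive by fold over negative controls
#'
#' A clone is ELISA-positive when its antigen signal is at least
#' `fold_threshold` times the strongest negative-control signal (BSA,
#' milk, unrelated antigen, ...). The maximum of the negatives is the
#' most conservative denominator; the threshold comparison is inclusive
#' (`fold >= 4` is positive). The call is invariant to rescaling all ODs
#' of a record by a positive constant.
#'
#' @param od_antigen antigen-well optical density (non-negative).
#' @param od_negatives numeric vector of negative-control ODs (at least
#'   one).
#' @param fold_threshold positivity threshold (default 4).
#' @return list with `positive`, `fold` (`NA` and a `flagged` record when
#'   every negative is zero, which leaves the fold undefined).
#' @examples
#' call_positive(1.2, c(BSA = 0.20, milk = 0.25)) # fold 4.8, positive
#' call_positive(0.6, c(BSA = 0.20))              # fold 3.0, negative
#' @export
call_positive <- function(od_antigen, od_negatives, fold_threshold = 4) {
  stopifnot(length(od_negatives) >= 1, all(is.finite(od_negatives)),
            all(od_negatives >= 0), is.finite(od_antigen), od_antigen >= 0)
  mx <- max(od_negatives)
  if (mx <= 0)
    return(list(positive = FALSE, fold = NA_real_, flagged = TRUE))
  fold <- od_antigen / mx
  list(positive = fold >= fold_threshold, fold = fold, flagged = FALSE)
}

# Negative-control columns of a wide ELISA tibble: every od_* column
# except od_antigen.
negative_columns <- function(records) {
  setdiff(grep("^od_", names(records), value = TRUE), "od_antigen")
}

# Per-record folds and calls for a wide ELISA tibble.
call_positive_all <- function(records, fold_threshold = 4) {
  negs <- negative_columns(records)
  if (!length(negs)) stop("no negative-control od_* columns found")
  mx <- do.call(pmax, records[negs])
  fold <- ifelse(mx > 0, records$od_antigen / mx, NA_real_)
  records$fold <- fold
  records$positive <- !is.na(fold) & fold >= fold_threshold
  records
}

#' Summarize one biopanning round of phage-ELISA screens
#'
#' Collapses replicate wells per clone and reports the round's positivity
#' and OD-bin composition. A clone is a consistent binder when it is
#' positive ([call_positive()]) in at least `min_replicates` independent
#' replicates (or in all of them when fewer were run). Positive clones
#' are binned by mean antigen OD: high (> 1.0), medium (0.5-1.0,
#' inclusive on both ends), low (< 0.5).
#'
#' @param records wide ELISA tibble for a single round: `clone_id`,
#'   `round_index`, `replicate`, `od_antigen`, plus one `od_*` column per
#'   negative control.
#' @param fold_threshold see [call_positive()].
#' @param min_replicates replicates required for a consistent call
#'   (default 3, matching triplicate phage-ELISA confirmation).
#' @return one-row tibble: `round_index`, `n_screened`, `n_positive`,
#'   `positivity_pct` (integer, half-up), `od_high`, `od_medium`,
#'   `od_low`, `high_od_fraction_of_positives`.
#' @examples
#' pan <- generate_panning_dataset(c(0.1, 0.2, 0.4), seed = 1)
#' summarize_round(pan$records[pan$records$round_index == 3, ])
#' @export
summarize_round <- function(records, fold_threshold = 4,
                            min_replicates = 3) {
  if (is.null(records) || nrow(records) == 0) stop("no ELISA records")
  rounds <- unique(records$round_index)
  if (length(rounds) != 1)
    stop("records span multiple rounds: ", paste(rounds, collapse = ", "))
  rec <- call_positive_all(records, fold_threshold)
  byclone <- split(rec, rec$clone_id)
  n_screened <- length(byclone)
  pos <- vapply(byclone, function(d)
    sum(d$positive) >= min(min_replicates, nrow(d)), logical(1))
  mean_od <- vapply(byclone, function(d) mean(d$od_antigen), numeric(1))
  n_positive <- sum(pos)
  od_pos <- mean_od[pos]
  high <- sum(od_pos > 1.0)
  medium <- sum(od_pos >= 0.5 & od_pos <= 1.0)
  low <- sum(od_pos < 0.5)
  tibble::tibble(
    round_index = rounds,
    n_screened = n_screened,
    n_positive = n_positive,
    positivity_pct = percentage(n_positive, n_screened),
    od_high = high, od_medium = medium, od_low = low,
    high_od_fraction_of_positives =
      if (n_positive > 0) high / n_positive else NA_real_)
}

#' Per-antigen uniqueness of sequenced binder clones
#'
#' Counts distinct sequences among the clones sent for sequencing for one
#' antigen, reproducing the "percentage of unique clones" bookkeeping of
#' a biopanning campaign.
#'
#' @param antigen antigen name.
#' @param sequenced_ids clone ids that were sequenced.
#' @param sequences named character vector (or tibble with `clone_id` and
#'   `aa`/`sequence`) resolving ids to sequences.
#' @return one-row tibble: `antigen`, `n_sequenced`, `n_unique`,
#'   `unique_pct` (integer, half-up).
#' @export
summarize_antigen <- function(antigen, sequenced_ids, sequences) {
  if (is.data.frame(sequences)) {
    col <- if ("aa" %in% names(sequences)) "aa" else "sequence"
    sequences <- stats::setNames(sequences[[col]], sequences$clone_id)
  }
  missing <- setdiff(sequenced_ids, names(sequences))
  if (length(missing))
    stop("no sequence for clone id(s): ", paste(missing, collapse = ", "))
  seqs <- sequences[sequenced_ids]
  n <- length(seqs)
  u <- length(unique(seqs))
  tibble::tibble(antigen = antigen, n_sequenced = n, n_unique = u,
                 unique_pct = percentage(u, n))
}

#' Positivity and uniqueness trajectory across biopanning rounds
#'
#' Joins per-round screen summaries with per-round uniqueness summaries
#' and reports the expected enrichment pattern flags: positivity
#' nondecreasing and uniqueness nonincreasing across rounds (reported,
#' never enforced).
#'
#' @param round_summaries tibble of rows from [summarize_round()]
#'   (>= 2 rounds).
#' @param antigen_summaries optional tibble with `round_index` and
#'   `unique_pct` columns (e.g. built from [summarize_antigen()] per
#'   round).
#' @return list with `trajectory` (tibble: `round_index`,
#'   `positivity_pct`, `unique_pct`), `positivity_nondecreasing`,
#'   `uniqueness_nonincreasing` (`NA` when uniqueness is absent).
#' @export
enrichment_trajectory <- function(round_summaries,
                                  antigen_summaries = NULL) {
  if (nrow(round_summaries) < 2)
    stop("trajectory needs at least two rounds")
  ord <- order(round_summaries$round_index)
  traj <- tibble::tibble(
    round_index = round_summaries$round_index[ord],
    positivity_pct = round_summaries$positivity_pct[ord],
    unique_pct = NA_real_)
  if (!is.null(antigen_summaries)) {
    m <- match(traj$round_index, antigen_summaries$round_index)
    traj$unique_pct <- antigen_summaries$unique_pct[m]
  }
  list(trajectory = traj,
       positivity_nondecreasing = !is.unsorted(traj$positivity_pct),
       uniqueness_nonincreasing =
         if (all(is.na(traj$unique_pct))) NA
         else !is.unsorted(rev(traj$unique_pct[!is.na(traj$unique_pct)])))
}

#' Read long-format ELISA records into the wide per-well layout
#'
#' Long input has one row per measured channel: columns `clone_id`,
#' `round`, `replicate`, `channel`, `od`, where `channel` is `antigen`
#' or a negative-control name. Output is the wide tibble used by
#' [summarize_round()].
#'
#' @param path TSV/CSV path (delimiter inferred from extension).
#' @return wide ELISA tibble.
#' @export
read_elisa_long <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  long <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
  need <- c("clone_id", "round", "replicate", "channel", "od")
  if (!all(need %in% names(long)))
    stop("long ELISA input needs columns: ", paste(need, collapse = ", "))
  key <- interaction(long$clone_id, long$round, long$replicate, drop = TRUE)
  rows <- lapply(split(long, key), function(d) {
    out <- data.frame(clone_id = d$clone_id[1], round_index = d$round[1],
                      replicate = d$replicate[1])
    for (j in seq_len(nrow(d))) {
      nm <- if (d$channel[j] == "antigen") "od_antigen"
            else paste0("od_", d$channel[j])
      out[[nm]] <- d$od[j]
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  tibble::as_tibble(out[order(out$round_index, out$clone_id,
                              out$replicate), ])
}
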