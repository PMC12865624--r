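#' Read cloned vNAR nucleotide sequences from FASTA or FASTQ
#'
#' Thin wrapper around Biostrings readers producing the tibble of
#' nucleotide clones used throughout the pipeline. Gzip-compressed files are
#' handled transparently. FASTQ base qualities are summarized into a
#' `mean_quality` column and otherwise discarded: no quality filtering is
#' applied.
#'
#' @param path path to a FASTA or FASTQ file (optionally gzipped).
#' @param format `"auto"` (by extension), `"fasta"` or `"fastq"`.
#' @param source provenance label stored on each clone, one of
#'   `"sanger"`, `"ngs"`, `"synthetic"`.
#' @return tibble with columns `clone_id`, `sequence`, `source` (and
#'   `mean_quality` for FASTQ input), one row per record in file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">c1", "CCATGGCTGCGGCCGC", ">c2", "ACGTACGT"), fa)
#' read_sequences(fa)
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq"),
                           source = c("ngs", "sanger", "synthetic")) {
  format <- match.arg(format)
  source <- match.arg(source)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.f(ast)?q(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  mean_quality <- NULL
  if (format == "fastq") {
    set <- tryCatch(
      suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path)),
      error = function(e) stop("failed to parse FASTQ '", path, "': ",
                               conditionMessage(e), call. = FALSE))
    if (length(set)) {
      qints <- as(Biostrings::quality(set), "IntegerList")
      mean_quality <- vapply(seq_along(set),
                             function(i) mean(qints[[i]]), numeric(1))
    }
  } else {
    set <- tryCatch(
      Biostrings::readDNAStringSet(path, format = "fasta"),
      error = function(e) stop("failed to parse FASTA '", path, "': ",
                               conditionMessage(e), call. = FALSE))
  }
  if (length(set) == 0) {
    warning("no sequence records in ", path)
    return(tibble::tibble(clone_id = character(), sequence = character(),
                          source = character()))
  }
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated clone id(s): ", paste(dup, collapse = ", "))
  seqs <- unname(toupper(as.character(set)))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-ACGTN characters in record(s): ",
         paste(ids[bad], collapse = ", "))
  out <- tibble::tibble(clone_id = ids, sequence = seqs, source = source)
  if (!is.null(mean_quality)) out$mean_quality <- mean_quality
  out
}

#' Write clone nucleotide sequences to FASTA
#'
#' @param clones tibble with `clone_id` and a nucleotide column
#'   (`sequence` or `nt`).
#' @param path output file path (`.gz` suffix triggers compression).
#' @return `path`, invisibly.
#' @export
write_sequences <- function(clones, path) {
  col <- if ("sequence" %in% names(clones)) "sequence" else "nt"
  set <- Biostrings::DNAStringSet(clones[[col]])
  names(set) <- clones$clone_id
  Biostrings::writeXStringSet(set, path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

# Scan one oriented sequence for the cloning flanks. Returns the first 5'
# motif occurrence and the last 3' motif occurrence after it; the insert
# span is the half-open interval [5' motif start, 3' motif start), so it
# contains the full 5' motif (including its embedded ATG).
scan_flanks <- function(sequence, flank_5p, flank_3p) {
  s5 <- gregexpr(flank_5p, sequence, fixed = TRUE)[[1]]
  s3 <- gregexpr(flank_3p, sequence, fixed = TRUE)[[1]]
  found_5p <- s5[1] > 0
  found_3p_any <- s3[1] > 0
  first5 <- if (found_5p) min(s5) else NA_integer_
  last3 <- NA_integer_
  if (found_5p && found_3p_any) {
    after <- s3[s3 >= first5 + nchar(flank_5p)]
    if (length(after)) last3 <- max(after)
  } else if (found_3p_any) {
    last3 <- max(s3)
  }
  list(found_5p = found_5p,
       found_3p = found_3p_any,
       insert_start = first5,
       insert_end = if (found_5p && !is.na(last3)) last3 else NA_integer_)
}

#' Locate the cloning-site flanks of a vNAR insert
#'
#' Searches a read for the 5' and 3' restriction-site motifs that flank the
#' cloned insert (NcoI `CCATGG` and NotI `GCGGCCGC` by default). When the 5'
#' motif is absent on the forward strand the reverse complement is scanned
#' and, if it carries the motif, coordinates are reported on that strand.
#' When a motif occurs more than once, the first 5' occurrence and the last
#' compatible 3' occurrence are paired, which maximizes the recovered
#' insert length.
#'
#' @param sequence a nucleotide string, or a one-row clone tibble with a
#'   `sequence` column.
#' @param flank_5p,flank_3p non-empty DNA motifs.
#' @return list with `found_5p`, `found_3p` (logicals), `insert_start`,
#'   `insert_end` (the half-open interval `[insert_start, insert_end)` on
#'   the oriented sequence, `NA` when either motif is missing),
#'   `orientation` (`"forward"` or `"reverse"`) and `oriented_sequence`.
#' @examples
#' detect_flanks(paste0("CCATGG", strrep("A", 330), "GCGGCCGC"))
#' @export
detect_flanks <- function(sequence, flank_5p = "CCATGG",
                          flank_3p = "GCGGCCGC") {
  stopifnot(nchar(flank_5p) > 0, nchar(flank_3p) > 0)
  if (is.data.frame(sequence)) sequence <- sequence$sequence[1]
  hit <- scan_flanks(sequence, flank_5p, flank_3p)
  orientation <- "forward"
  oriented <- sequence
  # Both default motifs are palindromic, so 5'-motif presence alone does
  # not identify the strand: adopt the reverse complement only when it
  # carries a valid 5' -> 3' arrangement that the forward strand lacks.
  valid <- function(h) h$found_5p && !is.na(h$insert_end)
  if (!valid(hit)) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
    rhit <- scan_flanks(rc, flank_5p, flank_3p)
    if (valid(rhit) || (!hit$found_5p && rhit$found_5p)) {
      hit <- rhit
      orientation <- "reverse"
      oriented <- rc
    }
  }
  list(found_5p = hit$found_5p, found_3p = hit$found_3p,
       insert_start = hit$insert_start, insert_end = hit$insert_end,
       orientation = orientation, oriented_sequence = oriented)
}

#' Translate cloned inserts and apply open-reading-frame quality control
#'
#' The workhorse QC step for "bald"/defective clones. For each clone the
#' cloning flanks are located ([detect_flanks()]); translation starts at
#' the ATG embedded in the 5' flank and runs to the last full codon before
#' the 3' flank, using the standard genetic code. Flags:
#' \describe{
#'   \item{missing_5p_flank / missing_3p_flank}{flank motif not found (in
#'     either orientation for the 5' flank); such clones are incomplete.}
#'   \item{untranslatable}{no ATG available under the flank policy; no
#'     protein is reported.}
#'   \item{frameshift}{coding length (ATG through the last base before the
#'     3' flank) is not a multiple of 3; no protein is reported.}
#'   \item{premature_stop}{a stop codon occurs before the 3' flank; no
#'     protein is reported.}
#'   \item{too_short}{translated domain shorter than `min_aa_length`
#'     (protein retained).}
#' }
#' When the 3' flank is missing, translation runs to the end of the read
#' (trimmed to a full codon) and the frameshift check is skipped because
#' the insert end is unknown.
#'
#' @param clones tibble from [read_sequences()] (or any tibble with
#'   `clone_id` and `sequence` columns).
#' @param flank_5p,flank_3p cloning-site motifs (defaults NcoI/NotI).
#' @param min_aa_length minimum translated length in residues; vNAR
#'   domains run ~100-115 aa, so the default 80 guards region annotation
#'   against fragments.
#' @return tibble of clone records: `clone_id`, `nt` (oriented sequence),
#'   `orientation`, `frame_offset`, `qc_flags` (";"-joined, `""` if
#'   clean), `is_complete_insert`, `aa` (`NA` when untranslatable,
#'   frameshifted, or stopped).
#' @seealso [completeness_rate()], [annotate_repertoire()]
#' @export
translate_repertoire <- function(clones, flank_5p = "CCATGG",
                                 flank_3p = "GCGGCCGC",
                                 min_aa_length = 80) {
  stopifnot(nrow(clones) > 0)
  n <- nrow(clones)
  nt <- character(n); orientation <- character(n)
  frame_offset <- rep(NA_integer_, n)
  is_complete <- logical(n)
  flags <- vector("list", n)
  coding <- rep(NA_character_, n)
  atg_rel <- regexpr("ATG", flank_5p, fixed = TRUE)[1]

  for (i in seq_len(n)) {
    fl <- character(0)
    det <- detect_flanks(clones$sequence[i], flank_5p, flank_3p)
    seq_i <- det$oriented_sequence
    nt[i] <- seq_i
    orientation[i] <- det$orientation
    found3_valid <- det$found_3p && !is.na(det$insert_end)
    if (!det$found_5p) fl <- c(fl, "missing_5p_flank")
    if (!found3_valid) fl <- c(fl, "missing_3p_flank")
    is_complete[i] <- det$found_5p && found3_valid

    atg <- NA_integer_
    if (det$found_5p) {
      if (atg_rel > 0) {
        atg <- det$insert_start + atg_rel - 1L
      } else {
        rel <- regexpr("ATG", substring(seq_i, det$insert_start +
                                          nchar(flank_5p)), fixed = TRUE)[1]
        if (rel > 0) atg <- det$insert_start + nchar(flank_5p) + rel - 1L
      }
    }
    if (is.na(atg)) {
      fl <- c(fl, "untranslatable")
      flags[[i]] <- fl
      next
    }
    frame_offset[i] <- (atg - 1L) %% 3L
    cod_end <- if (found3_valid) det$insert_end - 1L else nchar(seq_i)
    len <- cod_end - atg + 1L
    if (found3_valid && len %% 3L != 0L) {
      fl <- c(fl, "frameshift")
      flags[[i]] <- fl
      next
    }
    len <- 3L * (len %/% 3L)
    if (len < 3L) {
      fl <- c(fl, "untranslatable")
      flags[[i]] <- fl
      next
    }
    coding[i] <- substring(seq_i, atg, atg + len - 1L)
    flags[[i]] <- fl
  }

  aa <- rep(NA_character_, n)
  idx <- which(!is.na(coding))
  if (length(idx)) {
    prot <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(coding[idx]), if.fuzzy.codon = "solve"))
    for (k in seq_along(idx)) {
      i <- idx[k]
      if (grepl("*", prot[k], fixed = TRUE)) {
        flags[[i]] <- c(flags[[i]], "premature_stop")
      } else {
        aa[i] <- prot[k]
        if (nchar(prot[k]) < min_aa_length)
          flags[[i]] <- c(flags[[i]], "too_short")
      }
    }
  }

  tibble::tibble(
    clone_id = clones$clone_id,
    nt = nt,
    orientation = orientation,
    frame_offset = frame_offset,
    qc_flags = vapply(flags, join_flags, character(1)),
    is_complete_insert = is_complete,
    aa = aa)
}

#' @rdname translate_repertoire
#' @param clone a one-row clone tibble (or list with `clone_id` and
#'   `sequence`).
#' @param ... passed on to [translate_repertoire()].
#' @export
translate_and_qc <- function(clone, ...) {
  if (!is.data.frame(clone)) clone <- tibble::as_tibble(clone[c("clone_id", "sequence")])
  translate_repertoire(clone[1, , drop = FALSE], ...)
}

#' Fraction of clone records with a complete insert
#'
#' A clone is complete when both cloning flanks were found; this mirrors
#' colony-PCR/digest screening of a phagemid library for full-length
#' inserts.
#'
#' @param records tibble from [translate_repertoire()].
#' @return fraction in `[0, 1]`.
#' @examples
#' # 97 of 100 clones retaining both flanks gives 0.97
#' @export
completeness_rate <- function(records) {
  if (is.null(records) || nrow(records) == 0)
    stop("no clone records supplied")
  mean(records$is_complete_insert)
}

#' Write a clone-record table as TSV
#'
#' Columns: `clone_id`, `frame_offset`, `qc_flags` (";"-joined),
#' `is_complete_insert`, `aa`.
#'
#' @param records tibble from [translate_repertoire()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clone_tsv <- function(records, path) {
  utils::write.table(
    records[, c("clone_id", "frame_offset", "qc_flags",
                "is_complete_insert", "aa")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
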