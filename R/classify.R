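#' Classify annotated vNAR clones into types I, IIa, IIb, III and IV
#'
#' Assigns each `annotation_status == "ok"` clone a vNAR type from the
#' noncanonical cysteine/tryptophan pattern of its CDR1 and CDR3, using a
#' strict precedence so that every evidence pattern fires exactly one
#' rule:
#' \enumerate{
#'   \item \strong{III} — CDR1 has Cys at scheme position 29 \emph{and}
#'     Trp at position 30;
#'   \item \strong{IIa} — at least one Cys in CDR1 and at least one in
#'     CDR3 (the "typical type II" CDR1-CDR3 interloop pattern);
#'   \item \strong{I} — no CDR1 Cys and an even CDR3 Cys count >= 2
#'     (paired intraloop/interloop linkages);
#'   \item \strong{IIb} — a Cys in exactly one of the two loops (odd
#'     CDR3 counts 1, 3, 5 with a Cys-free CDR1 land here);
#'   \item \strong{IV} — no noncanonical Cys in either loop.
#' }
#' The canonical Cys22/Cys83 anchors lie in framework spans and never
#' enter these counts. Cysteines in HV2/HV4 play no role in typing but
#' raise a warning (`hv_cys_warning` column).
#'
#' @param maps region-map tibble from [annotate_repertoire()]; rows with
#'   `annotation_status != "ok"` are excluded with a warning.
#' @param records ignored (accepted so the full clone-record table can be
#'   passed alongside the maps); all evidence is read from the map's
#'   region sequences.
#' @return tibble with one row per classified clone, in input order:
#'   `clone_id`, `label` (factor I/IIa/IIb/III/IV), `cdr1_cys_positions`
#'   (absolute residue indices, ";"-joined), `cdr3_cys_count`,
#'   `cdr1_trp30`, `rule_fired`, `hv_cys_warning`.
#' @examples
#' lib <- generate_library(library_spec(n_clones = 50, seed = 1))
#' rec <- translate_repertoire(lib)
#' maps <- annotate_repertoire(rec)
#' table(classify_repertoire(maps)$label)
#' @export
classify_repertoire <- function(maps, records = NULL) {
  if (nrow(maps) == 0) stop("empty annotation table")
  drop <- maps$annotation_status != "ok"
  if (all(drop)) {
    warning("no clones with annotation_status == 'ok'")
    return(tibble::tibble(clone_id = character(),
                          label = factor(character(), levels = vnar_types),
                          cdr1_cys_positions = character(),
                          cdr3_cys_count = integer(),
                          cdr1_trp30 = logical(),
                          rule_fired = character(),
                          hv_cys_warning = logical()))
  }
  if (any(drop))
    warning(sum(drop), " unannotated clone(s) excluded from classification")
  m <- maps[!drop, ]

  cdr1_rel <- gregexpr("C", m$cdr1_seq, fixed = TRUE)
  cdr1_pos <- lapply(seq_len(nrow(m)), function(i) {
    p <- cdr1_rel[[i]]
    p <- p[p > 0]
    if (length(p)) p + m$cdr1_start[i] - 1L else integer(0)
  })
  n_cdr1 <- lengths(cdr1_pos)
  n_cdr3 <- nchar(m$cdr3_seq) - nchar(gsub("C", "", m$cdr3_seq, fixed = TRUE))
  cys29 <- substring(m$cdr1_seq, 5, 5) == "C"
  trp30 <- substring(m$cdr1_seq, 6, 6) == "W"

  label <- ifelse(cys29 & trp30, "III",
           ifelse(n_cdr1 >= 1 & n_cdr3 >= 1, "IIa",
           ifelse(n_cdr1 == 0 & n_cdr3 >= 2 & n_cdr3 %% 2 == 0, "I",
           ifelse(xor(n_cdr1 >= 1, n_cdr3 >= 1), "IIb", "IV"))))
  rule <- c(III = "cys29_trp30_cdr1",
            IIa = "interloop_cdr1_cdr3_cys",
            I = "even_cdr3_cys_no_cdr1_cys",
            IIb = "single_loop_cys",
            IV = "no_noncanonical_cys")[label]

  hv_warn <- grepl("C", m$hv2_seq, fixed = TRUE) |
    grepl("C", m$hv4_seq, fixed = TRUE)
  if (any(hv_warn))
    warning(sum(hv_warn),
            " clone(s) carry HV2/HV4 cysteines (ignored for typing)")

  tibble::tibble(
    clone_id = m$clone_id,
    label = factor(label, levels = vnar_types),
    cdr1_cys_positions = vapply(cdr1_pos, function(p)
      paste(p, collapse = ";"), character(1)),
    cdr3_cys_count = as.integer(n_cdr3),
    cdr1_trp30 = trp30,
    rule_fired = unname(rule),
    hv_cys_warning = hv_warn)
}

#' The five vNAR type labels
#' @export
vnar_types <- c("I", "IIa", "IIb", "III", "IV")

#' @rdname classify_repertoire
#' @param map one-row region-map tibble for a single clone.
#' @param aa ignored (kept for symmetry with the per-clone call style);
#'   evidence is read from the map.
#' @export
classify_type <- function(map, aa = NULL) {
  if (map$annotation_status[1] != "ok")
    stop("clone ", map$clone_id[1], " is not annotated (status = ",
         map$annotation_status[1], ")")
  classify_repertoire(map[1, , drop = FALSE])
}

#' Write a type-call table as TSV
#'
#' @param calls tibble from [classify_repertoire()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_typecall_tsv <- function(calls, path) {
  utils::write.table(
    calls[, c("clone_id", "label", "cdr1_cys_positions", "cdr3_cys_count",
              "cdr1_trp30", "rule_fired")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
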