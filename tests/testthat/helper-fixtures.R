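# Shared fixtures for the test suite. Everything is built in code; no
# files are stored.

# A clean cloned insert: CC + ATG + 111 Ala codons + NotI site. The
# coding region (ATG..last base before the 3' flank) is 336 nt and
# translates to Met + 111 Ala = 112 residues.
clean_nt <- function(n_ala = 111) {
  paste0("CC", "ATG", strrep("GCT", n_ala), "GCGGCCGC")
}

clone_tbl <- function(sequences, ids = sprintf("c%d", seq_along(sequences))) {
  tibble::tibble(clone_id = ids, sequence = sequences, source = "synthetic")
}

# Minimal one-row region map carrying exactly the evidence the classifier
# reads, on the 112-residue reference frame.
make_map <- function(cdr1, cdr3, id = "m1") {
  stopifnot(nchar(cdr1) == 9)
  tibble::tibble(
    clone_id = id,
    cdr1_start = 25L, cdr1_end = 33L,
    cdr3_start = 87L, cdr3_end = 86L + nchar(cdr3),
    cdr3_length = nchar(cdr3),
    cdr1_seq = cdr1, cdr3_seq = cdr3,
    hv2_seq = "STNEESIS", hv4_seq = "DSAKNT",
    leu31_present = substr(cdr1, 7, 7) == "L",
    annotation_status = "ok")
}

# Independent restatement of the published typing rules, evaluated in
# their textual order, for cross-checking the classifier over the
# enumerated evidence space.
oracle_type <- function(cdr1, cdr3) {
  ch1 <- strsplit(cdr1, "")[[1]]
  n1 <- sum(ch1 == "C")
  n3 <- sum(strsplit(cdr3, "")[[1]] == "C")
  if (ch1[5] == "C" && ch1[6] == "W") return("III")       # Cys29 + Trp30
  if (n1 >= 1 && n3 >= 1) return("IIa")                   # interloop pair
  if (n1 == 0 && n3 >= 2 && n3 %% 2 == 0) return("I")     # paired CDR3 Cys
  if ((n1 >= 1) != (n3 >= 1)) return("IIb")               # one loop only
  "IV"                                                    # no noncanonical
}

# Small defect-free library shared by several structural tests.
small_clean_library <- function(n = 400, seed = 11, ...) {
  generate_library(library_spec(
    n_clones = n, seed = seed,
    defect_rates = c(missing_flank = 0, premature_stop = 0,
                     frameshift = 0), ...))
}
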