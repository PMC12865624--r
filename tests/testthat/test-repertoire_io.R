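test_that("FASTA round trip preserves ids and sequences, FASTQ parses, duplicates error", {
  clones <- clone_tbl(c(clean_nt(), "ACGTNACGT"), ids = c("a", "b"))
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_sequences(clones, fa)
  back <- read_sequences(fa, source = "synthetic")
  expect_equal(back$clone_id, clones$clone_id)
  expect_equal(back$sequence, clones$sequence)

  fq <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGTN", "+", "IIIII",
               "@r2", "CCATGGAA", "+", "IIIIIIII"), fq)
  recs <- read_sequences(fq)
  expect_equal(recs$clone_id, c("r1", "r2"))
  expect_equal(recs$sequence[1], "ACGTN")
  expect_true(all(recs$mean_quality == 40))

  dupfa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "ACGT", ">x", "GGCC"), dupfa)
  expect_error(read_sequences(dupfa), "x")

  emptyfa <- withr::local_tempfile(fileext = ".fasta")
  file.create(emptyfa)
  expect_warning(out <- read_sequences(emptyfa), "no sequence")
  expect_equal(nrow(out), 0)
})

test_that("flank detection reports spans, absences, and strand orientation", {
  s <- paste0("CCATGG", strrep("A", 330), "GCGGCCGC")
  det <- detect_flanks(s)
  expect_true(det$found_5p && det$found_3p)
  expect_equal(det$insert_end - det$insert_start, 336)

  no3 <- paste0("CCATGG", strrep("A", 50))
  det2 <- detect_flanks(no3)
  expect_true(det2$found_5p)
  expect_false(det2$found_3p)
  expect_true(is.na(det2$insert_end))

  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  det3 <- detect_flanks(rc)
  expect_equal(det3$orientation, "reverse")
  expect_equal(det3$insert_end - det3$insert_start, 336)
})

test_that("repeated flank occurrences resolve to the maximal insert (brute force oracle)", {
  s <- paste0("TT", "CCATGG", strrep("A", 30), "CCATGG", strrep("G", 40),
              "GCGGCCGC", strrep("T", 20), "GCGGCCGC", "AA")
  det <- detect_flanks(s)
  # oracle: enumerate all (5' occurrence, downstream 3' occurrence) pairs
  p5 <- gregexpr("CCATGG", s, fixed = TRUE)[[1]]
  p3 <- gregexpr("GCGGCCGC", s, fixed = TRUE)[[1]]
  pairs <- expand.grid(a = as.integer(p5), b = as.integer(p3))
  pairs <- pairs[pairs$b >= pairs$a + 6, ]
  best <- pairs[which.max(pairs$b - pairs$a), ]
  expect_equal(det$insert_start, best$a)
  expect_equal(det$insert_end, best$b)
})

test_that("translation QC flags clean, stopped, frameshifted and flankless inserts", {
  clean <- clean_nt()
  rec <- translate_and_qc(clone_tbl(clean, "clean"))
  expect_equal(rec$qc_flags, "")
  expect_true(rec$is_complete_insert)
  expect_equal(nchar(rec$aa), 112)
  expect_equal(rec$aa, paste0("M", strrep("A", 111)))
  expect_equal(rec$frame_offset, 2L)

  stopped <- clean
  substr(stopped, 120, 122) <- "TAA"  # codon 40
  rec2 <- translate_and_qc(clone_tbl(stopped, "stop"))
  expect_true(has_stop <- grepl("premature_stop", rec2$qc_flags))
  expect_true(is.na(rec2$aa))

  shift <- paste0(substring(clean, 1, 9), substring(clean, 11))
  rec3 <- translate_and_qc(clone_tbl(shift, "fs"))
  expect_match(rec3$qc_flags, "frameshift")
  expect_true(is.na(rec3$aa))

  no3p <- substring(clean, 1, nchar(clean) - 8)
  rec4 <- translate_and_qc(clone_tbl(no3p, "no3"))
  expect_match(rec4$qc_flags, "missing_3p_flank")
  expect_false(rec4$is_complete_insert)
  expect_equal(rec4$aa, paste0("M", strrep("A", 111)))

  no5p <- substring(clean, 7)
  rec5 <- translate_and_qc(clone_tbl(no5p, "no5"))
  expect_match(rec5$qc_flags, "missing_5p_flank")
  expect_match(rec5$qc_flags, "untranslatable")
  expect_true(is.na(rec5$aa))
})

test_that("translation agrees with an independent codon-table oracle on generated clones", {
  lib <- small_clean_library(n = 60, seed = 5)
  rec <- translate_repertoire(lib)
  expect_true(all(rec$qc_flags == ""))
  for (i in seq_len(nrow(rec))) {
    coding <- substring(lib$sequence[i], 3, nchar(lib$sequence[i]) - 8)
    oracle <- paste(seqinr::translate(strsplit(tolower(coding), "")[[1]]),
                    collapse = "")
    expect_equal(rec$aa[i], oracle)
  }
  expect_equal(rec$aa, lib$true_aa)
})

test_that("records with a protein never carry fatal flags, and reverse reads translate", {
  lib <- generate_library(library_spec(
    n_clones = 150, seed = 9,
    defect_rates = c(missing_flank = 0.04, premature_stop = 0.04,
                     frameshift = 0.02)))
  rec <- translate_repertoire(lib)
  with_aa <- !is.na(rec$aa)
  fatal <- grepl("premature_stop|frameshift|untranslatable", rec$qc_flags)
  expect_true(!any(with_aa & fatal))

  # reverse-complemented clean reads are recovered on the opposite strand
  rc <- vapply(lib$sequence[1:5], function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
    character(1))
  rec_rc <- translate_repertoire(clone_tbl(unname(rc)))
  fwd <- translate_repertoire(lib[1:5, ])
  expect_equal(rec_rc$aa, fwd$aa)
  expect_true(all(rec_rc$orientation[!is.na(rec_rc$aa)] == "reverse"))
})

test_that("completeness rate equals the count fraction", {
  lib <- generate_library(library_spec(
    n_clones = 100, seed = 2,
    defect_rates = c(missing_flank = 0.03, premature_stop = 0,
                     frameshift = 0)))
  rec <- translate_repertoire(lib)
  expect_equal(completeness_rate(rec), 0.97)
  expect_equal(completeness_rate(rec),
               sum(rec$is_complete_insert) / nrow(rec))
  expect_equal(completeness_rate(rec[rec$is_complete_insert, ]), 1.0)
  expect_equal(completeness_rate(rec[!rec$is_complete_insert, ]), 0.0)
  expect_error(completeness_rate(rec[0, ]), "no clone")
})
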