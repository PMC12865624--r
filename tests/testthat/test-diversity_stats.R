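test_that("half-up rounding and percentage helpers reproduce printed-style values", {
  expect_equal(round_half_up(41.46, 1), 41.5)
  expect_equal(round_half_up(15.2077, 1), 15.2)
  expect_equal(round_half_up(72.727), 73)
  expect_equal(round_half_up(0.5), 1)   # half goes up
  expect_equal(percentage(12, 16), 75)
  expect_equal(largest_remainder(c(a = 0.2, b = 0.5, c = 0.3), 7),
               c(a = 1L, b = 4L, c = 2L))
  expect_equal(sum(largest_remainder(c(1, 1, 1), 100)), 100)
})

test_that("dedupe keeps first occurrences with multiplicities and is idempotent", {
  recs <- tibble::tibble(clone_id = c("c1", "c2", "c3"),
                         aa = c("AAA", "AAA", "BBB"))
  d <- dedupe_sequences(recs)
  expect_equal(d$unique$clone_id, c("c1", "c3"))
  expect_equal(unname(d$multiplicity), c(2L, 1L))
  expect_equal(names(d$multiplicity), c("AAA", "BBB"))

  again <- dedupe_sequences(d$unique)
  expect_equal(again$unique, d$unique)
  expect_true(all(again$multiplicity == 1))

  distinct <- tibble::tibble(clone_id = c("a", "b"), aa = c("X", "Y"))
  expect_equal(dedupe_sequences(distinct)$unique, distinct)
})

test_that("dedupe matches the quadratic pairwise oracle on planted duplicates", {
  set.seed(31)
  n <- 500
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  pool <- vapply(seq_len(200), function(i)
    paste(sample(alphabet, 12, TRUE), collapse = ""), character(1))
  seqs <- sample(pool, n, replace = TRUE)  # guaranteed collisions
  recs <- tibble::tibble(clone_id = sprintf("c%03d", seq_len(n)), aa = seqs)
  d <- dedupe_sequences(recs)

  # O(n^2) oracle: a record is kept iff no earlier record equals it
  keep <- logical(n)
  for (i in seq_len(n)) {
    dup <- FALSE
    for (j in seq_len(i - 1)) if (seqs[j] == seqs[i]) { dup <- TRUE; break }
    keep[i] <- !dup
  }
  expect_equal(d$unique$clone_id, recs$clone_id[keep])
  counts <- vapply(seqs[keep], function(s) sum(seqs == s), integer(1))
  expect_equal(unname(d$multiplicity), unname(counts))
})

test_that("CDR3 uniqueness partition counts singletons and sums to input size", {
  maps <- do.call(rbind, lapply(seq_along(c("X", "X", "Y", "Z")), function(i)
    make_map("DSNQALLAS", c("XAKDYSEYAP", "XAKDYSEYAP", "YAKDYSEYAP",
                            "ZAKDYSEYAP")[i], id = paste0("c", i))))
  part <- unique_cdr3_partition(maps)
  expect_equal(part$n_unique_cdr3, 2L)
  expect_equal(part$n_variable_elsewhere, 2L)
  expect_equal(part$n_unique_cdr3 + part$n_variable_elsewhere, 4L)

  distinct <- do.call(rbind, lapply(1:4, function(i)
    make_map("DSNQALLAS", paste0(LETTERS[i], "AKDYSEYAP"),
             id = paste0("d", i))))
  expect_equal(unique_cdr3_partition(distinct)$n_unique_cdr3, 4L)
})

test_that("repertoire summary conserves counts and reproduces its percentages", {
  lib <- small_clean_library(n = 1000, seed = 23, duplicate_rate = 0.1)
  rec <- translate_repertoire(lib)
  uni <- dedupe_sequences(rec)$unique
  maps <- annotate_repertoire(uni)
  calls <- classify_repertoire(maps)
  s <- summarize_repertoire(calls, maps)

  expect_equal(nrow(uni), 900)  # 10% planted duplicates, by count
  expect_equal(sum(s$per_type_counts), s$n_total_unique)
  expect_equal(sum(s$cdr3_length_hist), s$n_total_unique)
  expect_equal(sum(s$cdr3_cys_hist$counts), s$cdr3_cys_hist$n_distinct_cdr3)
  # recomputing percentages from counts reproduces the stored values
  expect_equal(s$per_type_pct,
               repertoire_percentages(s$per_type_counts, 1))
  expect_equal(s$pct_unique_cdr3,
               percentage(s$n_unique_cdr3, s$n_total_unique))
  expect_equal(s$cdr3_cys_hist$pct,
               percentage(s$cdr3_cys_hist$counts,
                          s$cdr3_cys_hist$n_distinct_cdr3))
  expect_error(summarize_repertoire(calls[-1, ], maps), "different clone")
})

test_that("per-type percentages converge to the generator proportions", {
  spec <- library_spec(n_clones = 10000, seed = 29,
                       defect_rates = c(missing_flank = 0,
                                        premature_stop = 0, frameshift = 0))
  lib <- generate_library(spec)
  maps <- annotate_repertoire(translate_repertoire(lib))
  calls <- classify_repertoire(maps)
  s <- summarize_repertoire(calls, maps)
  for (t in vnar_types) {
    p <- spec$type_proportions[[t]]
    se <- sqrt(p * (1 - p) / 10000)
    expect_lt(abs(s$per_type_counts[[t]] / 10000 - p), 3 * se + 1e-4)
  }
  lens <- as.integer(names(s$cdr3_length_hist))
  expect_gte(min(lens), 6)
  expect_lte(max(lens), 28)
})

test_that("CDR3 length stats report range and band fraction", {
  all10 <- do.call(rbind, lapply(1:6, function(i)
    make_map("DSNQALLAS", "AKDYSEYAPR", id = paste0("t", i))))
  st <- cdr3_length_stats(all10)
  expect_equal(st, list(min = 10L, max = 10L, band_fraction = 0))

  mixed <- do.call(rbind, lapply(1:10, function(i) {
    len <- if (i <= 5) 15 else 12
    make_map("DSNQALLAS", strrep("A", len), id = paste0("m", i))
  }))
  expect_equal(cdr3_length_stats(mixed)$band_fraction, 0.5)
  expect_error(cdr3_length_stats(all10[0, ]), "no annotated")
})
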