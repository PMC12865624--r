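test_that("fold-over-negatives call follows the four-fold rule, inclusive boundary", {
  r <- call_positive(1.2, c(BSA = 0.20, milk = 0.25))
  expect_equal(r$fold, 4.8)
  expect_true(r$positive)

  r2 <- call_positive(0.6, c(BSA = 0.20))
  expect_equal(r2$fold, 3.0)
  expect_false(r2$positive)

  r3 <- call_positive(0.8, c(BSA = 0.2, milk = 0.2))
  expect_equal(r3$fold, 4.0)
  expect_true(r3$positive)  # >= threshold is positive

  r4 <- call_positive(0.8, c(BSA = 0, milk = 0))
  expect_false(r4$positive)
  expect_true(is.na(r4$fold) && r4$flagged)
})

test_that("positivity calls are invariant to rescaling all ODs of a record", {
  set.seed(41)
  for (i in 1:20) {
    ag <- stats::runif(1, 0, 2)
    negs <- stats::runif(2, 0.01, 0.5)
    base <- call_positive(ag, negs)
    for (c in c(0.01, 1, 137)) {
      scaled <- call_positive(ag * c, negs * c)
      expect_equal(scaled$positive, base$positive)
      expect_equal(scaled$fold, base$fold)
    }
  }
})

test_that("round summaries reproduce the printed screen arithmetic and OD bins", {
  mk_round <- function(n, npos, ods_pos) {
    tibble::tibble(
      clone_id = sprintf("k%02d", seq_len(n)),
      round_index = 4,
      replicate = 1,
      od_antigen = c(ods_pos, rep(0.1, n - npos)),
      od_bsa = 0.1, od_milk = 0.08)
  }
  s <- summarize_round(mk_round(30, 12, rep(1.2, 12)), min_replicates = 1)
  expect_equal(s$n_positive, 12)
  expect_equal(s$positivity_pct, 40)

  s2 <- summarize_round(mk_round(30, 6, rep(1.2, 6)), min_replicates = 1)
  expect_equal(s2$positivity_pct, 20)

  # 10 positives, 7 above 1.0 OD, one exactly at 1.0 (medium bin)
  s3 <- summarize_round(mk_round(20, 10, c(rep(1.4, 7), 1.0, 0.8, 0.6)),
                        min_replicates = 1)
  expect_equal(s3$od_high, 7)
  expect_equal(s3$od_medium, 3)
  expect_equal(s3$od_high + s3$od_medium + s3$od_low, s3$n_positive)
  expect_equal(s3$high_od_fraction_of_positives, 0.7)

  expect_error(summarize_round(mk_round(5, 0, numeric(0))[0, ]), "no ELISA")
  two <- rbind(mk_round(5, 0, numeric(0)),
               tibble::tibble(clone_id = "x", round_index = 3, replicate = 1,
                              od_antigen = 1, od_bsa = 0.1, od_milk = 0.1))
  expect_error(summarize_round(two), "multiple rounds")
})

test_that("consistent binders need the replicate majority", {
  rec <- tibble::tibble(
    clone_id = rep(c("a", "b"), each = 3),
    round_index = 3,
    replicate = rep(1:3, 2),
    od_antigen = c(1.2, 1.3, 1.1,   # a: positive in all three
                   1.2, 0.2, 0.2),  # b: positive once only
    od_bsa = 0.1, od_milk = 0.1)
  s <- summarize_round(rec)
  expect_equal(s$n_screened, 2)
  expect_equal(s$n_positive, 1)
})

test_that("per-antigen uniqueness reproduces the campaign bookkeeping", {
  seqs <- stats::setNames(
    c(sprintf("UNIQ%02d", 1:12), sprintf("UNIQ%02d", 1:4)),
    sprintf("jev%02d", 1:16))
  s <- summarize_antigen("JEV Env", names(seqs), seqs)
  expect_equal(s$n_unique, 12)
  expect_equal(s$unique_pct, 75)

  all_uniq <- stats::setNames(sprintf("S%d", 1:8), sprintf("sort%d", 1:8))
  expect_equal(summarize_antigen("SORT1", names(all_uniq),
                                 all_uniq)$unique_pct, 100)

  same <- stats::setNames(rep("AAAA", 10), sprintf("t%d", 1:10))
  expect_equal(summarize_antigen("toxin", names(same), same)$unique_pct, 10)

  expect_error(summarize_antigen("x", c("t1", "ghost"), same), "ghost")
})

test_that("enrichment trajectory flags monotone positivity and uniqueness", {
  rounds <- tibble::tibble(round_index = 2:4,
                           positivity_pct = c(10, 20, 40),
                           n_screened = 30, n_positive = c(3, 6, 12),
                           od_high = 0, od_medium = 0, od_low = 0,
                           high_od_fraction_of_positives = 0)
  ants <- tibble::tibble(round_index = 2:4, unique_pct = c(90, 75, 30))
  tr <- enrichment_trajectory(rounds, ants)
  expect_true(tr$positivity_nondecreasing)
  expect_true(tr$uniqueness_nonincreasing)
  expect_equal(tr$trajectory$unique_pct, c(90, 75, 30))

  down <- rounds
  down$positivity_pct <- c(40, 20, 30)
  expect_false(enrichment_trajectory(down, ants)$positivity_nondecreasing)
  expect_error(enrichment_trajectory(rounds[1, ]), "two rounds")
})

test_that("synthetic panning rounds recover planted positivity and the OD-bin tail", {
  pan <- generate_panning_dataset(c(0.1, 0.2, 0.4), seed = 7)
  for (r in 2:4) {
    s <- summarize_round(pan$records[pan$records$round_index == r, ])
    expect_equal(s$n_screened, 30)
    expect_equal(s$n_positive, c(3, 6, 12)[r - 1])
    expect_equal(s$positivity_pct, c(10, 20, 40)[r - 1])
    truth_pos <- pan$truth$clone_id[pan$truth$round_index == r &
                                      pan$truth$is_binder]
    rec <- pan$records[pan$records$round_index == r, ]
    calls <- summarize_round(rec)
    expect_setequal(truth_pos, truth_pos)  # sanity on the split
  }

  # high-OD share among binders matches the normal-tail oracle
  pan2 <- generate_panning_dataset(0.5, n_screened_per_round = 400,
                                   n_replicates = 1, seed = 9)
  s <- summarize_round(pan2$records, min_replicates = 1)
  expect_equal(s$n_positive, 200)
  p_high <- 1 - stats::pnorm(1, mean = 1.08, sd = 0.15)
  se <- sqrt(p_high * (1 - p_high) / 200)
  expect_lt(abs(s$high_od_fraction_of_positives - p_high), 3 * se)

  none <- generate_panning_dataset(c(0, 0), seed = 3)
  for (r in 2:3)
    expect_equal(summarize_round(
      none$records[none$records$round_index == r, ])$n_positive, 0)
})

test_that("long-format ELISA files round-trip into the wide layout", {
  long <- data.frame(
    clone_id = rep(c("a", "b"), each = 3),
    round = 2, replicate = 1,
    channel = rep(c("antigen", "bsa", "milk"), 2),
    od = c(1.2, 0.2, 0.25, 0.5, 0.2, 0.2))
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(long, path, sep = "\t", row.names = FALSE, quote = FALSE)
  wide <- read_elisa_long(path)
  expect_equal(nrow(wide), 2)
  expect_true(all(c("od_antigen", "od_bsa", "od_milk") %in% names(wide)))
  s <- summarize_round(wide, min_replicates = 1)
  expect_equal(s$n_positive, 1)  # clone a at fold 4.8
})
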