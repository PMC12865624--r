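# Fixed framework scaffold used by the generator. One scaffold with
# per-position substitution noise outside the anchors stands in for a
# position-specific repertoire profile; positions are 1-based on the
# 112-residue reference frame (86-residue "head" up to FR3b, then CDR3,
# then a 10-residue FR4 carrying the [YW]G.G anchor).
scaffold <- list(
  fr1 = "MARVDQTPQTITKETGESLTICVL",     # 1-24, canonical Cys at 22
  cdr1 = "DSNQALLAS",                   # 25-33, Leu at 31
  fr2 = "TYEGRVKASE",                   # 34-43
  hv2 = "STNEESIS",                     # 44-51
  fr3a = "EGRFTVSR",                    # 52-59
  hv4 = "DSAKNT",                       # 60-65
  fr3b = "VYLQMNNLTPEDSGTYYCKAQ",       # 66-86, canonical Cys at 83
  fr4 = "YGAGTVLTVN")                   # FR4 anchor motif YGAG first

scaffold_head <- function() {
  paste0(scaffold$fr1, scaffold$cdr1, scaffold$fr2, scaffold$hv2,
         scaffold$fr3a, scaffold$hv4, scaffold$fr3b)
}

# Head positions free to mutate: framework/HV residues excluding the
# initiator Met, the Ala whose codon completes the NcoI site, the two
# canonical cysteines, and the CDR1 slot (handled separately).
head_noise_positions <- c(3:21, 23, 24, 34:82, 84:86)
fr4_noise_positions <- 5:10

aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
aa_no_c <- setdiff(aa20, "C")
aa_no_cw <- setdiff(aa20, c("C", "W"))

# Default CDR3 length model: discretized normal on 6..28 centred between
# 15 and 16 with sd 1.483, so that the 15-16 band carries ~half the mass.
default_cdr3_length_model <- function() {
  support <- 6:28
  w <- stats::dnorm(support, mean = 15.5, sd = 1.483)
  stats::setNames(w / sum(w), support)
}

# Default per-type CDR3 cysteine-count models. Each distribution respects
# the classification rule of its type (e.g. type I only even counts >= 2,
# type IIb's CDR3 branch only odd counts).
default_cdr3_cys_model <- function() {
  list(I = c("2" = 0.88, "4" = 0.12),
       IIa = c("1" = 0.70, "2" = 0.20, "3" = 0.10),
       IIb = c("1" = 0.92, "3" = 0.06, "5" = 0.02),
       III = c("0" = 0.5, "1" = 0.5),
       IV = c("0" = 1))
}

# Per-type counts printed for the naive-library NGS composition.
fig3a_counts <- c(I = 36256, IIa = 57112, IIb = 98849, III = 8, IV = 46190)

#' Specification of a synthetic vNAR library
#'
#' Bundles and validates every tunable of the generator. Defaults encode
#' the naive bamboo-shark library as characterized by NGS: the five-type
#' composition, CDR3 lengths 6-28 with roughly half the clones at 15-16,
#' per-type CDR3 cysteine counts within 0-5, a conserved CDR1 Leu31 in
#' 95% of clones, and clone-defect rates compatible with >97% complete
#' inserts and >90% functional open reading frames.
#'
#' @param n_clones number of clones to generate.
#' @param type_proportions named fractions over types I/IIa/IIb/III/IV,
#'   summing to 1 (default: the NGS composition of the naive library).
#' @param cdr3_length_model named probability vector over CDR3 lengths
#'   (names are lengths; default support 6..28, see above).
#' @param cdr3_cys_model per-type named probability vectors over CDR3
#'   cysteine counts; each must respect its type's rule (type I even
#'   counts >= 2, type IIa counts >= 1, type IIb CDR3 branch odd counts,
#'   type IV all mass at 0).
#' @param iib_cdr1_share for type IIb, the probability that the single
#'   noncanonical cysteine sits in CDR1 (with a Cys-free CDR3) rather
#'   than in CDR3.
#' @param leu31_prob probability of Leu at scheme position 31.
#' @param cdr1_mut_prob per-clone probability of one CDR1 substitution
#'   (drawn from an alphabet excluding Cys and Trp).
#' @param framework_mut_rate per-position substitution rate over the
#'   mutable framework/HV positions (alphabet excluding Cys and Trp).
#' @param defect_rates named fractions for `missing_flank`,
#'   `premature_stop`, `frameshift`; defects are applied by count
#'   (half-up of `rate * n_clones`), not by Bernoulli draws.
#' @param duplicate_rate fraction of clones replaced by exact copies of
#'   other clones (by count).
#' @param seed integer seed; generation is deterministic given the spec.
#' @return validated `vnar_library_spec` list.
#' @seealso [fig3a_spec()] for the NGS-composition preset,
#'   [generate_library()].
#' @export
library_spec <- function(n_clones,
                         type_proportions = fig3a_counts / sum(fig3a_counts),
                         cdr3_length_model = default_cdr3_length_model(),
                         cdr3_cys_model = default_cdr3_cys_model(),
                         iib_cdr1_share = 0.35,
                         leu31_prob = 0.95,
                         cdr1_mut_prob = 0.06,
                         framework_mut_rate = 0.005,
                         defect_rates = c(missing_flank = 0.03,
                                          premature_stop = 0.02,
                                          frameshift = 0.01),
                         duplicate_rate = 0,
                         seed = 1) {
  stopifnot(n_clones > 0, n_clones == as.integer(n_clones))
  if (!setequal(names(type_proportions), vnar_types))
    stop("type_proportions must be named over ", paste(vnar_types, collapse = "/"))
  type_proportions <- type_proportions[vnar_types]
  if (abs(sum(type_proportions) - 1) > 1e-9)
    stop("type_proportions must sum to 1")
  lens <- as.integer(names(cdr3_length_model))
  if (anyNA(lens) || any(cdr3_length_model < 0))
    stop("cdr3_length_model must be a named non-negative vector over lengths")
  check_support <- function(type, allowed) {
    cnt <- as.integer(names(cdr3_cys_model[[type]]))
    if (!all(cnt %in% allowed))
      stop("cdr3_cys_model for type ", type,
           " has support outside its rule (allowed: ",
           paste(allowed, collapse = ","), ")")
  }
  check_support("I", c(2L, 4L))
  check_support("IIa", 1:5)
  check_support("IIb", c(1L, 3L, 5L))
  check_support("III", 0:5)
  check_support("IV", 0L)
  need <- c("missing_flank", "premature_stop", "frameshift")
  if (!all(need %in% names(defect_rates)))
    defect_rates <- stats::setNames(
      ifelse(need %in% names(defect_rates), defect_rates[need], 0), need)
  stopifnot(all(defect_rates >= 0), sum(defect_rates) <= 1,
            duplicate_rate >= 0, duplicate_rate < 1,
            leu31_prob >= 0, leu31_prob <= 1,
            iib_cdr1_share >= 0, iib_cdr1_share <= 1)
  structure(list(n_clones = as.integer(n_clones),
                 type_proportions = type_proportions,
                 cdr3_length_model = cdr3_length_model,
                 cdr3_cys_model = cdr3_cys_model,
                 iib_cdr1_share = iib_cdr1_share,
                 leu31_prob = leu31_prob,
                 cdr1_mut_prob = cdr1_mut_prob,
                 framework_mut_rate = framework_mut_rate,
                 defect_rates = defect_rates[need],
                 duplicate_rate = duplicate_rate,
                 seed = as.integer(seed)),
            class = "vnar_library_spec")
}

#' Library spec preset replicating the NGS composition at reduced scale
#'
#' Encodes the per-type counts of the sequenced naive library (36,256 I /
#' 57,112 IIa / 98,849 IIb / 8 III / 46,190 IV; 238,415 total) as exact
#' proportions, scaled to `floor(238415 * scale)` clones with
#' largest-remainder apportionment at generation time. The preset is
#' defect-free: the NGS statistics describe translated unique protein
#' sequences, which have already passed ORF quality control.
#'
#' @param scale scale factor on the sequenced-library size (default 1/10).
#' @param seed integer seed.
#' @param ... further overrides passed to [library_spec()].
#' @return a `vnar_library_spec`.
#' @export
fig3a_spec <- function(scale = 0.1, seed = 1, ...) {
  library_spec(n_clones = floor(sum(fig3a_counts) * scale),
               type_proportions = fig3a_counts / sum(fig3a_counts),
               defect_rates = c(missing_flank = 0, premature_stop = 0,
                                frameshift = 0),
               duplicate_rate = 0, seed = seed, ...)
}

sample_from <- function(model, n) {
  vals <- as.integer(names(model))
  if (length(vals) == 1) rep(vals, n)
  else sample(vals, n, replace = TRUE, prob = model)
}

# Remove every occurrence of `motif` from `x` by point substitution
# (used when deleting a cloning flank must leave no residual match
# anywhere, including on the reverse complement: both flank motifs are
# palindromic, so scrubbing the forward strand suffices).
scrub_motif <- function(x, motif, at, repl) {
  repeat {
    p <- regexpr(motif, x, fixed = TRUE)[1]
    if (p < 1) return(x)
    substr(x, p + at, p + at) <- repl
  }
}

#' Generate a labeled synthetic vNAR library
#'
#' Builds nucleotide clones on a fixed vNAR scaffold (canonical Cys at
#' scheme positions 22 and 83, FR4 anchor `YGAG`), flanked by the
#' NcoI/NotI cloning sites, with per-clone CDR3 length, CDR3/CDR1
#' cysteines and CDR1 Trp placed to realize each clone's intended type
#' under the classification precedence. Per-type counts, duplicate counts
#' and defect counts are fixed by largest-remainder apportionment (not
#' sampled), so small libraries match their spec exactly; sequence
#' content is stochastic but fully determined by `spec$seed`.
#'
#' Defects are injected after construction: `missing_flank` deletes one
#' cloning site (and scrubs accidental occurrences of the motif so the
#' defect is unambiguous), `premature_stop` rewrites one internal codon
#' to a stop, `frameshift` deletes a single nucleotide inside the coding
#' region.
#'
#' @param spec a [library_spec()].
#' @return tibble with one row per clone: `clone_id`, `sequence`
#'   (nucleotide, ready for [translate_repertoire()]), `source`,
#'   `true_label`, `true_aa` (the constructed protein before defect
#'   injection), `true_cdr3_start`, `true_cdr3_end`, `defect`.
#' @examples
#' lib <- generate_library(library_spec(n_clones = 100, seed = 7,
#'   defect_rates = c(premature_stop = 0.03)))
#' table(lib$defect)
#' @export
generate_library <- function(spec) {
  stopifnot(inherits(spec, "vnar_library_spec"))
  with_seed(spec$seed, {
    n <- spec$n_clones
    counts <- largest_remainder(spec$type_proportions, n)
    labels <- sample(rep(vnar_types, counts))

    # CDR3 lengths and cysteine counts
    L <- sample_from(spec$cdr3_length_model, n)
    k <- integer(n)
    iib_branch_cdr1 <- logical(n)
    for (t in vnar_types) {
      idx <- which(labels == t)
      if (!length(idx)) next
      if (t == "IIb") {
        iib_branch_cdr1[idx] <- stats::runif(length(idx)) < spec$iib_cdr1_share
        cdr3_branch <- idx[!iib_branch_cdr1[idx]]
        k[cdr3_branch] <- sample_from(spec$cdr3_cys_model$IIb,
                                      length(cdr3_branch))
      } else {
        k[idx] <- sample_from(spec$cdr3_cys_model[[t]], length(idx))
      }
    }

    # CDR1: modal string, Leu31 dropout, optional substitution, then
    # label-required Cys/Trp evidence
    cdr1 <- matrix(strsplit(scaffold$cdr1, "")[[1]], n, 9, byrow = TRUE)
    drop31 <- stats::runif(n) > spec$leu31_prob
    if (any(drop31))
      cdr1[drop31, 7] <- sample(setdiff(aa_no_cw, "L"), sum(drop31), TRUE)
    mut <- stats::runif(n) < spec$cdr1_mut_prob
    if (any(mut)) {
      cdr1[cbind(which(mut), sample.int(9, sum(mut), TRUE))] <-
        sample(aa_no_cw, sum(mut), TRUE)
    }
    needs_cdr1_cys <- labels == "IIa" | (labels == "IIb" & iib_branch_cdr1)
    if (any(needs_cdr1_cys)) {
      rows <- which(needs_cdr1_cys)
      cdr1[cbind(rows, sample(c(1:6, 8:9), length(rows), TRUE))] <- "C"
    }
    is3 <- labels == "III"
    if (any(is3)) {
      cdr1[is3, 5] <- "C"
      cdr1[is3, 6] <- "W"
    }
    cdr1_str <- do.call(paste0, as.data.frame(cdr1))

    # CDR3: random residues (Cys excluded, placed explicitly), rejecting
    # any string that would carry the FR4 anchor pattern, including
    # across the CDR3/FR4 junction
    draw_cdr3 <- function(lens, kk) {
      chars <- split(sample(aa_no_c, sum(lens), TRUE),
                     rep(seq_along(lens), lens))
      for (i in which(kk > 0))
        chars[[i]][sample.int(lens[i], kk[i])] <- "C"
      vapply(chars, paste0, character(1), collapse = "")
    }
    cdr3_str <- draw_cdr3(L, k)
    junction <- substr(scaffold$fr4, 1, 3)
    repeat {
      bad <- grepl("[YW]G.G", paste0(cdr3_str, junction))
      if (!any(bad)) break
      cdr3_str[bad] <- draw_cdr3(L[bad], k[bad])
    }

    # framework head and FR4 with substitution noise outside anchors
    head <- rep(scaffold_head(), n)
    apply_noise <- function(strings, positions, rate) {
      hit <- which(matrix(stats::runif(length(strings) * length(positions)) <
                            rate, length(strings)), arr.ind = TRUE)
      if (nrow(hit)) {
        repl <- sample(aa_no_cw, nrow(hit), TRUE)
        for (h in seq_len(nrow(hit))) {
          p <- positions[hit[h, 2]]
          substr(strings[hit[h, 1]], p, p) <- repl[h]
        }
      }
      strings
    }
    head <- apply_noise(head, head_noise_positions, spec$framework_mut_rate)
    substr(head, 25, 33) <- cdr1_str
    fr4 <- apply_noise(rep(scaffold$fr4, n), fr4_noise_positions,
                       spec$framework_mut_rate)
    aa <- paste0(head, cdr3_str, fr4)

    # reverse-translate with uniformly sampled synonymous codons; the
    # initiator Met (ATG) completes the NcoI site CCATGG together with
    # the fixed Ala at position 2 (codons GCN)
    cod_by_aa <- split(names(Biostrings::GENETIC_CODE),
                       unname(Biostrings::GENETIC_CODE))
    cod_by_aa[["*"]] <- NULL
    width <- max(lengths(cod_by_aa))
    codmat <- t(vapply(cod_by_aa,
                       function(x) c(x, rep(NA_character_, width - length(x))),
                       character(width)))
    flat <- unlist(strsplit(aa, "", fixed = TRUE), use.names = FALSE)
    row <- match(flat, rownames(codmat))
    pick <- floor(stats::runif(length(flat)) *
                    lengths(cod_by_aa)[flat]) + 1L
    codons <- codmat[cbind(row, pick)]
    body <- vapply(split(codons, rep(seq_len(n), nchar(aa))),
                   paste0, character(1), collapse = "")
    nt <- paste0("CC", body, "GCGGCCGC")

    truth <- tibble::tibble(
      clone_id = sprintf("synth_%06d", seq_len(n)),
      sequence = nt,
      source = "synthetic",
      true_label = labels,
      true_aa = aa,
      true_cdr3_start = 87L,
      true_cdr3_end = 86L + L,
      defect = "none")

    # exact duplicates by count
    n_dup <- round_half_up(n * spec$duplicate_rate)
    if (n_dup > 0) {
      tgt <- sample(n, n_dup)
      src <- sample(setdiff(seq_len(n), tgt), n_dup, replace = TRUE)
      copy_cols <- c("sequence", "true_label", "true_aa",
                     "true_cdr3_start", "true_cdr3_end")
      truth[tgt, copy_cols] <- truth[src, copy_cols]
    }

    # defects by count, on disjoint clones
    n_def <- round_half_up(n * spec$defect_rates)
    pool <- sample(n)
    offset <- 0
    for (d in names(n_def)) {
      idx <- pool[seq_len(n_def[d]) + offset]
      offset <- offset + n_def[d]
      if (!length(idx)) next
      truth$defect[idx] <- d
      for (i in idx) {
        s <- truth$sequence[i]
        if (d == "missing_flank") {
          if (stats::runif(1) < 0.5) {
            s <- substring(s, 7)                       # drop CCATGG
            s <- scrub_motif(s, "CCATGG", at = 2, repl = "T")
          } else {
            s <- substring(s, 1, nchar(s) - 8)         # drop GCGGCCGC
            s <- scrub_motif(s, "GCGGCCGC", at = 3, repl = "T")
          }
        } else if (d == "premature_stop") {
          r <- sample(40:70, 1)                        # codon index
          substr(s, 3 * r, 3 * r + 2) <- sample(c("TAA", "TAG", "TGA"), 1)
        } else if (d == "frameshift") {
          p <- sample(10:100, 1)                       # inside coding
          s <- paste0(substring(s, 1, p - 1), substring(s, p + 1))
        }
        truth$sequence[i] <- s
      }
    }
    truth
  })
}

#' Write a synthetic library's ground truth as TSV
#'
#' @param library tibble from [generate_library()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(library, path) {
  utils::write.table(
    library[, c("clone_id", "true_label", "true_cdr3_start",
                "true_cdr3_end", "defect")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a synthetic biopanning ELISA dataset with ground truth
#'
#' Emulates per-round phage-ELISA screens of randomly picked clones
#' during biopanning. Each round screens `n_screened_per_round` clones in
#' `n_replicates` replicate wells against the antigen and two negative
#' controls (BSA, milk). The number of true binders per round is the
#' half-up count of `fraction * n_screened`, so the printed screen ratios
#' are reproduced exactly. Negative-control ODs are uniform on
#' `[neg_min, neg_max]`; binder antigen ODs are normal
#' (`pos_mean`, `pos_sd`) truncated from below at four times the largest
#' negative of the well, and non-binder antigen ODs are uniform below
#' that threshold — so the planted truth and the four-fold rule agree by
#' construction.
#'
#' @param binder_fraction_by_round fractions in `[0, 1]`, one per round.
#' @param n_screened_per_round clones picked per round (default 30).
#' @param n_replicates replicate wells per clone (default 3).
#' @param od_model list with `pos_mean`, `pos_sd`, `neg_min`, `neg_max`.
#'   The default binder model N(1.08, 0.15) puts ~70% of binders above
#'   1.0 OD, the high-OD share seen in a late panning round.
#' @param first_round round index of the first screened round (screening
#'   conventionally starts after the second round of panning).
#' @param seed integer seed.
#' @return list with `records` (wide ELISA tibble: `clone_id`,
#'   `round_index`, `replicate`, `od_antigen`, `od_bsa`, `od_milk`) and
#'   `truth` (`clone_id`, `round_index`, `is_binder`).
#' @export
generate_panning_dataset <- function(binder_fraction_by_round,
                                     n_screened_per_round = 30,
                                     n_replicates = 3,
                                     od_model = list(pos_mean = 1.08,
                                                     pos_sd = 0.15,
                                                     neg_min = 0.04,
                                                     neg_max = 0.12),
                                     first_round = 2,
                                     seed = 1) {
  stopifnot(all(binder_fraction_by_round >= 0),
            all(binder_fraction_by_round <= 1),
            n_screened_per_round > 0, n_replicates >= 1)
  with_seed(seed, {
    rec_list <- list()
    truth_list <- list()
    for (r in seq_along(binder_fraction_by_round)) {
      round_index <- first_round + r - 1
      n <- n_screened_per_round
      n_pos <- round_half_up(binder_fraction_by_round[r] * n)
      is_binder <- c(rep(TRUE, n_pos), rep(FALSE, n - n_pos))[sample(n)]
      ids <- sprintf("bp%d_clone_%03d", round_index, seq_len(n))
      nw <- n * n_replicates
      od_bsa <- stats::runif(nw, od_model$neg_min, od_model$neg_max)
      od_milk <- stats::runif(nw, od_model$neg_min, od_model$neg_max)
      thresh <- 4 * pmax(od_bsa, od_milk)
      binder_w <- rep(is_binder, each = n_replicates)
      od_ag <- numeric(nw)
      od_ag[binder_w] <- pmax(
        stats::rnorm(sum(binder_w), od_model$pos_mean, od_model$pos_sd),
        thresh[binder_w])
      od_ag[!binder_w] <- thresh[!binder_w] *
        stats::runif(sum(!binder_w), 0.05, 0.9)
      rec_list[[r]] <- tibble::tibble(
        clone_id = rep(ids, each = n_replicates),
        round_index = round_index,
        replicate = rep(seq_len(n_replicates), times = n),
        od_antigen = od_ag,
        od_bsa = od_bsa,
        od_milk = od_milk)
      truth_list[[r]] <- tibble::tibble(
        clone_id = ids, round_index = round_index, is_binder = is_binder)
    }
    list(records = do.call(rbind, rec_list),
         truth = do.call(rbind, truth_list))
  })
}
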