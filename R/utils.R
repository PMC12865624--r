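#' Round half away from zero at a fixed number of decimals
#'
#' Commercial ("round half up") rounding, as opposed to the IEEE
#' round-half-to-even used by [base::round()]. Used for every printed
#' percentage in repertoire and screening summaries so that recomputing a
#' percentage from its counts reproduces the stored value exactly.
#'
#' @param x numeric vector (non-negative in all package uses).
#' @param digits integer, number of decimal places to keep.
#' @return numeric vector rounded half-up at `digits` decimals.
#' @examples
#' round_half_up(41.46, 1) # 41.5
#' round_half_up(72.727)   # 73
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Percentage of a count over a total, rounded half-up
#'
#' @param count numeric count(s).
#' @param total positive denominator.
#' @param digits decimals to keep (0 for integer percentages, 1 for the
#'   one-decimal type percentages).
#' @return `round_half_up(100 * count / total, digits)`.
#' @examples
#' percentage(98849, 238415, digits = 1) # 41.5
#' percentage(91600, 238415)             # 38
#' @export
percentage <- function(count, total, digits = 0) {
  stopifnot(is.numeric(total), length(total) == 1, total > 0)
  round_half_up(100 * count / total, digits)
}

#' Largest-remainder apportionment of integer counts
#'
#' Distributes `n` units over categories proportionally to `weights`,
#' assigning each category the floor of its quota and handing the remaining
#' units to the categories with the largest fractional remainders (ties
#' broken by input order). Guarantees the counts sum to `n` exactly, which
#' keeps small synthetic libraries faithful to their target composition.
#'
#' @param weights non-negative numeric vector (need not sum to 1).
#' @param n total number of units to apportion.
#' @return integer vector of the same length (and names) as `weights`
#'   summing to `n`.
#' @examples
#' largest_remainder(c(I = 0.2, II = 0.5, IV = 0.3), 7)
#' @export
largest_remainder <- function(weights, n) {
  stopifnot(is.numeric(weights), all(weights >= 0), sum(weights) > 0,
            length(n) == 1, n >= 0, n == as.integer(n))
  quota <- n * weights / sum(weights)
  base <- floor(quota)
  left <- as.integer(n - sum(base))
  if (left > 0) {
    top <- order(quota - base, decreasing = TRUE)[seq_len(left)]
    base[top] <- base[top] + 1
  }
  counts <- as.integer(base)
  names(counts) <- names(weights)
  counts
}

# Evaluate `expr` under a fixed RNG seed without clobbering the caller's
# RNG stream (the global .Random.seed is restored on exit).
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Collapse a character vector of flags to a single ";"-joined string.
join_flags <- function(flags) {
  if (length(flags) == 0) "" else paste(flags, collapse = ";")
}

has_flag <- function(qc_flags, flag) {
  vapply(strsplit(qc_flags, ";", fixed = TRUE),
         function(f) flag %in% f, logical(1))
}
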