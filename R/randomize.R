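#' Allocate patients to centres
#'
#' Splits a total sample size over a fixed number of centres. The `"even"`
#' scheme gives every centre `floor(n_total / n_centres)` patients, with the
#' remainder spread one-per-centre over the lowest-indexed centres, so sizes
#' never differ by more than 1. The `"skewed"` scheme concentrates recruitment:
#' 10% of centres (rounded up, minimum 1) share half the patients equally and
#' the remaining centres share the other half, again with remainders going to
#' the lowest-indexed centres in each group. The skewed profile is a synthetic
#' stand-in for the kind of recruitment imbalance seen in real multicentre
#' trials, where a handful of large centres dominate.
#'
#' @param n_total Total number of patients (positive integer, `>= n_centres`).
#' @param n_centres Number of centres (positive integer).
#' @param scheme `"even"` or `"skewed"`.
#' @return Integer vector of centre sizes summing to `n_total`, one entry per
#'   centre, all entries `>= 1`.
#' @examples
#' allocate_centres(200, 5, "even")    # 40 patients per centre
#' allocate_centres(10, 3, "even")     # c(4, 3, 3)
#' allocate_centres(200, 100, "skewed")
#' @export
allocate_centres <- function(n_total, n_centres, scheme = c("even", "skewed")) {
  scheme <- match.arg(scheme)
  check_count(n_total, "n_total")
  check_count(n_centres, "n_centres")
  if (n_total < n_centres) {
    stop_config("n_total (", n_total, ") must be at least n_centres (",
                n_centres, ")")
  }
  if (scheme == "even") {
    base <- n_total %/% n_centres
    rem <- n_total - base * n_centres
    sizes <- rep.int(base, n_centres) + (seq_len(n_centres) <= rem)
  } else {
    n_big <- max(1L, ceiling(0.10 * n_centres))
    n_small <- n_centres - n_big
    if (n_small == 0L) {
      return(allocate_centres(n_total, n_centres, "even"))
    }
    big_total <- n_total %/% 2L
    # every small centre must keep at least one patient
    big_total <- min(big_total, n_total - n_small)
    small_total <- n_total - big_total
    big <- rep.int(big_total %/% n_big, n_big) +
      (seq_len(n_big) <= big_total %% n_big)
    small <- rep.int(small_total %/% n_small, n_small) +
      (seq_len(n_small) <= small_total %% n_small)
    sizes <- c(big, small)
  }
  as.integer(sizes)
}

#' Simple randomisation
#'
#' Assigns each patient independently to the treatment arm with probability
#' 0.5 (coin-flip randomisation, no balancing).
#'
#' @param n Number of patients.
#' @return Integer vector of 0 (control) / 1 (treatment) of length `n`.
#' @examples
#' set.seed(1)
#' simple_randomization(10)
#' @export
simple_randomization <- function(n) {
  check_count(n, "n")
  as.integer(stats::runif(n) < 0.5)
}

#' Stratified permuted-block randomisation
#'
#' Within each centre, patients are assigned in consecutive permuted blocks
#' containing exactly `block_size / 2` patients per arm in random order. When
#' a centre's size is not a multiple of the block size, the final block is a
#' random permutation of a full balanced block truncated to the remaining
#' patients, so the arm imbalance within any centre never exceeds
#' `block_size / 2`.
#'
#' @param sizes Integer vector of centre sizes (a centre allocation, see
#'   [allocate_centres()]).
#' @param block_size Positive even integer block length.
#' @return Integer 0/1 arm assignment of length `sum(sizes)`, ordered by
#'   centre (all patients of centre 1 first, and so on).
#' @examples
#' set.seed(1)
#' arm <- stratified_permuted_blocks(c(4, 6), block_size = 4)
#' sum(arm[1:4])  # exactly 2 treated in the size-4 centre
#' @export
stratified_permuted_blocks <- function(sizes, block_size) {
  check_sizes(sizes)
  check_count(block_size, "block_size")
  if (block_size %% 2L != 0L) {
    stop_config("block_size must be even, got ", block_size)
  }
  sizes <- as.integer(sizes)
  n_blocks_per_centre <- ceiling(sizes / block_size)
  n_blocks <- sum(n_blocks_per_centre)
  n_slots <- n_blocks * block_size
  # permute each balanced block by ranking iid uniform keys within block
  block_id <- rep(seq_len(n_blocks), each = block_size)
  ord <- order(block_id, stats::runif(n_slots))
  arm_slots <- integer(n_slots)
  arm_slots[ord] <- rep.int(rep(c(0L, 1L), each = block_size %/% 2L), n_blocks)
  # each centre consumes the first sizes[j] slots of its own blocks
  slot_start <- cumsum(c(0L, n_blocks_per_centre * block_size))
  idx <- sequence(sizes) + rep(slot_start[seq_along(sizes)], sizes)
  arm_slots[idx]
}

check_count <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 1 || x != floor(x)) {
    stop_config(name, " must be a single positive integer")
  }
  invisible(TRUE)
}

check_sizes <- function(sizes) {
  if (length(sizes) < 1L || anyNA(sizes) || any(sizes < 1) ||
      any(sizes != floor(sizes))) {
    stop_config("centre sizes must be positive integers")
  }
  invisible(TRUE)
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("centresim_config_error", "error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("centresim_data_error", "error")))
}
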