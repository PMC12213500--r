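#' Optimal histogram bin width by cost minimisation
#'
#' Selects the bin width for a continuous sample by minimising the
#' Shimazaki-Shinomoto cost. For each candidate bin count `N` the range
#' `[min(x), max(x)]` is split into `N` equal bins of width `delta`; with
#' per-bin counts `k_i`, mean `kbar` and biased variance
#' `v = mean((k_i - kbar)^2)`, the cost is
#' `C(delta) = (2*kbar - v) / delta^2`. The width minimising `C` is returned;
#' ties go to the smaller bin count.
#'
#' @param values Numeric vector with at least two distinct values.
#' @param candidate_range Integer pair `c(N_min, N_max)` of bin counts to
#'   search (default `c(2, min(200, length(values)))`).
#' @return A list with `bin_width`, `n_bins`, and `costs`, a tibble of the
#'   full candidate scan (`n_bins`, `bin_width`, `cost`).
#' @examples
#' set.seed(1)
#' optimal_bin_width(rlnorm(500, log(300), 0.4))$n_bins
#' @export
optimal_bin_width <- function(values, candidate_range = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 2) {
    stop("need at least two values to choose a bin width", call. = FALSE)
  }
  rng <- range(values)
  if (diff(rng) == 0) {
    stop("all values are identical; bin width is undefined", call. = FALSE)
  }
  if (is.null(candidate_range)) {
    candidate_range <- c(2L, min(200L, length(values)))
  }
  candidate_range <- as.integer(round(candidate_range))
  if (length(candidate_range) != 2 || candidate_range[1] < 2 ||
      candidate_range[1] > candidate_range[2]) {
    stop("candidate_range must be c(N_min, N_max) with 2 <= N_min <= N_max",
         call. = FALSE)
  }
  ns <- seq.int(candidate_range[1], candidate_range[2])
  costs <- vapply(ns, function(n) ss_cost(values, n, rng), numeric(1))
  widths <- diff(rng) / ns
  best <- which.min(costs)            # which.min takes the first (smallest N) tie
  list(
    bin_width = widths[best],
    n_bins = ns[best],
    costs = tibble::tibble(n_bins = ns, bin_width = widths, cost = costs)
  )
}

ss_cost <- function(values, n_bins, rng = range(values)) {
  k <- bin_counts(values, n_bins, rng)
  delta <- diff(rng) / n_bins
  kbar <- mean(k)
  v <- mean((k - kbar)^2)             # biased variance, 1/N
  (2 * kbar - v) / delta^2
}

# Half-open bins [lo, hi), last bin closed so max(values) is always counted.
bin_counts <- function(values, n_bins, rng = range(values)) {
  delta <- diff(rng) / n_bins
  idx <- floor((values - rng[1]) / delta) + 1
  idx[idx > n_bins] <- n_bins
  tabulate(idx, nbins = n_bins)
}

#' Histogram frequency table for a continuous descriptor
#'
#' Bins a continuous sample with the optimal width from
#' [optimal_bin_width()] (or a forced bin count) and returns the frequency
#' table used as curve-fitting input. The x coordinate of each bin is its
#' centre.
#'
#' @inheritParams optimal_bin_width
#' @return A `qea_freq` tibble with columns `x` (bin centres) and `count`,
#'   and attributes `kind = "continuous"`, `bin_width`, `n_total`.
#' @export
bin_frequencies <- function(values, candidate_range = NULL) {
  sel <- optimal_bin_width(values, candidate_range)
  values <- values[is.finite(values)]
  rng <- range(values)
  counts <- bin_counts(values, sel$n_bins, rng)
  centers <- rng[1] + (seq_len(sel$n_bins) - 0.5) * sel$bin_width
  new_freq_table(centers, counts, kind = "continuous",
                 bin_width = sel$bin_width)
}

#' Exact frequency table for a count descriptor
#'
#' Tallies non-negative integers over the full range `0:max(values)`, so
#' unobserved intermediate values appear with count zero.
#'
#' @param values Non-negative integer vector (length >= 1).
#' @return A `qea_freq` tibble with columns `x` (integers) and `count`, and
#'   attributes `kind = "discrete"`, `n_total`.
#' @examples
#' integer_frequencies(c(0, 0, 1, 3))
#' @export
integer_frequencies <- function(values) {
  if (length(values) == 0) stop("need at least one value", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0) ||
      any(values != round(values))) {
    stop("values must be non-negative integers", call. = FALSE)
  }
  xs <- 0:max(values)
  counts <- tabulate(values + 1, nbins = length(xs))
  new_freq_table(xs, counts, kind = "discrete")
}

new_freq_table <- function(x, count, kind, bin_width = NULL) {
  out <- tibble::new_tibble(
    list(x = as.numeric(x), count = as.numeric(count)),
    nrow = length(x), class = "qea_freq"
  )
  attr(out, "kind") <- kind
  attr(out, "bin_width") <- bin_width
  attr(out, "n_total") <- sum(count)
  out
}

#' @export
print.qea_freq <- function(x, ...) {
  cat(sprintf("<qea_freq> %s, %d bins, n = %d\n", attr(x, "kind"),
              nrow(x), as.integer(attr(x, "n_total"))))
  NextMethod()
}

#' Write a frequency table to CSV
#'
#' @param freq A `qea_freq` table.
#' @param path Output path; columns `value,count`.
#' @return `path`, invisibly.
#' @export
write_frequencies <- function(freq, path) {
  readr::write_csv(tibble::tibble(value = freq$x, count = freq$count), path,
                   progress = FALSE)
  invisible(path)
}
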