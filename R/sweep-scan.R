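#' Sliding windows over chromosomes
#'
#' Builds the window grid for the diversity scan: windows of `window_size` bp
#' advancing by `step` bp, anchored at position 1 on each chromosome, with no
#' trailing partial window. A chromosome shorter than `window_size` yields a
#' single window spanning the whole chromosome. For length L >= W the window
#' count is `floor((L - W) / S) + 1`.
#'
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param window_size Window size in bp, default 50000.
#' @param step Step size in bp, default 5000.
#' @return Tibble with columns `chrom`, `start`, `end` (1-based inclusive).
#' @export
make_windows <- function(chrom_lengths, window_size = 50000, step = 5000) {
  stopifnot(step > 0, step <= window_size, all(chrom_lengths >= 1))
  purrr::map_dfr(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    if (L < window_size) {
      return(tibble(chrom = ch, start = 1L, end = as.integer(L)))
    }
    n <- floor((L - window_size) / step) + 1
    starts <- 1L + step * (seq_len(n) - 1L)
    tibble(chrom = ch, start = as.integer(starts),
           end = as.integer(starts + window_size - 1L))
  })
}

#' Windowed nucleotide diversity for one sample pool
#'
#' Computes per-bp nucleotide diversity (theta-pi) in a window:
#' `pi = sum(h_site) / window_length`, where for a site with non-missing
#' allele counts n_1..n_k over n called alleles,
#' `h_site = (n^2 - sum(n_i^2)) / (n * (n - 1))` — the sample-size-corrected
#' expected pairwise difference among called alleles. Monomorphic positions
#' (inside or outside the variant set) contribute zero, so pi is a per-bp
#' rate over the full window length.
#'
#' @param gm A [genotype_matrix()].
#' @param samples Character vector of sample ids forming the pool (>= 2).
#' @param chrom,start,end Window coordinates, 1-based inclusive.
#' @return A single numeric pi value.
#' @export
window_pi <- function(gm, samples, chrom, start, end) {
  if (length(samples) == 0) abort("undefined pool: no samples")
  if (length(samples) < 2) abort("pool must contain at least 2 samples")
  sub <- subset_samples(gm, samples)
  in_win <- sub$sites$chrom == chrom & sub$sites$pos >= start & sub$sites$pos <= end
  if (!any(in_win)) return(0)
  h <- site_heterozygosity(sub$allele1[in_win, , drop = FALSE],
                           sub$allele2[in_win, , drop = FALSE])
  sum(h) / (end - start + 1)
}

#' Windowed theta-pi ratio scan (wild / cultivated)
#'
#' Runs the windowed diversity scan over both pools of a panel and forms the
#' wild-to-cultivated theta-pi ratio per window, the statistic used to locate
#' candidate domestication sweeps. Windows where cultivated diversity is zero
#' get `status = "undefined_denominator"` and no numeric ratio; they are
#' excluded from downstream quantile computation rather than assigned
#' infinity.
#'
#' @param gm A [genotype_matrix()] (typically after [apply_variant_filters()]).
#' @param panel Panel tibble with pools `"wild"` and `"cultivated"`.
#' @param window_size,step Window grid parameters, defaults 50 kb / 5 kb.
#' @param windows Optional precomputed window tibble (overrides the grid).
#' @return A tibble of class `sweep_scan` with columns `chrom`, `start`,
#'   `end`, `n_sites`, `pi_wild`, `pi_cult`, `ratio`, `status`.
#' @export
pi_ratio_scan <- function(gm, panel, window_size = 50000, step = 5000,
                          windows = NULL) {
  wild <- pool_samples(panel, "wild", gm)
  cult <- pool_samples(panel, "cultivated", gm)
  if (is.null(windows)) {
    windows <- make_windows(gm$chrom_lengths, window_size, step)
  }

  # per-site heterozygosity once per pool, then window sums by cumulative sums
  pool_h <- function(samples) {
    sub <- subset_samples(gm, samples)
    site_heterozygosity(sub$allele1, sub$allele2)
  }
  h_wild <- pool_h(wild)
  h_cult <- pool_h(cult)

  res <- purrr::map_dfr(split(windows, windows$chrom), function(w) {
    ch <- w$chrom[1]
    on_ch <- which(gm$sites$chrom == ch)
    pos <- gm$sites$pos[on_ch]
    csw <- c(0, cumsum(h_wild[on_ch]))
    csc <- c(0, cumsum(h_cult[on_ch]))
    lo <- findInterval(w$start - 1L, pos)
    hi <- findInterval(w$end, pos)
    len <- w$end - w$start + 1
    tibble(
      chrom = ch, start = w$start, end = w$end,
      n_sites = hi - lo,
      pi_wild = (csw[hi + 1] - csw[lo + 1]) / len,
      pi_cult = (csc[hi + 1] - csc[lo + 1]) / len
    )
  })
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  res$status <- ifelse(res$pi_cult == 0, "undefined_denominator", "ok")
  res$ratio <- ifelse(res$status == "ok", res$pi_wild / res$pi_cult, NA_real_)
  res <- res[, c("chrom", "start", "end", "n_sites", "pi_wild", "pi_cult",
                 "ratio", "status")]
  class(res) <- c("sweep_scan", class(res))
  res
}

# empirical quantile by the nearest-rank method: the ceiling(p * n)-th
# smallest value.
nearest_rank_quantile <- function(x, p) {
  x <- sort(x)
  x[max(1L, ceiling(p * length(x)))]
}

#' Call selective-sweep intervals from a ratio scan
#'
#' The sweep threshold is the empirical `(1 - top_fraction)` quantile of the
#' ok-status ratios by the nearest-rank method; windows with ratio strictly
#' above the threshold are called, and overlapping or abutting called windows
#' on a chromosome are merged into maximal intervals.
#'
#' @param scan A `sweep_scan` tibble from [pi_ratio_scan()], or any tibble
#'   with columns `chrom`, `start`, `end`, `ratio`, `status`.
#' @param top_fraction Upper tail fraction defining sweeps, default 0.05.
#' @return An object of class `sweep_calls`: a list with `threshold`,
#'   `windows` (the scan with a logical `called` column) and `intervals`
#'   (tibble `chrom`, `start`, `end`, `peak_ratio`, `n_windows_merged`).
#' @export
call_sweeps <- function(scan, top_fraction = 0.05) {
  stopifnot(top_fraction > 0, top_fraction < 1)
  ok <- scan$status == "ok"
  if (!any(ok)) abort("no windows with a defined theta-pi ratio")
  threshold <- nearest_rank_quantile(scan$ratio[ok], 1 - top_fraction)
  called <- ok & scan$ratio > threshold
  windows <- dplyr::mutate(as_tibble(scan), called = called)

  called_w <- windows[windows$called, , drop = FALSE]
  intervals <- if (nrow(called_w) == 0) {
    tibble(chrom = character(), start = integer(), end = integer(),
           peak_ratio = numeric(), n_windows_merged = integer())
  } else {
    called_w |>
      dplyr::arrange(.data$chrom, .data$start) |>
      dplyr::group_by(.data$chrom) |>
      dplyr::mutate(
        gap = .data$start > dplyr::lag(cummax(as.numeric(.data$end)), default = -Inf) + 1,
        run = cumsum(.data$gap)
      ) |>
      dplyr::group_by(.data$chrom, .data$run) |>
      dplyr::summarise(
        start = min(.data$start), end = max(.data$end),
        peak_ratio = max(.data$ratio),
        n_windows_merged = dplyr::n(), .groups = "drop"
      ) |>
      dplyr::select("chrom", "start", "end", "peak_ratio", "n_windows_merged")
  }
  structure(list(threshold = threshold, windows = windows,
                 intervals = intervals, top_fraction = top_fraction),
            class = "sweep_calls")
}

#' @exportS3Method base::print
print.sweep_calls <- function(x, ...) {
  cat(sprintf(
    "<sweep_calls> threshold %.4g (top %.0f%%): %d/%d windows called, %d interval(s)\n",
    x$threshold, 100 * x$top_fraction, sum(x$windows$called),
    nrow(x$windows), nrow(x$intervals)
  ))
  invisible(x)
}

#' @export
tidy.sweep_calls <- function(x, ...) x$windows

#' @export
glance.sweep_calls <- function(x, ...) {
  tibble(threshold = x$threshold, top_fraction = x$top_fraction,
         n_windows = nrow(x$windows), n_called = sum(x$windows$called),
         n_intervals = nrow(x$intervals))
}

#' Genes overlapping sweep intervals
#'
#' A gene is reported iff the total bp of overlap between the gene and the
#' union of sweep intervals is at least `min_overlap` times the gene length
#' (boundary inclusive, mirroring a minimum overlap fraction of the gene
#' record).
#'
#' @param intervals Interval tibble (`chrom`, `start`, `end`, optionally
#'   `peak_ratio`) — typically `sweep_calls$intervals`.
#' @param genes Gene tibble from [read_gff()].
#' @param min_overlap Minimum overlap as fraction of gene length, default 0.10.
#' @return Tibble `gene_id`, `chrom`, `start`, `end`, `overlap_bp`,
#'   `overlap_fraction`, `peak_ratio` (max over overlapped intervals).
#' @export
genes_in_sweeps <- function(intervals, genes, min_overlap = 0.10) {
  if (inherits(intervals, "sweep_calls")) intervals <- intervals$intervals
  empty <- tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer(),
                  overlap_bp = integer(), overlap_fraction = numeric(),
                  peak_ratio = numeric())
  hits <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    iv <- intervals[intervals$chrom == g$chrom, , drop = FALSE]
    if (nrow(iv) == 0) return(NULL)
    ov <- pmax(0, pmin(iv$end, g$end) - pmax(iv$start, g$start) + 1)
    # merged intervals are disjoint, so the union overlap is the plain sum
    overlap_bp <- sum(ov)
    frac <- overlap_bp / (g$end - g$start + 1)
    if (frac < min_overlap) return(NULL)
    tibble(
      gene_id = g$gene_id, chrom = g$chrom, start = g$start, end = g$end,
      overlap_bp = overlap_bp, overlap_fraction = frac,
      peak_ratio = if ("peak_ratio" %in% names(iv) && any(ov > 0))
        max(iv$peak_ratio[ov > 0]) else NA_real_
    )
  })
  if (nrow(hits) == 0) empty else hits
}
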