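#' Detect spikes in a membrane-potential trace
#'
#' Spikes are local maxima of `x` with height at least `height_min` and
#' topographic prominence at least `prominence_min`, separated by at
#' least `min_separation` time units (the higher of two conflicting
#' peaks wins).  Thresholds are not part of the model and are exposed as
#' configuration.  The default height threshold is *adaptive*: half the
#' trace maximum.  Full action potentials of this model reach x of
#' about 2-3 while the ripples imprinted by the fast drive stay around
#' 0.3-1.1, so half-maximum separates the two robustly; on subthreshold
#' traces (maximum below 0) it excludes everything, which is the wanted
#' quiescent reading.
#'
#' @param traj An `hr_trajectory` (transient already discarded).
#' @param height_min Minimum peak height; `NULL` (default) uses half the
#'   trace maximum.
#' @param prominence_min Minimum topographic prominence (default 0.5).
#' @param min_separation Minimum spacing between spikes (default 0.5).
#' @return Object of class `hr_spike_train`: `times`, `peaks` (x at each
#'   spike), `isi` (successive differences).  May be empty.
#' @export
detect_spikes <- function(traj, height_min = NULL, prominence_min = 0.5,
                          min_separation = 0.5) {
  stopifnot(inherits(traj, "hr_trajectory"))
  x <- traj$states[, 1]
  t <- traj$t
  n <- length(x)
  empty <- structure(list(times = numeric(0), peaks = numeric(0),
                          isi = numeric(0)), class = "hr_spike_train")
  if (n < 3L) return(empty)
  if (is.null(height_min)) height_min <- max(x) / 2
  is_peak <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(is_peak) == 0L) return(empty)
  prom <- peak_prominence(x, is_peak)
  keep <- x[is_peak] >= height_min & prom >= prominence_min
  idx <- is_peak[keep]
  if (length(idx) == 0L) return(empty)
  idx <- enforce_separation(idx, x, t, min_separation)
  structure(list(times = t[idx], peaks = x[idx], isi = diff(t[idx])),
            class = "hr_spike_train")
}

# Topographic prominence of the peaks at indices `idx` of series x:
# for each peak, scan each side over strictly lower terrain (equal
# height counts as higher terrain, so plateaus are not prominent),
# track the side minimum; prominence = height - max(side bases).
peak_prominence <- function(x, idx) {
  n <- length(x)
  vapply(idx, function(i) {
    h <- x[i]
    left_base <- h
    j <- i - 1L
    while (j >= 1L && x[j] < h) {
      if (x[j] < left_base) left_base <- x[j]
      j <- j - 1L
    }
    right_base <- h
    j <- i + 1L
    while (j <= n && x[j] < h) {
      if (x[j] < right_base) right_base <- x[j]
      j <- j + 1L
    }
    h - max(left_base, right_base)
  }, numeric(1))
}

enforce_separation <- function(idx, x, t, min_separation) {
  repeat {
    if (length(idx) < 2L) return(idx)
    gaps <- diff(t[idx])
    bad <- which(gaps < min_separation)
    if (length(bad) == 0L) return(idx)
    i <- bad[1]
    drop <- if (x[idx[i]] >= x[idx[i + 1]]) i + 1L else i
    idx <- idx[-drop]
  }
}

#' @export
print.hr_spike_train <- function(x, ...) {
  cat("<hr_spike_train> ", length(x$times), "spikes")
  if (length(x$isi) > 0)
    cat(";  ISI median =", format(stats::median(x$isi), digits = 4),
        " CV =", format(stats::sd(x$isi) / mean(x$isi), digits = 3))
  cat("\n")
  invisible(x)
}

#' Segment a spike train into bursts
#'
#' Two complementary burst signatures are recognized.  (1) A *bimodal*
#' ISI distribution: a multiplicative gap of at least `gap_ratio`
#' between the short (intra-burst) and long (inter-burst) ISI modes; an
#' ISI exceeding `gap_ratio` times the median of the short mode then
#' opens a new burst.  (2) A *ladder* of drive-locked ISIs (integer
#' multiples of the fast drive period, which defeats any multiplicative
#' gap test): when the base ISI is at burst scale — at most
#' `burst_isi_max` time units, i.e. comparable to the spike width, so
#' consecutive-cycle firing — and the ISI range spans at least three
#' base intervals, an ISI beyond `gap_ratio` base intervals opens a new
#' burst.  Either way the train is only *called* bursting when at
#' least half of its spikes sit in multi-spike runs; otherwise it is a
#' single tonic segment (irregular gaps between single spikes are
#' tonic firing).
#'
#' @param train An `hr_spike_train` with at least 4 spikes.
#' @param gap_ratio Bimodality/segmentation ratio (default 3).
#' @param burst_isi_max Largest base ISI still treated as intra-burst
#'   scale (default 3 time units).
#' @return Object of class `hr_bursts`: `is_bursting`, `bursts` (list of
#'   spike-index vectors), `spikes_per_burst`, `threshold` (ISI cut),
#'   `frac_multi` (fraction of spikes in multi-spike runs), and
#'   `indeterminate` (TRUE when there are too few spikes).
#' @export
segment_bursts <- function(train, gap_ratio = 3, burst_isi_max = 3) {
  n <- length(train$times)
  tonic <- function(indet = FALSE)
    structure(list(is_bursting = FALSE,
                   bursts = if (indet) list() else list(seq_len(n)),
                   spikes_per_burst = if (indet) integer(0) else n,
                   threshold = NA_real_, frac_multi = NA_real_,
                   indeterminate = indet),
              class = "hr_bursts")
  if (n < 4L) return(tonic(indet = TRUE))
  isi <- sort(train$isi)
  ratios <- isi[-1] / isi[-length(isi)]
  split_at <- which.max(ratios)
  threshold <- if (ratios[split_at] >= gap_ratio) {
    gap_ratio * stats::median(isi[seq_len(split_at)])
  } else {
    base <- stats::median(isi[isi <= 1.5 * isi[1]])
    if (base <= burst_isi_max && isi[length(isi)] >= 3 * base)
      gap_ratio * base
    else return(tonic())
  }
  starts <- c(1L, which(train$isi > threshold) + 1L)
  ends <- c(which(train$isi > threshold), n)
  sizes <- ends - starts + 1L
  frac_multi <- sum(sizes[sizes >= 2L]) / n
  if (frac_multi < 0.5) return(tonic())
  structure(list(is_bursting = TRUE, bursts = Map(seq, starts, ends),
                 spikes_per_burst = sizes, threshold = threshold,
                 frac_multi = frac_multi, indeterminate = FALSE),
            class = "hr_bursts")
}

#' @export
print.hr_bursts <- function(x, ...) {
  if (x$indeterminate) cat("<hr_bursts>  indeterminate (too few spikes)\n")
  else if (!x$is_bursting) cat("<hr_bursts>  tonic,",
                               x$spikes_per_burst[1], "spikes\n")
  else cat("<hr_bursts> ", length(x$bursts), "bursts, modal size",
           modal_count(x$spikes_per_burst), "\n")
  invisible(x)
}

modal_count <- function(counts) {
  if (length(counts) == 0L) return(NA_integer_)
  # interior bursts only when possible: first/last may be clipped
  if (length(counts) > 4L) counts <- counts[2:(length(counts) - 1L)]
  tb <- table(counts)
  as.integer(names(tb)[which.max(tb)])
}

# greedy gap clustering of sorted values: clusters split where the gap
# between consecutive sorted values exceeds tol
cluster_count <- function(values, tol) {
  v <- sort(values)
  if (length(v) == 0L) return(0L)
  sum(diff(v) > tol) + 1L
}

#' Classify the firing pattern of a trajectory
#'
#' Combines spike/burst structure with the leading Lyapunov exponent:
#' quiescent (fixed point or small subthreshold response) when the spike
#' rate is below `quiescent_rate`; otherwise bursting vs tonic from the
#' ISI segmentation; periodic vs chaotic from the sign of `le1`
#' (threshold 0.005, with an indeterminate band between -0.005 and
#' 0.005).  For tonic periodic trains the period count is the number of
#' distinct peak-amplitude clusters (gap tolerance `period_tol`).
#' Bursting labels carry the modal spikes-per-burst and the within-burst
#' ISI coefficient of variation as an intra-burst-irregularity
#' descriptor.
#'
#' @param traj Post-transient `hr_trajectory`.
#' @param le1 Leading Lyapunov exponent for the same parameters.
#' @param train Optional precomputed [detect_spikes()] result.
#' @param bursts Optional precomputed [segment_bursts()] result.
#' @param quiescent_rate Spike-rate cut for quiescence (default
#'   0.001 per time unit).
#' @param quiescent_var Tail state-variance cut distinguishing a true
#'   fixed point from a subthreshold oscillation (default 1e-4).
#' @param period_tol Peak-amplitude clustering tolerance (default 1e-2).
#' @param chaos_tol Half-width of the indeterminate band on `le1`
#'   (default 0.005).
#' @param ... Passed to [detect_spikes()] when `train` is NULL.
#' @return Object of class `hr_firing_pattern`: `label` in
#'   `{quiescent, periodic spiking, periodic bursting, chaotic spiking,
#'   chaotic bursting, indeterminate}`, `period_count` (periodic spiking
#'   only), `spikes_per_burst` (bursting only), `le1`, `rate`,
#'   `subthreshold` (quiescent with visible oscillation), and
#'   `intra_burst_isi_cv`.
#' @export
classify_firing <- function(traj, le1, train = NULL, bursts = NULL,
                            quiescent_rate = 0.001, quiescent_var = 1e-4,
                            period_tol = 1e-2, chaos_tol = 0.005, ...) {
  if (is.null(train)) train <- detect_spikes(traj, ...)
  duration <- traj$t[length(traj$t)] - traj$t[1]
  rate <- length(train$times) / duration
  tail_idx <- traj$t >= traj$t[1] + 0.8 * duration
  tail_var <- stats::var(traj$states[tail_idx, 1])
  pattern <- function(label, period_count = NA_integer_,
                      spikes_per_burst = NA_integer_, cv = NA_real_,
                      subthreshold = FALSE)
    structure(list(label = label, period_count = period_count,
                   spikes_per_burst = spikes_per_burst, le1 = le1,
                   rate = rate, subthreshold = subthreshold,
                   intra_burst_isi_cv = cv),
              class = "hr_firing_pattern")
  if (rate < quiescent_rate)
    return(pattern("quiescent", subthreshold = tail_var >= quiescent_var))
  if (is.null(bursts)) bursts <- segment_bursts(train)
  regime <- if (le1 > chaos_tol) "chaotic"
            else if (le1 < -chaos_tol) "periodic"
            else "indeterminate"
  if (regime == "indeterminate") return(pattern("indeterminate"))
  if (isTRUE(bursts$indeterminate)) return(pattern("indeterminate"))
  if (bursts$is_bursting) {
    within <- unlist(lapply(bursts$bursts, function(b) {
      if (length(b) < 3L) return(numeric(0))
      diff(train$times[b])
    }))
    cv <- if (length(within) > 1L) stats::sd(within) / mean(within)
          else NA_real_
    sizes <- bursts$spikes_per_burst
    return(pattern(paste(regime, "bursting"),
                   spikes_per_burst = modal_count(sizes[sizes >= 2L]),
                   cv = cv))
  }
  if (regime == "chaotic") return(pattern("chaotic spiking"))
  pattern("periodic spiking",
          period_count = cluster_count(train$peaks, period_tol))
}

#' @export
print.hr_firing_pattern <- function(x, ...) {
  cat("<hr_firing_pattern> ", x$label)
  if (!is.na(x$period_count)) cat("  period-", x$period_count, sep = "")
  if (!is.na(x$spikes_per_burst))
    cat(" ", x$spikes_per_burst, "spikes/burst")
  cat("  (LE1 =", format(x$le1, digits = 3), ", rate =",
      format(x$rate, digits = 3), ")\n")
  invisible(x)
}
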