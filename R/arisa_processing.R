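#' ARISA binning scheme
#'
#' Fragment-length bins standing in for OTUs. The default scheme tiles the
#' detectable 200-1150 bp window with a fixed grid anchored at the window
#' start: 3-bp bins up to 700 bp, 5-bp bins between 700 and 1000 bp, and
#' 10-bp bins above 1000 bp. Bins are half-open `[lo, hi)`; the last bin of a
#' regime is truncated at the regime boundary and the final bin of the window
#' is closed so that both window endpoints are observable.
#'
#' @param min_bp,max_bp detection window in base pairs.
#' @param regime_breaks upper boundaries of the first regimes (the last regime
#'   ends at `max_bp`).
#' @param widths bin width (bp) per regime; positive integers.
#' @return A `binning_scheme` with a `bins` data.frame (`lo`, `hi`, `label`).
#' @export
binning_scheme <- function(min_bp = 200, max_bp = 1150,
                           regime_breaks = c(700, 1000),
                           widths = c(3, 5, 10)) {
  if (length(widths) != length(regime_breaks) + 1) {
    config_error("need one width per regime (breaks + 1)")
  }
  if (any(widths <= 0) || any(widths != round(widths))) {
    config_error("bin widths must be positive integers")
  }
  starts <- c(min_bp, regime_breaks)
  ends <- c(regime_breaks, max_bp)
  if (any(ends <= starts)) config_error("regime boundaries must increase across the window")
  bins <- do.call(rbind, lapply(seq_along(starts), function(r) {
    k <- ceiling((ends[r] - starts[r]) / widths[r])
    lo <- starts[r] + widths[r] * (seq_len(k) - 1)
    data.frame(lo = lo, hi = pmin(lo + widths[r], ends[r]), regime = r)
  }))
  bins$label <- sprintf("bp%04d_%04d", as.integer(round(bins$lo)), as.integer(round(bins$hi)))
  structure(list(min_bp = min_bp, max_bp = max_bp,
                 regime_starts = starts, regime_ends = ends, widths = widths,
                 bins = bins),
            class = "binning_scheme")
}

#' Number of bins in a scheme
#' @param scheme a [binning_scheme()].
#' @export
n_bins <- function(scheme) nrow(scheme$bins)

#' ARISA filter parameters
#'
#' @param min_rfu peaks with intensity at or below this RFU value are
#'   excluded (strict: equality is excluded). Default 10 RFU.
#' @param min_relative_intensity bins contributing less than this fraction of
#'   a sample's total summed intensity are excluded. Default 0.001 (0.1%).
#' @export
filter_params <- function(min_rfu = 10, min_relative_intensity = 0.001) {
  if (min_rfu < 0) config_error("min_rfu must be >= 0")
  if (min_relative_intensity < 0 || min_relative_intensity >= 1) {
    config_error("min_relative_intensity must be in [0, 1)")
  }
  structure(list(min_rfu = min_rfu,
                 min_relative_intensity = min_relative_intensity),
            class = "filter_params")
}

#' Intensity floor filter
#'
#' Removes every peak whose fluorescence intensity is less than or equal to
#' `min_rfu` (10 RFU by default), the instrument noise floor.
#'
#' @param peaks a [peak_table()].
#' @param params a [filter_params()].
#' @return The filtered [peak_table()], with attribute `n_removed`.
#' @export
filter_min_rfu <- function(peaks, params = filter_params()) {
  keep <- peaks$intensity_rfu > params$min_rfu
  out <- peak_table(as.data.frame(peaks)[keep, , drop = FALSE],
                    provenance = attr(peaks, "provenance"))
  if (nrow(out) == 0) warning("no peaks remain after the RFU filter")
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Clip peaks to the detection window
#'
#' Removes peaks whose called size falls outside the scheme's detectable
#' window (endpoints included).
#'
#' @inheritParams filter_min_rfu
#' @param scheme a [binning_scheme()].
#' @export
clip_to_window <- function(peaks, scheme = binning_scheme()) {
  keep <- peaks$size_bp >= scheme$min_bp & peaks$size_bp <= scheme$max_bp
  out <- peak_table(as.data.frame(peaks)[keep, , drop = FALSE],
                    provenance = attr(peaks, "provenance"))
  attr(out, "n_removed") <- sum(!keep)
  out
}

# Vectorized bin lookup: returns the row index into scheme$bins for each size.
# Sizes must already lie inside the window.
bin_index <- function(size_bp, scheme) {
  if (length(size_bp) == 0) return(integer(0))
  if (any(size_bp < scheme$min_bp | size_bp > scheme$max_bp)) {
    abort_arisacomp("peak outside the binning window: clip_to_window must run first",
                    "arisacomp_internal_error")
  }
  regime <- findInterval(size_bp, scheme$regime_starts,
                         rightmost.closed = FALSE, left.open = FALSE)
  s <- scheme$regime_starts[regime]
  w <- scheme$widths[regime]
  k <- floor((size_bp - s) / w)
  lo <- s + k * w
  # the window's upper endpoint belongs to the (closed) last bin
  at_end <- lo >= scheme$regime_ends[regime]
  lo[at_end] <- lo[at_end] - w[at_end]
  match(paste(regime, lo), paste(scheme$bins$regime, scheme$bins$lo))
}

#' Assign peaks to fragment-length bins and sum intensities
#'
#' Each peak is assigned to exactly one bin of the scheme and intensities are
#' summed per bin within each sample x replicate profile. Deterministic for a
#' fixed scheme; total intensity is conserved.
#'
#' @inheritParams clip_to_window
#' @return A `binned_profiles` data.frame with columns `sample_id`,
#'   `replicate_id`, `bin`, `intensity`.
#' @export
assign_bins <- function(peaks, scheme = binning_scheme()) {
  idx <- bin_index(peaks$size_bp, scheme)
  key <- interaction(peaks$sample_id, peaks$replicate_id, idx, drop = TRUE, sep = "\r")
  sums <- tapply(peaks$intensity_rfu, key, sum)
  parts <- do.call(rbind, strsplit(names(sums), "\r", fixed = TRUE))
  out <- data.frame(sample_id = parts[, 1], replicate_id = parts[, 2],
                    bin = scheme$bins$label[as.integer(parts[, 3])],
                    intensity = as.numeric(sums), stringsAsFactors = FALSE)
  out <- out[order(out$sample_id, out$replicate_id, out$bin), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("binned_profiles", "data.frame")
  out
}

#' Relative-intensity filter
#'
#' Computes each bin's share of its profile's total summed intensity and
#' drops, in a single pass, bins below `min_relative_intensity` (0.1% by
#' default). Shares are computed against the pre-filter total; surviving bins
#' are then re-normalized to sum to one.
#'
#' @param profiles a `binned_profiles` data.frame from [assign_bins()].
#' @param params a [filter_params()].
#' @return `binned_profiles` with an added `rel_intensity` column summing to
#'   one within each profile.
#' @export
relative_intensity_filter <- function(profiles, params = filter_params()) {
  key <- interaction(profiles$sample_id, profiles$replicate_id, drop = TRUE)
  totals <- tapply(profiles$intensity, key, sum)
  if (any(totals <= 0)) {
    empty_input_error("profile with zero total intensity cannot be normalized")
  }
  rel <- profiles$intensity / as.numeric(totals[key])
  keep <- rel >= params$min_relative_intensity
  out <- profiles[keep, , drop = FALSE]
  key2 <- interaction(out$sample_id, out$replicate_id, drop = TRUE)
  if (nlevels(key2) < nlevels(key)) {
    empty_input_error("a profile lost all bins to the relative-intensity filter")
  }
  kept_tot <- tapply(rel[keep], key2, sum)
  out$rel_intensity <- rel[keep] / as.numeric(kept_tot[key2])
  rownames(out) <- NULL
  class(out) <- c("binned_profiles", "data.frame")
  out
}

# Pull one (sample, replicate) profile out of a binned_profiles frame.
profile_of <- function(profiles, sample_id, replicate_id) {
  p <- profiles[profiles$sample_id == sample_id &
                  profiles$replicate_id == replicate_id, , drop = FALSE]
  rownames(p) <- NULL
  p
}

#' Compare and merge two technical replicates
#'
#' Technical duplicates act as an internal quality control: the Bray-Curtis
#' similarity of the two relative-intensity profiles (on the union of their
#' bins) must reach `min_similarity` for the sample to pass. Passing profiles
#' are merged as the arithmetic mean of relative intensities per bin,
#' re-normalized; failing samples are reported, not merged.
#'
#' @param p1,p2 single-profile `binned_profiles` rows for the same sample and
#'   different replicates, with `rel_intensity` present.
#' @param min_similarity QC threshold on Bray-Curtis similarity (default 0.8).
#' @return A list with `sample_id`, `similarity`, `passed`, and
#'   `merged_profile` (NULL when QC fails).
#' @export
merge_technical_replicates <- function(p1, p2, min_similarity = 0.8) {
  if (length(unique(c(p1$sample_id, p2$sample_id))) != 1) {
    validation_error("technical replicates must share one sample_id")
  }
  if (unique(p1$replicate_id) == unique(p2$replicate_id)) {
    validation_error("technical replicates must have distinct replicate_id")
  }
  bins <- sort(union(p1$bin, p2$bin))
  v1 <- stats::setNames(numeric(length(bins)), bins)
  v2 <- v1
  v1[p1$bin] <- p1$rel_intensity
  v2[p2$bin] <- p2$rel_intensity
  sim <- bray_curtis(v1, v2)$similarity
  passed <- sim >= min_similarity
  merged <- NULL
  if (passed) {
    m <- (v1 + v2) / 2
    m <- m[m > 0]
    m <- m / sum(m)
    merged <- data.frame(sample_id = p1$sample_id[1], replicate_id = "merged",
                         bin = names(m), intensity = NA_real_,
                         rel_intensity = as.numeric(m),
                         stringsAsFactors = FALSE)
    class(merged) <- c("binned_profiles", "data.frame")
  }
  list(sample_id = p1$sample_id[1], similarity = sim, passed = passed,
       merged_profile = merged)
}

#' Replicate QC and merge across all samples
#'
#' Applies [merge_technical_replicates()] to the two replicates of every
#' sample in a `binned_profiles` frame.
#'
#' @param profiles `binned_profiles` with `rel_intensity`.
#' @param min_similarity QC threshold.
#' @return list(`merged`: `binned_profiles` of passing samples;
#'   `qc`: data.frame sample_id, similarity, passed).
#' @export
merge_replicates <- function(profiles, min_similarity = 0.8) {
  samples <- unique(profiles$sample_id)
  qc <- data.frame(sample_id = samples, similarity = NA_real_, passed = FALSE)
  merged_list <- list()
  for (i in seq_along(samples)) {
    s <- samples[i]
    reps <- unique(profiles$replicate_id[profiles$sample_id == s])
    if (length(reps) != 2) {
      validation_error(sprintf("sample %s has %d replicate(s); exactly 2 required",
                               s, length(reps)))
    }
    res <- merge_technical_replicates(profile_of(profiles, s, reps[1]),
                                      profile_of(profiles, s, reps[2]),
                                      min_similarity)
    qc$similarity[i] <- res$similarity
    qc$passed[i] <- res$passed
    if (res$passed) merged_list[[s]] <- res$merged_profile
  }
  merged <- if (length(merged_list)) do.call(rbind, merged_list) else NULL
  if (!is.null(merged)) {
    rownames(merged) <- NULL
    class(merged) <- c("binned_profiles", "data.frame")
  }
  list(merged = merged, qc = qc)
}

#' Assemble per-sample profiles into a relative-intensity OTU table
#'
#' Bin labels become OTU ids (union over samples, in fragment-length order);
#' bins absent from a sample are zero.
#'
#' @param profiles `binned_profiles` with `rel_intensity`, one profile per
#'   sample (e.g. the merged output of [merge_replicates()]).
#' @return An [otu_table()] of kind `relative_intensity`.
#' @export
profiles_to_otu_table <- function(profiles) {
  if (is.null(profiles) || nrow(profiles) == 0) {
    empty_input_error("no profiles to assemble into an OTU table")
  }
  if (anyDuplicated(unique(profiles[c("sample_id", "replicate_id")])$sample_id)) {
    validation_error("profiles_to_otu_table expects one profile per sample")
  }
  samples <- unique(profiles$sample_id)
  bins <- sort(unique(profiles$bin))
  m <- matrix(0, nrow = length(samples), ncol = length(bins),
              dimnames = list(samples, bins))
  m[cbind(match(profiles$sample_id, samples), match(profiles$bin, bins))] <-
    profiles$rel_intensity
  otu_table(m, "relative_intensity")
}

#' Full ARISA processing pipeline
#'
#' Runs the supported stage order — intensity-floor filter, window clip, bin
#' assignment with per-bin intensity summation, relative-intensity filter,
#' replicate QC and merge — and assembles the per-sample OTU table.
#'
#' @param peaks a [peak_table()] with two technical replicates per sample.
#' @param params a [filter_params()].
#' @param scheme a [binning_scheme()].
#' @param replicate_threshold Bray-Curtis similarity required of duplicates.
#' @return list(`otu_table`, `qc`, `attrition` = per-stage peak counts).
#' @export
process_arisa <- function(peaks, params = filter_params(),
                          scheme = binning_scheme(),
                          replicate_threshold = 0.8) {
  n0 <- nrow(peaks)
  p1 <- filter_min_rfu(peaks, params)
  p2 <- clip_to_window(p1, scheme)
  prof <- assign_bins(p2, scheme)
  prof <- relative_intensity_filter(prof, params)
  mr <- merge_replicates(prof, replicate_threshold)
  tab <- profiles_to_otu_table(mr$merged)
  attrition <- data.frame(
    stage = c("input", "rfu_filter", "window_clip"),
    peaks_retained = c(n0, nrow(p1), nrow(p2)),
    peaks_removed = c(0L, attr(p1, "n_removed"), attr(p2, "n_removed"))
  )
  list(otu_table = tab, qc = mr$qc, attrition = attrition)
}
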