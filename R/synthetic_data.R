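#' Specification of a group-structured community design
#'
#' Describes the simulated study: groups of samples whose true richness rises
#' across the group order (young to old rumen communities span roughly
#' hundreds to thousands of taxa), a log-normal ranked-abundance model, a
#' within-group similarity knob theta, and a shared-core fraction linking
#' adjacent groups.
#'
#' @param labels group labels, in increasing-richness order.
#' @param n_samples samples per group.
#' @param richness true per-sample taxon richness per group (non-decreasing).
#' @param theta in `[0, 1]`: mixture weight of the group template in each
#'   sample's composition (1 = identical samples within a group). Higher
#'   theta means higher expected within-group Bray-Curtis similarity.
#' @param sigma_log SD of the log-normal ranked-abundance draws.
#' @param shared_core fraction of the smaller adjacent group's taxa shared
#'   between consecutive groups.
#' @param seed RNG seed for the community draw.
#' @return A `community_spec` list.
#' @export
community_spec <- function(labels = c("1-3 days", "2 months", "6 months", "2 years"),
                           n_samples = c(6, 5, 5, 5),
                           richness = c(200, 600, 2000, 2400),
                           theta = 0.85,
                           sigma_log = 1.5,
                           shared_core = 0.5,
                           seed = 1) {
  if (length(labels) != length(n_samples) || length(labels) != length(richness)) {
    config_error("labels, n_samples and richness must have equal length")
  }
  if (is.unsorted(richness)) config_error("richness must be non-decreasing across groups")
  if (theta < 0 || theta > 1) config_error("theta must be in [0, 1]")
  if (any(n_samples < 2)) config_error("each group needs >= 2 samples")
  structure(list(labels = labels, n_samples = n_samples, richness = richness,
                 theta = theta, sigma_log = sigma_log,
                 shared_core = shared_core, seed = seed),
            class = "community_spec")
}

#' Simulate true communities
#'
#' Each group gets a template community: its taxa (a shared core inherited
#' from the previous group plus new taxa) with log-normal ranked relative
#' abundances. Each sample is a mixture theta * template +
#' (1 - theta) * sample-specific log-normal perturbation over the same taxa,
#' so within-group similarity rises monotonically with theta and support size
#' equals the configured richness. Fully deterministic given the seed.
#'
#' @param spec a [community_spec()].
#' @return A `true_communities` list: `abundance` (samples x pool matrix, rows
#'   sum to 1), `metadata` ([sample_metadata()]), `spec`.
#' @export
simulate_true_communities <- function(spec = community_spec()) {
  withr::with_seed(spec$seed, {
    g <- length(spec$labels)
    taxa_sets <- vector("list", g)
    pool <- character(0)
    new_taxon <- function(k) sprintf("taxon_%05d", k)
    for (i in seq_len(g)) {
      r <- spec$richness[i]
      if (i == 1) {
        taxa <- new_taxon(seq_len(r))
      } else {
        prev <- taxa_sets[[i - 1]]
        n_shared <- round(spec$shared_core * min(length(prev), r))
        shared <- sample(prev, n_shared)
        taxa <- c(shared, new_taxon(length(pool) + seq_len(r - n_shared)))
      }
      if (r > length(taxa)) config_error("richness exceeds available taxon pool")
      taxa_sets[[i]] <- taxa
      pool <- union(pool, taxa)
    }
    pool <- sort(pool)
    n_total <- sum(spec$n_samples)
    abundance <- matrix(0, n_total, length(pool),
                        dimnames = list(sprintf("S%02d", seq_len(n_total)), pool))
    groups <- rep(spec$labels, spec$n_samples)
    row <- 1L
    for (i in seq_len(g)) {
      taxa <- taxa_sets[[i]]
      template <- stats::rlnorm(length(taxa), 0, spec$sigma_log)
      template <- sort(template, decreasing = TRUE) / sum(template)
      for (s in seq_len(spec$n_samples[i])) {
        indiv <- stats::rlnorm(length(taxa), 0, spec$sigma_log)
        indiv <- indiv / sum(indiv)
        p <- spec$theta * template + (1 - spec$theta) * indiv
        abundance[row, taxa] <- p / sum(p)
        row <- row + 1L
      }
    }
    structure(list(abundance = abundance,
                   metadata = sample_metadata(rownames(abundance), groups),
                   spec = spec),
              class = "true_communities")
  })
}

#' Simulate pyrosequencing read counts
#'
#' Draws a per-sample depth from a truncated normal (default 10800 +/- 2860,
#' floor 1000 reads) and samples reads multinomially from the true relative
#' abundances. Taxa never observed in any sample are dropped from the table.
#'
#' @param truth a `true_communities` object.
#' @param depth_mean,depth_sd,depth_min sequencing-depth model (reads).
#' @param seed RNG seed.
#' @return An [otu_table()] of kind `read_count`.
#' @export
simulate_pyrosequencing <- function(truth, depth_mean = 10800, depth_sd = 2860,
                                    depth_min = 1000, seed = 1) {
  if (depth_mean <= 0) config_error("depth_mean must be positive")
  withr::with_seed(seed, {
    n <- nrow(truth$abundance)
    depths <- integer(n)
    for (i in seq_len(n)) {
      repeat {
        d <- round(stats::rnorm(1, depth_mean, depth_sd))
        if (d >= depth_min) break
      }
      depths[i] <- d
    }
    counts <- t(vapply(seq_len(n), function(i) {
      as.numeric(stats::rmultinom(1, depths[i], truth$abundance[i, ]))
    }, numeric(ncol(truth$abundance))))
    dimnames(counts) <- dimnames(truth$abundance)
    counts <- counts[, colSums(counts) > 0, drop = FALSE]
    otu_table(counts, "read_count")
  })
}

#' ARISA signal model
#'
#' Maps taxa to intergenic-spacer fragment lengths and fluorescence. Each
#' taxon gets one length drawn uniformly on the detection window and, with
#' probability `multi_length_prob`, a second length (multiple rRNA operons
#' with different spacers). Distinct taxa can land on the same length, so
#' signals collide additively - the two mechanisms that make fragment
#' fingerprints underestimate richness.
#'
#' @param taxa taxon ids (the pool of a `true_communities` object).
#' @param window fragment-length window in bp.
#' @param multi_length_prob probability of a second fragment length per taxon.
#' @param gain fluorescence per unit relative abundance (RFU); with the
#'   default 1e5, taxa below 1e-4 abundance fall under a 10-RFU floor.
#' @param size_sd SD (bp) of size-calling noise per observed peak.
#' @param intensity_sd SD of log-normal run-to-run intensity noise.
#' @param noise_rate expected number of spurious baseline peaks per run.
#' @param noise_rfu_scale exponential scale (RFU) of baseline peak intensity.
#' @param seed RNG seed for the length assignment.
#' @return An `arisa_signal_model` list with a `lengths` data.frame
#'   (taxon, length_bp).
#' @export
arisa_signal_model <- function(taxa, window = c(200, 1150),
                               multi_length_prob = 0.2, gain = 1e5,
                               size_sd = 0.3, intensity_sd = 0.1,
                               noise_rate = 25, noise_rfu_scale = 5,
                               seed = 1) {
  if (gain <= 0) config_error("gain must be positive")
  withr::with_seed(seed, {
    n <- length(taxa)
    primary <- stats::runif(n, window[1], window[2])
    extra <- stats::runif(n) < multi_length_prob
    lengths <- data.frame(
      taxon = c(taxa, taxa[extra]),
      length_bp = c(primary, stats::runif(sum(extra), window[1], window[2])),
      stringsAsFactors = FALSE
    )
    structure(list(lengths = lengths, window = window, gain = gain,
                   size_sd = size_sd, intensity_sd = intensity_sd,
                   noise_rate = noise_rate, noise_rfu_scale = noise_rfu_scale,
                   multi_length_prob = multi_length_prob, seed = seed),
              class = "arisa_signal_model")
  })
}

#' Simulate ARISA peak tables
#'
#' For every sample x replicate run, each taxon emits `gain * abundance` RFU
#' at each of its fragment lengths; taxa sharing a length merge into one peak
#' with summed intensity. The observed size adds Gaussian size-calling noise,
#' intensities get log-normal run noise, and spurious low-RFU baseline peaks
#' are appended. Peaks weaker than the instrument floor are emitted as-is;
#' the downstream 10-RFU filter removes them.
#'
#' @param truth a `true_communities` object.
#' @param model an [arisa_signal_model()] over the same taxon pool.
#' @param replicates technical replicates per sample (default 2).
#' @param seed RNG seed.
#' @return A [peak_table()].
#' @export
simulate_arisa <- function(truth, model, replicates = 2, seed = 1) {
  withr::with_seed(seed, {
    samples <- rownames(truth$abundance)
    out <- vector("list", length(samples) * replicates)
    k <- 1L
    for (s in samples) {
      ab <- truth$abundance[s, ]
      ab <- ab[ab > 0]
      lens <- model$lengths[model$lengths$taxon %in% names(ab), ]
      signal <- model$gain * ab[lens$taxon]
      # collision: distinct taxa with identical length form one true peak
      true_peaks <- tapply(signal, lens$length_bp, sum)
      true_len <- as.numeric(names(true_peaks))
      for (r in seq_len(replicates)) {
        n_p <- length(true_len)
        obs_size <- true_len + stats::rnorm(n_p, 0, model$size_sd)
        obs_int <- as.numeric(true_peaks) *
          stats::rlnorm(n_p, 0, model$intensity_sd)
        n_noise <- stats::rpois(1, model$noise_rate)
        out[[k]] <- data.frame(
          sample_id = s,
          replicate_id = paste0("rep", r),
          size_bp = c(obs_size,
                      stats::runif(n_noise, model$window[1], model$window[2])),
          intensity_rfu = c(obs_int,
                            stats::rexp(n_noise, 1 / model$noise_rfu_scale)),
          stringsAsFactors = FALSE
        )
        k <- k + 1L
      }
    }
    df <- do.call(rbind, out)
    df <- df[df$size_bp > 0, , drop = FALSE]
    peak_table(df, provenance = sprintf("simulate_arisa(seed=%d)", seed))
  })
}

#' Simulate a full paired dataset
#'
#' Convenience wrapper: true communities, pyrosequencing counts and an ARISA
#' peak table with technical duplicates, all from one master seed (sub-seeds
#' are derived deterministically).
#'
#' @param spec a [community_spec()]; its seed is overridden by `seed`.
#' @param seed master seed.
#' @param ... passed to [arisa_signal_model()].
#' @return list(truth, pyro (otu_table), peaks (peak_table), metadata).
#' @export
simulate_dataset <- function(spec = community_spec(), seed = 1, ...) {
  spec$seed <- seed
  truth <- simulate_true_communities(spec)
  pyro <- simulate_pyrosequencing(truth, seed = seed + 1000L)
  model <- arisa_signal_model(colnames(truth$abundance), seed = seed + 2000L, ...)
  peaks <- simulate_arisa(truth, model, seed = seed + 3000L)
  list(truth = truth, pyro = pyro, peaks = peaks,
       metadata = truth$metadata, model = model)
}
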