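# Synthetic chromatogram generator: seeded surrogate for an HPLC-UV/FLD
# fingerprinting campaign with pooled-QC injections and sensitivity drift.

#' Default retention-time grid
#'
#' 0--25 min at 0.01 min per point (2501 points), matching the
#' chromatographic run length.
#'
#' @param t_max Run length in minutes.
#' @param step Grid step in minutes (must be > 0).
#' @return Numeric vector of retention times.
#' @export
default_grid <- function(t_max = 25, step = 0.01) {
  if (!is.numeric(step) || step <= 0) {
    stop("grid step must be > 0", call. = FALSE)
  }
  seq(0, t_max, by = step)
}

#' Instrument sensitivity drift model
#'
#' Multiplicative sensitivity factor across the injection sequence,
#' `s(i) = (1 + slope * (i - 1) / (N - 1)) * exp(walk_i)`, where `walk` is a
#' seeded Gaussian random walk started at 0. Emulates lamp-intensity decay
#' plus wander over a long sequence. An explicit `factors` vector overrides
#' the formula, e.g. to impose sensitivity steps at QC events.
#'
#' @param slope Fractional sensitivity change across the full sequence
#'   (default -0.15, i.e. 15% loss by the last injection).
#' @param walk_sd Per-injection random-walk s.d. (default 0.005).
#' @param factors Optional explicit per-injection factor vector (all > 0).
#' @return A `drift_model` object.
#' @export
drift_model <- function(slope = -0.15, walk_sd = 0.005, factors = NULL) {
  if (walk_sd < 0) stop("walk_sd must be >= 0", call. = FALSE)
  if (!is.null(factors) && any(factors <= 0)) {
    stop("explicit drift factors must all be > 0", call. = FALSE)
  }
  structure(list(slope = slope, walk_sd = walk_sd, factors = factors),
            class = "drift_model")
}

#' Realized drift factors for a sequence
#'
#' @param drift A [drift_model()].
#' @param n_injections Sequence length.
#' @param seed Integer seed for the random walk.
#' @return Numeric vector of length `n_injections`, all > 0.
#' @export
drift_factors <- function(drift, n_injections, seed) {
  stopifnot(inherits(drift, "drift_model"), n_injections >= 1)
  if (!is.null(drift$factors)) {
    if (length(drift$factors) < n_injections) {
      stop("explicit drift factors shorter than the sequence", call. = FALSE)
    }
    return(drift$factors[seq_len(n_injections)])
  }
  ramp <- if (n_injections == 1L) 1 else {
    1 + drift$slope * (seq_len(n_injections) - 1) / (n_injections - 1)
  }
  walk <- if (drift$walk_sd > 0 && n_injections > 1L) {
    with_seed(seed, cumsum(c(0, stats::rnorm(n_injections - 1L,
                                             sd = drift$walk_sd))))
  } else {
    numeric(n_injections)
  }
  s <- ramp * exp(walk)
  if (any(s <= 0)) {
    stop("drift parameters yield a non-positive sensitivity factor",
         call. = FALSE)
  }
  s
}

# Gaussian peak sum on a grid for one channel.
gaussian_sum <- function(grid, rt, width, amp) {
  trace <- numeric(length(grid))
  for (k in seq_along(rt)) {
    if (amp[k] > 0) {
      trace <- trace + amp[k] * exp(-(grid - rt[k])^2 / (2 * width[k]^2))
    }
  }
  trace
}

# Lot-level realization of a template: per-peak lognormal amplitude factors
# (mean 1, CV = amp_cv; compositional lot variation) and one shared
# retention shift for the whole injection, as retention drift moves all
# peaks together. Both channels see the same realization.
realize_peaks <- function(template, seed) {
  rt <- peak_field(template, "rt_min")
  width <- peak_field(template, "width_min")
  n <- length(rt)
  sdlog <- sqrt(log(1 + template$amp_cv^2))
  with_seed(seed, {
    amp_factor <- if (template$amp_cv > 0) {
      exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
    } else {
      rep(1, n)
    }
    shift <- if (template$rt_jitter_sd > 0) {
      stats::rnorm(1, sd = template$rt_jitter_sd)
    } else {
      0
    }
    data.frame(rt_min = rt + shift, width_min = width,
               amp_uv = peak_field(template, "amp_uv") * amp_factor,
               amp_fld = peak_field(template, "amp_fld") * amp_factor)
  })
}

# Smooth low-frequency baseline: two cosines with seeded phases, non-negative.
make_baseline <- function(grid, amp, seed) {
  if (amp <= 0) return(numeric(length(grid)))
  span <- max(grid) - min(grid)
  with_seed(seed, {
    phi <- stats::runif(2, 0, 2 * pi)
    amp * (1.5 + cos(2 * pi * grid / span + phi[1]) +
             0.5 * cos(4 * pi * grid / span + phi[2]))
  })
}

template_max_amp <- function(template, channel) {
  amps <- peak_field(template, paste0("amp_", channel))
  if (length(amps)) max(amps) else 0
}

#' Generate one synthetic chromatogram
#'
#' Builds `drift_factor(i) * (Gaussian peak sum with lot amplitude jitter and
#' retention jitter + low-frequency baseline) + white noise` on the shared
#' grid. All stochastic terms are seeded; the lot/retention jitter draw
#' depends only on `(seed, injection_index)` so the UV and FLD traces of the
#' same injection share one realization.
#'
#' @param template A [class_template()].
#' @param channel `"uv"` or `"fld"`.
#' @param injection_index 1-based position in the sequence.
#' @param drift A [drift_model()].
#' @param seed Integer seed.
#' @param grid Retention-time grid (default [default_grid()]).
#' @param n_injections Total sequence length the drift ramp spans (defaults
#'   to `injection_index`).
#' @param noise_frac White-noise s.d. as a fraction of the template's maximum
#'   amplitude in this channel (default 0.005).
#' @param baseline_frac Baseline amplitude as the same fraction
#'   (default 0.02).
#' @return A [chromatogram()].
#' @export
generate_chromatogram <- function(template, channel = c("uv", "fld"),
                                  injection_index = 1L,
                                  drift = drift_model(0, 0), seed = 1L,
                                  grid = default_grid(),
                                  n_injections = injection_index,
                                  noise_frac = 0.005, baseline_frac = 0.02) {
  channel <- match.arg(channel)
  stopifnot(inherits(template, "class_template"), injection_index >= 1)
  peaks <- realize_peaks(template, derive_seed(seed, injection_index, 1L))
  ideal <- gaussian_sum(grid, peaks$rt_min, peaks$width_min,
                        peaks[[paste0("amp_", channel)]])
  ref_amp <- template_max_amp(template, channel)
  chan_stream <- if (channel == "uv") 10L else 11L
  baseline <- make_baseline(grid, baseline_frac * ref_amp,
                            derive_seed(seed, injection_index,
                                        chan_stream + 10L))
  s <- drift_factors(drift, n_injections, derive_seed(seed, 0L, 3L))
  trace <- s[injection_index] * (ideal + baseline)
  if (noise_frac > 0) {
    noise <- with_seed(derive_seed(seed, injection_index, chan_stream),
                       stats::rnorm(length(grid), sd = noise_frac * ref_amp))
    trace <- trace + noise
  }
  chromatogram(grid, trace, channel)
}

#' Build a randomized injection sequence with QC/blank insertions
#'
#' Samples are injected in seeded random order. A QC opens the sequence and,
#' after every block of 10 sample injections (including a final partial
#' block), one instrumental blank and one QC follow.
#'
#' @param sample_ids Character vector of unique sample ids.
#' @param seed Integer seed for the permutation.
#' @param qc_every Block size between QC/blank insertions (default 10).
#' @return A `sequence_design` data frame with columns `injection_index`,
#'   `sample_id`, `role`.
#' @export
build_injection_sequence <- function(sample_ids, seed = 1L, qc_every = 10L) {
  if (anyDuplicated(sample_ids)) {
    stop("sample_ids must be unique", call. = FALSE)
  }
  n <- length(sample_ids)
  if (n == 0L) {
    out <- data.frame(injection_index = integer(0),
                      sample_id = character(0), role = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("sequence_design", "data.frame")
    return(out)
  }
  order_ids <- with_seed(seed, sample(sample_ids))
  ids <- "QC_01"
  roles <- "qc"
  n_qc <- 1L
  n_blank <- 0L
  done <- 0L
  while (done < n) {
    block <- order_ids[(done + 1L):min(done + qc_every, n)]
    ids <- c(ids, block)
    roles <- c(roles, rep("sample", length(block)))
    done <- done + length(block)
    n_blank <- n_blank + 1L
    n_qc <- n_qc + 1L
    ids <- c(ids, sprintf("BLANK_%02d", n_blank), sprintf("QC_%02d", n_qc))
    roles <- c(roles, "blank", "qc")
  }
  out <- data.frame(injection_index = seq_along(ids), sample_id = ids,
                    role = roles, stringsAsFactors = FALSE)
  class(out) <- c("sequence_design", "data.frame")
  out
}

#' Block-constant drift factors keyed to the nearest QC
#'
#' Returns one sensitivity factor per injection that is constant within each
#' nearest-QC block (ties broken toward the preceding QC, as in
#' [qc_correct()]): the sensitivity changes only at QC events, so a sample
#' and the QC it will be divided by share the same factor and the division
#' cancels the drift exactly. Useful for studying the QC correction in
#' isolation from within-block drift.
#'
#' @param sequence A [build_injection_sequence()] design.
#' @param step Fractional sensitivity change from one QC block to the next
#'   (default -0.05).
#' @return Numeric factor vector (length = sequence length, all > 0).
#' @export
qc_block_factors <- function(sequence, step = -0.05) {
  qc_idx <- sequence$injection_index[sequence$role == "qc"]
  if (!length(qc_idx)) stop("sequence has no QC entries", call. = FALSE)
  group <- vapply(sequence$injection_index, function(i) {
    d <- abs(qc_idx - i)
    nearest <- which(d == min(d))
    if (length(nearest) > 1L) nearest <- nearest[qc_idx[nearest] <= i][1L]
    nearest
  }, integer(1))
  s <- 1 + step * (group - 1L)
  if (any(s <= 0)) {
    stop("step yields non-positive factors for this sequence", call. = FALSE)
  }
  s
}

#' Pooled QC fingerprint
#'
#' The ideal QC trace is the unweighted mean of all drift-free sample traces,
#' mirroring the pooling of equal aliquots of every study extract into one
#' quality-control solution.
#'
#' @param samples A [fingerprint_matrix()] (or plain matrix) of drift-free
#'   sample traces.
#' @return A [chromatogram()] holding the mean trace (for a plain matrix, a
#'   numeric vector).
#' @export
make_pooled_qc <- function(samples) {
  if (inherits(samples, "fingerprint_matrix")) {
    if (nrow(samples$intensity) == 0L) {
      stop("cannot pool a QC from zero samples", call. = FALSE)
    }
    return(chromatogram(samples$time_min, colMeans(samples$intensity),
                        samples$channel))
  }
  samples <- as.matrix(samples)
  if (nrow(samples) == 0L) {
    stop("cannot pool a QC from zero samples", call. = FALSE)
  }
  colMeans(samples)
}

#' Mix two fingerprints at an adulteration level
#'
#' Linear in-silico analogue of physically blending a tea extract with
#' chicory: `(1 - p/100) * tea + (p/100) * chicory`, optionally with a fresh
#' white-noise realization (absorbance and fluorescence are additive at the
#' working concentrations).
#'
#' @param tea,chicory [chromatogram()] objects on the same grid and channel.
#' @param adulterant_pct Chicory percentage `p` in `[0, 100]`.
#' @param noise_frac Noise s.d. as a fraction of the mixed trace maximum
#'   (0 for noise-free mixing).
#' @param seed Seed for the noise draw (required when `noise_frac > 0`).
#' @return A [chromatogram()].
#' @export
mix_fingerprints <- function(tea, chicory, adulterant_pct, noise_frac = 0,
                             seed = NULL) {
  stopifnot(inherits(tea, "chromatogram"), inherits(chicory, "chromatogram"))
  if (tea$channel != chicory$channel) {
    stop("tea and chicory traces must share the detection channel",
         call. = FALSE)
  }
  if (length(tea$time_min) != length(chicory$time_min) ||
      max(abs(tea$time_min - chicory$time_min)) > 1e-9) {
    stop("tea and chicory traces must share the retention-time grid",
         call. = FALSE)
  }
  if (!is.numeric(adulterant_pct) || adulterant_pct < 0 ||
      adulterant_pct > 100) {
    stop("adulterant_pct must lie in [0, 100]", call. = FALSE)
  }
  p <- adulterant_pct / 100
  mixed <- (1 - p) * tea$intensity + p * chicory$intensity
  if (noise_frac > 0) {
    if (is.null(seed)) stop("seed required for noisy mixing", call. = FALSE)
    mixed <- mixed + with_seed(seed,
      stats::rnorm(length(mixed), sd = noise_frac * max(abs(mixed))))
  }
  chromatogram(tea$time_min, mixed, tea$channel)
}

#' Run configuration for the synthetic study
#'
#' Defaults reproduce the study design: 107 samples with class counts
#' 35/20/10/12/10/20 (white split 5 + 5 across its two sub-types), QC + blank
#' insertions after every 10 sample injections, a -15% linear sensitivity
#' drift with a 0.005-s.d. random walk, 0.5% white noise and a 2%
#' two-cosine baseline, on the 0--25 min / 0.01 min grid.
#'
#' @param class_counts Named integer vector of samples per template class.
#' @param grid Retention-time grid.
#' @param drift A [drift_model()].
#' @param amp_cv,rt_jitter_sd Template variability overrides.
#' @param noise_frac,baseline_frac Noise and baseline amplitudes as fractions
#'   of each class's maximum amplitude.
#' @param qc_every QC/blank insertion cadence.
#' @param templates Optional template list overriding
#'   [build_default_templates()].
#' @return A `run_config` list.
#' @export
run_config <- function(class_counts = c(black = 35, green = 20, oolong = 10,
                                        red = 12, white_a = 5, white_b = 5,
                                        chicory = 20),
                       grid = default_grid(), drift = drift_model(),
                       amp_cv = 0.05, rt_jitter_sd = 0.02,
                       noise_frac = 0.005, baseline_frac = 0.02,
                       qc_every = 10L, templates = NULL) {
  if (any(class_counts < 0)) {
    stop("class counts must be >= 0", call. = FALSE)
  }
  if (is.null(templates)) {
    templates <- build_default_templates(amp_cv = amp_cv,
                                         rt_jitter_sd = rt_jitter_sd)
  }
  if (!all(names(class_counts) %in% names(templates))) {
    stop("class_counts names must match template names", call. = FALSE)
  }
  structure(list(class_counts = class_counts, grid = grid, drift = drift,
                 amp_cv = amp_cv, rt_jitter_sd = rt_jitter_sd,
                 noise_frac = noise_frac, baseline_frac = baseline_frac,
                 qc_every = as.integer(qc_every), templates = templates),
            class = "run_config")
}

#' Generate a full synthetic dataset (both channels)
#'
#' Realizes one campaign: a lot-level peak realization per sample, a seeded
#' random injection order with QC/blank insertions, per-channel drift walks,
#' and per-injection baseline + noise. The pooled QC ideal trace is the mean
#' of all drift-free sample traces; realized QC injections receive the drift
#' and noise of their own sequence positions (no lot or retention jitter --
#' all QC injections draw from one pooled solution).
#'
#' @param config A [run_config()].
#' @param seed Integer master seed.
#' @return A `chrom_dataset`: `uv` and `fld` [fingerprint_matrix()] objects
#'   sharing one sequence, a `truth` table, the realized `sequence`, drift
#'   factors, ideal (noise/drift-free) traces, and the configuration.
#' @export
generate_dataset <- function(config = run_config(), seed = 1L) {
  stopifnot(inherits(config, "run_config"))
  grid <- config$grid
  counts <- config$class_counts[config$class_counts > 0]
  sample_ids <- unlist(lapply(names(counts), function(cl) {
    sprintf("%s_%02d", cl, seq_len(counts[[cl]]))
  }), use.names = FALSE)
  sample_class <- rep(names(counts), counts)
  names(sample_class) <- sample_ids

  sequence <- build_injection_sequence(sample_ids,
                                       seed = derive_seed(seed, 0L, 20L),
                                       qc_every = config$qc_every)
  n_inj <- nrow(sequence)

  empty_fpm <- function(channel) {
    fingerprint_matrix(matrix(numeric(0), nrow = 0, ncol = length(grid)),
                       grid,
                       data.frame(sample_id = character(0),
                                  class_label = character(0),
                                  injection_index = integer(0),
                                  role = character(0)),
                       channel)
  }
  if (n_inj == 0L) {
    return(structure(list(uv = empty_fpm("uv"), fld = empty_fpm("fld"),
                          sequence = sequence,
                          truth = data.frame(sample_id = character(0),
                                             template_class = character(0),
                                             class_label = character(0)),
                          drift_factors = list(uv = numeric(0),
                                               fld = numeric(0)),
                          ideal = NULL, config = config, seed = seed),
                     class = "chrom_dataset"))
  }

  # Lot realizations and ideal (drift/noise/baseline-free) traces per sample.
  realized <- lapply(seq_along(sample_ids), function(j) {
    realize_peaks(config$templates[[sample_class[j]]],
                  derive_seed(seed, j, 1L))
  })
  names(realized) <- sample_ids
  ideal <- list()
  for (ch in c("uv", "fld")) {
    m <- t(vapply(realized, function(p) {
      gaussian_sum(grid, p$rt_min, p$width_min, p[[paste0("amp_", ch)]])
    }, numeric(length(grid))))
    rownames(m) <- sample_ids
    ideal[[ch]] <- m
  }
  qc_ideal <- list(uv = make_pooled_qc(ideal$uv), fld = make_pooled_qc(ideal$fld))

  s_factors <- list(
    uv = drift_factors(config$drift, n_inj, derive_seed(seed, 0L, 30L)),
    fld = drift_factors(config$drift, n_inj, derive_seed(seed, 0L, 31L)))

  build_channel <- function(ch) {
    chan_stream <- if (ch == "uv") 10L else 11L
    qc_amp <- max(qc_ideal[[ch]])
    mat <- matrix(0, nrow = n_inj, ncol = length(grid))
    for (i in seq_len(n_inj)) {
      role <- sequence$role[i]
      id <- sequence$sample_id[i]
      if (role == "sample") {
        base_ref <- template_max_amp(config$templates[[sample_class[id]]], ch)
        pure <- ideal[[ch]][id, ]
      } else if (role == "qc") {
        base_ref <- qc_amp
        pure <- qc_ideal[[ch]]
      } else {
        base_ref <- qc_amp
        pure <- numeric(length(grid))
      }
      baseline <- make_baseline(grid, config$baseline_frac * base_ref,
                                derive_seed(seed, i, chan_stream + 10L))
      trace <- s_factors[[ch]][i] * (pure + baseline)
      if (config$noise_frac > 0) {
        trace <- trace + with_seed(derive_seed(seed, i, chan_stream),
          stats::rnorm(length(grid), sd = config$noise_frac * base_ref))
      }
      mat[i, ] <- trace
    }
    meta <- data.frame(
      sample_id = sequence$sample_id,
      class_label = ifelse(sequence$role == "sample",
                           external_label(sample_class[sequence$sample_id]),
                           ""),
      injection_index = sequence$injection_index,
      role = sequence$role, stringsAsFactors = FALSE)
    fingerprint_matrix(mat, grid, meta, ch)
  }

  truth <- data.frame(sample_id = sample_ids,
                      template_class = unname(sample_class),
                      class_label = unname(external_label(sample_class)),
                      stringsAsFactors = FALSE)

  structure(list(uv = build_channel("uv"), fld = build_channel("fld"),
                 sequence = sequence, truth = truth,
                 drift_factors = s_factors,
                 ideal = list(uv = ideal$uv, fld = ideal$fld,
                              qc_uv = qc_ideal$uv, qc_fld = qc_ideal$fld),
                 config = config, seed = seed),
            class = "chrom_dataset")
}

#' @export
print.chrom_dataset <- function(x, ...) {
  cat(sprintf("<chrom_dataset> %d injections (%d samples), %d grid points, seed %s\n",
              nrow(x$sequence), sum(x$sequence$role == "sample"),
              length(x$config$grid), format(x$seed)))
  if (nrow(x$truth)) print(table(x$truth$class_label))
  invisible(x)
}
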