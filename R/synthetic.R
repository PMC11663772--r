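# Synthetic cohorts with the statistical structure the analysis assumes:
# two groups, Gaussian equicorrelated feature tables with planted
# standardized group effects, coupled-oscillator network time series with
# controllable band-limited coherence and phase lag, and HDRS scores whose
# outcome labels are recoverable by construction.

#' Feature-set dimensionalities of the reference study design
#'
#' Element counts per feature set as printed for the clinical study: T1
#' volumes/thickness (113), T2 subfield/nuclei volumes (66), five DTI
#' edge-metric sets over 84 regions (C(84,2) = 3486 each), task-activation
#' contrasts (11 ROIs x 2 contrasts = 22), and the three network-interaction
#' sets over 15 networks (sFC 105, nCC 105, leadCoh 210). Set sizes are
#' configuration, not constants: the printed T1/T2 totals differ by 2 from
#' the sum of their stated parts, so callers may override any entry.
#'
#' @return Named integer vector of element counts.
#' @export
default_set_dims <- function() {
  c(T1 = 113L, T2 = 66L, MD = 3486L, FA = 3486L, AD = 3486L, RD = 3486L,
    sSW = 3486L, Act = 22L, sFC = 105L, nCC = 105L, leadCoh = 210L)
}

#' Specification of a synthetic two-group cohort
#'
#' @param n_group_a,n_group_b group sizes (e.g. 31 HC + 32 MDD for
#'   diagnosis, 12 PO + 19 NO for outcome).
#' @param set_dims named vector: element count per feature set.
#' @param informative named list: per feature set, a list of
#'   `list(index, d, sign)` entries planting a standardized mean difference
#'   of `d * sign` SD on that element (group B minus group A).
#' @param rho equicorrelation of elements within a set, in `[0, 1)`.
#' @param group_labels labels for groups A and B.
#' @param hdrs_model list: `baseline_mean`, `baseline_sd` (MDD baseline
#'   severity), `po_mean`, `po_sd`, `no_mean`, `no_sd` (relative-reduction
#'   distributions per outcome group), `noise_rate` (label noise).
#' @param ts_spec list: `n_networks`, `n_samples` (>= 64), `dt` (sampling
#'   interval, s), `couplings` = list of
#'   `list(pair = c(i, j), freq, phase_lag, strength)`; positive
#'   `phase_lag` means network `i` leads `j`.
#' @param seed master seed; all stages derive child seeds from it.
#' @return A validated `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_group_a, n_group_b,
                           set_dims = c(set1 = 105L),
                           informative = list(), rho = 0,
                           group_labels = c("A", "B"),
                           hdrs_model = list(baseline_mean = 24.4,
                                             baseline_sd = 4.62,
                                             po_mean = 0.675, po_sd = 0.08,
                                             no_mean = 0.30, no_sd = 0.12,
                                             noise_rate = 0),
                           ts_spec = list(n_networks = 15L, n_samples = 300L,
                                          dt = 2, couplings = list()),
                           seed = 1L) {
  stopifnot(n_group_a >= 1L, n_group_b >= 1L,
            all(set_dims > 0), !is.null(names(set_dims)),
            rho >= 0, rho < 1, length(group_labels) == 2L)
  for (nm in names(informative)) {
    if (!nm %in% names(set_dims)) stop("informative set '", nm, "' unknown")
    for (e in informative[[nm]]) {
      if (!is.finite(e$d)) stop("effect size must be finite")
      if (e$index > set_dims[[nm]] || e$index < 1L)
        stop("informative index ", e$index, " outside set '", nm, "'")
    }
  }
  if (!is.null(ts_spec)) {
    stopifnot(ts_spec$n_samples >= 64L, ts_spec$n_networks >= 2L,
              ts_spec$dt > 0)
    for (cp in ts_spec$couplings) {
      if (cp$freq >= 1 / (2 * ts_spec$dt))
        stop("coupling band above Nyquist frequency")
      stopifnot(length(cp$pair) == 2L, all(cp$pair <= ts_spec$n_networks))
    }
  }
  structure(list(n_group_a = n_group_a, n_group_b = n_group_b,
                 set_dims = set_dims, informative = informative, rho = rho,
                 group_labels = group_labels, hdrs_model = hdrs_model,
                 ts_spec = ts_spec, seed = as.integer(seed)),
            class = "synthetic_spec")
}

spec_groups <- function(spec) {
  factor(rep(spec$group_labels, c(spec$n_group_a, spec$n_group_b)),
         levels = spec$group_labels)
}

spec_subject_ids <- function(spec) {
  sprintf("S%03d", seq_len(spec$n_group_a + spec$n_group_b))
}

#' Generate the feature tables of a synthetic cohort
#'
#' Each set is Gaussian with unit marginal variance and equicorrelation
#' `rho` (one shared standard normal per subject plus independent element
#' noise); informative elements receive a mean shift of `d * sign` standard
#' deviations in group B. Reproducible bit-for-bit under a fixed seed.
#'
#' @param spec a `synthetic_spec`.
#' @return Named list of `feature_set` matrices (subjects x elements),
#'   rownames = subject ids.
#' @export
generate_feature_tables <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_group_a + spec$n_group_b
  g_b <- spec_groups(spec) == spec$group_labels[2L]
  ids <- spec_subject_ids(spec)
  out <- lapply(names(spec$set_dims), function(nm) {
    p <- spec$set_dims[[nm]]
    set.seed(child_seed(spec$seed, paste0("features_", nm)))
    Z <- matrix(stats::rnorm(n * p), n, p)
    if (spec$rho > 0) {
      shared <- stats::rnorm(n)
      Z <- sqrt(spec$rho) * shared + sqrt(1 - spec$rho) * Z
    }
    for (e in spec$informative[[nm]])
      Z[g_b, e$index] <- Z[g_b, e$index] + e$d * e$sign
    dimnames(Z) <- list(ids, sprintf("%s_%03d", nm, seq_len(p)))
    feature_set(Z, nm)
  })
  stats::setNames(out, names(spec$set_dims))
}

#' Generate coupled resting-state network time series
#'
#' One `n_networks` x `n_samples` matrix per subject: independent Gaussian
#' noise per network, plus, for each coupling, a shared narrow-band
#' component (FFT band-filtered noise centred on `freq`) added to both
#' networks of the pair with amplitude `strength`; the copy in the second
#' network is delayed by `phase_lag / (2 pi freq)` seconds (exact FFT time
#' shift), so the first network leads in phase by `phase_lag` at the
#' coupling frequency. Uncoupled networks remain independent.
#'
#' @param spec a `synthetic_spec` with a valid `ts_spec`.
#' @return Named list (by subject id) of numeric matrices.
#' @export
generate_rsn_timeseries <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"), !is.null(spec$ts_spec))
  ts <- spec$ts_spec
  n <- spec$n_group_a + spec$n_group_b
  ids <- spec_subject_ids(spec)
  out <- lapply(seq_len(n), function(s) {
    set.seed(child_seed(spec$seed, "timeseries", s))
    M <- matrix(stats::rnorm(ts$n_networks * ts$n_samples),
                ts$n_networks, ts$n_samples)
    for (cp in ts$couplings) {
      sig <- narrowband_noise(ts$n_samples, ts$dt, cp$freq)
      lag_s <- cp$phase_lag / (2 * pi * cp$freq)
      M[cp$pair[1L], ] <- M[cp$pair[1L], ] + cp$strength * sig
      M[cp$pair[2L], ] <- M[cp$pair[2L], ] +
        cp$strength * fft_time_shift(sig, ts$dt, lag_s)
    }
    M
  })
  stats::setNames(out, ids)
}

# Gaussian-band-filtered white noise, centred on freq (Hz), unit variance.
narrowband_noise <- function(n, dt, freq, rel_bw = 1 / 8) {
  x <- stats::rnorm(n)
  xh <- stats::fft(x)
  f <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[seq_len(n)] / (n * dt)
  gain <- exp(-((abs(f) - freq)^2) / (2 * (rel_bw * freq)^2))
  y <- Re(stats::fft(xh * gain, inverse = TRUE)) / n
  as.vector(scale(y))
}

# delay x by lag_s seconds via the FFT shift theorem (circular)
fft_time_shift <- function(x, dt, lag_s) {
  n <- length(x)
  f <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[seq_len(n)] / (n * dt)
  Re(stats::fft(stats::fft(x) * exp(-2i * pi * f * lag_s), inverse = TRUE)) / n
}

#' Generate HDRS baseline and follow-up scores for assigned outcomes
#'
#' Baselines are drawn from the configured severity distribution (default
#' mean 24.4, SD 4.62), rounded and clipped to the instrument range
#' `[1, 52]`. Relative reductions are drawn per assigned outcome group
#' (PO-like: >= 0.5 in expectation; NO-like: < 0.5), follow-up scores are
#' rounded and clipped to `[0, 52]`, and where integer rounding would flip
#' the label across the 50% boundary the follow-up is nudged by one point
#' so that [label_outcome()] recovers the effective assignment exactly.
#' With `noise_rate > 0` each subject's assignment is first flipped with
#' that probability (so label recovery errs at the noise rate).
#'
#' @param spec a `synthetic_spec`.
#' @param outcome_assignment character vector of `"PO"` / `"NO"` per
#'   subject.
#' @return Data frame with `assigned`, `effective`, `hdrs_baseline`,
#'   `hdrs_followup`.
#' @export
generate_hdrs <- function(spec, outcome_assignment) {
  stopifnot(inherits(spec, "synthetic_spec"),
            all(outcome_assignment %in% c("PO", "NO")))
  hm <- spec$hdrs_model
  n <- length(outcome_assignment)
  set.seed(child_seed(spec$seed, "hdrs"))
  baseline <- pmin(pmax(round(stats::rnorm(n, hm$baseline_mean,
                                           hm$baseline_sd)), 1), 52)
  flip <- stats::runif(n) < (hm$noise_rate %||% 0)
  effective <- ifelse(flip,
                      ifelse(outcome_assignment == "PO", "NO", "PO"),
                      outcome_assignment)
  po <- effective == "PO"
  red <- numeric(n)
  red[po] <- rtrunc_norm(sum(po), hm$po_mean, hm$po_sd, 0.5, 1)
  red[!po] <- rtrunc_norm(sum(!po), hm$no_mean, hm$no_sd, -0.5,
                          0.5 - 1e-9)
  followup <- pmin(pmax(round(baseline * (1 - red)), 0), 52)
  rc <- (baseline - followup) / baseline
  fix_up <- po & rc < 0.5
  followup[fix_up] <- pmax(followup[fix_up] - 1, 0)
  fix_dn <- !po & rc >= 0.5
  followup[fix_dn] <- pmin(followup[fix_dn] + 1, 52)
  data.frame(assigned = outcome_assignment, effective = effective,
             hdrs_baseline = baseline, hdrs_followup = followup,
             stringsAsFactors = FALSE)
}

# truncated-normal draws by inverse-CDF (deterministic given the RNG state)
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n)
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}

#' Build the clinical table of a synthetic cohort
#'
#' For a diagnosis-style cohort: group A subjects (controls) get
#' low-severity baselines and no follow-up; group B subjects (patients) get
#' HDRS trajectories from [generate_hdrs()] under the supplied outcome
#' assignment.
#'
#' @param spec a `synthetic_spec`.
#' @param outcome_assignment `"PO"`/`"NO"` per group-B subject; default
#'   splits the group ~40/60.
#' @return Data frame: `subject_id`, `group`, `hdrs_baseline`,
#'   `hdrs_followup`, `outcome` (NA for group A).
#' @export
make_clinical_table <- function(spec, outcome_assignment = NULL) {
  g <- spec_groups(spec)
  ids <- spec_subject_ids(spec)
  nb <- spec$n_group_b
  if (is.null(outcome_assignment)) {
    n_po <- max(1L, round(0.4 * nb))
    outcome_assignment <- rep(c("PO", "NO"), c(n_po, nb - n_po))
  }
  stopifnot(length(outcome_assignment) == nb)
  hd <- generate_hdrs(spec, outcome_assignment)
  set.seed(child_seed(spec$seed, "hdrs_controls"))
  base_a <- pmin(pmax(round(stats::rnorm(spec$n_group_a, 0.67, 1.37)), 0), 52)
  out <- data.frame(
    subject_id = ids, group = g,
    hdrs_baseline = c(base_a, hd$hdrs_baseline),
    hdrs_followup = c(rep(NA_real_, spec$n_group_a), hd$hdrs_followup),
    stringsAsFactors = FALSE
  )
  out$outcome <- NA_character_
  out$outcome[g == spec$group_labels[2L]] <- hd$effective
  out
}
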