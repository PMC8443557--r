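#' Configuration for a simulated miniature-current recording
#'
#' Describes a voltage-clamp recording containing miniature synaptic events:
#' a homogeneous Poisson event train convolved with a difference-of-
#' exponentials kernel, plus additive Gaussian instrument noise. Defaults
#' describe a 60 s recording at 10 kHz with 1 Hz events of 15 pA mean peak
#' amplitude; amplitude and kinetic defaults are placeholders (no published
#' distributional parameters exist for these currents in marmoset cortex).
#'
#' @param seed Master seed; the generator is a pure function of the config.
#' @param duration_s Recording duration in seconds (> 0).
#' @param sampling_hz Sampling rate in Hz (> 0).
#' @param event_rate_hz Poisson event rate in Hz (>= 0).
#' @param amp_mean_pa Mean peak amplitude in pA (> 0).
#' @param amp_cv Coefficient of variation of peak amplitude (>= 0).
#' @param rise_ms,decay_ms Kernel rise and decay time constants in ms
#'   (rise < decay).
#' @param noise_sd_pa SD of additive white Gaussian noise in pA (>= 0).
#' @param polarity `"negative"` (inward currents, e.g. mEPSC at -65 mV) or
#'   `"positive"` (outward, e.g. mIPSC at 0 mV).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed, duration_s = 60, sampling_hz = 10000,
                       event_rate_hz = 1, amp_mean_pa = 15, amp_cv = 0.3,
                       rise_ms = 0.5, decay_ms = 5, noise_sd_pa = 2,
                       polarity = c("negative", "positive")) {
  polarity <- match.arg(polarity)
  cfg <- list(seed = seed, duration_s = duration_s, sampling_hz = sampling_hz,
              event_rate_hz = event_rate_hz, amp_mean_pa = amp_mean_pa,
              amp_cv = amp_cv, rise_ms = rise_ms, decay_ms = decay_ms,
              noise_sd_pa = noise_sd_pa, polarity = polarity)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field) if (!ok) stop("invalid sim_config field: ", field,
                                           call. = FALSE)
  chk(is.numeric(cfg$duration_s) && cfg$duration_s > 0, "duration_s")
  chk(is.numeric(cfg$sampling_hz) && cfg$sampling_hz > 0, "sampling_hz")
  chk(is.numeric(cfg$event_rate_hz) && cfg$event_rate_hz >= 0, "event_rate_hz")
  chk(is.numeric(cfg$amp_mean_pa) && cfg$amp_mean_pa > 0, "amp_mean_pa")
  chk(is.numeric(cfg$amp_cv) && cfg$amp_cv >= 0, "amp_cv")
  chk(is.numeric(cfg$rise_ms) && cfg$rise_ms > 0, "rise_ms")
  chk(is.numeric(cfg$decay_ms) && cfg$decay_ms > cfg$rise_ms, "decay_ms")
  chk(is.numeric(cfg$noise_sd_pa) && cfg$noise_sd_pa >= 0, "noise_sd_pa")
  chk(cfg$polarity %in% c("negative", "positive"), "polarity")
  invisible(cfg)
}

# Difference-of-exponentials kernel normalized so its peak equals 1
# (peak-amplitude parameterization: detection thresholds are amplitude-based).
mini_kernel <- function(rise_ms, decay_ms, sampling_hz) {
  tr <- rise_ms / 1000
  td <- decay_ms / 1000
  t_peak <- tr * td / (td - tr) * log(td / tr)
  support_s <- t_peak + 8 * td
  t <- seq(0, support_s, by = 1 / sampling_hz)
  k <- exp(-t / td) - exp(-t / tr)
  k / max(k)
}

#' Simulate a miniature-current trace with planted ground truth
#'
#' Event times are a homogeneous Poisson process; each event contributes a
#' peak-normalized difference-of-exponentials kernel scaled by a Gamma-
#' distributed positive amplitude (mean `amp_mean_pa`, CV `amp_cv`).
#' Overlapping events sum linearly. White Gaussian noise is added and the
#' polarity sign applied to the event deflections.
#'
#' @param cfg A [sim_config()].
#' @return A list with `trace` (a [trace()] object) and `truth`, a data frame
#'   of planted events (`time_s`, `amplitude_pa`), amplitudes positive.
#' @export
gen_mini_trace <- function(cfg) {
  validate_sim_config(cfg)
  n <- round(cfg$duration_s * cfg$sampling_hz)
  with_seed(derive_seed(cfg$seed, "mini_trace"), {
    n_ev <- stats::rpois(1L, cfg$event_rate_hz * cfg$duration_s)
    times <- sort(stats::runif(n_ev, 0, cfg$duration_s))
    if (cfg$amp_cv > 0) {
      shape <- 1 / cfg$amp_cv^2
      amps <- stats::rgamma(n_ev, shape = shape,
                            rate = shape / cfg$amp_mean_pa)
    } else {
      amps <- rep(cfg$amp_mean_pa, n_ev)
    }
    noise <- if (cfg$noise_sd_pa > 0) stats::rnorm(n, 0, cfg$noise_sd_pa)
             else numeric(n)
  })
  signal_pa <- numeric(n)
  if (n_ev > 0) {
    k <- mini_kernel(cfg$rise_ms, cfg$decay_ms, cfg$sampling_hz)
    for (i in seq_len(n_ev)) {
      i0 <- floor(times[i] * cfg$sampling_hz) + 1L
      idx <- i0:min(n, i0 + length(k) - 1L)
      signal_pa[idx] <- signal_pa[idx] + amps[i] * k[seq_along(idx)]
    }
  }
  sgn <- if (cfg$polarity == "negative") -1 else 1
  tr <- trace(sgn * signal_pa + noise, sampling_hz = cfg$sampling_hz,
              polarity = cfg$polarity)
  list(trace = tr,
       truth = data.frame(time_s = times, amplitude_pa = amps))
}

#' Simulate spine intensity profiles with planted diameters and volumes
#'
#' For each spine, transverse and axial 1-D Gaussian intensity profiles are
#' generated with sigma = true_diameter / 2 (so the fitted 2-sigma diameter
#' recovers the truth exactly at zero noise), a constant background offset,
#' and multiplicative noise. Optical density is proportional to the true
#' volume: `od = od_coeff * volume * (1 + noise)`.
#'
#' @param seed Master seed.
#' @param n_spines Number of spines.
#' @param diam_range_um Length-2 range of true diameters in um, within (0, 2].
#' @param profile_noise_frac Multiplicative noise fraction on intensities.
#' @param od_coeff OD units per um^3 (the calibration coefficient recovered
#'   downstream is `1 / od_coeff`).
#' @param od_noise_frac Multiplicative noise fraction on optical density.
#' @return List with `profiles` (data frame: `spine_id`, `axis` in t/a,
#'   `position_um`, `intensity`) and `truth` (data frame: `spine_id`,
#'   `d_t_um`, `d_a_um`, `volume_um3`, `optical_density`).
#' @export
gen_spine_profiles <- function(seed, n_spines = 20,
                               diam_range_um = c(0.2, 0.8),
                               profile_noise_frac = 0.05,
                               od_coeff = 2.5, od_noise_frac = 0.05) {
  stopifnot(length(diam_range_um) == 2, n_spines >= 1)
  if (any(diam_range_um <= 0) || any(diam_range_um > 2))
    stop("diam_range_um must lie within (0, 2]")
  with_seed(derive_seed(seed, "spine_profiles"), {
    d_t <- stats::runif(n_spines, diam_range_um[1], diam_range_um[2])
    d_a <- stats::runif(n_spines, diam_range_um[1], diam_range_um[2])
    vol <- spine_volume(d_t, d_a)
    od <- od_coeff * vol *
      (1 + od_noise_frac * stats::rnorm(n_spines))
    prof <- do.call(rbind, lapply(seq_len(n_spines), function(i) {
      one_axis <- function(axis, d) {
        x <- seq(-1.5 * d, 1.5 * d, length.out = 25)
        y <- 100 + 1000 * exp(-x^2 / (2 * (d / 2)^2))
        y <- y * (1 + profile_noise_frac * stats::rnorm(length(x)))
        data.frame(spine_id = i, axis = axis, position_um = x, intensity = y)
      }
      rbind(one_axis("t", d_t[i]), one_axis("a", d_a[i]))
    }))
  })
  list(profiles = prof,
       truth = data.frame(spine_id = seq_len(n_spines), d_t_um = d_t,
                          d_a_um = d_a, volume_um3 = vol,
                          optical_density = od))
}

#' Controlled vocabulary of call-type labels
#' @return Character vector of the seven call-type labels.
#' @export
call_types <- function() {
  c("ekk/cough", "phee", "trill", "tsik", "twitter",
    "phee-trill/trill-phee", "other")
}

#' Simulate an annotated call session
#'
#' Call types are i.i.d. categorical draws over the seven-label vocabulary;
#' onsets are ordered uniform draws over a 300 s session with short call
#' durations, so the table can also exercise bout merging.
#'
#' @param seed Master seed.
#' @param n_calls Number of calls (>= 0).
#' @param type_probs Named probability vector over [call_types()]; must sum
#'   to 1 within 1e-9. Unnamed vectors of length 7 are taken in the
#'   vocabulary order.
#' @return List with `calls` (data frame: `onset_s`, `offset_s`,
#'   `call_type`) and `truth` (list: `type_probs`, `counts`).
#' @export
gen_call_session <- function(seed, n_calls, type_probs) {
  labels <- call_types()
  if (is.null(names(type_probs))) {
    stopifnot(length(type_probs) == length(labels))
    names(type_probs) <- labels
  }
  extra <- setdiff(names(type_probs), c(labels, "noise-excluded"))
  if (length(extra)) stop("unknown call type(s): ", paste(extra, collapse = ", "))
  p <- type_probs[names(type_probs) != "noise-excluded"]
  if (any(p < 0)) stop("call-type probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-9)
    stop("call-type probabilities must sum to 1 (got ", sum(p), ")")
  full <- stats::setNames(rep(0, length(labels)), labels)
  full[names(p)] <- p
  if (n_calls == 0) {
    calls <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                        call_type = character(0))
    counts <- stats::setNames(rep(0L, length(labels)), labels)
    return(list(calls = calls, truth = list(type_probs = full, counts = counts)))
  }
  with_seed(derive_seed(seed, "call_session"), {
    type <- sample(labels, n_calls, replace = TRUE, prob = full)
    onset <- sort(stats::runif(n_calls, 0, 300))
    dur <- stats::runif(n_calls, 0.1, 0.5)
  })
  calls <- data.frame(onset_s = onset, offset_s = onset + dur,
                      call_type = type)
  counts <- table(factor(type, levels = labels))
  list(calls = calls,
       truth = list(type_probs = full,
                    counts = stats::setNames(as.integer(counts), labels)))
}

#' Configuration for the synthetic expression study
#'
#' Emulates a log2-scale expression matrix over a 3-age x 2-group design
#' with three planted clusters of differentially expressed genes whose
#' log fold-change trajectories differ in timing and sign: cluster 1
#' strongly down at birth, cluster 2 down in infancy, cluster 3 up in
#' infancy.
#'
#' @param seed Master seed.
#' @param n_genes Number of genes.
#' @param n_samples_per_cell Samples per (age x group) cell (>= 2).
#' @param baseline_mean,baseline_sd Per-gene baseline distribution
#'   (log2 units).
#' @param noise_sd Per-sample measurement noise SD (log2 units).
#' @param deg_fraction Fraction of genes that are planted DEGs.
#' @param cluster_fractions Length-3 split of DEGs across clusters
#'   (non-negative, sums to <= 1).
#' @param cluster_effects 3 x 3 matrix of planted logFC by (cluster x age),
#'   age columns ordered 0M, 3M, 6M.
#' @return An `expr_sim_config` list.
#' @export
expr_sim_config <- function(seed, n_genes = 5000, n_samples_per_cell = 8,
                            baseline_mean = 7, baseline_sd = 1.5,
                            noise_sd = 0.3, deg_fraction = 0.1,
                            cluster_fractions = c(0.4, 0.3, 0.3),
                            cluster_effects = rbind(c(-0.8, -0.2, -0.1),
                                                    c(-0.1, -0.7, -0.3),
                                                    c(0.1, 0.7, 0.3))) {
  if (any(n_samples_per_cell < 2))
    stop("n_samples_per_cell must be >= 2 in every cell (Welch test undefined)")
  if (any(cluster_fractions < 0) || sum(cluster_fractions) > 1 + 1e-12)
    stop("cluster_fractions must be non-negative and sum to <= 1")
  cluster_effects <- as.matrix(cluster_effects)
  if (!all(dim(cluster_effects) == c(3, 3)))
    stop("cluster_effects must be a 3 x 3 (cluster x age) matrix")
  colnames(cluster_effects) <- c("0M", "3M", "6M")
  structure(list(seed = seed, n_genes = n_genes,
                 n_samples_per_cell = n_samples_per_cell,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 noise_sd = noise_sd, deg_fraction = deg_fraction,
                 cluster_fractions = cluster_fractions,
                 cluster_effects = cluster_effects),
            class = "expr_sim_config")
}

#' Simulate an expression study with planted DEG trajectories
#'
#' Per-gene baselines are Normal(baseline_mean, baseline_sd^2); each sample
#' value is baseline + planted effect (exposed-group samples of a DEG gene
#' at age t receive `cluster_effects[cluster, t]`) + Normal(0, noise_sd^2).
#' Areas (A8, A12, TE) are assigned cyclically and treated as exchangeable
#' replicates.
#'
#' @param cfg An [expr_sim_config()].
#' @return List with `matrix` (genes x samples, log2), `metadata` (data
#'   frame: `sample_id`, `age`, `group`, `area`) and `truth` (data frame:
#'   `gene`, `is_deg`, `cluster` with `NA` for non-DEGs).
#' @export
gen_expression <- function(cfg) {
  stopifnot(inherits(cfg, "expr_sim_config"))
  ages <- c("0M", "3M", "6M")
  groups <- c("UE", "VPA")
  nsc <- cfg$n_samples_per_cell
  meta <- expand.grid(rep = seq_len(nsc), group = groups, age = ages,
                      stringsAsFactors = FALSE)[, c("age", "group", "rep")]
  meta$sample_id <- sprintf("%s_%s_%02d", meta$age, meta$group, meta$rep)
  meta$area <- rep_len(c("A8", "A12", "TE"), nrow(meta))
  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  n_deg <- round(cfg$deg_fraction * cfg$n_genes)
  # largest-remainder split of the DEG budget across the three clusters
  raw <- cfg$cluster_fractions * n_deg
  n_per_cluster <- floor(raw)
  short <- round(sum(cfg$cluster_fractions) * n_deg) - sum(n_per_cluster)
  if (short > 0) {
    bump <- order(raw - n_per_cluster, decreasing = TRUE)[seq_len(short)]
    n_per_cluster[bump] <- n_per_cluster[bump] + 1L
  }
  with_seed(derive_seed(cfg$seed, "expression"), {
    baseline <- stats::rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
    deg_idx <- sample.int(cfg$n_genes, sum(n_per_cluster))
    cluster <- rep(NA_integer_, cfg$n_genes)
    cluster[deg_idx] <- sample(rep.int(1:3, n_per_cluster))
    noise <- matrix(stats::rnorm(cfg$n_genes * nrow(meta), 0, cfg$noise_sd),
                    nrow = cfg$n_genes)
  })
  effect <- matrix(0, cfg$n_genes, nrow(meta))
  for (a in seq_along(ages)) {
    cols <- which(meta$age == ages[a] & meta$group == "VPA")
    for (cl in 1:3) {
      rows <- which(cluster == cl)
      if (length(rows)) effect[rows, cols] <- cfg$cluster_effects[cl, a]
    }
  }
  mat <- baseline + effect + noise
  dimnames(mat) <- list(genes, meta$sample_id)
  list(matrix = mat,
       metadata = meta[, c("sample_id", "age", "group", "area")],
       truth = data.frame(gene = genes, is_deg = !is.na(cluster),
                          cluster = cluster))
}

#' Simulate paired cross-species logFC tables with planted module concordance
#'
#' Per gene, `logFC_model` is Normal(0, effect_sd^2); the sign of
#' `logFC_ext` agrees with the model sign with the gene's module concordance
#' probability. Adjusted p-values are Uniform(0, 0.1) placeholders so the
#' tables satisfy the cross-table schema.
#'
#' @param seed Master seed.
#' @param module_sizes Named integer vector of genes per module (all >= 1).
#' @param concordance_probs Per-module sign-agreement probability in
#'   \[0, 1\]; recycled against `module_sizes` names.
#' @param effect_sd SD of logFC values.
#' @return List with `table` (data frame: `gene`, `logFC_model`,
#'   `padj_model`, `logFC_ext`, `padj_ext`), `module_map` (data frame:
#'   `gene`, `module`) and `truth` (named vector of planted concordance
#'   probabilities).
#' @export
gen_cross_species <- function(seed, module_sizes, concordance_probs,
                              effect_sd = 0.5) {
  if (any(module_sizes < 1)) stop("empty module in module_sizes")
  if (any(concordance_probs < 0 | concordance_probs > 1))
    stop("concordance_probs must lie in [0, 1]")
  if (is.null(names(module_sizes)))
    names(module_sizes) <- sprintf("M%02d", seq_along(module_sizes))
  concordance_probs <- rep_len(concordance_probs, length(module_sizes))
  names(concordance_probs) <- names(module_sizes)
  n <- sum(module_sizes)
  module <- rep(names(module_sizes), module_sizes)
  genes <- sprintf("%s_g%04d", module, unlist(lapply(module_sizes, seq_len)))
  with_seed(derive_seed(seed, "cross_species"), {
    lfc_a <- stats::rnorm(n, 0, effect_sd)
    agree <- stats::rbinom(n, 1L, concordance_probs[module]) == 1L
    mag_b <- abs(stats::rnorm(n, 0, effect_sd))
    padj_a <- stats::runif(n, 0, 0.1)
    padj_b <- stats::runif(n, 0, 0.1)
  })
  sgn_a <- ifelse(lfc_a >= 0, 1, -1)
  lfc_b <- ifelse(agree, sgn_a, -sgn_a) * mag_b
  list(table = data.frame(gene = genes, logFC_model = lfc_a,
                          padj_model = padj_a, logFC_ext = lfc_b,
                          padj_ext = padj_b),
       module_map = data.frame(gene = genes, module = module),
       truth = concordance_probs)
}
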