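#' Read a current trace from TSV
#'
#' Two-column layout (`time_s`, `current_pa`); the sampling rate is taken
#' from the time column spacing unless a `# sampling_hz:` comment line is
#' present.
#'
#' @param path TSV path.
#' @param polarity,condition,age Trace metadata (see [trace()]).
#' @return A [trace()].
#' @export
read_trace_tsv <- function(path, polarity = "negative", condition = "mEPSC",
                           age = "3M") {
  header <- readLines(path, n = 5L)
  fs <- NA_real_
  hit <- grep("^#\\s*sampling_hz:", header, value = TRUE)
  if (length(hit)) fs <- as.numeric(sub("^#\\s*sampling_hz:\\s*", "", hit[1]))
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  if (is.na(fs)) fs <- 1 / stats::median(diff(d$time_s))
  trace(d$current_pa, sampling_hz = fs, polarity = polarity,
        condition = condition, age = age)
}

#' Write a trace to TSV
#' @param tr A [trace()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_trace_tsv <- function(tr, path) {
  fs <- attr(tr, "sampling_hz")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# sampling_hz: %g", fs), con)
  utils::write.table(
    data.frame(time_s = (seq_along(tr) - 1) / fs, current_pa = as.numeric(tr)),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

pipeline_stages <- c("simulate", "ephys", "spines", "vocal", "degs",
                     "integrate")

default_run_config <- function() {
  list(seed = 1,
       out_dir = ".",
       stages = pipeline_stages,
       trace = list(duration_s = 60, event_rate_hz = 1, amp_mean_pa = 16,
                    noise_sd_pa = 2, age = "3M", condition = "mEPSC"),
       spines = list(n_spines = 24, profile_noise_frac = 0.05,
                     od_coeff = 2.5, od_noise_frac = 0.05),
       calls = list(n_calls = 200,
                    type_probs = c(0.05, 0.44, 0.2, 0.05, 0.15, 0.06, 0.05)),
       expr = list(n_genes = 2000),
       xspecies = list(module_sizes = c(M01 = 200, M02 = 200),
                       concordance_probs = c(0.9, 0.5)),
       degs = list(k_range = 1:8, n_restarts = 50),
       p_cut = 0.1)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Run the end-to-end synthetic/analysis pipeline
#'
#' Executes the enabled stages in dependency order (simulate, ephys,
#' spines, vocal, degs, integrate), writing each stage's outputs as TSV
#' files under `out_dir` plus a machine-readable `manifest.json` recording
#' the configuration, seed and an MD5 hash of every output. The same
#' config and seed reproduce byte-identical outputs.
#'
#' @param config A list (or path to a YAML file) overriding the default
#'   configuration; `seed` and `out_dir` are the commonly set fields, and
#'   `stages` selects a subset of stages.
#' @return The manifest, invisibly (list with `seed`, `stages`, `outputs`).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_run_config(), config)
  stages <- match.arg(cfg$stages, pipeline_stages, several.ok = TRUE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(cfg$out_dir, f)
  need <- function(f, stage, wanted_by) {
    if (!file.exists(path(f)))
      stop("stage '", wanted_by, "' requires '", f, "' from stage '", stage,
           "' (enable it or provide the file)")
    path(f)
  }
  outputs <- character(0)
  emit <- function(x, f) { write_tsv(x, path(f)); outputs <<- c(outputs, f) }

  if ("simulate" %in% stages) {
    scfg <- sim_config(seed = cfg$seed,
                       duration_s = cfg$trace$duration_s,
                       event_rate_hz = cfg$trace$event_rate_hz,
                       amp_mean_pa = cfg$trace$amp_mean_pa,
                       noise_sd_pa = cfg$trace$noise_sd_pa)
    mt <- gen_mini_trace(scfg)
    write_trace_tsv(mt$trace, path("trace.tsv"))
    outputs <- c(outputs, "trace.tsv")
    emit(mt$truth, "events_truth.tsv")

    sp <- gen_spine_profiles(cfg$seed, n_spines = cfg$spines$n_spines,
                             profile_noise_frac = cfg$spines$profile_noise_frac,
                             od_coeff = cfg$spines$od_coeff,
                             od_noise_frac = cfg$spines$od_noise_frac)
    emit(sp$profiles, "spine_profiles.tsv")
    emit(sp$truth[c("spine_id", "optical_density")], "spine_od.tsv")
    emit(sp$truth, "spine_truth.tsv")

    cs <- gen_call_session(cfg$seed, cfg$calls$n_calls, cfg$calls$type_probs)
    emit(cs$calls, "calls.tsv")

    ex <- gen_expression(expr_sim_config(cfg$seed, n_genes = cfg$expr$n_genes))
    emit(data.frame(gene = rownames(ex$matrix), ex$matrix,
                    check.names = FALSE), "expr_matrix.tsv")
    emit(ex$metadata, "expr_metadata.tsv")
    emit(ex$truth, "expr_truth.tsv")

    xs <- gen_cross_species(cfg$seed,
                            module_sizes = unlist(cfg$xspecies$module_sizes),
                            concordance_probs = cfg$xspecies$concordance_probs)
    emit(xs$table, "xspecies_table.tsv")
    emit(xs$module_map, "xspecies_modules.tsv")

    eff <- expr_sim_config(cfg$seed)$cluster_effects
    pheno <- rbind(spine_density_like = eff[1, ],
                   ei_ratio_like = eff[2, ],
                   ltd_like = -eff[3, ])
    emit(data.frame(phenotype = rownames(pheno), pheno, check.names = FALSE),
         "phenotype_trajectories.tsv")
  }

  if ("ephys" %in% stages) {
    tr <- read_trace_tsv(need("trace.tsv", "simulate", "ephys"),
                         age = cfg$trace$age, condition = cfg$trace$condition)
    dp <- detection_params(age = cfg$trace$age,
                           condition = cfg$trace$condition)
    ev <- detect_minis(tr, dp)
    emit(ev, "events.tsv")
    emit(summarize_cells(ev, condition = cfg$trace$condition,
                         age = cfg$trace$age, group = "synthetic"),
         "cell_summary.tsv")
  }

  if ("spines" %in% stages) {
    prof <- read_tsv(need("spine_profiles.tsv", "simulate", "spines"))
    od <- read_tsv(need("spine_od.tsv", "simulate", "spines"))
    fits <- fit_spine_profiles(prof)
    fits <- merge(fits, od, by = "spine_id")
    cal <- calibrate_od(fits)
    fits$volume_from_od_um3 <- estimate_volume_from_od(fits$optical_density,
                                                       cal)
    emit(fits, "spines.tsv")
    emit(data.frame(coefficient = cal$coefficient, n_used = cal$n_used,
                    n_excluded = cal$n_excluded), "od_calibration.tsv")
  }

  if ("vocal" %in% stages) {
    calls <- read_tsv(need("calls.tsv", "simulate", "vocal"))
    s <- summarize_session(calls)
    emit(data.frame(call_type = names(s$counts), count = s$counts,
                    ratio = s$ratios), "call_ratios.tsv")
    emit(data.frame(total_calls = s$total_calls,
                    entropy_bits = s$entropy_bits), "vocal_summary.tsv")
  }

  if ("degs" %in% stages) {
    m <- read_tsv(need("expr_matrix.tsv", "simulate", "degs"))
    mat <- as.matrix(m[, -1, drop = FALSE])
    rownames(mat) <- m$gene
    meta <- read_tsv(need("expr_metadata.tsv", "simulate", "degs"))
    degs <- deg_analysis(mat, meta)
    emit(degs, "deg_table.tsv")
    traj <- as.matrix(degs[degs$is_deg, grep("^logFC_", names(degs))])
    cm <- cluster_trajectories(traj, k_range = cfg$degs$k_range,
                               n_restarts = cfg$degs$n_restarts,
                               seed = cfg$seed)
    emit(data.frame(gene = degs$gene[degs$is_deg],
                    cluster = cm$assignments), "clusters.tsv")
    emit(cm$aic, "aic.tsv")
    emit(data.frame(cluster = rownames(cm$centroids), cm$centroids,
                    check.names = FALSE), "centroids.tsv")
  }

  if ("integrate" %in% stages) {
    cen <- read_tsv(need("centroids.tsv", "degs", "integrate"))
    centroids <- as.matrix(cen[, -1, drop = FALSE])
    rownames(centroids) <- as.character(cen$cluster)
    ph <- read_tsv(need("phenotype_trajectories.tsv", "simulate", "integrate"))
    pheno <- as.matrix(ph[, -1, drop = FALSE])
    rownames(pheno) <- ph$phenotype
    dm <- distance_matrix(centroids, pheno)
    emit(data.frame(cluster = rownames(dm), dm, check.names = FALSE),
         "distance_matrix.tsv")
    xt <- read_tsv(need("xspecies_table.tsv", "simulate", "integrate"))
    xm <- read_tsv(need("xspecies_modules.tsv", "simulate", "integrate"))
    emit(module_concordance(xt, xm), "module_concordance.tsv")
    sp <- cross_species_spearman(xt, p_cut = cfg$p_cut)
    emit(data.frame(rho = sp$rho, p.value = sp$p.value, n_genes = sp$n_genes),
         "xspecies_spearman.tsv")
  }

  manifest <- list(seed = cfg$seed, stages = stages,
                   config = cfg[setdiff(names(cfg), c("out_dir"))],
                   outputs = as.list(unname(tools::md5sum(
                     file.path(cfg$out_dir, outputs)))))
  names(manifest$outputs) <- outputs
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# Per-kind schema checks used by validate_inputs().
input_schemas <- list(
  trace = c("time_s", "current_pa"),
  events = c("time_s", "amplitude_pa"),
  spine_profiles = c("spine_id", "axis", "position_um", "intensity"),
  calls = c("onset_s", "call_type"),
  expr_matrix = "gene",
  expr_metadata = c("sample_id", "age", "group"),
  cross_table = c("gene", "logFC_model", "padj_model", "logFC_ext",
                  "padj_ext"),
  module_map = c("gene", "module"))

#' Validate pipeline input files
#'
#' Schema checks on every supplied TSV: required columns present, numeric
#' columns numeric, and (when both an expression matrix and its metadata
#' are given) every matrix sample present in the metadata.
#'
#' @param paths Named character vector or list of file paths; names must be
#'   input kinds (`trace`, `events`, `spine_profiles`, `calls`,
#'   `expr_matrix`, `expr_metadata`, `cross_table`, `module_map`).
#' @return Data frame: `kind`, `file`, `ok`, `message`.
#' @export
validate_inputs <- function(paths) {
  paths <- as.list(paths)
  if (is.null(names(paths)) || any(names(paths) == ""))
    stop("paths must be named by input kind")
  unknown <- setdiff(names(paths), names(input_schemas))
  if (length(unknown)) stop("unknown input kind(s): ",
                            paste(unknown, collapse = ", "))
  check_one <- function(kind, p) {
    if (!file.exists(p)) return(c(FALSE, "file not found"))
    d <- tryCatch(read_tsv(p, comment.char = "#"),
                  error = function(e) NULL)
    if (is.null(d)) return(c(FALSE, "unreadable as TSV"))
    missing <- setdiff(input_schemas[[kind]], names(d))
    if (length(missing))
      return(c(FALSE, paste("missing column(s):",
                            paste(missing, collapse = ", "))))
    num_cols <- switch(kind,
      trace = c("time_s", "current_pa"),
      events = c("time_s", "amplitude_pa"),
      spine_profiles = c("position_um", "intensity"),
      calls = "onset_s",
      expr_matrix = setdiff(names(d), "gene"),
      cross_table = c("logFC_model", "padj_model", "logFC_ext", "padj_ext"),
      character(0))
    for (cc in num_cols) {
      if (!is.numeric(d[[cc]])) {
        bad <- which(is.na(suppressWarnings(as.numeric(d[[cc]]))))[1]
        return(c(FALSE, sprintf("non-numeric value in column '%s' (row %d)",
                                cc, bad)))
      }
    }
    c(TRUE, "ok")
  }
  res <- t(vapply(names(paths),
                  function(k) check_one(k, paths[[k]]), character(2)))
  out <- data.frame(kind = names(paths), file = unlist(paths),
                    ok = res[, 1] == "TRUE", message = res[, 2])
  # cross-file check: every matrix sample must carry metadata
  if (all(c("expr_matrix", "expr_metadata") %in% names(paths)) &&
      all(out$ok[out$kind %in% c("expr_matrix", "expr_metadata")])) {
    m <- read_tsv(paths$expr_matrix)
    meta <- read_tsv(paths$expr_metadata)
    orphans <- setdiff(setdiff(names(m), "gene"), meta$sample_id)
    if (length(orphans)) {
      i <- out$kind == "expr_metadata"
      out$ok[i] <- FALSE
      out$message[i] <- paste("sample(s) missing from metadata:",
                              paste(orphans, collapse = ", "))
    }
  }
  rownames(out) <- NULL
  out
}
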