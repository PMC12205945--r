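#' Pipeline configuration
#'
#' Assembles (and validates) the configuration for [run_pipeline()].
#' Defaults describe the demonstration fixture: 16 MZ + 16 DZ families, a
#' 2-ROI box atlas on a 20 x 20 x 12 grid, 64 volumes per run. The
#' configuration can also be read from a flat key-value YAML file with
#' [read_pipeline_config()]; unknown keys are rejected.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed; every random draw in the pipeline flows from it
#'   through a documented splitting scheme (`stage_seed`).
#' @param stages named logical list enabling `simulate`, `metrics`, `twin`,
#'   `assoc`, `report`. Disabled stages expect their outputs to exist
#'   already under `out_dir`.
#' @param n_mz_pairs,n_dz_pairs cohort size.
#' @param n_roi number of atlas ROIs.
#' @param grid_shape,n_volumes,tr,voxel_size image geometry.
#' @param motion_scale simulator motion scale (mm).
#' @param p_missing_wave2,p_unpaired cohort missingness.
#' @param fd_threshold,scrub_threshold motion QC (mm).
#' @param band,full_range,fwhm,falff_mode local-metrics settings.
#' @param model_set candidate component sets for selection.
#' @param covariates mean-model covariates for the twin stage.
#' @param compute_ci compute profile CIs for the chosen model's
#'   standardized components (slower).
#' @param ci_level confidence level.
#' @param fdr_q FDR level applied within each test family.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "twinlocal_out", seed = 1L,
                            stages = list(simulate = TRUE, metrics = TRUE,
                                          twin = TRUE, assoc = TRUE,
                                          report = TRUE),
                            n_mz_pairs = 16, n_dz_pairs = 16, n_roi = 2,
                            grid_shape = c(20, 20, 12), n_volumes = 64,
                            tr = 0.93, voxel_size = 2, motion_scale = 0.02,
                            p_missing_wave2 = 0.25, p_unpaired = 0.1,
                            fd_threshold = 0.3, scrub_threshold = 0.5,
                            band = c(0.01, 0.08), full_range = c(0, 0.25),
                            fwhm = 6, falff_mode = "amplitude",
                            model_set = c("ACE", "AE", "CE", "E"),
                            covariates = c("age_years", "sex", "mean_fd_mm"),
                            compute_ci = FALSE, ci_level = 0.95,
                            fdr_q = 0.05) {
  stopifnot(fdr_q > 0, fdr_q < 1, n_roi >= 1, n_volumes >= 64,
            all(model_set %in% c("ACE", "AE", "CE", "E")))
  structure(as.list(environment()), class = "pipeline_config")
}

#' @param path flat key-value YAML file; vector values are comma-separated
#'   or YAML lists.
#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- read_flat_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}

# minimal flat "key: value" reader (comments with #, numeric/logical
# coercion, comma-separated vectors); stage toggles as stage_<name>: yes/no
read_flat_yaml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  stages <- NULL
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3) stop("cannot parse config line: ", ln)
    key <- kv[2]
    val <- parse_scalar_vec(kv[3])
    if (grepl("^stage_", key)) {
      if (is.null(stages)) stages <- list()
      stages[[sub("^stage_", "", key)]] <- isTRUE(val)
    } else out[[key]] <- val
  }
  if (!is.null(stages)) {
    full <- list(simulate = TRUE, metrics = TRUE, twin = TRUE,
                 assoc = TRUE, report = TRUE)
    full[names(stages)] <- stages
    out$stages <- full
  }
  out
}

parse_scalar_vec <- function(s) {
  parts <- trimws(strsplit(s, ",")[[1]])
  one <- function(x) {
    if (tolower(x) %in% c("true", "yes")) return(TRUE)
    if (tolower(x) %in% c("false", "no")) return(FALSE)
    n <- suppressWarnings(as.numeric(x))
    if (!is.na(n)) n else x
  }
  v <- lapply(parts, one)
  if (all(vapply(v, is.numeric, TRUE)) || all(vapply(v, is.logical, TRUE)) ||
      all(vapply(v, is.character, TRUE))) unlist(v) else unlist(v)
}

#' Derive a stage seed from the master seed
#'
#' Deterministic splitting: `(seed * 7919 + k) mod (2^31 - 1)`, with `k` a
#' fixed per-use offset. Keeps all derived seeds valid 32-bit integers.
#'
#' @param seed master seed.
#' @param k offset.
#' @return integer seed.
#' @export
stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k) %% 2147483647)
}

pipeline_log <- function(cfg, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
  message(msg)
  logfile <- file.path(cfg$out_dir, "pipeline.log")
  cat(msg, "\n", file = logfile, append = TRUE)
}

# ---- simulate stage ---------------------------------------------------------

# One cohort of families with shared covariates/missingness and one latent
# ACE phenotype per (ROI, channel). Channel "coh" drives voxel coherence
# (ReHo ground truth), channel "bf" the in-band amplitude fraction (fALFF
# ground truth). Phenotypes are mapped to (0,1) targets by plogis.
simulate_stage <- function(cfg) {
  dir.create(file.path(cfg$out_dir, "sim"), recursive = TRUE,
             showWarnings = FALSE)
  truth_paths <- cholesky_params(a = c(sqrt(0.4), 0.45, 0.35),
                                 c = c(sqrt(0.2), 0.30, 0.20),
                                 e = c(sqrt(0.4), 0.25, 0.50))
  channels <- as.vector(outer(seq_len(cfg$n_roi), c("coh", "bf"),
                              function(r, ch) paste0(ch, "_roi", r)))
  sims <- list()
  for (i in seq_along(channels)) {
    scfg <- twin_sim_config(
      n_mz_pairs = cfg$n_mz_pairs, n_dz_pairs = cfg$n_dz_pairs,
      cholesky_truth = truth_paths,
      beta_age = 0, beta_sex = 0, beta_fd = 0,
      p_missing_wave2 = 0, p_unpaired = 0,
      seed = stage_seed(cfg$seed, 100 + i))
    sims[[channels[i]]] <- simulate_twin_cohort(scfg)
  }
  base <- sims[[1]]$data
  # covariates come from the first phenotype; one shared missingness
  # pattern (family-level wave-2 attrition, per-family unpaired twins) is
  # applied to every phenotype
  cohort <- base[c("family_id", "twin_id", "birth_order", "zygosity",
                   "sex", "age_years", "mean_fd_mm", "wave")]
  miss <- with_seed(stage_seed(cfg$seed, 198), {
    fams <- unique(cohort$family_id)
    miss_w2 <- fams[stats::runif(length(fams)) < cfg$p_missing_wave2]
    unp <- fams[stats::runif(length(fams)) < cfg$p_unpaired]
    drop_bo <- sample(1:2, length(unp), replace = TRUE)
    (cohort$wave == 2 & cohort$family_id %in% miss_w2) |
      (cohort$family_id %in% unp &
         cohort$birth_order == drop_bo[match(cohort$family_id, unp)])
  })
  values <- lapply(sims, function(s) {
    v <- s$data$value
    v[miss] <- NA_real_
    v
  })
  # behavior scores: scale 1 loads on the ROI-1 coherence phenotype,
  # scale 2 is independent noise (null association)
  with_seed(stage_seed(cfg$seed, 199), {
    n <- nrow(cohort)
    cohort$behavior_1 <- 0.6 * values[[paste0("coh_roi", 1)]] +
      stats::rnorm(n, 0, sqrt(1 - 0.36))
    cohort$behavior_2 <- stats::rnorm(n)
  })
  for (ch in channels) cohort[[paste0("pheno_", ch)]] <- values[[ch]]
  utils::write.table(cohort, file.path(cfg$out_dir, "sim", "cohort.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_truth_json(sims[[1]]$truth,
                   file.path(cfg$out_dir, "sim", "truth.json"))
  atlas <- make_box_atlas(cfg$grid_shape, cfg$n_roi)
  write_atlas_nifti(atlas, file.path(cfg$out_dir, "sim", "atlas.nii.gz"),
                    cfg$voxel_size)
  # images per individual-wave with non-missing phenotypes
  idx <- which(!miss)
  pipeline_log(cfg, "simulate: ", length(idx), " acquisitions (AP+PA each)")
  for (j in idx) {
    coh <- vapply(seq_len(cfg$n_roi), function(r)
      stats::plogis(values[[paste0("coh_roi", r)]][j]), numeric(1))
    bf <- vapply(seq_len(cfg$n_roi), function(r)
      stats::plogis(values[[paste0("bf_roi", r)]][j]), numeric(1))
    fcfg <- fmri_sim_config(
      grid_shape = cfg$grid_shape, voxel_size = cfg$voxel_size,
      n_volumes = cfg$n_volumes, tr = cfg$tr,
      coherence_by_roi = stats::setNames(coh, seq_len(cfg$n_roi)),
      band_fraction_by_roi = stats::setNames(bf, seq_len(cfg$n_roi)),
      motion_scale = cfg$motion_scale,
      seed = stage_seed(cfg$seed, 1000 + j))
    sim <- simulate_fmri_run(fcfg, atlas)
    stem <- file.path(cfg$out_dir, "sim",
                      sprintf("%s_wave-%d", cohort$twin_id[j],
                              cohort$wave[j]))
    write_fmri_nifti(sim$ap, paste0(stem, "_ap.nii.gz"), cfg$voxel_size)
    write_fmri_nifti(sim$pa, paste0(stem, "_pa.nii.gz"), cfg$voxel_size)
    write_motion_params(sim$motion$AP, paste0(stem, "_ap.par"))
    write_motion_params(sim$motion$PA, paste0(stem, "_pa.par"))
  }
  invisible(NULL)
}

# ---- metrics stage ----------------------------------------------------------

metrics_stage <- function(cfg) {
  simdir <- file.path(cfg$out_dir, "sim")
  cohort <- utils::read.delim(file.path(simdir, "cohort.tsv"))
  atlas <- read_atlas_nifti(file.path(simdir, "atlas.nii.gz"))
  rows <- list()
  for (j in seq_len(nrow(cohort))) {
    stem <- file.path(simdir, sprintf("%s_wave-%d", cohort$twin_id[j],
                                      cohort$wave[j]))
    if (!file.exists(paste0(stem, "_ap.nii.gz"))) next
    runs <- list(ap = read_fmri_nifti(paste0(stem, "_ap.nii.gz"), cfg$tr, "AP"),
                 pa = read_fmri_nifti(paste0(stem, "_pa.nii.gz"), cfg$tr, "PA"))
    runs$ap$mask <- runs$pa$mask <- array(atlas$labels > 0, dim(atlas$labels))
    motion <- list(AP = read_motion_params(paste0(stem, "_ap.par")),
                   PA = read_motion_params(paste0(stem, "_pa.par")))
    rows[[length(rows) + 1]] <- run_metrics(
      cohort$twin_id[j], cohort$wave[j], runs, motion, atlas,
      fd_threshold = cfg$fd_threshold, scrub_threshold = cfg$scrub_threshold,
      band = cfg$band, full_range = cfg$full_range, fwhm = cfg$fwhm,
      voxel_size = cfg$voxel_size, falff_mode = cfg$falff_mode)
  }
  tab <- do.call(rbind, rows)
  write_metric_tsv(tab, file.path(cfg$out_dir, "metrics.tsv"))
  pipeline_log(cfg, "metrics: ", nrow(tab), " rows")
  invisible(tab)
}

# ---- twin stage -------------------------------------------------------------

metric_twin_table <- function(cfg, metric, roi) {
  cohort <- utils::read.delim(file.path(cfg$out_dir, "sim", "cohort.tsv"))
  met <- read_metric_tsv(file.path(cfg$out_dir, "metrics.tsv"))
  met <- met[met$metric == metric, ]
  key <- paste(met$subject, met$wave)
  val <- met[[paste0("roi_", roi)]]
  val[met$excluded] <- NA_real_
  cohort$value <- val[match(paste(cohort$twin_id, cohort$wave), key)]
  twin_data(cohort[c("family_id", "twin_id", "birth_order", "zygosity",
                     "sex", "age_years", "mean_fd_mm", "wave", "value")])
}

twin_stage <- function(cfg) {
  results <- list(); assum <- list(); covar <- list(); corr <- list()
  aictabs <- list(); fitdumps <- list()
  for (metric in c("ReHo", "fALFF")) for (roi in seq_len(cfg$n_roi)) {
    td <- metric_twin_table(cfg, metric, roi)
    if (sum(!is.na(td$value)) < 20) next
    label <- sprintf("%s_roi%d", metric, roi)
    at <- test_assumptions(td, cfg$covariates)
    at$trait <- label
    assum[[label]] <- at
    cv <- test_covariates_all(td, cfg$covariates)
    cv$trait <- label
    covar[[label]] <- cv
    tc <- twin_correlations(td, cfg$covariates)
    tc$trait <- label
    corr[[label]] <- tc
    seed_f <- stage_seed(cfg$seed, 3000 + roi)
    fits <- lapply(cfg$model_set, function(m)
      fit_cholesky(td, m, covariates = cfg$covariates, seed = seed_f))
    names(fits) <- cfg$model_set
    sel <- select_model(fits)
    ace <- fits[["ACE"]] %||% sel$chosen
    ampA <- test_amplification(ace, "A")
    ampC <- test_amplification(ace, "C")
    tests <- rbind(test_new_influence(ace, "A"),
                   test_new_influence(ace, "C"),
                   ampA[1:4], ampC[1:4])
    dec <- decompose_variance(sel$chosen)
    row <- data.frame(trait = label, metric = metric, roi = roi,
                      chosen = sel$name, ambiguous = sel$ambiguous,
                      minus2ll = sel$chosen$minus2ll,
                      aic = sel$chosen$aic,
                      std_A1 = dec$standardized["A", 1],
                      std_C1 = dec$standardized["C", 1],
                      std_E1 = dec$standardized["E", 1],
                      std_A2 = dec$standardized["A", 2],
                      std_C2 = dec$standardized["C", 2],
                      std_E2 = dec$standardized["E", 2],
                      raw_A1 = dec$raw["A", 1], raw_A2 = dec$raw["A", 2],
                      a22_chisq = tests$chisq[1], a22_p = tests$p[1],
                      c22_chisq = tests$chisq[2], c22_p = tests$p[2],
                      amp_A_chisq = tests$chisq[3], amp_A_p = tests$p[3],
                      amp_A_dir = ampA$direction,
                      amp_C_chisq = tests$chisq[4], amp_C_p = tests$p[4],
                      stringsAsFactors = FALSE)
    if (cfg$compute_ci && grepl("A", sel$name)) {
      ci <- tryCatch(profile_ci(sel$chosen, "std_A1", cfg$ci_level),
                     error = function(e) c(NA, NA))
      row$std_A1_lo <- ci[1]; row$std_A1_hi <- ci[2]
    }
    results[[label]] <- row
    ch <- sel$chosen$params
    fitdumps[[label]] <- list(
      chosen = sel$name, minus2ll = sel$chosen$minus2ll,
      aic = sel$chosen$aic, n_free = sel$chosen$n_free,
      paths = list(a = ch$a, c = ch$c, e = ch$e),
      mu = ch$mu,
      beta = if (!is.null(ch$beta)) as.data.frame(ch$beta))
    at2 <- sel$aic_table; at2$trait <- label
    aictabs[[label]] <- at2
  }
  out <- list(results = do.call(rbind, results),
              assumptions = do.call(rbind, assum),
              covariates = do.call(rbind, covar),
              correlations = do.call(rbind, corr),
              aic = do.call(rbind, aictabs))
  jsonlite::write_json(fitdumps, file.path(cfg$out_dir, "twin_fits.json"),
                       auto_unbox = TRUE, digits = NA)
  for (nm in names(out)) {
    utils::write.table(out[[nm]],
                       file.path(cfg$out_dir, paste0("twin_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  pipeline_log(cfg, "twin: ", nrow(out$results), " trait models")
  invisible(out)
}

# ---- association stage ------------------------------------------------------

assoc_stage <- function(cfg) {
  cohort <- utils::read.delim(file.path(cfg$out_dir, "sim", "cohort.tsv"))
  rows <- list()
  for (metric in c("ReHo", "fALFF")) for (roi in seq_len(cfg$n_roi)) {
    td <- metric_twin_table(cfg, metric, roi)
    for (b in c("behavior_1", "behavior_2")) {
      long <- data.frame(
        participant_id = td$twin_id, family_id = td$family_id,
        wave = td$wave - 1, age_years = td$age_years, sex = td$sex,
        mean_fd = td$mean_fd_mm, roi_value = td$value,
        behavior_score = cohort[[b]][match(paste(td$twin_id, td$wave),
                                           paste(cohort$twin_id, cohort$wave))],
        stringsAsFactors = FALSE)
      long <- long[stats::complete.cases(long), ]
      res <- tryCatch(suppressWarnings(fit_lmm(long)),
                      error = function(e) NULL)
      if (is.null(res)) next
      rows[[length(rows) + 1]] <- data.frame(
        metric = metric, roi = roi, behavior = b,
        estimate = res$estimate, se = res$se, z = res$z, p = res$p,
        singular_refit = res$singular_refit, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  utils::write.table(tab, file.path(cfg$out_dir, "assoc_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pipeline_log(cfg, "assoc: ", nrow(tab), " models")
  invisible(tab)
}

# ---- report stage -----------------------------------------------------------

report_stage <- function(cfg) {
  rd <- function(f) {
    p <- file.path(cfg$out_dir, f)
    if (file.exists(p)) utils::read.delim(p) else NULL
  }
  twin <- rd("twin_results.tsv")
  assum <- rd("twin_assumptions.tsv")
  covar <- rd("twin_covariates.tsv")
  assoc <- rd("assoc_results.tsv")
  # BH within each declared family, never across
  fdr_block <- function(tab, pcol = "p") {
    if (is.null(tab) || !nrow(tab)) return(tab)
    res <- bh_fdr(tab[[pcol]], cfg$fdr_q)
    tab$p_fdr <- res$p_adj
    tab$significant <- res$reject
    tab
  }
  covar <- fdr_block(covar)
  assum <- fdr_block(assum)
  if (!is.null(twin) && nrow(twin)) {
    ps <- c(twin$a22_p, twin$c22_p, twin$amp_A_p, twin$amp_C_p)
    res <- bh_fdr(ps, cfg$fdr_q)
    n <- nrow(twin)
    twin$a22_p_fdr <- res$p_adj[seq_len(n)]
    twin$c22_p_fdr <- res$p_adj[n + seq_len(n)]
    twin$amp_A_p_fdr <- res$p_adj[2 * n + seq_len(n)]
    twin$amp_C_p_fdr <- res$p_adj[3 * n + seq_len(n)]
  }
  assoc <- fdr_block(assoc)
  for (pair in list(list("twin_results.tsv", twin),
                    list("twin_assumptions.tsv", assum),
                    list("twin_covariates.tsv", covar),
                    list("assoc_results.tsv", assoc))) {
    if (!is.null(pair[[2]]))
      utils::write.table(pair[[2]], file.path(cfg$out_dir, pair[[1]]),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    package = "twinlocal",
    version = as.character(utils::packageVersion("twinlocal")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), c("stages"))],
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  s <- c(sprintf("twinlocal pipeline summary (seed %d)", cfg$seed),
         if (!is.null(twin)) sprintf(
           "trait %s: chosen %s, wave-1 A/C/E = %.2f/%.2f/%.2f%s",
           twin$trait, twin$chosen, twin$std_A1, twin$std_C1, twin$std_E1,
           ifelse(twin$ambiguous, " (AIC ambiguous)", "")),
         if (!is.null(assoc)) sprintf(
           "assoc %s roi%d ~ %s: beta = %.3f (p_fdr = %.3f)%s",
           assoc$metric, assoc$roi, assoc$behavior, assoc$estimate,
           assoc$p_fdr, ifelse(assoc$significant, " *", "")))
  writeLines(s, file.path(cfg$out_dir, "summary.txt"))
  pipeline_log(cfg, "report written")
  invisible(list(twin = twin, assumptions = assum, covariates = covar,
                 associations = assoc))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order: simulate (cohort with known ACE
#' ground truth + synthetic AP/PA runs), metrics (ReHo/fALFF ROI tables
#' with motion QC), twin (saturated checks, Cholesky model selection and
#' tests per ROI x metric), assoc (mixed-model brain-behavior screens),
#' report (BH-FDR within each of the four test families, result TSVs, JSON
#' manifest, text summary). Deterministic given `config$seed`; a stage
#' failure aborts with a machine-readable error record in
#' `<out_dir>/error.json`.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the report stage's result list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_fns <- list(simulate = simulate_stage, metrics = metrics_stage,
                    twin = twin_stage, assoc = assoc_stage,
                    report = report_stage)
  out <- NULL
  for (nm in names(stage_fns)) {
    if (!isTRUE(cfg$stages[[nm]])) next
    out <- tryCatch(stage_fns[[nm]](cfg), error = function(e) {
      rec <- list(stage = nm, error = conditionMessage(e),
                  time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
      jsonlite::write_json(rec, file.path(cfg$out_dir, "error.json"),
                           auto_unbox = TRUE)
      stop("pipeline stage '", nm, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  invisible(out)
}
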