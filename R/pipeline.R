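#' Run configuration
#'
#' Collects every pipeline knob in one validated object. `setup_mm` and
#' `range_pct` default to the site profile's clinical settings (5 mm /
#' 3.5% for prostate, 3 mm / 3.5% for head and neck) when `NULL`.
#'
#' @param site_profile `"mixed"`, `"prostate"` or `"head_neck"` (synthetic
#'   mode).
#' @param n_plans number of synthetic plans.
#' @param seed root RNG seed; recorded in all outputs.
#' @param bin_width DVH / EVH / RVH bin width (Gy).
#' @param rmsed_mean divide the RMSED sum of squares by 12 (see
#'   [compute_rmsed]).
#' @param output_dir output directory.
#' @param write_volumes also write every nominal/scenario dose and the four
#'   robustness-map volumes (NRRD) per plan.
#' @param force overwrite a non-empty output directory.
#' @param dose_manifest,mask_manifest optional CSV paths for real-volume
#'   mode: `dose_manifest` has columns `plan_id, scenario_id, path` (13 rows
#'   per plan: `nominal`, `U1`..`U12`); `mask_manifest` has columns
#'   `plan_id, roi, role, rx, path` and optionally `metrics`
#'   (semicolon-separated labels, e.g. `"V90%;V65%"`).
#' @param setup_mm,range_pct uncertainty magnitudes used to label scenario
#'   descriptors in manifest mode (and to override profile defaults in
#'   synthetic mode).
#' @return Object of class `run_config`.
#' @export
run_config <- function(site_profile = "mixed", n_plans = 20, seed = 1,
                       bin_width = 0.05, rmsed_mean = TRUE,
                       output_dir = "impt_robust_out", write_volumes = FALSE,
                       force = FALSE, dose_manifest = NULL, mask_manifest = NULL,
                       setup_mm = NULL, range_pct = NULL) {
  impt_check(site_profile %in% c("mixed", "prostate", "head_neck"),
             "site_profile must be mixed, prostate or head_neck",
             "impt_error_invalid_config")
  impt_check(is.numeric(seed) && length(seed) == 1L && abs(seed) < 2^31,
             "seed must be a single integer", "impt_error_invalid_config")
  impt_check(is.numeric(bin_width) && bin_width > 0, "bin_width must be > 0",
             "impt_error_invalid_config")
  if (!is.null(dose_manifest))
    impt_check(!is.null(mask_manifest),
               "manifest mode needs both dose_manifest and mask_manifest",
               "impt_error_invalid_config")
  structure(list(site_profile = site_profile, n_plans = as.integer(n_plans),
                 seed = as.integer(seed), bin_width = bin_width,
                 rmsed_mean = isTRUE(rmsed_mean), output_dir = output_dir,
                 write_volumes = isTRUE(write_volumes), force = isTRUE(force),
                 dose_manifest = dose_manifest, mask_manifest = mask_manifest,
                 setup_mm = setup_mm, range_pct = range_pct),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file whose keys are `run_config()` arguments.
#' @export
read_run_config <- function(path) {
  impt_check(file.exists(path), sprintf("config file not found: %s", path),
             "impt_error_missing_file")
  do.call(run_config, yaml::read_yaml(path))
}

# Load plans from dose/mask manifests (real-volume mode).
load_cohort_from_manifest <- function(config) {
  dm <- utils::read.csv(config$dose_manifest, stringsAsFactors = FALSE)
  mm <- utils::read.csv(config$mask_manifest, stringsAsFactors = FALSE)
  setup_mm <- config$setup_mm %||% 0
  range_pct <- config$range_pct %||% 0
  table <- build_scenario_table(setup_mm, range_pct)
  lapply(unique(dm$plan_id), function(pid) {
    rows <- dm[dm$plan_id == pid, ]
    need <- c("nominal", paste0("U", 1:12))
    missing <- setdiff(need, rows$scenario_id)
    if (length(missing))
      impt_abort(sprintf("plan %s: missing scenario %s in dose manifest",
                         pid, paste(missing, collapse = ", ")),
                 "impt_error_missing_scenario")
    grids <- lapply(need, function(sid)
      read_volume(rows$path[match(sid, rows$scenario_id)]))
    set <- assemble_scenario_set(grids[[1]], grids[-1], table)
    mrows <- mm[mm$plan_id == pid, ]
    impt_check(nrow(mrows) >= 1, sprintf("plan %s: no masks in manifest", pid),
               "impt_error_invalid_config")
    rx <- mrows$rx[1]
    masks <- lapply(seq_len(nrow(mrows)), function(i)
      read_mask(mrows$path[i], mrows$roi[i], mrows$role[i], rx = mrows$rx[i]))
    metrics <- stats::setNames(lapply(seq_len(nrow(mrows)), function(i) {
      role <- mrows$role[i]
      labels <- if (!is.null(mrows$metrics) && nzchar(mrows$metrics[i]))
        strsplit(mrows$metrics[i], ";")[[1]]
      else if (role == "target") "D95%" else "Dmean"
      lapply(labels, parse_metric_label,
             direction = if (role == "target") "lower_is_worse" else "higher_is_worse")
    }), mrows$roi)
    list(plan_id = pid, site = "manifest", rx = rx, seed = config$seed,
         spec = NULL, set = set, masks = masks, metrics = metrics,
         scenario_table = table, abutting_oar = NA_character_)
  })
}

write_run_csv <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full robustness-evaluation pipeline
#'
#' Generates (or loads) the cohort, computes the robustness maps, the DVH
#' band / physical-scenario worst-case metrics, the voxel-wise worst-case
#' metrics and the EVH/RVH AUCs for every ROI, then the method-comparison
#' table, the stratum correlation matrices and the conservativeness summary.
#' All CSV outputs plus a run manifest (file list with MD5 hashes, the seed
#' and the config hash) are written under `config$output_dir`. Rerunning
#' with the same config reproduces all CSVs bit-identically.
#'
#' @param config a [run_config] (or YAML path understood by
#'   [read_run_config]).
#' @return Invisibly, a list with `table` (the `method_table`),
#'   `correlations`, `conservativeness`, `cohort_manifest`, `output_dir`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  impt_check(inherits(config, "run_config"), "config must be a run_config",
             "impt_error_invalid_config")
  dir <- config$output_dir
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !config$force)
    impt_abort(sprintf("output directory %s is not empty (use force = TRUE)", dir),
               "impt_error_output_exists")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- if (!is.null(config$dose_manifest)) load_cohort_from_manifest(config)
            else generate_cohort(config$n_plans, config$site_profile, config$seed)

  tbl <- build_method_table(cohort, bin_width = config$bin_width,
                            rmsed_mean = config$rmsed_mean)
  # a stratum with < 3 rows carries no correlation information; emit nothing
  cors <- do.call(rbind, lapply(c("ctv", "oar"), function(st) {
    role <- if (st == "ctv") "target" else "oar"
    if (sum(tbl$role == role) >= 3) pearson_matrix(tbl, st) else NULL
  }))
  if (is.null(cors))
    cors <- data.frame(stratum = character(), var1 = character(),
                       var2 = character(), r = numeric(), p = numeric(),
                       p_holm = numeric(), n = integer(), flag = character())
  cons <- summarize_conservativeness(tbl)
  cohort_manifest <- do.call(rbind, lapply(cohort, function(p) data.frame(
    plan_id = p$plan_id, site = p$site, rx = p$rx, seed = p$seed,
    roi = vapply(p$masks, `[[`, "", "name"),
    role = vapply(p$masks, `[[`, "", "role"),
    stringsAsFactors = FALSE)))

  files <- c(write_run_csv(tbl, dir, "method_table.csv"),
             write_run_csv(cors, dir, "correlations.csv"),
             write_run_csv(cons, dir, "conservativeness.csv"),
             write_run_csv(cohort_manifest, dir, "cohort_manifest.csv"))

  if (config$write_volumes) {
    for (p in cohort) {
      maps <- compute_maps(p$set, mean = config$rmsed_mean)
      files <- c(files, write_maps(maps, file.path(dir, p$plan_id)))
      for (sid in names(scenario_grids(p$set))) {
        vp <- file.path(dir, sprintf("%s_%s.nrrd", p$plan_id, sid))
        write_volume(scenario_grids(p$set)[[sid]], vp)
        files <- c(files, vp)
      }
    }
  }

  cfg_path <- file.path(dir, "config.yaml")
  cfg <- config[!vapply(config, is.null, logical(1))]
  yaml::write_yaml(cfg[setdiff(names(cfg), c("output_dir", "force"))], cfg_path)
  manifest <- data.frame(file = basename(c(files, cfg_path)),
                         md5 = unname(tools::md5sum(c(files, cfg_path))),
                         seed = config$seed, stringsAsFactors = FALSE)
  write_run_csv(manifest, dir, "run_manifest.csv")
  invisible(list(table = tbl, correlations = cors, conservativeness = cons,
                 cohort_manifest = cohort_manifest, output_dir = dir))
}
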