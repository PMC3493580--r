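#' Validate a pipeline configuration file
#'
#' Reads a YAML (or JSON) run configuration, checks it, and returns it as a
#' `run_config` object. All problems are collected and reported together,
#' not just the first.
#'
#' A configuration names an `output_dir`, an integer `seed`, the `stages`
#' to run (any of `fluct`, `ed`, `hbond`, `stack`, `ti`, `tautomer`,
#' `linkage`), the input paths each requested stage needs (`trajectory`
#' for the trajectory-based stages, `ti$tables` mapping lambda values to
#' dH/dlambda files, `tautomer$conformer_table`), and per-stage parameter
#' blocks.
#'
#' @param path Path to the configuration file (`.json` parsed as JSON,
#'   anything else as YAML).
#' @return A `run_config` list.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  problems <- character(0)
  need <- function(cond, msg) if (!cond) problems <<- c(problems, msg)

  need(!is.null(cfg$output_dir), "missing field: output_dir")
  need(!is.null(cfg$stages) && length(cfg$stages) > 0, "missing field: stages")
  known <- c("fluct", "ed", "hbond", "stack", "ti", "tautomer", "linkage")
  if (!is.null(cfg$stages)) {
    bad <- setdiff(cfg$stages, known)
    need(length(bad) == 0,
         sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  }
  if (!is.null(cfg$seed)) {
    need(is.numeric(cfg$seed) && length(cfg$seed) == 1 &&
           cfg$seed == round(cfg$seed),
         "field `seed` must be a single integer")
  } else {
    cfg$seed <- 1L
  }
  traj_stages <- intersect(cfg$stages, c("fluct", "ed", "hbond", "stack"))
  if (length(traj_stages)) {
    need(!is.null(cfg$trajectory), "missing field: trajectory")
    if (!is.null(cfg$trajectory)) {
      need(file.exists(cfg$trajectory),
           sprintf("trajectory file not found: %s", cfg$trajectory))
    }
  }
  if (!is.null(cfg$apo_trajectory)) {
    need(file.exists(cfg$apo_trajectory),
         sprintf("apo trajectory file not found: %s", cfg$apo_trajectory))
  }
  if ("hbond" %in% cfg$stages) {
    need(!is.null(cfg$hbond$donors) && !is.null(cfg$hbond$acceptors),
         "stage hbond needs fields hbond$donors and hbond$acceptors")
  }
  if ("stack" %in% cfg$stages) {
    need(!is.null(cfg$stack$ring_a) && !is.null(cfg$stack$ring_b),
         "stage stack needs fields stack$ring_a and stack$ring_b")
  }
  if ("ti" %in% cfg$stages) {
    need(!is.null(cfg$ti$tables), "stage ti needs field ti$tables")
    if (!is.null(cfg$ti$tables)) {
      miss <- unlist(cfg$ti$tables)[!file.exists(unlist(cfg$ti$tables))]
      need(length(miss) == 0,
           sprintf("ti table file(s) not found: %s", paste(miss, collapse = ", ")))
    }
  }
  if ("tautomer" %in% cfg$stages) {
    need(!is.null(cfg$tautomer$conformer_table),
         "stage tautomer needs field tautomer$conformer_table")
    if (!is.null(cfg$tautomer$conformer_table)) {
      need(file.exists(cfg$tautomer$conformer_table),
           sprintf("conformer table not found: %s", cfg$tautomer$conformer_table))
    }
  }
  if ("linkage" %in% cfg$stages) {
    need(!is.null(cfg$linkage$ddmu_a) && !is.null(cfg$linkage$ddmu_b),
         "stage linkage needs fields linkage$ddmu_a and linkage$ddmu_b")
    if (!("tautomer" %in% cfg$stages)) {
      need(!is.null(cfg$linkage$k_taut),
           "stage linkage needs linkage$k_taut when the tautomer stage is not run")
    }
  }
  if (length(problems)) {
    abort(paste(c("invalid configuration:", paste("-", problems)),
                collapse = "\n"))
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes the requested stages in dependency order (`linkage` consumes
#' the `tautomer` stage's equilibrium constant when both are requested;
#' all other stages are independent). A failing stage is recorded with its
#' error message and aborts only its dependents; independent stages still
#' run. The report is always written to `<output_dir>/report.json`,
#' together with per-stage CSV outputs, and carries provenance (package
#' version, config hash, seed) sufficient to re-run the identical
#' analysis.
#'
#' @param config A `run_config` from [validate_config()], or a path to a
#'   configuration file.
#' @return A `pipeline_report` list with elements `results` (per-stage
#'   blocks), `errors`, `provenance` and `status` (0 if every requested
#'   stage succeeded).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  results <- list()
  errors <- list()
  run_stage <- function(name, fn) {
    tryCatch(results[[name]] <<- fn(),
             error = function(e) errors[[name]] <<- conditionMessage(e))
  }

  traj <- NULL
  if (length(intersect(config$stages, c("fluct", "ed", "hbond", "stack")))) {
    traj <- tryCatch(read_multimodel_pdb(config$trajectory),
                     error = function(e) {
                       errors[["trajectory"]] <<- conditionMessage(e)
                       NULL
                     })
  }
  sel_from <- function(spec_sel) {
    if (is.null(spec_sel)) NULL
    else do.call(select_atoms, c(list(traj), spec_sel))
  }

  if ("fluct" %in% config$stages && !is.null(traj)) {
    run_stage("fluct", function() {
      discard <- config$fluct$discard_frames %||% 0L
      tr <- traj
      if (discard > 0 && discard < n_frames(tr)) {
        tr <- trajectory(tr$atoms,
                         tr$coords[-seq_len(discard), , , drop = FALSE])
      }
      sel <- sel_from(config$selection)
      rs <- rmsd_series(tr, 1L, sel)
      rf <- per_atom_rmsf(tr, sel)
      utils::write.csv(rs, file.path(config$output_dir, "rmsd_series.csv"),
                       row.names = FALSE)
      utils::write.csv(rf, file.path(config$output_dir, "rmsf.csv"),
                       row.names = FALSE)
      be <- block_standard_error(rs$rmsd_nm)
      out <- list(mean_rmsd_nm = be$mean, mean_rmsd_se_nm = be$standard_error,
                  mean_rmsf_nm = mean(rf$value_nm), n_frames = n_frames(tr))
      if (!is.null(config$apo_trajectory)) {
        apo <- read_multimodel_pdb(config$apo_trajectory)
        prof_c <- per_residue_rmsd(tr, 1L, sel)
        prof_a <- per_residue_rmsd(apo, 1L, sel)
        dd <- delta_rmsd(prof_c, prof_a)
        utils::write.csv(dd, file.path(config$output_dir, "delta_rmsd.csv"),
                         row.names = FALSE)
        out$max_abs_delta_rmsd_nm <- max(abs(dd$value_nm))
      }
      out
    })
  }
  if ("ed" %in% config$stages && !is.null(traj)) {
    run_stage("ed", function() {
      sel <- sel_from(config$selection)
      model <- build_covariance(traj, sel)
      proj <- project_trajectory(traj, model)
      basins <- extract_basins(proj,
                               grid_bins = config$ed$grid_bins %||% 50L,
                               n_basins = config$ed$n_basins %||% 1L)
      utils::write.csv(tidy(model),
                       file.path(config$output_dir, "eigenvalues.csv"),
                       row.names = FALSE)
      utils::write.csv(proj, file.path(config$output_dir, "projection.csv"),
                       row.names = FALSE)
      jsonlite::write_json(basins, file.path(config$output_dir, "basins.json"),
                           dataframe = "rows", auto_unbox = TRUE, digits = NA)
      for (b in seq_len(nrow(basins))) {
        f <- basins$representative_frame[b]
        write_multimodel_pdb(
          trajectory(traj$atoms, traj$coords[f, , , drop = FALSE]),
          file.path(config$output_dir, sprintf("basin_%d_representative.pdb", b)))
      }
      list(trace_nm2 = model$trace,
           eigenvalues_nm2 = head(model$eigenvalues, 20),
           basins = as.data.frame(basins))
    })
  }
  if ("hbond" %in% config$stages && !is.null(traj)) {
    run_stage("hbond", function() {
      crit <- do.call(hbond_criterion, config$hbond$criterion %||% list())
      hb <- hbond_count(traj, config$hbond$donors, config$hbond$acceptors,
                        crit)
      utils::write.csv(hb, file.path(config$output_dir, "hbond_counts.csv"),
                       row.names = FALSE)
      be <- attr(hb, "block_error")
      list(mean_count = be$mean, se = be$standard_error,
           criterion = unclass(crit))
    })
  }
  if ("stack" %in% config$stages && !is.null(traj)) {
    run_stage("stack", function() {
      ss <- stacking_series(traj, unlist(config$stack$ring_a),
                            unlist(config$stack$ring_b))
      utils::write.csv(ss, file.path(config$output_dir, "stacking.csv"),
                       row.names = FALSE)
      occ <- do.call(stacking_occupancy,
                     c(list(ss), config$stack$thresholds %||% list()))
      list(occupancy = as.numeric(occ), thresholds = attr(occ, "thresholds"))
    })
  }
  if ("ti" %in% config$stages) {
    run_stage("ti", function() {
      tabs <- config$ti$tables
      lam <- as.numeric(names(tabs))
      ord <- order(lam)
      samples <- lapply(unlist(tabs)[ord],
                        function(p) read_dhdl_table(p)$dhdl)
      prof <- ti_profile(lam[ord], samples,
                         temperature = config$ti$temperature %||% 300)
      fe <- integrate_ti(prof, n_blocks = config$ti$n_blocks %||% 3L)
      list(delta_f_kj_mol = fe$value, se_kj_mol = fe$standard_error,
           temperature_k = fe$temperature, n_lambda = length(lam))
    })
  }
  if ("tautomer" %in% config$stages) {
    run_stage("tautomer", function() {
      tab <- utils::read.csv(config$tautomer$conformer_table,
                             stringsAsFactors = FALSE)
      eq <- tautomer_equilibrium(tab,
                                 temperature = config$tautomer$temperature %||% 300)
      list(K = eq$K, delta_mu_kj_mol = eq$delta_mu,
           temperature_k = eq$temperature)
    })
  }
  if ("linkage" %in% config$stages) {
    run_stage("linkage", function() {
      k <- if (!is.null(results$tautomer)) results$tautomer$K
           else config$linkage$k_taut
      if (is.null(k)) abort("tautomer stage failed and no linkage$k_taut given")
      tt <- config$linkage$temperature %||% 300
      list(bound_ratio = bound_tautomer_ratio(k, config$linkage$ddmu_a,
                                              config$linkage$ddmu_b, tt),
           k_taut = k, temperature_k = tt)
    })
  }

  report <- list(
    results = results,
    errors = errors,
    provenance = list(
      package_version = as.character(utils::packageVersion("tidytraj")),
      seed = config$seed,
      stages = config$stages,
      config_hash = .config_hash(config)),
    status = if (length(errors)) 1L else 0L)
  class(report) <- "pipeline_report"
  jsonlite::write_json(report[c("results", "errors", "provenance", "status")],
                       file.path(config$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "rows")
  report
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> status %d; stages: %s\n", x$status,
              paste(names(x$results), collapse = ", ")))
  if (length(x$errors)) {
    cat("failed:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}
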