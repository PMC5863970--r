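# Delimited-text readers/writers for the pipeline's tabular artifacts.
# Dialect: UTF-8, header required, "." decimal; comma by default, any
# single-character delimiter (e.g. "\t") via `sep`.

# read a delimited file as character and convert named columns to numeric,
# reporting the first offending cell by row and column
.read_numeric_table <- function(path, numeric_cols, required_cols, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", stringsAsFactors = FALSE,
                           check.names = TRUE, comment.char = "",
                           encoding = "UTF-8")
  missing_cols <- setdiff(required_cols, names(raw))
  if (length(missing_cols)) {
    stop("`", basename(path), "` lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (cl in intersect(numeric_cols, names(raw))) {
    vals <- raw[[cl]]
    empty <- is.na(vals) | vals == "" | vals == "NA"
    parsed <- suppressWarnings(as.numeric(vals))
    bad <- which(!empty & is.na(parsed))
    if (length(bad)) {
      stop("`", basename(path), "`: cannot parse \"", vals[bad[1L]],
           "\" as a number (row ", bad[1L], ", column `", cl, "`)",
           call. = FALSE)
    }
    raw[[cl]] <- parsed
  }
  raw
}

#' Read a ligand descriptor table
#'
#' Reads a delimited text file with one row per ligand and validates it via
#' [as_ligand_table()]. Required columns: `id`, `mw_da`, `n_hba`, `n_hbd`,
#' `logp`; recognised optional descriptor columns are converted to numeric
#' when present, and empty cells become `NA`.
#'
#' @param path Path to a CSV/TSV file with a header.
#' @param sep Field delimiter (default comma; use `"\t"` for TSV).
#' @return A [as_ligand_table()].
#' @export
read_ligand_table <- function(path, sep = ",") {
  numeric_cols <- c("mw_da", "n_hba", "n_hbd", "logp", "tpsa_a2", "nha",
                    "n_polar", "n_tdof", "n_rot", "n_rb", "formal_charge")
  raw <- .read_numeric_table(path, numeric_cols,
                             c("id", "mw_da", "n_hba", "n_hbd", "logp"), sep)
  as_ligand_table(raw)
}

#' Read a run-level docking result table
#'
#' @param path Path to a CSV/TSV file with a header and columns
#'   `ligand_id`, `crystal_id`, `binding_energy_kcal`; optional `target`,
#'   `run_index`, `torsional_kcal`, `cluster_id`.
#' @inheritParams read_ligand_table
#' @return Data frame of docking runs.
#' @export
read_docking_table <- function(path, sep = ",") {
  runs <- .read_numeric_table(
    path,
    numeric_cols = c("binding_energy_kcal", "torsional_kcal", "run_index",
                     "cluster_id"),
    required_cols = c("ligand_id", "crystal_id", "binding_energy_kcal"),
    sep = sep)
  if (any(is.na(runs$binding_energy_kcal))) {
    stop("`", basename(path), "`: missing binding energy in row(s) ",
         paste(utils::head(which(is.na(runs$binding_energy_kcal)), 5),
               collapse = ", "), call. = FALSE)
  }
  if ("torsional_kcal" %in% names(runs) &&
      any(!is.na(runs$torsional_kcal) & runs$torsional_kcal < 0)) {
    stop("torsional free energy must be non-negative", call. = FALSE)
  }
  runs
}

#' Write a table in the pipeline's delimited-text dialect
#'
#' @param x Data frame.
#' @param path Output path.
#' @param sep Field delimiter.
#' @return `path`, invisibly.
#' @export
write_delim_table <- function(x, path, sep = ",") {
  utils::write.table(x, path, sep = sep, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the full docking post-processing pipeline
#'
#' Orchestrates screen -> summarize -> aggregate -> indices -> plot-data ->
#' rank on file inputs and writes every artifact to `out_dir`:
#' `lipinski_verdicts.csv`, `crystal_summaries.csv`,
#' `campaign_summaries.csv`, `ranking.csv`, `efficiency_indices.csv`,
#' `plot_points.csv`, `plot_lines.csv`, `leads.csv` and a `pipeline_log.txt`
#' recording parameters, stage counts, the package version and a hash of
#' the configuration. Only ligands passing the Lipinski screen are carried
#' into docking aggregation. Reruns on identical inputs produce
#' byte-identical outputs.
#'
#' @param ligand_file Path to the ligand descriptor table.
#' @param runs_file Path to the run-level docking table.
#' @param out_dir Output directory (created if needed).
#' @param z Critical value for confidence intervals.
#' @param temperature_k Temperature for the thermodynamic conversions, K.
#' @param max_violations Lipinski screening policy (0 = strict).
#' @param leads_k Number of lead compounds per target.
#' @param sep Field delimiter of input and output tables.
#' @return Invisibly, a list with the fitted [dock_campaign()] object and
#'   the paths of all written files.
#' @export
run_pipeline <- function(ligand_file, runs_file, out_dir,
                         z = 1.96, temperature_k = 298.15,
                         max_violations = 0, leads_k = 3, sep = ",") {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- thermo_config(temperature_k = temperature_k)
  params <- list(ligand_file = ligand_file, runs_file = runs_file, z = z,
                 temperature_k = temperature_k,
                 max_violations = max_violations, leads_k = leads_k,
                 sep = sep)
  cfg_file <- tempfile(fileext = ".txt")
  writeLines(deparse(params), cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)

  ligands <- stage("read", read_ligand_table(ligand_file, sep))
  runs <- stage("read", read_docking_table(runs_file, sep))

  screened <- stage("screen", filter_library(ligands, max_violations))
  kept <- runs$ligand_id %in% screened$passing$id
  if (!any(kept)) {
    stop("[stage screen] no docking runs remain after the Lipinski screen",
         call. = FALSE)
  }
  fit <- stage("aggregate",
               dock_campaign(runs[kept, , drop = FALSE],
                             ligands = screened$passing, z = z, config = cfg,
                             leads_k = leads_k))
  plot_data <- stage("plot-data", {
    if (is.null(fit$profiles)) list(points = NULL, lines = NULL)
    else bivariate_plot_data(fit$profiles)
  })

  files <- c(
    lipinski_verdicts = "lipinski_verdicts.csv",
    crystal_summaries = "crystal_summaries.csv",
    campaign_summaries = "campaign_summaries.csv",
    ranking = "ranking.csv",
    efficiency_indices = "efficiency_indices.csv",
    plot_points = "plot_points.csv",
    plot_lines = "plot_lines.csv",
    leads = "leads.csv")
  paths <- file.path(out_dir, files)
  names(paths) <- names(files)
  stage("write", {
    write_delim_table(screened$verdicts, paths["lipinski_verdicts"], sep)
    write_delim_table(fit$crystal_summaries, paths["crystal_summaries"], sep)
    write_delim_table(fit$campaign_summaries, paths["campaign_summaries"], sep)
    write_delim_table(fit$ranking, paths["ranking"], sep)
    if (!is.null(fit$profiles)) {
      write_delim_table(fit$profiles, paths["efficiency_indices"], sep)
      write_delim_table(plot_data$points, paths["plot_points"], sep)
      write_delim_table(plot_data$lines, paths["plot_lines"], sep)
      leads_df <- do.call(rbind, lapply(names(fit$leads), function(tg) {
        data.frame(target = tg, rank = seq_along(fit$leads[[tg]]),
                   ligand_id = fit$leads[[tg]], stringsAsFactors = FALSE)
      }))
      write_delim_table(leads_df, paths["leads"], sep)
    }
  })

  log_path <- file.path(out_dir, "pipeline_log.txt")
  log_lines <- c(
    paste0("dockrank ", as.character(utils::packageVersion("dockrank"))),
    paste0("config_hash: ", cfg_hash),
    paste0("parameters: z=", z, " T=", temperature_k,
           "K max_violations=", max_violations, " leads_k=", leads_k),
    paste0("ligands_in: ", nrow(ligands)),
    paste0("ligands_pass_lipinski: ", nrow(screened$passing)),
    paste0("runs_in: ", nrow(runs)),
    paste0("runs_kept: ", sum(kept)),
    paste0("crystal_groups: ", nrow(fit$crystal_summaries)),
    paste0("campaign_groups: ", nrow(fit$campaign_summaries)))
  writeLines(log_lines, log_path)

  invisible(list(campaign = fit,
                 files = c(paths, pipeline_log = log_path),
                 config_hash = cfg_hash))
}
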