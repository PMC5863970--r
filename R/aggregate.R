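#' Summarize docking runs for one ligand on one receptor crystal
#'
#' Reduces the repeated docking runs of a single ligand against a single
#' crystal to its per-crystal summary: lowest (best) energy, mean energy,
#' the inhibition constant of the lowest energy, and the number of distinct
#' conformational clusters when cluster labels are supplied.
#'
#' @param runs Data frame of run-level results sharing one `ligand_id` and
#'   one `crystal_id`, with column `binding_energy_kcal` and optionally
#'   `cluster_id` and `target`.
#' @param config A [thermo_config()] used for the Ki conversion.
#' @return One-row data frame: `ligand_id`, `crystal_id`, `n_runs`,
#'   `n_clusters` (NA without cluster labels), `lowest_energy_kcal`,
#'   `mean_energy_kcal`, `lowest_ki_nm`.
#' @seealso [summarize_crystals()] for a whole run table at once.
#' @export
summarize_crystal <- function(runs, config = thermo_config()) {
  if (!is.data.frame(runs) || nrow(runs) < 1L) {
    stop("`runs` must be a data frame with at least one run", call. = FALSE)
  }
  needed <- c("ligand_id", "crystal_id", "binding_energy_kcal")
  missing_cols <- setdiff(needed, names(runs))
  if (length(missing_cols)) {
    stop("`runs` lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(runs$ligand_id)) != 1L ||
      length(unique(runs$crystal_id)) != 1L) {
    stop("`runs` mixes ligands or crystals; summarize one ligand x crystal group",
         call. = FALSE)
  }
  e <- runs$binding_energy_kcal
  if (!is.numeric(e) || any(!is.finite(e))) {
    stop("`binding_energy_kcal` must be finite numeric", call. = FALSE)
  }
  low <- min(e)
  data.frame(
    ligand_id = as.character(runs$ligand_id[1L]),
    crystal_id = as.character(runs$crystal_id[1L]),
    n_runs = nrow(runs),
    n_clusters = if ("cluster_id" %in% names(runs))
      length(unique(runs$cluster_id)) else NA_integer_,
    lowest_energy_kcal = low,
    mean_energy_kcal = mean(e),
    lowest_ki_nm = ki_from_energy(low, config),
    stringsAsFactors = FALSE
  )
}

#' Per-crystal summaries for a full run table
#'
#' Splits a run-level docking table by ligand and crystal (keeping first-
#' appearance order) and applies [summarize_crystal()] to each group.
#'
#' @param runs Run-level docking table: `ligand_id`, `crystal_id`,
#'   `binding_energy_kcal`, optional `target` and `cluster_id`.
#' @inheritParams summarize_crystal
#' @return Data frame of per-crystal summaries, one row per ligand x crystal,
#'   with a `target` column when present in `runs`.
#' @export
summarize_crystals <- function(runs, config = thermo_config()) {
  if (!is.data.frame(runs) || nrow(runs) < 1L) {
    stop("`runs` must be a non-empty data frame", call. = FALSE)
  }
  key <- paste(runs$ligand_id, runs$crystal_id, sep = "\r")
  groups <- split(seq_len(nrow(runs)), factor(key, levels = unique(key)))
  out <- do.call(rbind, lapply(groups, function(idx) {
    smry <- summarize_crystal(runs[idx, , drop = FALSE], config)
    if ("target" %in% names(runs)) {
      smry <- cbind(target = as.character(runs$target[idx[1L]]), smry,
                    stringsAsFactors = FALSE)
    }
    smry
  }))
  rownames(out) <- NULL
  out
}

#' Aggregate per-iteration inhibition constants for one ligand and target
#'
#' Pools the iteration-level Ki values of a ligand over every crystal of a
#' target and attaches uncertainty: the arithmetic mean, the standard error
#' of the mean (sample SD / sqrt(n)), a symmetric normal confidence interval
#' mean +/- z * SE on the nM scale (default z = 1.96 for 95%), and the pKi
#' of the mean. A log-scale interval (computed on log10 Ki and
#' back-transformed, hence asymmetric in nM) is available via `scale`.
#'
#' @param ki_nm Numeric vector of per-iteration inhibition constants in nM;
#'   at least two positive values (the SE is undefined for n < 2).
#' @param z Critical value for the confidence interval (1.96 = normal 95%).
#' @param ligand_id,target Optional labels carried into the output.
#' @param scale `"nM"` (default) or `"log"` for the interval scale.
#' @return One-row data frame: `ligand_id`, `target`, `n`, `mean_ki_nm`,
#'   `se_ki_nm`, `ci_low_nm`, `ci_high_nm`, `pki`.
#' @examples
#' set.seed(1)
#' aggregate_target(rlnorm(50, log(300), 0.5), ligand_id = "X", target = "BRAF")
#' @export
aggregate_target <- function(ki_nm, z = 1.96, ligand_id = NA_character_,
                             target = NA_character_,
                             scale = c("nM", "log")) {
  scale <- match.arg(scale)
  if (!is.numeric(ki_nm) || length(ki_nm) < 2L) {
    stop("`ki_nm` needs at least two values (SE undefined for n < 2)",
         call. = FALSE)
  }
  if (any(!is.finite(ki_nm)) || any(ki_nm <= 0)) {
    stop("`ki_nm` values must be positive and finite", call. = FALSE)
  }
  stopifnot(is.numeric(z), length(z) == 1L, z > 0)
  n <- length(ki_nm)
  m <- mean(ki_nm)
  se <- stats::sd(ki_nm) / sqrt(n)
  if (scale == "nM") {
    lo <- m - z * se
    hi <- m + z * se
  } else {
    lk <- log10(ki_nm)
    se_l <- stats::sd(lk) / sqrt(n)
    lo <- 10^(mean(lk) - z * se_l)
    hi <- 10^(mean(lk) + z * se_l)
  }
  data.frame(
    ligand_id = as.character(ligand_id),
    target = as.character(target),
    n = n,
    mean_ki_nm = m,
    se_ki_nm = se,
    ci_low_nm = lo,
    ci_high_nm = hi,
    pki = pki_from_ki(m),
    stringsAsFactors = FALSE
  )
}

#' Rank ligands by potency
#'
#' Orders campaign summaries by descending pKi; ties broken by lower mean
#' Ki, then alphabetically by ligand id. Ranking is performed within each
#' target when a `target` column is present.
#'
#' @param summaries Data frame with columns `ligand_id`, `pki` and
#'   optionally `mean_ki_nm` and `target`.
#' @return `summaries` reordered, with an integer `rank` column (1 = most
#'   potent, per target).
#' @export
rank_ligands <- function(summaries) {
  if (!is.data.frame(summaries) || !all(c("ligand_id", "pki") %in% names(summaries))) {
    stop("`summaries` must contain `ligand_id` and `pki`", call. = FALSE)
  }
  mean_ki <- if ("mean_ki_nm" %in% names(summaries))
    summaries$mean_ki_nm else rep(0, nrow(summaries))
  tgt <- if ("target" %in% names(summaries))
    as.character(summaries$target) else rep("", nrow(summaries))
  ord <- order(tgt, -summaries$pki, mean_ki, summaries$ligand_id)
  out <- summaries[ord, , drop = FALSE]
  out$rank <- stats::ave(out$pki, tgt[ord],
                         FUN = function(p) seq_along(p))
  out$rank <- as.integer(out$rank)
  rownames(out) <- NULL
  out
}
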