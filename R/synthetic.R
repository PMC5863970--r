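#' Specification for a synthetic docking campaign
#'
#' Describes a campaign with known ground truth: how many ligands, which
#' crystals per target, how many runs per crystal, the run-level Gaussian
#' noise on the energy scale, and what fraction of the generated library
#' should violate the rule of five. The defaults mirror a typical
#' multi-crystal kinase campaign: five BRAF crystals and one CRAF crystal,
#' ten runs each (so fifty pooled iterations per BRAF ligand), 0.4 kcal/mol
#' run-to-run spread, and a library in which roughly two thirds of the
#' compounds are not drug-like.
#'
#' @param n_ligands Number of ligands to generate.
#' @param crystals Named list mapping target name to character vector of
#'   crystal ids.
#' @param runs_per_crystal Docking runs per ligand x crystal (>= 2).
#' @param energy_sd Run-level Gaussian SD of the binding energy, kcal/mol.
#' @param true_mean_energy Optional matrix of true mean binding energies,
#'   `n_ligands` rows by total number of crystals (columns in the order of
#'   `unlist(crystals)`). Drawn uniformly from `energy_range` when `NULL`.
#' @param energy_range Range the true mean energies are drawn from, kcal/mol.
#' @param torsional_range Range of the per-ligand torsional penalty, kcal/mol.
#' @param violating_fraction Expected fraction of ligands planted with at
#'   least one Lipinski violation (default 1059/1544, the published
#'   fraction of a berberine-similarity library failing the screen).
#' @param seed Integer seed; every draw descends from it deterministically.
#' @return Object of class `"campaign_spec"`.
#' @export
campaign_spec <- function(n_ligands = 12,
                          crystals = list(
                            BRAF = c("1uwh", "1uwj", "3c4c", "3og7", "3psd"),
                            CRAF = "3omv"),
                          runs_per_crystal = 10,
                          energy_sd = 0.4,
                          true_mean_energy = NULL,
                          energy_range = c(-12, -7),
                          torsional_range = c(0.6, 1.8),
                          violating_fraction = 1059 / 1544,
                          seed = 1L) {
  stopifnot(is.numeric(n_ligands), n_ligands >= 1,
            is.list(crystals), length(crystals) >= 1,
            !is.null(names(crystals)), all(nzchar(names(crystals))),
            is.numeric(runs_per_crystal), runs_per_crystal >= 2,
            is.numeric(energy_sd), energy_sd >= 0,
            length(energy_range) == 2L, energy_range[1] <= energy_range[2],
            length(torsional_range) == 2L,
            is.numeric(violating_fraction),
            violating_fraction >= 0, violating_fraction <= 1,
            is.numeric(seed), abs(seed) < 2^31)
  all_crystals <- unlist(crystals, use.names = FALSE)
  if (anyDuplicated(all_crystals)) {
    stop("crystal ids must be unique across targets", call. = FALSE)
  }
  if (!is.null(true_mean_energy)) {
    true_mean_energy <- as.matrix(true_mean_energy)
    if (nrow(true_mean_energy) != n_ligands ||
        ncol(true_mean_energy) != length(all_crystals)) {
      stop("`true_mean_energy` must be ", n_ligands, " x ",
           length(all_crystals), " (ligands x crystals); got ",
           nrow(true_mean_energy), " x ", ncol(true_mean_energy),
           call. = FALSE)
    }
    if (any(!is.finite(true_mean_energy))) {
      stop("`true_mean_energy` must be finite", call. = FALSE)
    }
  }
  structure(
    list(n_ligands = as.integer(n_ligands), crystals = crystals,
         runs_per_crystal = as.integer(runs_per_crystal),
         energy_sd = energy_sd, true_mean_energy = true_mean_energy,
         energy_range = energy_range, torsional_range = torsional_range,
         violating_fraction = violating_fraction, seed = as.integer(seed)),
    class = "campaign_spec"
  )
}

# deterministic per-ligand substream seed below 2^31, so that adding
# ligands to a spec never perturbs the draws of earlier ligands
.ligand_seed <- function(seed, i) {
  (abs(seed) + 104729 * i) %% 2147483629
}

#' Generate a synthetic docking campaign with known ground truth
#'
#' Draws a ligand library and a run-level docking table from a
#' [campaign_spec()]. Run energies are Gaussian around the ligand x crystal
#' true mean on the energy scale (docking repeats spread roughly
#' symmetrically in energy, which makes the induced Ki spread log-normal);
#' energies are not truncated and may take any real value. Descriptors are
#' drawn uniformly, integer fields rounded; a planted fraction of ligands
#' violates one to four Lipinski rules. Each ligand consumes an independent
#' RNG substream derived from the global seed.
#'
#' @param spec A [campaign_spec()].
#' @return List with `ligands` (a [as_ligand_table()] including the planted
#'   `lipinski_violator` flag), `runs` (ligand_id, target, crystal_id,
#'   run_index, binding_energy_kcal, torsional_kcal, cluster_id) and
#'   `truth` (the spec plus the per-ligand x crystal true mean energies and
#'   their Ki equivalents).
#' @examples
#' camp <- generate_campaign(campaign_spec(n_ligands = 3, seed = 7))
#' head(camp$runs)
#' @export
generate_campaign <- function(spec) {
  stopifnot(inherits(spec, "campaign_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })

  all_crystals <- unlist(spec$crystals, use.names = FALSE)
  crystal_target <- rep(names(spec$crystals), lengths(spec$crystals))
  lig_rows <- vector("list", spec$n_ligands)
  run_rows <- vector("list", spec$n_ligands)
  truth_rows <- vector("list", spec$n_ligands)

  for (i in seq_len(spec$n_ligands)) {
    set.seed(.ligand_seed(spec$seed, i))
    id <- sprintf("SYN-%03d", i)
    violator <- stats::runif(1) < spec$violating_fraction
    mw <- stats::runif(1, 250, 500)
    logp <- stats::runif(1, -1, 5)
    hbd <- sample(0:5, 1)
    hba <- sample(0:10, 1)
    if (violator) {
      broken <- sample(c("mw", "logp", "hbd", "hba"), sample(1:4, 1))
      if ("mw" %in% broken) mw <- stats::runif(1, 500.5, 900)
      if ("logp" %in% broken) logp <- stats::runif(1, 5.1, 9)
      if ("hbd" %in% broken) hbd <- sample(6:10, 1)
      if ("hba" %in% broken) hba <- sample(11:15, 1)
    }
    nha <- sample(20:45, 1)
    n_polar <- min(sample(2:10, 1), nha)
    torsional <- round(stats::runif(1, spec$torsional_range[1],
                                    spec$torsional_range[2]), 2)
    lig_rows[[i]] <- data.frame(
      id = id, mw_da = round(mw, 2), n_hba = hba, n_hbd = hbd,
      logp = round(logp, 3), tpsa_a2 = round(stats::runif(1, 30, 130), 2),
      nha = nha, n_polar = n_polar, n_tdof = sample(1:8, 1),
      n_rot = sample(1:8, 1), formal_charge = sample(0:1, 1),
      lipinski_violator = violator, stringsAsFactors = FALSE)

    mu <- if (is.null(spec$true_mean_energy)) {
      stats::runif(length(all_crystals), spec$energy_range[1],
                   spec$energy_range[2])
    } else {
      as.numeric(spec$true_mean_energy[i, ])
    }
    truth_rows[[i]] <- data.frame(
      ligand_id = id, target = crystal_target, crystal_id = all_crystals,
      true_mean_kcal = mu, true_ki_nm = ki_from_energy(mu),
      stringsAsFactors = FALSE)

    per_crystal <- lapply(seq_along(all_crystals), function(j) {
      e <- stats::rnorm(spec$runs_per_crystal, mu[j], spec$energy_sd)
      data.frame(
        ligand_id = id, target = crystal_target[j],
        crystal_id = all_crystals[j],
        run_index = seq_len(spec$runs_per_crystal),
        binding_energy_kcal = e, torsional_kcal = torsional,
        cluster_id = as.integer(factor(round(e * 2) / 2)),
        stringsAsFactors = FALSE)
    })
    run_rows[[i]] <- do.call(rbind, per_crystal)
  }

  ligands <- as_ligand_table(do.call(rbind, lig_rows))
  runs <- do.call(rbind, run_rows)
  rownames(runs) <- NULL
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  list(ligands = ligands, runs = runs,
       truth = list(spec = spec, energies = truth,
                    violator = stats::setNames(ligands$lipinski_violator,
                                               ligands$id)))
}
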