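#' Fit a docking-campaign model
#'
#' The central entry point of the package. Takes a run-level docking table
#' (one row per docking iteration of a ligand against a receptor crystal)
#' and reduces it to the quantities used to prioritize ligands:
#'
#' 1. per-crystal summaries (lowest/mean energy, lowest Ki, cluster count);
#' 2. per-target campaign statistics — per-iteration inhibition constants
#'    pooled over a target's crystals, with mean Ki, standard error,
#'    `mean +/- z * SE` confidence interval, and pKi of the mean;
#' 3. a potency ranking (descending pKi, ties by lower mean Ki);
#' 4. when ligand descriptors are supplied, Lipinski verdicts, the five
#'    binding-efficiency indices per ligand and target, and lead compounds
#'    selected from the nBEI-vs-NSEI efficiency plane.
#'
#' @param runs Data frame with columns `ligand_id`, `crystal_id`,
#'   `binding_energy_kcal`, and optionally `target` (defaults to a single
#'   pooled target), `run_index`, `torsional_kcal`, `cluster_id`.
#' @param ligands Optional ligand descriptor table ([as_ligand_table()]);
#'   required for efficiency indices and lead selection.
#' @param z Critical value of the confidence interval (default 1.96,
#'   normal two-sided 95%).
#' @param config A [thermo_config()].
#' @param ki_method How per-target mean Ki is formed: `"per_run"` (default)
#'   converts every run energy to Ki and pools across the target's
#'   crystals; `"per_crystal"` converts each crystal's mean energy to Ki
#'   and averages those.
#' @param leads_k How many lead compounds to flag per target (capped at the
#'   number of profiled ligands).
#' @return An object of class `"dock_campaign"` with components
#'   `crystal_summaries`, `campaign_summaries`, `ranking`, `profiles`,
#'   `leads`, `verdicts`, plus the inputs and settings. Supported methods:
#'   [print()], [summary()], [coef()] (pKi estimates), [confint()]
#'   (intervals on mean Ki), [predict()] (energy to Ki/pKi conversion),
#'   [residuals()] (run energy minus crystal mean), [simulate()]
#'   (parametric re-draws of the run table) and [plot()] (bivariate
#'   efficiency plot).
#' @examples
#' camp <- generate_campaign(campaign_spec(n_ligands = 4, seed = 3))
#' fit <- dock_campaign(camp$runs, camp$ligands)
#' fit
#' coef(fit)
#' @export
dock_campaign <- function(runs, ligands = NULL, z = 1.96,
                          config = thermo_config(),
                          ki_method = c("per_run", "per_crystal"),
                          leads_k = 3) {
  ki_method <- match.arg(ki_method)
  cl <- match.call()
  if (!is.data.frame(runs) || nrow(runs) < 1L) {
    stop("`runs` must be a non-empty data frame", call. = FALSE)
  }
  if (!"target" %in% names(runs)) runs$target <- "pooled"
  runs$ligand_id <- as.character(runs$ligand_id)
  runs$target <- as.character(runs$target)

  crystal_summaries <- summarize_crystals(runs, config)

  key <- paste(runs$ligand_id, runs$target, sep = "\r")
  groups <- split(seq_len(nrow(runs)), factor(key, levels = unique(key)))
  campaign_summaries <- do.call(rbind, lapply(groups, function(idx) {
    sub <- runs[idx, , drop = FALSE]
    kis <- if (ki_method == "per_run") {
      ki_from_energy(sub$binding_energy_kcal, config)
    } else {
      means <- tapply(sub$binding_energy_kcal, sub$crystal_id, mean)
      ki_from_energy(as.numeric(means), config)
    }
    if (length(kis) < 2L) {
      # a single crystal in per-crystal mode: no spread to estimate
      data.frame(ligand_id = sub$ligand_id[1L], target = sub$target[1L],
                 n = 1L, mean_ki_nm = kis, se_ki_nm = NA_real_,
                 ci_low_nm = NA_real_, ci_high_nm = NA_real_,
                 pki = pki_from_ki(kis), stringsAsFactors = FALSE)
    } else {
      aggregate_target(kis, z = z, ligand_id = sub$ligand_id[1L],
                       target = sub$target[1L])
    }
  }))
  rownames(campaign_summaries) <- NULL
  ranking <- rank_ligands(campaign_summaries)

  verdicts <- NULL
  profiles <- NULL
  leads <- NULL
  if (!is.null(ligands)) {
    ligands <- as_ligand_table(as.data.frame(ligands))
    verdicts <- lipinski_check(ligands)
    have_desc <- all(c("n_polar", "nha") %in% names(ligands))
    if (have_desc) {
      profiles <- do.call(rbind, lapply(unique(campaign_summaries$target),
                                        function(tg) {
        smry <- campaign_summaries[campaign_summaries$target == tg, ]
        lig <- ligands[match(smry$ligand_id, ligands$id), , drop = FALSE]
        keep <- !is.na(lig$id)
        if (!any(keep)) return(NULL)
        efficiency_profile(lig[keep, , drop = FALSE],
                           pki = smry$pki[keep], target = tg)
      }))
      rownames(profiles) <- NULL
      leads <- lapply(split(profiles, profiles$target), function(pf) {
        select_leads(pf, k = min(leads_k, nrow(pf)))
      })
    }
  }

  structure(
    list(call = cl, runs = runs, ligands = ligands, z = z, config = config,
         ki_method = ki_method, leads_k = leads_k,
         crystal_summaries = crystal_summaries,
         campaign_summaries = campaign_summaries,
         ranking = ranking, verdicts = verdicts,
         profiles = profiles, leads = leads),
    class = "dock_campaign"
  )
}

.coef_names <- function(object) {
  cs <- object$campaign_summaries
  if (length(unique(cs$target)) > 1L) {
    paste(cs$ligand_id, cs$target, sep = ":")
  } else {
    cs$ligand_id
  }
}

#' @export
print.dock_campaign <- function(x, ...) {
  cs <- x$campaign_summaries
  cat("Docking campaign fit\n")
  cat(sprintf("  %d runs | %d ligands | %d crystals | %d target(s)\n",
              nrow(x$runs), length(unique(cs$ligand_id)),
              length(unique(x$runs$crystal_id)),
              length(unique(cs$target))))
  cat(sprintf("  mean Ki: %s of iteration-level Ki; CI: mean +/- %.2f SE (nM scale)\n",
              x$ki_method, x$z))
  for (tg in unique(x$ranking$target)) {
    top <- x$ranking[x$ranking$target == tg, ][1L, ]
    cat(sprintf("  %s: top ligand %s (pKi %.2f, mean Ki %.4g nM)\n",
                tg, top$ligand_id, top$pki, top$mean_ki_nm))
  }
  invisible(x)
}

#' @export
summary.dock_campaign <- function(object, ...) {
  structure(
    list(call = object$call,
         crystal_summaries = object$crystal_summaries,
         ranking = object$ranking,
         leads = object$leads,
         verdicts = object$verdicts),
    class = "summary.dock_campaign"
  )
}

#' @export
print.summary.dock_campaign <- function(x, ...) {
  cat("Docking campaign summary\n\nCall:\n  ")
  print(x$call)
  cat("\nPer-target ranking (mean Ki in nM):\n")
  rk <- x$ranking
  rk$mean_ki_nm <- signif(rk$mean_ki_nm, 4)
  rk$se_ki_nm <- signif(rk$se_ki_nm, 3)
  rk$ci_low_nm <- signif(rk$ci_low_nm, 4)
  rk$ci_high_nm <- signif(rk$ci_high_nm, 4)
  rk$pki <- round(rk$pki, 2)
  print(rk, row.names = FALSE)
  if (!is.null(x$leads)) {
    cat("\nLead compounds (nBEI/NSEI dominance):\n")
    for (tg in names(x$leads)) {
      cat("  ", tg, ": ", paste(x$leads[[tg]], collapse = ", "), "\n", sep = "")
    }
  }
  if (!is.null(x$verdicts)) {
    cat(sprintf("\nLipinski screen: %d/%d ligands pass\n",
                sum(x$verdicts$passed), nrow(x$verdicts)))
  }
  invisible(x)
}

#' @export
coef.dock_campaign <- function(object, ...) {
  stats::setNames(object$campaign_summaries$pki, .coef_names(object))
}

#' Confidence intervals on the campaign mean inhibition constants
#'
#' Normal intervals `mean Ki +/- z * SE` on the nM scale, with
#' `z = qnorm((1 + level) / 2)` (1.96 at the default 95% level).
#'
#' @param object A [dock_campaign()] fit.
#' @param parm Coefficient names to keep (default all).
#' @param level Confidence level.
#' @param ... Unused.
#' @return Matrix with one row per ligand x target and columns `mean_ki_nm`,
#'   lower and upper bounds.
#' @export
confint.dock_campaign <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm((1 + level) / 2)
  cs <- object$campaign_summaries
  out <- cbind(mean_ki_nm = cs$mean_ki_nm,
               lower = cs$mean_ki_nm - z * cs$se_ki_nm,
               upper = cs$mean_ki_nm + z * cs$se_ki_nm)
  rownames(out) <- .coef_names(object)
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' Convert new docking energies with a fitted campaign's thermodynamics
#'
#' @param object A [dock_campaign()] fit.
#' @param newdata Data frame with column `binding_energy_kcal` (or a bare
#'   numeric vector of energies).
#' @param type `"ki_nm"` or `"pki"`.
#' @param ... Unused.
#' @return Numeric vector of converted values.
#' @export
predict.dock_campaign <- function(object, newdata,
                                  type = c("ki_nm", "pki"), ...) {
  type <- match.arg(type)
  e <- if (is.data.frame(newdata)) newdata$binding_energy_kcal else newdata
  ki <- ki_from_energy(e, object$config)
  if (type == "ki_nm") ki else pki_from_ki(ki)
}

#' @export
residuals.dock_campaign <- function(object, ...) {
  cs <- object$crystal_summaries
  key <- paste(object$runs$ligand_id, object$runs$crystal_id, sep = "\r")
  ckey <- paste(cs$ligand_id, cs$crystal_id, sep = "\r")
  object$runs$binding_energy_kcal - cs$mean_energy_kcal[match(key, ckey)]
}

#' Parametric simulation of new run tables from a fitted campaign
#'
#' Draws fresh run-level energies from Normal(crystal mean energy, sigma),
#' where sigma is the pooled within-crystal residual SD of the fit — the
#' same Gaussian-on-energy noise model used by [generate_campaign()].
#'
#' @param object A [dock_campaign()] fit.
#' @param nsim Number of simulated run tables.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A list of `nsim` run tables shaped like `object$runs`.
#' @export
simulate.dock_campaign <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  res <- residuals(object)
  n_groups <- nrow(object$crystal_summaries)
  sigma <- if (nrow(object$runs) > n_groups) {
    sqrt(sum(res^2) / (nrow(object$runs) - n_groups))
  } else 0
  cs <- object$crystal_summaries
  key <- paste(object$runs$ligand_id, object$runs$crystal_id, sep = "\r")
  ckey <- paste(cs$ligand_id, cs$crystal_id, sep = "\r")
  mu <- cs$mean_energy_kcal[match(key, ckey)]
  lapply(seq_len(nsim), function(s) {
    out <- object$runs
    out$binding_energy_kcal <- stats::rnorm(length(mu), mu, sigma)
    out
  })
}

#' Bivariate efficiency plot of a fitted campaign
#'
#' Scatter of one efficiency index against another for a chosen target,
#' with the construction-line family `y = NPOL * x + log10(nha)` drawn for
#' the canonical nBEI-vs-NSEI plot. Lead compounds sit in the top right
#' corner.
#'
#' @param x A [dock_campaign()] fit built with ligand descriptors.
#' @param target Target to plot (default: first target of the fit).
#' @param x_index,y_index Index names among `nsei`, `nbei`, `nbei_log`,
#'   `mbei`, `lle`.
#' @param ... Passed on to [graphics::plot()].
#' @return Invisibly, the [bivariate_plot_data()] used for the plot.
#' @export
plot.dock_campaign <- function(x, target = NULL, x_index = "nsei",
                               y_index = "nbei_log", ...) {
  if (is.null(x$profiles)) {
    stop("the fit has no efficiency profiles; supply `ligands` with ",
         "`n_polar` and `nha` to dock_campaign()", call. = FALSE)
  }
  if (is.null(target)) target <- x$profiles$target[1L]
  pf <- x$profiles[x$profiles$target == target, , drop = FALSE]
  if (!nrow(pf)) stop("no profiles for target `", target, "`", call. = FALSE)
  pd <- bivariate_plot_data(pf, x = x_index, y = y_index)
  graphics::plot(pd$points$x, pd$points$y,
                 xlab = toupper(x_index), ylab = toupper(y_index),
                 main = paste0(target, ": ", toupper(y_index), " vs ",
                               toupper(x_index)), pch = 19, ...)
  if (nrow(pd$lines)) {
    for (i in seq_len(nrow(pd$lines))) {
      graphics::abline(pd$lines$intercept[i], pd$lines$slope[i],
                       col = "grey60", lty = 2)
    }
  }
  graphics::text(pd$points$x, pd$points$y, labels = pd$points$ligand_id,
                 pos = 3, cex = 0.7)
  invisible(pd)
}
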