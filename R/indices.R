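#' Ligand binding-efficiency and lipophilicity indices
#'
#' Computes the five Abad-Zapatero-style efficiency indices that normalise a
#' docking-derived potency (pKi) by molecular size and polarity:
#'
#' * `nsei` — NSEI, pKi / (N+O polar atom count);
#' * `nbei` — NBEI, pKi / heavy-atom count;
#' * `nbei_log` — nBEI, pKi + log10(heavy atoms);
#' * `mbei` — mBEI, pKi + log10(MW in kilodaltons);
#' * `lle` — ligand lipophilicity efficiency, pKi − LogP.
#'
#' The ligand table must carry `n_polar`, `nha`, `mw_da` and `logp`.
#'
#' @param ligands A [as_ligand_table()] (or coercible data frame).
#' @param pki Numeric vector of pKi values, one per ligand row (potency on
#'   the molar −log10 scale, e.g. from [aggregate_target()]).
#' @param target Optional target label carried into the output.
#' @return Data frame with `ligand_id`, `target`, descriptor columns
#'   (`n_polar`, `nha`, `mw_kd`, `logp`), `pki` and the five indices.
#' @examples
#' tabs <- berberine_raf_tables()
#' bbr <- tabs$ligands[tabs$ligands$id == "BBR", ]
#' efficiency_profile(bbr, pki = pki_from_ki(832)) # NSEI 1.22, LLE 3.61, ...
#' @export
efficiency_profile <- function(ligands, pki, target = NA_character_) {
  ligands <- as_ligand_table(as.data.frame(ligands))
  needed <- c("n_polar", "nha", "mw_da", "logp")
  missing_cols <- setdiff(needed, names(ligands))
  if (length(missing_cols)) {
    stop("ligand table lacks descriptor(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(pki) || length(pki) != nrow(ligands) || any(!is.finite(pki))) {
    stop("`pki` must be finite numeric with one value per ligand", call. = FALSE)
  }
  for (cl in needed) {
    if (any(is.na(ligands[[cl]]))) {
      stop("descriptor `", cl, "` is missing for ligand(s): ",
           paste(ligands$id[is.na(ligands[[cl]])], collapse = ", "),
           call. = FALSE)
    }
  }
  if (any(ligands$n_polar == 0) || any(ligands$nha == 0)) {
    stop("`n_polar` and `nha` must be positive to form efficiency indices",
         call. = FALSE)
  }
  mw_kd <- ligands$mw_da / 1000
  data.frame(
    ligand_id = ligands$id,
    target = as.character(target),
    n_polar = ligands$n_polar,
    nha = ligands$nha,
    mw_kd = mw_kd,
    logp = ligands$logp,
    pki = pki,
    nsei = pki / ligands$n_polar,
    nbei = pki / ligands$nha,
    nbei_log = pki + log10(ligands$nha),
    mbei = pki + log10(mw_kd),
    lle = pki - ligands$logp,
    stringsAsFactors = FALSE
  )
}

.index_names <- c("nsei", "nbei", "nbei_log", "mbei", "lle")

#' Points and regression-line family for a bivariate efficiency plot
#'
#' Builds the plotting data behind size-vs-polarity efficiency plots: one
#' point per ligand at the chosen index pair, and — for the canonical
#' nBEI-vs-NSEI plot — the family of construction lines
#' `y = NPOL * x + log10(nha)`. Every ligand lies exactly on the line of its
#' (NPOL, nha) group, since
#' nBEI = pKi + log10(nha) = NPOL * (pKi/NPOL) + log10(nha).
#'
#' @param profiles Output of [efficiency_profile()].
#' @param x,y Index names among `nsei`, `nbei`, `nbei_log`, `mbei`, `lle`.
#' @return List with `points` (ligand_id, x, y) and `lines` (npol, nha,
#'   slope, intercept, members) — `lines` has zero rows unless
#'   `x = "nsei", y = "nbei_log"`.
#' @export
bivariate_plot_data <- function(profiles, x = "nsei", y = "nbei_log") {
  stopifnot(is.data.frame(profiles))
  if (!x %in% .index_names) {
    stop("unknown index name for x axis: `", x, "`", call. = FALSE)
  }
  if (!y %in% .index_names) {
    stop("unknown index name for y axis: `", y, "`", call. = FALSE)
  }
  points <- data.frame(
    ligand_id = profiles$ligand_id,
    x = profiles[[x]],
    y = profiles[[y]],
    stringsAsFactors = FALSE
  )
  lines <- data.frame(npol = numeric(0), nha = numeric(0), slope = numeric(0),
                      intercept = numeric(0), members = character(0),
                      stringsAsFactors = FALSE)
  if (x == "nsei" && y == "nbei_log" && nrow(profiles)) {
    key <- paste(profiles$n_polar, profiles$nha, sep = "\r")
    groups <- split(seq_len(nrow(profiles)), factor(key, levels = unique(key)))
    lines <- do.call(rbind, lapply(groups, function(idx) {
      data.frame(
        npol = profiles$n_polar[idx[1L]],
        nha = profiles$nha[idx[1L]],
        slope = profiles$n_polar[idx[1L]],
        intercept = log10(profiles$nha[idx[1L]]),
        members = paste(profiles$ligand_id[idx], collapse = ","),
        stringsAsFactors = FALSE
      )
    }))
    rownames(lines) <- NULL
  }
  list(points = points, lines = lines)
}

#' Select lead compounds from the efficiency plane
#'
#' Operationalizes the "top right corner" of the nBEI-vs-NSEI plot as a
#' joint dominance sort: descending nBEI, ties broken by descending NSEI.
#'
#' @param profiles Output of [efficiency_profile()].
#' @param k Number of leads to return (>= 1). If `k` exceeds the number of
#'   profiles, all ligands are returned with a warning.
#' @return Character vector of ligand ids, most efficient first.
#' @examples
#' tabs <- berberine_raf_tables()
#' pk <- berberine_braf_pki()
#' prof <- efficiency_profile(tabs$ligands,
#'                            pki = pki_from_ki(pk$mean_ki_nm), target = "BRAF")
#' select_leads(prof, k = 3) # BBR-9, BBR-7, BBR-10
#' @export
select_leads <- function(profiles, k) {
  stopifnot(is.data.frame(profiles),
            all(c("ligand_id", "nbei_log", "nsei") %in% names(profiles)))
  if (!is.numeric(k) || length(k) != 1L || k < 1) {
    stop("`k` must be a single integer >= 1", call. = FALSE)
  }
  if (k > nrow(profiles)) {
    warning("k = ", k, " exceeds the ", nrow(profiles),
            " available ligands; returning all of them", call. = FALSE)
    k <- nrow(profiles)
  }
  ord <- order(-profiles$nbei_log, -profiles$nsei, profiles$ligand_id)
  profiles$ligand_id[ord][seq_len(k)]
}
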