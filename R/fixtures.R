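#' Bundled berberine/RAF-kinase reference tables
#'
#' Returns the published reference dataset shipped with the package: a
#' berberine-derivative docking campaign against the BRAF and CRAF kinase
#' domains. The tables are stored as printed in the source publication and
#' are used as golden fixtures throughout the test suite:
#'
#' * `ligands` — physicochemical descriptors of the 12 compounds (berberine,
#'   nine derivatives, vemurafenib and sorafenib controls), including polar
#'   (N+O) and heavy-atom counts;
#' * `crystals` — the six receptor crystal structures (five BRAF, one CRAF)
#'   with DFG conformation and resolution;
#' * `crystal_summaries` — per-ligand, per-BRAF-crystal docking summaries
#'   (clusters, torsional penalty, lowest/mean energy, lowest Ki), with the
#'   per-ligand mean Ki and pKi on each ligand's first row;
#' * `campaign_summaries` — per-target aggregated statistics (n, lowest and
#'   mean energy, mean Ki with SE and 95% CI, pKi); ATP rows are labelled
#'   `Kd` in `constant` as they report dissociation constants;
#' * `efficiency` — the published efficiency-index table (NSEI, NBEI, nBEI,
#'   mBEI, LLE) with its standalone printed pKi column kept as opaque
#'   `pki_printed`.
#'
#' A handful of printed cells are internally inconsistent in the source
#' (e.g. a transposed lowest/mean energy pair, a CI computed with z = 1
#' instead of 1.96). Values are kept verbatim; each affected row carries a
#' human-readable explanation in its `note` column, and tests treat flagged
#' cells as documented source errata.
#'
#' @return Named list of data frames as described above.
#' @examples
#' tabs <- berberine_raf_tables()
#' nrow(tabs$ligands)                      # 12
#' subset(tabs$crystals, target == "CRAF") # 3omv
#' @export
berberine_raf_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "dockrank",
                                  mustWork = TRUE)
  read <- function(f) utils::read.csv(path(f), stringsAsFactors = FALSE)
  lig <- read("berberine_ligands.csv")
  list(
    ligands = as_ligand_table(lig),
    crystals = read("berberine_crystals.csv"),
    crystal_summaries = read("berberine_braf_docking.csv"),
    campaign_summaries = read("berberine_campaigns.csv"),
    efficiency = read("berberine_efficiency.csv")
  )
}

#' Per-ligand BRAF potency of the bundled reference campaign
#'
#' Convenience accessor combining the per-ligand mean inhibition constants
#' of the bundled BRAF docking tables: the ten berberine compounds from the
#' per-crystal table plus the vemurafenib and sorafenib controls from the
#' campaign table, aligned with the ligand descriptor table.
#'
#' @return Data frame: `ligand_id`, `mean_ki_nm` (printed), `pki_printed`
#'   (printed), in the order of the bundled ligand table.
#' @export
berberine_braf_pki <- function() {
  tabs <- berberine_raf_tables()
  per_lig <- tabs$crystal_summaries[!is.na(tabs$crystal_summaries$mean_ki_nm),
                                    c("ligand_id", "mean_ki_nm", "pki")]
  braf <- tabs$campaign_summaries[tabs$campaign_summaries$target == "BRAF" &
                                    tabs$campaign_summaries$constant == "Ki",
                                  c("ligand_id", "mean_ki_nm", "pki")]
  extra <- braf[!braf$ligand_id %in% per_lig$ligand_id, ]
  out <- rbind(per_lig, extra)
  names(out)[3] <- "pki_printed"
  out <- out[match(tabs$ligands$id, out$ligand_id), ]
  rownames(out) <- NULL
  out
}
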