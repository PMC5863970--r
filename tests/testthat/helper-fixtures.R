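# shared fixtures: bundled reference tables are read once per test run
ref_tables <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- berberine_raf_tables()
    cache
  }
})

# full-precision BRAF pKi recomputed from the printed per-ligand mean Ki,
# aligned with the bundled ligand table
ref_braf_pki <- function() pki_from_ki(berberine_braf_pki()$mean_ki_nm)

# tiny run-table builder: one ligand x crystal group per energy vector
make_runs <- function(energies, ligand_id = "L1", crystal_id = "xtal",
                      target = "T", cluster_id = NULL) {
  out <- data.frame(
    ligand_id = ligand_id, target = target, crystal_id = crystal_id,
    run_index = seq_along(energies), binding_energy_kcal = energies,
    stringsAsFactors = FALSE)
  if (!is.null(cluster_id)) out$cluster_id <- cluster_id
  out
}

# a printed lowest-energy / lowest-Ki pair is self-consistent iff the
# printed Ki lies in the interval induced by rounding the energy to the
# 2 decimals the table prints (plus the Ki's own printed resolution)
printed_pair_consistent <- function(energy, ki_nm) {
  lo <- ki_from_energy(energy - 0.005)
  hi <- ki_from_energy(energy + 0.005)
  ulp <- ifelse(ki_nm == round(ki_nm), 0.5, 0.005)
  (ki_nm + ulp >= lo) & (ki_nm - ulp <= hi)
}
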