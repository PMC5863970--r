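test_that("zero noise makes every run equal its generating truth", {
  mu <- matrix(-8.5, nrow = 2, ncol = 6)
  spec <- campaign_spec(n_ligands = 2, energy_sd = 0, true_mean_energy = mu,
                        seed = 9)
  camp <- generate_campaign(spec)
  expect_true(all(camp$runs$binding_energy_kcal == -8.5))
  cs <- summarize_crystals(camp$runs)
  expect_equal(cs$lowest_energy_kcal, cs$mean_energy_kcal)
  expect_equal(unique(cs$lowest_energy_kcal), -8.5)
  # the full pipeline recovers the closed-form truth exactly
  fit <- dock_campaign(camp$runs)
  expect_equal(fit$campaign_summaries$pki,
               rep(pki_from_ki(ki_from_energy(-8.5)),
                   nrow(fit$campaign_summaries)),
               tolerance = 1e-9)
})

test_that("generation is reproducible and uses per-ligand substreams", {
  spec <- campaign_spec(n_ligands = 4, seed = 123)
  a <- generate_campaign(spec)
  b <- generate_campaign(spec)
  expect_identical(a, b)
  # same seed => byte-identical files
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_delim_table(a$runs, f1); write_delim_table(b$runs, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  unlink(c(f1, f2))
  # extending the library leaves earlier ligands' draws untouched
  bigger <- generate_campaign(campaign_spec(n_ligands = 6, seed = 123))
  first4 <- bigger$runs[bigger$runs$ligand_id %in% a$runs$ligand_id, ]
  rownames(first4) <- NULL
  expect_identical(first4, a$runs)
  expect_identical(as.data.frame(bigger$ligands)[1:4, ],
                   as.data.frame(a$ligands))
})

test_that("generated campaigns satisfy the run-table contract", {
  camp <- generate_campaign(campaign_spec(n_ligands = 5, seed = 77))
  expect_s3_class(camp$ligands, "ligand_table")
  expect_true(all(camp$runs$run_index >= 1))
  expect_true(all(camp$runs$torsional_kcal >= 0))
  expect_identical(nrow(camp$runs), 5L * 6L * 10L)
  expect_setequal(unique(camp$runs$crystal_id),
                  c("1uwh", "1uwj", "3c4c", "3og7", "3psd", "3omv"))
  expect_identical(unique(camp$runs$target[camp$runs$crystal_id == "3omv"]),
                   "CRAF")
})

test_that("the planted Lipinski-violating fraction is respected", {
  n <- 400
  frac <- 0.3
  camp <- generate_campaign(campaign_spec(
    n_ligands = n, crystals = list(BRAF = "1uwh"), runs_per_crystal = 2,
    violating_fraction = frac, seed = 55))
  v <- lipinski_check(camp$ligands)
  # screening verdicts agree exactly with the planted flags
  expect_identical(v$passed, !camp$ligands$lipinski_violator)
  # observed violator count within central 95% binomial bounds
  k <- sum(camp$ligands$lipinski_violator)
  expect_gte(k, stats::qbinom(0.025, n, frac))
  expect_lte(k, stats::qbinom(0.975, n, frac))
})

test_that("malformed specs are rejected", {
  expect_error(campaign_spec(runs_per_crystal = 1), "runs_per_crystal")
  expect_error(campaign_spec(energy_sd = -0.1), "energy_sd")
  expect_error(campaign_spec(violating_fraction = 1.2), "violating_fraction")
  expect_error(campaign_spec(n_ligands = 3,
                             true_mean_energy = matrix(-8, 2, 6)),
               "3 x 6")
  expect_error(
    campaign_spec(crystals = list(BRAF = c("a", "b"), CRAF = "a")),
    "unique")
})

test_that("true mean energies are recovered from noisy campaigns", {
  # energy-scale recovery is unbiased: the pooled mean of the 50 run
  # energies should sit within 3 SE of the generating mean almost always
  mu <- matrix(-8.5, nrow = 1, ncol = 5)
  n_seeds <- 150
  hit_e <- hit_ki <- logical(n_seeds)
  # Gaussian energy noise makes Ki log-normal: the mean of the iteration
  # Kis centres on exp(sigma^2/2) * Ki(mu), not on Ki(mu) itself
  sd_e <- 0.4
  sigma <- sd_e / thermo_config()$rt_kcal
  ki_center <- exp(sigma^2 / 2) * ki_from_energy(-8.5)
  for (s in seq_len(n_seeds)) {
    camp <- generate_campaign(campaign_spec(
      n_ligands = 1, crystals = list(BRAF = c("c1", "c2", "c3", "c4", "c5")),
      runs_per_crystal = 10, energy_sd = sd_e, true_mean_energy = mu,
      seed = 1000 + s))
    e <- camp$runs$binding_energy_kcal
    hit_e[s] <- abs(mean(e) - (-8.5)) <= 3 * stats::sd(e) / sqrt(length(e))
    agg <- aggregate_target(ki_from_energy(e))
    hit_ki[s] <- abs(agg$mean_ki_nm - ki_center) <= 3 * agg$se_ki_nm
  }
  expect_gte(mean(hit_e), 0.97)
  expect_gte(mean(hit_ki), 0.95) # heavier-tailed statistic on the Ki scale
})
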