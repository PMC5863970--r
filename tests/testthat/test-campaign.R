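make_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      camp <- generate_campaign(campaign_spec(n_ligands = 4, seed = 3))
      cache <<- list(camp = camp,
                     fit = dock_campaign(camp$runs, camp$ligands))
    }
    cache
  }
})

test_that("the campaign fit aggregates per-run Ki values per target", {
  fx <- make_fit()
  fit <- fx$fit
  runs <- fx$camp$runs
  cs <- fit$campaign_summaries
  expect_identical(nrow(cs), 4L * 2L) # 4 ligands x 2 targets
  one <- runs[runs$ligand_id == "SYN-001" & runs$target == "BRAF", ]
  kis <- ki_from_energy(one$binding_energy_kcal)
  row <- cs[cs$ligand_id == "SYN-001" & cs$target == "BRAF", ]
  expect_equal(row$mean_ki_nm, mean(kis))
  expect_equal(row$se_ki_nm, stats::sd(kis) / sqrt(length(kis)))
  expect_equal(row$n, 50L)
  expect_equal(row$pki, pki_from_ki(mean(kis)))
})

test_that("the per-crystal aggregation mode averages crystal-level Ki", {
  fx <- make_fit()
  runs <- fx$camp$runs
  fit2 <- dock_campaign(runs, ki_method = "per_crystal")
  one <- runs[runs$ligand_id == "SYN-002" & runs$target == "BRAF", ]
  crystal_ki <- ki_from_energy(
    tapply(one$binding_energy_kcal, one$crystal_id, mean))
  row <- fit2$campaign_summaries[
    fit2$campaign_summaries$ligand_id == "SYN-002" &
      fit2$campaign_summaries$target == "BRAF", ]
  expect_equal(row$mean_ki_nm, mean(crystal_ki))
  expect_equal(row$n, 5L)
})

test_that("fit accessors expose pKi, intervals, predictions and residuals", {
  fx <- make_fit()
  fit <- fx$fit
  cf <- coef(fit)
  expect_named(cf)
  expect_identical(unname(cf), fit$campaign_summaries$pki)
  ci <- confint(fit, level = 0.95)
  expect_equal(unname(ci[, "lower"]),
               fit$campaign_summaries$mean_ki_nm -
                 stats::qnorm(0.975) * fit$campaign_summaries$se_ki_nm)
  expect_true(all(ci[, "lower"] <= ci[, "mean_ki_nm"] &
                    ci[, "mean_ki_nm"] <= ci[, "upper"]))
  expect_equal(predict(fit, data.frame(binding_energy_kcal = -8.41)),
               684.74, tolerance = 0.01)
  expect_equal(predict(fit, -8.41, type = "pki"),
               pki_from_ki(ki_from_energy(-8.41)))
  res <- residuals(fit)
  expect_identical(length(res), nrow(fit$runs))
  # residuals are centred within every ligand x crystal cell
  cell <- paste(fit$runs$ligand_id, fit$runs$crystal_id)
  expect_equal(max(abs(tapply(res, cell, mean))), 0, tolerance = 1e-12)
})

test_that("simulate redraws run tables under the fitted noise model", {
  fx <- make_fit()
  fit <- fx$fit
  s1 <- simulate(fit, nsim = 2, seed = 42)
  s2 <- simulate(fit, nsim = 2, seed = 42)
  expect_identical(s1, s2)
  expect_identical(dim(s1[[1]]), dim(fit$runs))
  expect_false(identical(s1[[1]]$binding_energy_kcal,
                         s1[[2]]$binding_energy_kcal))
  # refitting a simulated table keeps the crystal means close to the parent
  refit <- dock_campaign(s1[[1]])
  expect_equal(refit$crystal_summaries$mean_energy_kcal,
               fit$crystal_summaries$mean_energy_kcal, tolerance = 0.5)
})

test_that("print, summary and plot run on a fitted campaign", {
  fx <- make_fit()
  fit <- fx$fit
  expect_output(print(fit), "Docking campaign fit")
  expect_output(print(summary(fit)), "ranking")
  expect_output(print(summary(fit)), "Lipinski screen")
  pdf(NULL)
  on.exit(dev.off())
  pd <- plot(fit)
  expect_named(pd, c("points", "lines"))
  bare <- dock_campaign(fx$camp$runs) # no descriptors, no profiles
  expect_error(plot(bare), "profiles")
})

test_that("reference potencies flow through the fit to the published leads", {
  # rebuild a degenerate run table whose per-run Ki equals each ligand's
  # printed BRAF mean Ki, then check ranking and lead selection end to end
  tabs <- ref_tables()
  pk <- berberine_braf_pki()
  runs <- do.call(rbind, lapply(seq_len(nrow(pk)), function(i) {
    make_runs(rep(energy_from_ki(pk$mean_ki_nm[i]), 3),
              ligand_id = pk$ligand_id[i], crystal_id = "braf",
              target = "BRAF")
  }))
  fit <- dock_campaign(runs, tabs$ligands)
  rk <- fit$ranking
  expect_identical(rk$ligand_id[1], "BBR-9")
  expect_equal(round(rk$pki[1], 2), 6.81)
  expect_identical(fit$leads$BRAF, c("BBR-9", "BBR-7", "BBR-10"))
})
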