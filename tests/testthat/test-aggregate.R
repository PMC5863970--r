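test_that("per-crystal summaries reduce runs to lowest/mean/Ki/clusters", {
  runs <- make_runs(rep(-8.41, 10), cluster_id = c(rep(1, 6), rep(2, 4)))
  s <- summarize_crystal(runs)
  expect_equal(s$lowest_energy_kcal, -8.41)
  expect_equal(s$mean_energy_kcal, -8.41)
  expect_equal(s$lowest_ki_nm, 684.74, tolerance = 0.01)
  expect_identical(s$n_runs, 10L)
  expect_identical(s$n_clusters, 2L)

  s2 <- summarize_crystal(make_runs(c(-8.41, rep(-8.33, 9))))
  expect_equal(s2$lowest_energy_kcal, -8.41)
  expect_equal(s2$mean_energy_kcal, -8.338)
  expect_true(s2$lowest_energy_kcal <= s2$mean_energy_kcal)
  expect_true(is.na(s2$n_clusters)) # no cluster labels supplied

  s3 <- summarize_crystal(make_runs(-9.2))
  expect_equal(s3$lowest_energy_kcal, s3$mean_energy_kcal)
  expect_identical(s3$n_runs, 1L)
})

test_that("mixed or empty run groups are rejected", {
  runs <- rbind(make_runs(-8, crystal_id = "a"), make_runs(-9, crystal_id = "b"))
  expect_error(summarize_crystal(runs), "mixes")
  expect_error(summarize_crystal(runs[0, ]), "at least one")
  expect_error(summarize_crystal(make_runs(NA_real_)), "finite")
})

test_that("summarize_crystals splits a table and keeps first-appearance order", {
  runs <- rbind(
    make_runs(c(-8, -8.5), ligand_id = "B", crystal_id = "x1"),
    make_runs(c(-9, -9.5), ligand_id = "A", crystal_id = "x1"),
    make_runs(c(-7, -7.5), ligand_id = "B", crystal_id = "x2"))
  out <- summarize_crystals(runs)
  expect_identical(out$ligand_id, c("B", "A", "B"))
  expect_identical(out$crystal_id, c("x1", "x1", "x2"))
  expect_equal(out$lowest_energy_kcal, c(-8.5, -9.5, -7.5))
  expect_true(all(out$target == "T"))
})

test_that("campaign aggregation matches a from-scratch oracle", {
  # oracle: mean/SD/SE computed by explicit summation
  oracle <- function(x, z = 1.96) {
    n <- length(x)
    m <- sum(x) / n
    sdev <- sqrt(sum((x - m)^2) / (n - 1))
    se <- sdev / sqrt(n)
    c(mean = m, se = se, lo = m - z * se, hi = m + z * se,
      pki = -log10(m * 1e-9))
  }
  set.seed(31)
  for (n in c(2, 5, 50, 1e3, 1e4)) {
    x <- stats::rlnorm(n, log(500), 0.7)
    got <- aggregate_target(x)
    want <- oracle(x)
    expect_equal(got$mean_ki_nm, unname(want["mean"]), tolerance = 1e-9)
    expect_equal(got$se_ki_nm, unname(want["se"]), tolerance = 1e-9)
    expect_equal(got$ci_low_nm, unname(want["lo"]), tolerance = 1e-9)
    expect_equal(got$ci_high_nm, unname(want["hi"]), tolerance = 1e-9)
    expect_equal(got$pki, unname(want["pki"]), tolerance = 1e-9)
    # interval geometry: width 2*z*SE, symmetric about the mean
    expect_equal(got$ci_high_nm - got$ci_low_nm, 2 * 1.96 * got$se_ki_nm)
    expect_equal((got$ci_high_nm + got$ci_low_nm) / 2, got$mean_ki_nm)
  }
})

test_that("published mean/SE pairs reproduce their confidence bounds", {
  # a two-point sample m +/- se has mean m and SE se exactly, so the
  # package's own CI arithmetic can be driven from printed summaries
  from_summary <- function(m, se) aggregate_target(c(m - se, m + se))
  a <- from_summary(265, 50)
  expect_equal(round(c(a$ci_low_nm, a$ci_high_nm)), c(167, 363))
  b <- from_summary(832, 326)
  expect_equal(round(c(b$ci_low_nm, b$ci_high_nm)), c(193, 1471))
  expect_equal(round(b$pki, 2), 6.08)
})

test_that("degenerate and invalid Ki vectors are handled", {
  cst <- aggregate_target(rep(100, 50))
  expect_equal(cst$se_ki_nm, 0)
  expect_equal(cst$ci_low_nm, 100)
  expect_equal(cst$ci_high_nm, 100)
  expect_error(aggregate_target(5), "at least two")
  expect_error(aggregate_target(numeric(0)), "at least two")
  expect_error(aggregate_target(c(10, -1)), "positive")
})

test_that("the log-scale interval is asymmetric and brackets the mean", {
  set.seed(5)
  x <- stats::rlnorm(50, log(300), 0.8)
  lg <- aggregate_target(x, scale = "log")
  nm <- aggregate_target(x, scale = "nM")
  expect_equal(lg$mean_ki_nm, nm$mean_ki_nm)
  expect_true(lg$ci_low_nm > 0)
  # log-normal geometry: upper/center ratio equals center/lower ratio
  center <- sqrt(lg$ci_low_nm * lg$ci_high_nm)
  expect_equal(lg$ci_high_nm / center, center / lg$ci_low_nm)
})

test_that("ligands rank by pKi with mean-Ki and id tie-breaks", {
  smry <- data.frame(
    ligand_id = c("BBR", "BBR-7", "BBR-9", "BBR-10", "Vemurafenib"),
    target = "BRAF",
    pki = c(6.08, 6.60, 6.81, 6.57, 6.26),
    mean_ki_nm = c(832, 245, 155, 269, 550))
  rk <- rank_ligands(smry)
  expect_identical(rk$ligand_id[1], "BBR-9")
  expect_identical(rk$ligand_id,
                   c("BBR-9", "BBR-7", "BBR-10", "Vemurafenib", "BBR"))
  expect_identical(rk$rank, 1:5)

  one <- rank_ligands(smry[1, ])
  expect_identical(one$ligand_id, "BBR")

  tie <- data.frame(ligand_id = c("a", "b"), pki = c(6, 6),
                    mean_ki_nm = c(900, 800))
  expect_identical(rank_ligands(tie)$ligand_id, c("b", "a"))
  tie2 <- data.frame(ligand_id = c("z", "y"), pki = c(6, 6),
                     mean_ki_nm = c(100, 100))
  expect_identical(rank_ligands(tie2)$ligand_id, c("y", "z"))
})
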