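test_that("residual fractions match the annotated peak percentages", {
  # printed peaks at 6.95 nS open conductance, 200 mV
  expect_equal(residual_fraction(688.4, 6.95, 200), 49.5, tolerance = 1e-3)
  expect_equal(residual_fraction(631.5, 6.95, 200), 45.4, tolerance = 1e-3)
  expect_equal(residual_fraction(643.8, 6.95, 200), 46.3, tolerance = 1e-3)
  expect_equal(residual_fraction(0, 6.95, 200), 0)
  expect_error(residual_fraction(688.4, 6.95, 0), "bias")
})

test_that("blockade conductances match the reference table within rounding", {
  expect_equal(blockade_conductance(688.4, 6.95, 200), 3508, tolerance = 1e-9)
  expect_equal(blockade_conductance(688.4, 6.95, 200), 3510,
               tolerance = 0.003)
  expect_equal(blockade_conductance(631.5, 6.95, 200), 3792.5,
               tolerance = 1e-9)
  expect_equal(blockade_conductance(631.5, 6.95, 200), 3800,
               tolerance = 0.003)
  expect_equal(blockade_conductance(6.95 * 200, 6.95, 200), 0)
  expect_warning(blockade_conductance(2000, 6.95, 200), "exceeds")
})

test_that("fraction and blockade conductance conserve the open-pore current", {
  g <- 6.95; v <- 200
  for (r in c(0, 100, 631.5, 688.4, 1200)) {
    frac <- residual_fraction(r, g, v)
    blk <- blockade_conductance(r, g, v)
    # fraction% plus the blockade's share of G must total 100%
    expect_equal(frac + 100 * (blk / 1000) / g, 100, tolerance = 1e-9)
  }
})

test_that("homopolymers are ranked by descending blockade conductance", {
  rk <- rank_homopolymers(data.frame(label = c("A", "T", "C"),
                                     dI_block_pS = c(3510, 3800, 3670)))
  expect_equal(rk$order, "T>C>A")
  expect_equal(rk$min_delta_pS, 130)
  rk2 <- rank_homopolymers(data.frame(label = c("A", "T"),
                                      dI_block_pS = c(1, 2)))
  expect_equal(rk2$order, "T>A")
  expect_equal(rk2$min_delta_pS, 1)
  tie <- rank_homopolymers(data.frame(label = c("T", "A"),
                                      dI_block_pS = c(5, 5)))
  expect_equal(tie$order, "A>T")  # alphabetical tie-break
  expect_equal(tie$min_delta_pS, 0)
  expect_error(rank_homopolymers(data.frame(label = c("A", "A"),
                                            dI_block_pS = c(1, 2))),
               "duplicate")
})

test_that("the static reference table carries the solid-state quartz row", {
  tab <- blockade_reference_table()
  row <- tab[tab$pore == "solid-state quartz", ]
  expect_equal(row$A_pS, 3510)
  expect_equal(row$T_pS, 3800)
  expect_equal(row$C_pS, 3670)
  expect_equal(row$open_pS, 6950)
  expect_equal(row$rank, "T>C>A")
  expect_equal(row$min_delta_pS, 130)
  rk <- rank_homopolymers(data.frame(label = c("A", "T", "C"),
                                     dI_block_pS = c(row$A_pS, row$T_pS,
                                                     row$C_pS)))
  expect_equal(rk$order, row$rank)
})

test_that("single-Gaussian histogram fit recovers mean and flags problems", {
  set.seed(101)
  x <- rnorm(500, 688.4, 43.1)
  g <- fit_single_gaussian(x)
  expect_lt(abs(g$mean_pA - 688.4), 3 * 43.1 / sqrt(500))
  expect_equal(g$sd_pA, 43.1, tolerance = 0.2)
  expect_false(g$poor_fit)

  gd <- fit_single_gaussian(rep(5, 100))
  expect_true(gd$degenerate)
  expect_equal(gd$sd_pA, 0)

  set.seed(102)
  bimodal <- c(rnorm(300, 400, 10), rnorm(300, 700, 10))
  gb <- fit_single_gaussian(bimodal)
  expect_true(gb$poor_fit)

  expect_error(fit_single_gaussian(rnorm(10)), "insufficient")
})

test_that("EM mixture recovers the two mixture-experiment components", {
  set.seed(77)
  x <- c(rnorm(300, 679.9, 21.3), rnorm(300, 641.2, 20.2))
  mx <- fit_two_gaussian_mixture(x, seed = 1)
  expect_equal(nrow(mx), 2)
  expect_true(mx$mean_pA[1] > mx$mean_pA[2])  # ordered descending
  # with 300+300 draws from components ~1.9 pooled SDs apart, the maximum
  # likelihood solution constrains each mean to ~+/-20 pA (calibrated over
  # 20 seeds); the sampling spread of the ML estimator, not EM failure
  expect_lt(abs(mx$mean_pA[1] - 679.9), 20)
  expect_lt(abs(mx$mean_pA[2] - 641.2), 20)
  expect_equal(sum(mx$weight), 1, tolerance = 1e-9)
})

test_that("EM mixture handles degenerate and well-separated cases", {
  # both components identical: the split is unidentifiable, but EM must
  # keep both means near the single true mean and preserve the total mean
  set.seed(55)
  x <- rnorm(400, 650, 20)
  mx <- fit_two_gaussian_mixture(x, seed = 2)
  expect_true(all(abs(mx$mean_pA - mean(x)) < sd(x)))
  expect_equal(sum(mx$weight * mx$mean_pA), mean(x), tolerance = 1e-3)

  # 10-SD separation: clean partition, weights within 0.02
  set.seed(56)
  y <- c(rnorm(250, 900, 10), rnorm(250, 500, 10))
  my <- fit_two_gaussian_mixture(y, seed = 3)
  expect_equal(my$mean_pA[1], 900, tolerance = 0.01)
  expect_equal(my$mean_pA[2], 500, tolerance = 0.01)
  expect_lt(max(abs(my$weight - 0.5)), 0.02)

  expect_error(fit_two_gaussian_mixture(rnorm(40)), "insufficient")
})

test_that("mixture fit is invariant to input order", {
  set.seed(60)
  x <- c(rnorm(300, 679.9, 21.3), rnorm(300, 641.2, 20.2))
  m1 <- fit_two_gaussian_mixture(x, seed = 9)
  m2 <- fit_two_gaussian_mixture(sample(x), seed = 9)
  expect_equal(m1$mean_pA, m2$mean_pA, tolerance = 1e-6)
  expect_equal(m1$weight, m2$weight, tolerance = 1e-6)
})

test_that("EM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  # moderately separated mixture: the likelihood optimum is unambiguous,
  # so two independent EM implementations must land on the same solution
  set.seed(61)
  x <- c(rnorm(300, 700, 15), rnorm(300, 620, 18))
  mx <- fit_two_gaussian_mixture(x, seed = 4)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  ref <- sort(mc$parameters$mean, decreasing = TRUE)
  expect_equal(mx$mean_pA, unname(ref), tolerance = 1e-3)
  expect_equal(sort(mx$weight), sort(unname(mc$parameters$pro)),
               tolerance = 0.02)
})

test_that("a simulated homopolymer mixture is resolved end to end", {
  # generate from the mixture-experiment component presets, detect, and
  # fit the mixture on the depth-reliable residuals; the recovered
  # separation should reproduce the reference ~39-pA peak spacing
  res <- list()
  for (i in 1:2) {
    pr <- homopolymer_preset(c("polyA_mix", "polyT_mix")[i])
    truth <- sample_events(pr, 200, seed = 70 + i)
    dur <- max(truth$start_s + truth$dwell_us * 1e-6) + 0.05
    tr <- bessel_lowpass(render_trace(1.39, truth, noise_preset("quartzBias"),
                                      duration_s = dur, seed = 80 + i))
    det <- detect_events(tr, correct_baseline(tr))
    res[[i]] <- det$residual_mean_pA[det$depth_reliable]
  }
  mx <- fit_two_gaussian_mixture(unlist(res), seed = 5)
  sep <- mx$mean_pA[1] - mx$mean_pA[2]
  expect_gt(sep, 25)
  expect_lt(sep, 55)
})
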