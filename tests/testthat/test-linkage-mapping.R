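test_that("BC1 recombination fraction and LOD follow the closed form", {
  x <- rep(c("AB", "BB"), 50)
  y <- x; y[1:10] <- ifelse(x[1:10] == "AB", "BB", "AB")
  est <- estimate_rf(x, y, "BC1")
  expect_equal(est$r_hat, 0.1)
  expect_equal(est$lod, 10 * log10(0.2) + 90 * log10(1.8), tolerance = 1e-10)
  expect_equal(est$n_informative, 100)

  # perfect cosegregation: r = 0, LOD = n log10 2
  est0 <- estimate_rf(x, x, "BC1")
  expect_identical(est0$r_hat, 0)
  expect_equal(est0$lod, 100 * log10(2))

  # monotonicity: adding a recombinant individual never decreases r-hat
  y2 <- c(y, "BB"); x2 <- c(x, "AB")
  expect_gt(estimate_rf(x2, y2, "BC1")$r_hat, est$r_hat - 1e-12)

  expect_error(estimate_rf(rep(NA_character_, 5), rep("AB", 5), "BC1"),
               "zero informative")
  expect_true(estimate_rf(rep("AB", 10), rep(c("AB", "BB"), 5), "BC1")$undefined)
})

test_that("F2 maximum-likelihood r matches the grid-search oracle", {
  # class counts set exactly to 100x the expected frequencies at r = 0.2
  P <- gmsmap:::f2_class_probs(0.2) * 1600
  cls <- c("AA", "AB", "BB")
  x <- character(0); y <- character(0)
  for (a in 1:3) for (b in 1:3) {
    k <- round(P[a, b])
    x <- c(x, rep(cls[a], k)); y <- c(y, rep(cls[b], k))
  }
  est <- estimate_rf(x, y, "F2")
  expect_equal(est$r_hat, 0.2, tolerance = 1e-3)

  # random tables: optimizer vs 1e-4 grid oracle, marker x marker and
  # marker x trait
  set.seed(14)
  for (rep in 1:8) {
    r <- runif(1, 0.02, 0.45); n <- sample(50:200, 1)
    N <- matrix(rmultinom(1, n, gmsmap:::f2_class_probs(r)), 3, 3)
    xx <- rep(rep(cls, 3), as.vector(N))
    yy <- rep(rep(cls, each = 3), as.vector(N))
    est <- estimate_rf(xx, yy, "F2")
    expect_lt(abs(est$r_hat - grid_rf_oracle(N)), 1e-3)

    Nt <- matrix(rmultinom(1, n, gmsmap:::f2_class_probs(r, TRUE)), 3, 2)
    xt <- rep(rep(cls, 2), as.vector(Nt))
    yt <- rep(rep(c("sterile", "fertile"), each = 3), as.vector(Nt))
    estt <- estimate_rf(xt, yt, "F2")
    expect_lt(abs(estt$r_hat - grid_rf_oracle(Nt, trait = TRUE)), 1e-3)
  }

  # identical F2 codominant columns: r = 0 with a larger LOD than BC1's
  xi <- rep(cls, times = c(25, 50, 25))
  esti <- estimate_rf(xi, xi, "F2")
  expect_identical(esti$r_hat, 0)
  expect_gt(esti$lod, 100 * log10(2))

  # symmetry in marker order
  e1 <- estimate_rf(x, y, "F2"); e2 <- estimate_rf(y, x, "F2")
  expect_equal(e1$r_hat, e2$r_hat, tolerance = 1e-9)
})

test_that("the Kosambi map function is exact, monotone and invertible", {
  expect_identical(kosambi_cM(0), 0)
  expect_equal(kosambi_cM(0.1), 25 * log(1.5), tolerance = 1e-12)
  expect_equal(kosambi_cM(0.1), 10.137, tolerance = 1e-3)
  expect_lt(abs(kosambi_r(kosambi_cM(0.2)) - 0.2), 1e-10)
  rs <- seq(0, 0.49, by = 0.007)
  expect_lt(max(abs(kosambi_r(kosambi_cM(rs)) - rs)), 1e-10)
  expect_true(all(diff(kosambi_cM(rs)) > 0))
  # d ~ 100 r for small r
  expect_equal(kosambi_cM(1e-4), 100 * 1e-4, tolerance = 1e-6)
  expect_error(kosambi_cM(0.5), "0.5")
  expect_error(kosambi_r(-1), ">= 0")
})

test_that("linkage grouping applies both gates strictly and recovers chromosomes", {
  # identical columns on few individuals: r = 0 but LOD only n log10 2
  calls <- cbind(m1 = rep(c("AA", "AB", "BB"), length.out = 10),
                 m2 = rep(c("AA", "AB", "BB"), length.out = 10))
  mat <- make_geno(calls, rep(c("sterile", "fertile"), 5))
  gr_hi <- form_groups(mat, rf_max = 0.3, lod_min = 7)   # LOD ~ 4.8 fails
  expect_equal(length(gr_hi), 2)
  gr_lo <- form_groups(mat, rf_max = 0.3, lod_min = 2)
  expect_equal(length(gr_lo), 1)

  # full 10-chromosome recovery, noise-free F2 n = 200, 40 markers/chrom
  gen <- genome_model(markers_per_chrom = 40)
  tr <- trait_locus_spec("A07", 11e6, gms_model("multi_allelic"),
                         list(P1 = "b", P2 = "a"), gen)
  big <- simulate_population(population_design("F2", 200, seed = 42),
                             gen, tr)
  groups <- form_groups(big)
  expect_equal(length(groups), 10)
  truth <- split(gen$markers$marker, gen$markers$chrom)
  for (g in groups) {
    ch <- unique(gen$markers$chrom[match(g, gen$markers$marker)])
    expect_length(ch, 1)
    expect_setequal(g, truth[[ch]])
  }
})

test_that("marker ordering is optimal on small groups and recovers truth", {
  # exhaustive-permutation oracle on 8 markers
  gen <- one_chrom_genome(8, length_cM = 40)
  tr <- multi_trait(gen)
  mat <- simulate_population(population_design("F2", 100, seed = 16),
                             gen, tr)
  pw <- pairwise_rf(mat)
  ord <- order_markers(colnames(mat$calls), mat, pw = pw)
  D <- pw$r_hat; D[is.na(D)] <- 0.5
  plen <- function(o) sum(D[cbind(o[-length(o)], o[-1])])
  best <- min(vapply(perms(colnames(mat$calls)), plen, 0))
  expect_equal(plen(ord), best, tolerance = 1e-12)

  # larger chromosome: recovered order equals bp order up to reversal
  gen2 <- one_chrom_genome(15)
  mat2 <- simulate_population(population_design("F2", 200, seed = 17),
                              gen2, multi_trait(gen2))
  ord2 <- order_markers(colnames(mat2$calls), mat2)
  true_ord <- gen2$markers$marker[order(gen2$markers$bp)]
  expect_true(identical(ord2, true_ord) || identical(rev(ord2), true_ord))

  # three markers with additive r: middle marker in the middle
  g3 <- one_chrom_genome(3, length_cM = 20)
  mat3 <- simulate_population(population_design("F2", 150, seed = 18),
                              g3, multi_trait(g3))
  ord3 <- order_markers(colnames(mat3$calls), mat3)
  expect_true(ord3[2] == g3$markers$marker[2])
})

test_that("the all-pairs scan agrees with the per-pair estimator", {
  gen <- one_chrom_genome(12)
  mat <- simulate_population(population_design("F2", 150, seed = 19),
                             gen, multi_trait(gen), noise_model())
  pw <- pairwise_rf(mat)
  mk <- colnames(mat$calls)
  for (pair in list(c(1, 2), c(3, 9), c(5, 12))) {
    e <- estimate_rf(mat$calls[, mk[pair[1]]], mat$calls[, mk[pair[2]]], "F2")
    expect_lt(abs(pw$r_hat[pair[1], pair[2]] - e$r_hat), 2e-3)
    expect_lt(abs(pw$lod[pair[1], pair[2]] - e$lod), 0.1)
  }
  expect_equal(pw$r_hat, t(pw$r_hat))

  # BC1 branch
  matb <- simulate_population(population_design("BC1", 186, seed = 20),
                              gen, multi_trait(gen, P2 = "c"))
  pwb <- pairwise_rf(matb)
  eb <- estimate_rf(matb$calls[, 1], matb$calls[, 4], "BC1")
  expect_equal(pwb$r_hat[1, 4], eb$r_hat, tolerance = 1e-12)
  expect_equal(pwb$lod[1, 4], eb$lod, tolerance = 1e-9)
})

test_that("BC1 r estimates are unbiased at the study's sample size", {
  # true r = 0.1 via Haldane-spaced markers, n = 186, 200 replicates
  d <- -50 * log(1 - 2 * 0.1)  # cM giving Haldane r = 0.1
  chr <- data.frame(chrom = "c1", length_cM = 50, length_bp = 1.4e7)
  pos <- data.frame(marker = c("mL", "mR"), chrom = "c1",
                    bp = round(c(2e6, 2e6 + d / 50 * 1.4e7)))
  gen <- genome_model(chr, marker_positions = pos)
  tr <- trait_locus_spec("c1", 1e6, gms_model("multi_allelic"),
                         list(P1 = "b", P2 = "c"), gen)
  rs <- vapply(1:200, function(s) {
    mt <- simulate_population(population_design("BC1", 186, seed = 3000 + s),
                              gen, tr)
    estimate_rf(mt$calls[, "mL"], mt$calls[, "mR"], "BC1")$r_hat
  }, 0)
  expect_lt(abs(mean(rs) - 0.1), 0.01)
})
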