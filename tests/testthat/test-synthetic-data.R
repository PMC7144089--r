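test_that("meiosis follows Haldane's map function", {
  gen <- genome_model(data.frame(chrom = "c1", length_cM = 100,
                                 length_bp = 1e7),
                      marker_positions = data.frame(
                        marker = c("m1", "m2"), chrom = "c1",
                        bp = c(1, 1e7)))
  f1 <- rbind(c(0L, 0L), c(1L, 1L))
  set.seed(21)
  rec <- replicate(10000, {
    g <- simulate_gamete(f1, gen)
    g[1] != g[2]
  })
  r_true <- 0.5 * (1 - exp(-2))  # 0.4323 at 1 Morgan
  expect_lt(abs(mean(rec) - r_true), 3 * sqrt(r_true * (1 - r_true) / 10000))

  # zero-length chromosome: whole parental haplotypes, never recombinant
  gen0 <- genome_model(data.frame(chrom = "c1", length_cM = 0,
                                  length_bp = 1e6),
                       marker_positions = data.frame(
                         marker = c("m1", "m2"), chrom = "c1",
                         bp = c(1, 1e6)))
  set.seed(22)
  rec0 <- replicate(200, { g <- simulate_gamete(f1, gen0); g[1] != g[2] })
  expect_true(!any(rec0))
})

test_that("short intervals recombine at the closed-form rate", {
  gen <- genome_model(data.frame(chrom = "c1", length_cM = 50,
                                 length_bp = 1e7),
                      marker_positions = data.frame(
                        marker = c("m1", "m2"), chrom = "c1",
                        bp = c(1e6, 1e6 + 0.5 / 50 * 1e7)))  # 0.5 cM apart
  f1 <- rbind(c(0L, 0L), c(1L, 1L))
  set.seed(31)
  n <- 2e5
  rec <- logical(n)
  for (i in seq_len(n)) { g <- simulate_gamete(f1, gen); rec[i] <- g[1] != g[2] }
  r_true <- 0.5 * (1 - exp(-2 * 0.005))
  expect_lt(abs(mean(rec) - r_true), 3 * sqrt(r_true * (1 - r_true) / n))
})

test_that("F2 and BC1 populations segregate as expected without noise", {
  gen <- one_chrom_genome(1)
  tr <- multi_trait(gen)
  mat <- simulate_population(population_design("F2", 10000, seed = 5),
                             gen, tr)
  counts <- table(mat$calls[, 1])
  for (cls in c("AA", "AB", "BB")) {
    p <- if (cls == "AB") 0.5 else 0.25
    expect_lt(abs(counts[[cls]] / 10000 - p), 3 * sqrt(p * (1 - p) / 10000))
  }

  # BC1 of the sterile F1 (b/c) to the maintainer: half the progeny sterile
  trbc <- trait_locus_spec("A07", 11e6, gms_model("multi_allelic"),
                           list(P1 = "b", P2 = "c"), gen)
  bc <- simulate_population(population_design("BC1", 10000, seed = 6),
                            gen, trbc)
  st <- mean(bc$phenotype == "sterile")
  expect_lt(abs(st - 0.5), 3 * sqrt(0.25 / 10000))
  expect_true(all(bc$calls %in% c("AB", "BB")))
})

test_that("phenotypes always equal the rule applied to the true trait genotype", {
  gen <- one_chrom_genome(5)
  tr <- multi_trait(gen)
  mat <- simulate_population(population_design("F2", 300, seed = 8),
                             gen, tr, noise_model(mean_depth = 3))
  m <- gms_model("multi_allelic")
  expect_identical(mat$phenotype,
                   vapply(mat$truth$trait_geno, phenotype_of, "",
                          model = m, USE.NAMES = FALSE))
  # noise never touches the truth matrix
  ok <- !is.na(mat$calls)
  expect_true(mean(mat$calls[ok] == mat$truth$calls[ok]) > 0.95)
})

test_that("read-depth gating reproduces the Poisson tail", {
  gen <- one_chrom_genome(250)
  tr <- multi_trait(gen)
  nm <- noise_model(mean_depth = 1, depth_min = 5, het_dropout = FALSE)
  mat <- simulate_population(population_design("F2", 200, seed = 9),
                             gen, tr, nm)
  p_called <- 1 - ppois(5, 1)  # depth > 5 under strict gating
  n_calls <- length(mat$calls)
  observed <- sum(!is.na(mat$calls))
  expect_lt(abs(observed - n_calls * p_called),
            3 * sqrt(n_calls * p_called * (1 - p_called)))
})

test_that("identical seeds give bit-identical populations", {
  gen <- one_chrom_genome(30)
  tr <- multi_trait(gen)
  a <- simulate_population(population_design("F2", 50, seed = 12), gen, tr,
                           noise_model())
  b <- simulate_population(population_design("F2", 50, seed = 12), gen, tr,
                           noise_model())
  expect_identical(a$calls, b$calls)
  expect_identical(a$phenotype, b$phenotype)
  c2 <- simulate_population(population_design("F2", 50, seed = 13), gen, tr,
                            noise_model())
  expect_false(identical(a$calls, c2$calls))
  expect_error(population_design("F2", 50, seed = NULL), "seed")
})

test_that("marker filters apply the strict missingness boundary", {
  calls <- matrix("AA", 10, 3,
                  dimnames = list(NULL, c("keep", "boundary", "low")))
  calls[, "keep"] <- c("AA", "AB", "BB", "AA", "AB", "BB", "AA", "AB", "BB", "AA")
  calls[, "boundary"] <- calls[, "keep"]; calls[1:2, "boundary"] <- NA  # 20%
  calls[, "low"] <- calls[, "keep"]; calls[1, "low"] <- NA              # 10%
  mat <- make_geno(calls, rep(c("sterile", "fertile"), 5))
  res <- apply_marker_filters(mat, noise_model())
  expect_setequal(colnames(res$matrix$calls), c("keep", "low"))
  expect_equal(res$report$reason[res$report$marker == "boundary"],
               "missingness")

  # monomorphic markers go too, and the filter is idempotent
  calls2 <- cbind(calls, mono = rep("AA", 10))
  res2 <- apply_marker_filters(make_geno(calls2, mat$phenotype),
                               noise_model())
  expect_false("mono" %in% colnames(res2$matrix$calls))
  res3 <- apply_marker_filters(res2$matrix, noise_model())
  expect_identical(res3$matrix$calls, res2$matrix$calls)
  expect_equal(res3$n_dropped, 0)

  expect_error(apply_marker_filters(
    make_geno(calls[, 0, drop = FALSE], mat$phenotype)), "empty")
})

test_that("progeny-test simulation matches the deterministic outcomes", {
  multi <- best_multi_hypothesis()
  sim <- simulate_progeny_tests(multi, study_designs(), seed = 1)
  expect_true(all(sim$B$outcomes == "all_sterile"))  # probability exactly 1
  expect_true(all(sim$C$outcomes == "all_fertile"))  # probability exactly 1
})
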