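fine_fixture <- function(n = 1590, seed = 11, d_cM = 0.3) {
  chr <- data.frame(chrom = "A07", length_cM = 82, length_bp = 22.96e6)
  bpcM <- chr$length_bp / chr$length_cM
  pos <- data.frame(marker = c("mL", "mR"), chrom = "A07",
                    bp = round(c(41 - d_cM, 41 + d_cM) * bpcM))
  gen <- genome_model(chr, marker_positions = pos)
  tr <- trait_locus_spec("A07", round(41 * bpcM), gms_model("multi_allelic"),
                         list(P1 = "b", P2 = "a"), gen)
  simulate_population(population_design("F2", n, seed = seed), gen, tr)
}

test_that("recombinant classification follows the phase logic", {
  calls <- rbind(c("AA", "AA"),   # sterile, consistent
                 c("AB", "AA"),   # sterile, left recombinant
                 c("AA", "BB"),   # sterile, right (double-crossover class)
                 c("AB", "AB"),   # fertile, consistent
                 c("AA", "AA"),   # fertile, double
                 c("BB", "AB"),   # fertile, consistent (het not evidence)
                 c(NA, NA))       # skipped
  colnames(calls) <- c("mL", "mR")
  phen <- c("sterile", "sterile", "sterile", "fertile", "fertile",
            "fertile", "fertile")
  mat <- make_geno(calls, phen)
  rec <- find_recombinants(mat, "mL", "mR")
  expect_equal(nrow(rec), 3)
  expect_equal(rec$side[rec$individual == "ind002"], "left")
  expect_equal(rec$side[rec$individual == "ind003"], "right")
  expect_equal(rec$side[rec$individual == "ind005"], "double")
  expect_equal(attr(rec, "skipped"), "ind007")
  expect_equal(attr(rec, "n_screened"), 6)
})

test_that("the detector never contradicts the simulator's crossover record", {
  mat <- fine_fixture()
  rec <- find_recombinants(mat, "mL", "mR")
  O1 <- mat$truth$origins$O1; O2 <- mat$truth$origins$O2  # cols mL, mR, trait
  for (id in rec$individual) {
    i <- match(id, rownames(mat$calls))
    has_crossover <- O1[i, 1] != O1[i, 3] || O1[i, 2] != O1[i, 3] ||
      O2[i, 1] != O2[i, 3] || O2[i, 2] != O2[i, 3]
    expect_true(has_crossover)
  }
  # plausible yield: every flagged plant is real, and a 0.6 cM interval in
  # 1,590 plants yields few recombinants
  expect_lt(nrow(rec), 30)
})

test_that("recombinant percentages are rounded and scale-invariant", {
  expect_identical(recombinant_percentage(data.frame(id = 1:3), 1590), 0.19)
  expect_identical(recombinant_percentage(data.frame(id = integer(0)), 500),
                   0)
  expect_identical(recombinant_percentage(data.frame(id = 1), 200), 0.5)
  r1 <- recombinant_percentage(data.frame(id = 1:7), 900)
  r2 <- recombinant_percentage(data.frame(id = 1:14), 1800)
  expect_identical(r1, r2)
  expect_error(recombinant_percentage(data.frame(id = 1), 0), "> 0")
})

test_that("marker-trait distances recover the simulated interval", {
  mat <- fine_fixture()
  dl <- marker_trait_distance(mat, "mL")
  expect_false(dl$unlinked)
  expect_lt(dl$cM, 2)

  iv <- interval_report(mat, "mL", "mR")
  expect_equal(iv$total_cM, iv$left_cM + iv$right_cM)
  expect_equal(iv$bp_span,
               abs(mat$markers$bp[2] - mat$markers$bp[1]))

  # median recovery across seeds for a 0.25 + 0.35 cM interval
  totals <- vapply(1:15, function(s) {
    chr <- data.frame(chrom = "A07", length_cM = 82, length_bp = 22.96e6)
    bpcM <- chr$length_bp / chr$length_cM
    pos <- data.frame(marker = c("mL", "mR"), chrom = "A07",
                      bp = round(c(41 - 0.25, 41 + 0.35) * bpcM))
    gen <- genome_model(chr, marker_positions = pos)
    tr <- trait_locus_spec("A07", round(41 * bpcM),
                           gms_model("multi_allelic"),
                           list(P1 = "b", P2 = "a"), gen)
    mt <- simulate_population(population_design("F2", 1590, seed = 500 + s),
                              gen, tr)
    interval_report(mt, "mL", "mR")$total_cM
  }, 0)
  expect_gte(median(totals), 0.2)
  expect_lte(median(totals), 1.2)

  # a marker identical to the trait classification maps at 0 cM
  calls <- cbind(mk = ifelse(fine_fixture(200, 3)$phenotype == "sterile",
                             "AA", "AB"))
  m0 <- make_geno(calls, fine_fixture(200, 3)$phenotype)
  expect_equal(marker_trait_distance(m0, "mk")$cM, 0)
})

test_that("cosegregation testing counts discordant plants", {
  mat <- fine_fixture(n = 923, seed = 13, d_cM = 0)  # markers at the locus
  ct <- cosegregation_test(mat, "mL")
  expect_equal(ct$n_individuals, 923)
  expect_equal(ct$n_discordant, 0)
  expect_equal(ct$verdict, "cosegregating")

  # one sterile heterozygote among 100
  calls <- cbind(mk = c(rep("AA", 24), "AB", rep("AB", 50), rep("BB", 25)))
  phen <- c(rep("sterile", 25), rep("fertile", 75))
  ct2 <- cosegregation_test(make_geno(calls, phen), "mk")
  expect_equal(ct2$n_discordant, 1)
  expect_equal(ct2$verdict, "discordant")

  # symmetric under allele-code relabeling with the phase map updated
  swapped <- calls
  swapped[calls == "AA"] <- "BB"; swapped[calls == "BB"] <- "AA"
  colnames(swapped) <- "mk"
  ct3 <- cosegregation_test(make_geno(swapped, phen), "mk",
                            sterile_class = "BB")
  expect_equal(ct3$n_discordant, ct2$n_discordant)
  expect_equal(ct3$verdict, ct2$verdict)

  allmiss <- make_geno(cbind(mk = rep(NA_character_, 5)),
                       rep("fertile", 5))
  expect_error(cosegregation_test(allmiss, "mk"), "missing")
})
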