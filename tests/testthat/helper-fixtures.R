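# Shared fixtures and independent oracles for the test suite.

# Build a gms_geno by hand from a call matrix and phenotype vector.
make_geno <- function(calls, phenotype, cross_type = "F2", markers = NULL) {
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("ind%03d", seq_len(nrow(calls)))
  if (is.null(markers))
    markers <- data.frame(marker = c(colnames(calls), character(0)),
                          chrom = rep("c1", ncol(calls)),
                          bp = seq_len(ncol(calls)) * 1e5,
                          cM = rep(NA_real_, ncol(calls)),
                          stringsAsFactors = FALSE)
  structure(list(calls = calls, phenotype = phenotype,
                 markers = markers, cross_type = cross_type,
                 trait = NULL, design = NULL, truth = NULL),
            class = "gms_geno")
}

# One-chromosome genome for small simulations.
one_chrom_genome <- function(n_markers, length_cM = 82,
                             length_bp = 22.96e6) {
  genome_model(data.frame(chrom = "A07", length_cM = length_cM,
                          length_bp = length_bp),
               markers_per_chrom = n_markers)
}

multi_trait <- function(genome, bp = 11e6, P1 = "b", P2 = "a") {
  trait_locus_spec("A07", bp, gms_model("multi_allelic"),
                   list(P1 = P1, P2 = P2), genome)
}

# Brute-force sterile fraction of a cross: enumerate the weighted gamete
# outer product directly from the parental haplotypes, with an inline
# phenotype rule, independent of the package's distribution machinery.
brute_sterile_fraction <- function(p1, p2, model) {
  gams <- function(g) {
    h1 <- g[1, ]; h2 <- g[2, ]
    if (ncol(g) == 1) {
      list(h = list(h1, h2), w = c(0.5, 0.5))
    } else {
      r <- model$inter_locus_rf
      list(h = list(h1, h2, c(h1[1], h2[2]), c(h2[1], h1[2])),
           w = c((1 - r) / 2, (1 - r) / 2, r / 2, r / 2))
    }
  }
  sterile <- function(hapA, hapB) {
    a1 <- c(hapA[1], hapB[1])
    if (model$model_id == "multi_allelic") {
      any(a1 == "b") && !any(a1 == "a")
    } else {
      a2 <- c(hapA[2], hapB[2])
      any(a1 == "Ms") && all(a2 == "rf")
    }
  }
  G1 <- gams(p1); G2 <- gams(p2)
  tot <- 0
  for (i in seq_along(G1$h)) for (j in seq_along(G2$h))
    if (sterile(G1$h[[i]], G2$h[[j]])) tot <- tot + G1$w[i] * G2$w[j]
  tot
}

# All permutations of a vector (for exhaustive ordering oracles).
perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  out
}

# Grid-search ML oracle for the F2 two-point likelihood.
grid_rf_oracle <- function(N, trait = FALSE, step = 1e-4) {
  grid <- seq(step, 0.5 - step, by = step)
  ll <- vapply(grid, gmsmap:::f2_loglik, 0, N = N, trait = trait)
  ll0 <- gmsmap:::f2_loglik(0, N, trait)
  if (is.finite(ll0) && ll0 >= max(ll)) 0 else grid[which.max(ll)]
}

# Observed recombination events between two call columns.
n_events <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  sum(x[ok] != y[ok])
}

best_multi_hypothesis <- function() {
  m <- gms_model("multi_allelic")
  gms_hypothesis(m, list("NH80-A" = genotype(m, "b", "b"),
                         "TA95" = genotype(m, "a", "a"),
                         "WH606" = genotype(m, "c", "c")))
}

two_gene_hypothesis <- function(restorer = c("msms_RfRf", "MsMs_RfRf")) {
  restorer <- match.arg(restorer)
  tg <- gms_model("two_gene")
  t_g <- if (restorer == "msms_RfRf") genotype(tg, c("ms", "Rf"), c("ms", "Rf"))
         else genotype(tg, c("Ms", "Rf"), c("Ms", "Rf"))
  gms_hypothesis(tg, list(
    "NH80-A" = genotype(tg, c("Ms", "rf"), c("Ms", "rf")),
    "TA95" = t_g,
    "WH606" = genotype(tg, c("ms", "rf"), c("ms", "rf"))))
}
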