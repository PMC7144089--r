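# Meiosis simulator: crossovers per chromosome are Poisson(length_cM/100)
# with breakpoints uniform in cM (no interference; Haldane map function).

#' Simulate one gamete from a pair of parental haplotypes
#'
#' @param parent_haplotypes 2 x P matrix (any storage mode): the parent's two
#'   haplotypes over P positions.
#' @param genome a \code{genome_model} (supplies chromosome lengths).
#' @param positions data.frame with columns chrom and cM, one row per column
#'   of \code{parent_haplotypes} (default: the genome's markers).
#' @return vector of length P: the transmitted allele at each position, a
#'   crossover mosaic of the two parental haplotypes.
#' @export
simulate_gamete <- function(parent_haplotypes, genome,
                            positions = genome$markers) {
  stopifnot(nrow(parent_haplotypes) == 2L,
            ncol(parent_haplotypes) == nrow(positions))
  out <- parent_haplotypes[1, ]
  for (ci in seq_len(nrow(genome$chromosomes))) {
    ch <- genome$chromosomes[ci, ]
    idx <- which(positions$chrom == ch$chrom)
    if (length(idx) == 0) next
    if (any(positions$cM[idx] < 0 | positions$cM[idx] > ch$length_cM))
      stop("position outside chromosome ", ch$chrom)
    ncross <- stats::rpois(1, ch$length_cM / 100)
    breaks <- sort(stats::runif(ncross, 0, ch$length_cM))
    start <- sample.int(2L, 1L)
    # strand at position x alternates at each breakpoint
    nb <- findInterval(positions$cM[idx], breaks)
    strand <- 1L + (start - 1L + nb) %% 2L
    out[idx] <- parent_haplotypes[cbind(strand, idx)]
  }
  out
}

call_from_origins <- function(o1, o2) {
  # origins are 0 (parent P1) / 1 (parent P2); calls coded AA = P1 homozygote
  c("AA", "AB", "BB")[o1 + o2 + 1L]
}

#' Simulate a mapping population with GBS-style genotype calls
#'
#' Founders are fully homozygous and carry alternate alleles at every marker
#' (P1 homozygote = "AA", P2 homozygote = "BB", heterozygote = "AB"). The F1
#' is heterozygous throughout; F2 individuals receive two F1 gametes, BC1
#' individuals one F1 gamete plus a recurrent-parent gamete. The sterility
#' phenotype is determined, error-free, by the trait-locus genotype under the
#' trait's genetic model. Genotype calls are then degraded by the noise model
#' (Poisson read depth with a minimum-depth gate, heterozygote dropout);
#' phenotypes are never degraded. True genotypes and gamete origin vectors
#' are retained for oracle checks.
#'
#' @param design a \code{population_design} (carries the mandatory seed).
#' @param genome a \code{genome_model}.
#' @param trait a \code{trait_locus_spec}.
#' @param noise a \code{noise_model}, or NULL for noise-free calls.
#' @return Object of class \code{gms_geno}: list with \code{calls} (n x m
#'   character matrix, codes AA/AB/BB/NA), \code{markers}, \code{phenotype}
#'   ("sterile"/"fertile"), \code{cross_type}, \code{trait}, and
#'   \code{truth} (true calls, trait genotype keys, gamete origin matrices).
#' @export
simulate_population <- function(design, genome, trait, noise = NULL) {
  stopifnot(inherits(design, "population_design"),
            inherits(genome, "genome_model"),
            inherits(trait, "trait_locus_spec"))
  if (is.null(design$seed)) stop("a seed is required")
  set.seed(design$seed)

  mk <- genome$markers
  m <- nrow(mk); n <- design$n
  L <- length(trait$chrom)
  pos <- rbind(mk[, c("chrom", "cM")],
               data.frame(chrom = trait$chrom, cM = trait$cM))
  tr_idx <- m + seq_len(L)

  f1 <- rbind(rep(0L, m + L), rep(1L, m + L))  # origin-coded haplotypes
  rec_origin <- if (design$recurrent_parent == "P1") 0L else 1L

  O1 <- matrix(0L, n, m + L); O2 <- matrix(0L, n, m + L)
  for (i in seq_len(n)) {
    O1[i, ] <- simulate_gamete(f1, genome, pos)
    O2[i, ] <- if (design$cross_type == "F2")
      simulate_gamete(f1, genome, pos) else rep(rec_origin, m + L)
  }

  true_calls <- matrix(call_from_origins(O1[, seq_len(m)], O2[, seq_len(m)]),
                       n, m, dimnames = list(sprintf("ind%04d", seq_len(n)),
                                             mk$marker))
  model <- trait$model
  haps <- rbind(trait$founder_haps$P1, trait$founder_haps$P2)
  trait_keys <- vapply(seq_len(n), function(i) {
    hA <- haps[cbind(O1[i, tr_idx] + 1L, seq_len(L))]
    hB <- haps[cbind(O2[i, tr_idx] + 1L, seq_len(L))]
    geno_key(genotype(model, hA, hB))
  }, "")
  phen <- vapply(trait_keys, phenotype_of, "", model = model, USE.NAMES = FALSE)

  calls <- true_calls
  if (!is.null(noise)) {
    depth <- matrix(stats::rpois(n * m, noise$mean_depth), n, m)
    called <- if (noise$depth_strict) depth > noise$depth_min
              else depth >= noise$depth_min
    calls[!called] <- NA_character_
    if (noise$het_dropout) {
      het <- which(called & calls == "AB")
      if (length(het)) {
        drop <- stats::runif(length(het)) < 2^(1 - depth[het])
        hom <- sample(c("AA", "BB"), sum(drop), replace = TRUE)
        calls[het[drop]] <- hom
      }
    }
  }

  structure(list(calls = calls, markers = mk, phenotype = phen,
                 cross_type = design$cross_type, trait = trait,
                 design = design,
                 truth = list(calls = true_calls, trait_geno = trait_keys,
                              origins = list(O1 = O1, O2 = O2),
                              positions = pos, trait_idx = tr_idx)),
            class = "gms_geno")
}

#' @export
print.gms_geno <- function(x, ...) {
  cat("Marker genotype matrix:", nrow(x$calls), "individuals x",
      ncol(x$calls), "markers (", x$cross_type, ")\n")
  cat("Phenotype:", sum(x$phenotype == "sterile"), "sterile /",
      sum(x$phenotype == "fertile"), "fertile\n")
  cat("Missing calls:",
      sprintf("%.1f%%", 100 * mean(is.na(x$calls))), "\n")
  invisible(x)
}

#' Apply per-marker filters (missingness, polymorphism)
#'
#' Drops markers missing in at least \code{marker_missing_max} of the
#' population (the kept set is strictly below the threshold) and, optionally,
#' markers that are monomorphic among the non-missing calls. Idempotent.
#'
#' @param mat a \code{gms_geno}.
#' @param noise a \code{noise_model} supplying \code{marker_missing_max}.
#' @param drop_monomorphic also drop non-segregating markers (default TRUE).
#' @return list with \code{matrix} (filtered \code{gms_geno}) and
#'   \code{report} (data.frame: marker, missing_frac, n_classes, kept,
#'   reason), plus \code{n_kept}/\code{n_dropped} counts.
#' @export
apply_marker_filters <- function(mat, noise = noise_model(),
                                 drop_monomorphic = TRUE) {
  stopifnot(inherits(mat, "gms_geno"))
  if (ncol(mat$calls) == 0 || nrow(mat$calls) == 0)
    stop("empty genotype matrix")
  miss <- colMeans(is.na(mat$calls))
  ncls <- apply(mat$calls, 2, function(x) length(unique(x[!is.na(x)])))
  keep <- miss < noise$marker_missing_max
  reason <- ifelse(keep, "", "missingness")
  if (drop_monomorphic) {
    mono <- keep & ncls < 2L
    keep <- keep & !mono
    reason[mono] <- "monomorphic"
  }
  report <- data.frame(marker = colnames(mat$calls), missing_frac = miss,
                       n_classes = ncls, kept = keep, reason = reason,
                       row.names = NULL, stringsAsFactors = FALSE)
  out <- mat
  out$calls <- mat$calls[, keep, drop = FALSE]
  out$markers <- mat$markers[keep, , drop = FALSE]
  rownames(out$markers) <- NULL
  list(matrix = out, report = report,
       n_kept = sum(keep), n_dropped = sum(!keep))
}
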