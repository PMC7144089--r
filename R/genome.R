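#' Chromosome structure used by the genome simulator
#'
#' Ten linkage groups (A01-A10) with genetic lengths matching an F2 map of
#' Brassica rapa (total about 1,011 cM). Physical lengths follow a uniform
#' linear scale (default about 280 kb per cM, giving a genome of roughly
#' 283 Mb).
#'
#' @param bp_per_cM physical distance corresponding to one cM.
#' @return data.frame with columns chrom, length_cM, length_bp.
#' @export
brapa_chromosomes <- function(bp_per_cM = 2.8e5) {
  len <- c(107.8, 98.2, 132.6, 93.4, 107, 102.8, 82, 76.5, 135.8, 75.1)
  data.frame(chrom = sprintf("A%02d", 1:10), length_cM = len,
             length_bp = round(len * bp_per_cM), stringsAsFactors = FALSE)
}

#' Build a genome model with marker positions
#'
#' Markers are placed evenly along each chromosome (or at supplied physical
#' positions) with a monotone linear bp-to-cM map per chromosome.
#'
#' @param chromosomes data.frame with chrom, length_cM, length_bp
#'   (default \code{\link{brapa_chromosomes}()}).
#' @param markers_per_chrom number of evenly spaced markers per chromosome
#'   (ignored when \code{marker_positions} is given).
#' @param marker_positions optional data.frame (marker, chrom, bp).
#' @return Object of class \code{genome_model}: list(chromosomes, markers)
#'   where markers has columns marker, chrom, bp, cM.
#' @export
genome_model <- function(chromosomes = brapa_chromosomes(),
                         markers_per_chrom = 40,
                         marker_positions = NULL) {
  stopifnot(all(c("chrom", "length_cM", "length_bp") %in% names(chromosomes)))
  if (any(chromosomes$length_bp <= 0))
    stop("chromosome bp lengths must be > 0")
  if (is.null(marker_positions)) {
    mk <- do.call(rbind, lapply(seq_len(nrow(chromosomes)), function(i) {
      ch <- chromosomes[i, ]
      bp <- round(seq(ch$length_bp / (markers_per_chrom + 1), ch$length_bp,
                      length.out = markers_per_chrom))
      data.frame(marker = sprintf("%s_m%03d", ch$chrom, seq_len(markers_per_chrom)),
                 chrom = ch$chrom, bp = bp, stringsAsFactors = FALSE)
    }))
  } else {
    mk <- marker_positions[, c("marker", "chrom", "bp")]
    if (anyDuplicated(mk$marker)) stop("duplicate marker ids")
  }
  mk$cM <- bp_to_cM(mk$chrom, mk$bp, chromosomes)
  mk <- mk[order(match(mk$chrom, chromosomes$chrom), mk$bp), ]
  rownames(mk) <- NULL
  structure(list(chromosomes = chromosomes, markers = mk),
            class = "genome_model")
}

bp_to_cM <- function(chrom, bp, chromosomes) {
  i <- match(chrom, chromosomes$chrom)
  if (anyNA(i)) stop("unknown chromosome: ", chrom[is.na(i)][1])
  bad <- bp < 0 | bp > chromosomes$length_bp[i]
  if (any(bad)) stop("position outside chromosome bounds")
  bp / chromosomes$length_bp[i] * chromosomes$length_cM[i]
}

#' @export
print.genome_model <- function(x, ...) {
  cat("Genome model:", nrow(x$chromosomes), "chromosomes,",
      nrow(x$markers), "markers,",
      round(sum(x$chromosomes$length_cM), 1), "cM total\n")
  invisible(x)
}

#' Specify the trait (sterility) locus for simulation
#'
#' @param chrom,bp chromosome and physical position of each model locus (one
#'   value for the multi-allelic model, two for the two-gene model).
#' @param model the \code{gms_model} governing the phenotype.
#' @param founder_haps list with components P1 and P2: the trait-locus
#'   haplotype (one allele per model locus) carried by each homozygous
#'   founder. E.g. for an F2 of sterile x restorer under the multi-allelic
#'   model: \code{list(P1 = "b", P2 = "a")}.
#' @param genome a \code{genome_model} (used to map bp to cM and validate).
#' @return Object of class \code{trait_locus_spec}.
#' @export
trait_locus_spec <- function(chrom, bp, model, founder_haps, genome) {
  L <- n_loci(model)
  if (length(chrom) != L || length(bp) != L)
    stop("chrom and bp must give one position per model locus")
  if (length(founder_haps$P1) != L || length(founder_haps$P2) != L)
    stop("founder haplotypes must give one allele per model locus")
  # validate alleles by constructing the founder genotypes
  genotype(model, founder_haps$P1, founder_haps$P1)
  genotype(model, founder_haps$P2, founder_haps$P2)
  cM <- bp_to_cM(chrom, bp, genome$chromosomes)
  structure(list(chrom = chrom, bp = bp, cM = cM, model = model,
                 founder_haps = founder_haps),
            class = "trait_locus_spec")
}

#' GBS-style genotype-call noise model
#'
#' Per-call read depth is Poisson(mean_depth); a call is made only when depth
#' exceeds \code{depth_min} (strictly, matching a "more than five reads"
#' filter; set \code{depth_strict = FALSE} for >=). Heterozygous calls may
#' drop out to a random homozygote with probability 2^(1-d) at depth d (the
#' chance all sampled reads come from one allele).
#'
#' @param mean_depth mean reads per tag per individual (> 0).
#' @param depth_min minimum depth gate (default 5, strict greater-than).
#' @param depth_strict if TRUE a call requires depth > depth_min, else >=.
#' @param marker_missing_max markers missing in at least this fraction of the
#'   population are excluded (default 0.20, strict less-than kept).
#' @param het_dropout model allele dropout of heterozygotes (default TRUE).
#' @return Object of class \code{noise_model}.
#' @export
noise_model <- function(mean_depth = 10, depth_min = 5, depth_strict = TRUE,
                        marker_missing_max = 0.20, het_dropout = TRUE) {
  if (mean_depth <= 0) stop("mean_depth must be > 0")
  if (marker_missing_max < 0 || marker_missing_max > 1)
    stop("marker_missing_max must be in [0, 1]")
  structure(list(mean_depth = mean_depth, depth_min = depth_min,
                 depth_strict = depth_strict,
                 marker_missing_max = marker_missing_max,
                 het_dropout = het_dropout),
            class = "noise_model")
}

#' Mapping-population design
#'
#' @param cross_type "F2" (selfed F1 of P1 x P2) or "BC1" (F1 backcrossed to
#'   a recurrent parent).
#' @param n number of individuals (>= 1).
#' @param recurrent_parent "P1" or "P2" (BC1 only; default "P2", the
#'   maintainer in the sterility mapping scheme).
#' @param seed RNG seed; required, reproducibility is mandatory.
#' @return Object of class \code{population_design}.
#' @export
population_design <- function(cross_type = c("F2", "BC1"), n,
                              recurrent_parent = "P2", seed) {
  cross_type <- match.arg(cross_type)
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  if (n < 1) stop("n must be >= 1")
  if (cross_type == "BC1" && !recurrent_parent %in% c("P1", "P2"))
    stop("BC1 requires recurrent_parent 'P1' or 'P2'")
  structure(list(cross_type = cross_type, n = as.integer(n),
                 recurrent_parent = recurrent_parent, seed = as.integer(seed)),
            class = "population_design")
}
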