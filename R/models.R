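#' Define a genic male sterility (GMS) genetic model
#'
#' Two competing models of GMS inheritance in Brassica are supported. The
#' \emph{multi-allelic} model has one locus with a dominance series of three
#' alleles a > b > c, where only the middle allele b confers sterility when it
#' is the expressed (highest-ranked present) allele: b/b and b/c plants are
#' sterile, any genotype carrying a is fertile, and c/c is fertile. The
#' \emph{two-gene} model has a dominant sterility gene Ms and an independent
#' dominant restorer Rf: a plant is sterile iff it carries at least one Ms
#' allele and is homozygous rf/rf. The two loci may be linked; the
#' recombination fraction between them is a model parameter.
#'
#' @param model_id "multi_allelic" or "two_gene".
#' @param inter_locus_rf recombination fraction between Ms and Rf loci
#'   (two-gene model only), in [0, 0.5]. Default 0.5 (independent assortment).
#' @return An object of class \code{gms_model}: a list with the allele sets
#'   per locus, the dominance order (multi-allelic), and the sterility rule.
#' @examples
#' m <- gms_model("multi_allelic")
#' phenotype_of(genotype(m, "b", "c"), m)   # "sterile"
#' @export
gms_model <- function(model_id = c("multi_allelic", "two_gene"),
                      inter_locus_rf = 0.5) {
  model_id <- match.arg(model_id)
  if (model_id == "multi_allelic") {
    obj <- list(
      model_id = "multi_allelic",
      loci = list(Ms = c("a", "b", "c")),
      dominance = c("a", "b", "c"),   # most dominant first
      sterile_allele = "b",
      inter_locus_rf = NA_real_
    )
  } else {
    if (!is.numeric(inter_locus_rf) || length(inter_locus_rf) != 1L ||
        is.na(inter_locus_rf) || inter_locus_rf < 0 || inter_locus_rf > 0.5)
      stop("inter_locus_rf must be a single value in [0, 0.5]")
    obj <- list(
      model_id = "two_gene",
      loci = list(Ms = c("Ms", "ms"), Rf = c("Rf", "rf")),
      dominance = NULL,
      sterile_allele = "Ms",
      inter_locus_rf = inter_locus_rf
    )
  }
  class(obj) <- "gms_model"
  obj
}

#' @export
print.gms_model <- function(x, ...) {
  cat("GMS genetic model:", x$model_id, "\n")
  for (nm in names(x$loci))
    cat("  locus", nm, ": alleles", paste(x$loci[[nm]], collapse = ", "), "\n")
  if (x$model_id == "multi_allelic")
    cat("  dominance:", paste(x$dominance, collapse = " > "),
        " (sterile when expressed allele is", paste0(x$sterile_allele, ")\n"))
  else
    cat("  sterile iff >=1 Ms and rf/rf; inter-locus r =", x$inter_locus_rf, "\n")
  invisible(x)
}

n_loci <- function(model) length(model$loci)

hap_key <- function(h) paste(h, collapse = ":")

#' Construct a genotype under a GMS model
#'
#' A genotype is an unordered pair of haplotypes, each haplotype giving one
#' allele per locus. For two-locus heterozygotes the haplotype pairing encodes
#' linkage phase (coupling vs repulsion), which matters when the inter-locus
#' recombination fraction is below 0.5.
#'
#' @param model a \code{gms_model}.
#' @param hap1,hap2 character vectors, one allele per model locus.
#' @return Object of class \code{gms_genotype}: a 2 x L character matrix in
#'   canonical (sorted) haplotype order.
#' @export
genotype <- function(model, hap1, hap2) {
  L <- n_loci(model)
  hap1 <- as.character(hap1); hap2 <- as.character(hap2)
  if (length(hap1) != L || length(hap2) != L)
    stop("each haplotype must supply one allele per locus (", L, " loci)")
  for (i in seq_len(L)) {
    ok <- c(hap1[i], hap2[i]) %in% model$loci[[i]]
    if (!all(ok))
      stop("invalid genotype: allele not in allele set of locus ",
           names(model$loci)[i])
  }
  g <- rbind(hap1, hap2, deparse.level = 0)
  # canonical row order so that equality ignores haplotype labelling
  if (hap_key(g[2, ]) < hap_key(g[1, ])) g <- g[2:1, , drop = FALSE]
  structure(g, class = "gms_genotype")
}

geno_key <- function(g) paste(hap_key(g[1, ]), hap_key(g[2, ]), sep = "/")

geno_from_key <- function(key, model) {
  haps <- strsplit(key, "/", fixed = TRUE)[[1]]
  genotype(model, strsplit(haps[1], ":", fixed = TRUE)[[1]],
           strsplit(haps[2], ":", fixed = TRUE)[[1]])
}

#' @export
print.gms_genotype <- function(x, ...) {
  cat("<genotype ", geno_key(x), ">\n", sep = "")
  invisible(x)
}

new_dist <- function(prob) {
  # named numeric keyed by genotype/haplotype key; aggregate duplicates
  agg <- tapply(prob, names(prob), sum)
  p <- as.numeric(agg); names(p) <- names(agg)
  p[order(names(p))]
}

#' Gamete (haplotype) distribution of a genotype
#'
#' Enumerates the gametes of a parent by Mendelian segregation. One-locus
#' heterozygotes transmit each allele with probability 1/2. Two-locus
#' genotypes transmit the two parental haplotypes with probability (1-r)/2
#' each and the two recombinants with probability r/2 each, where r is the
#' model's inter-locus recombination fraction.
#'
#' @param g a \code{gms_genotype}.
#' @param model the \code{gms_model} it belongs to.
#' @return named numeric vector of haplotype probabilities (names are
#'   ":"-joined allele strings), summing to 1.
#' @export
gamete_distribution <- function(g, model) {
  stopifnot(inherits(g, "gms_genotype"))
  L <- n_loci(model)
  h1 <- g[1, ]; h2 <- g[2, ]
  if (L == 1L) {
    p <- c(0.5, 0.5); names(p) <- c(hap_key(h1), hap_key(h2))
  } else if (L == 2L) {
    r <- model$inter_locus_rf
    haps <- list(h1, h2, c(h1[1], h2[2]), c(h2[1], h1[2]))
    p <- c((1 - r) / 2, (1 - r) / 2, r / 2, r / 2)
    names(p) <- vapply(haps, hap_key, "")
  } else stop("models with more than two loci are not supported")
  new_dist(p)
}

#' Cross two genotypes
#'
#' Offspring genotype distribution as the outer product of the parents'
#' gamete distributions. Selfing is \code{cross_genotypes(g, g, model)}.
#'
#' @param p1,p2 parental \code{gms_genotype}s under the same model.
#' @param model the shared \code{gms_model}.
#' @return Object of class \code{gms_dist}: named numeric vector of genotype
#'   probabilities keyed by canonical genotype key, summing to 1.
#' @export
cross_genotypes <- function(p1, p2, model) {
  # re-validate both parents against the model (catches model mismatch)
  p1 <- genotype(model, p1[1, ], p1[2, ])
  p2 <- genotype(model, p2[1, ], p2[2, ])
  g1 <- gamete_distribution(p1, model)
  g2 <- gamete_distribution(p2, model)
  keys <- character(length(g1) * length(g2))
  prob <- numeric(length(keys))
  k <- 0L
  for (i in seq_along(g1)) for (j in seq_along(g2)) {
    k <- k + 1L
    off <- genotype(model,
                    strsplit(names(g1)[i], ":", fixed = TRUE)[[1]],
                    strsplit(names(g2)[j], ":", fixed = TRUE)[[1]])
    keys[k] <- geno_key(off)
    prob[k] <- g1[i] * g2[j]
  }
  names(prob) <- keys
  structure(new_dist(prob), class = "gms_dist")
}

#' @export
print.gms_dist <- function(x, ...) {
  cat("Offspring distribution (", length(x), " genotype classes):\n", sep = "")
  print(unclass(x))
  invisible(x)
}

#' Phenotype of a genotype under a GMS model
#'
#' Multi-allelic model: the expressed allele is the highest-ranked allele
#' present in the dominance series; the plant is sterile iff that allele is
#' the sterility allele b. Two-gene model: sterile iff the genotype carries at
#' least one Ms allele and is rf/rf.
#'
#' @param g a \code{gms_genotype} (or a genotype key string).
#' @param model the \code{gms_model}.
#' @return "sterile" or "fertile".
#' @export
phenotype_of <- function(g, model) {
  if (!inherits(g, "gms_genotype")) g <- geno_from_key(g, model)
  alleles1 <- c(g[1, 1], g[2, 1])
  if (model$model_id == "multi_allelic") {
    expressed <- model$dominance[min(match(alleles1, model$dominance))]
    if (expressed == model$sterile_allele) "sterile" else "fertile"
  } else {
    alleles2 <- c(g[1, 2], g[2, 2])
    if (any(alleles1 == "Ms") && all(alleles2 == "rf")) "sterile" else "fertile"
  }
}

#' Sterile fraction of an offspring distribution
#'
#' @param dist a \code{gms_dist} (or named probability vector keyed by
#'   genotype key).
#' @param model the \code{gms_model}.
#' @return proportion of sterile offspring in [0, 1].
#' @examples
#' m <- gms_model("multi_allelic")
#' f1 <- genotype(m, "a", "b")
#' sterile_fraction(cross_genotypes(f1, f1, m), m)  # exactly 0.25
#' @export
sterile_fraction <- function(dist, model) {
  ph <- vapply(names(dist), phenotype_of, "", model = model)
  sum(dist[ph == "sterile"])
}
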