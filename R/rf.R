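# Two-point linkage machinery. Genotype call coding: AA = homozygous for the
# sterile-line parent (P1), BB = homozygous P2, AB = heterozygous. BC1 calls
# are {AB, BB} (recurrent parent P2). Phase is known from the founders
# (coupling), so F2 class probabilities are explicit functions of r.

# Joint F2 class probabilities at recombination fraction r.
# trait = FALSE: 3 x 3 (marker1 class x marker2 class), classes AA/AB/BB.
# trait = TRUE: 3 x 2 (marker class x {sterile, fertile}) with the sterile
# class equal to the P1 homozygote at the trait locus (recessive-classified).
f2_class_probs <- function(r, trait = FALSE) {
  gam <- rbind(c(0L, 0L), c(1L, 1L), c(0L, 1L), c(1L, 0L))
  gp <- c((1 - r) / 2, (1 - r) / 2, r / 2, r / 2)
  P <- matrix(0, 3, if (trait) 2 else 3)
  for (i in 1:4) for (j in 1:4) {
    a <- gam[i, 1] + gam[j, 1]          # P2 allele count at marker 1
    b <- gam[i, 2] + gam[j, 2]          # ... at marker 2 / trait locus
    col <- if (trait) (if (b == 0) 1 else 2) else b + 1
    P[a + 1, col] <- P[a + 1, col] + gp[i] * gp[j]
  }
  P
}

code_column <- function(x, cross_type) {
  # character calls / phenotypes -> integer class index (marker: 1..3)
  if (all(x %in% c("sterile", "fertile", NA))) {
    if (cross_type == "BC1") {
      # sterile = heterozygous-equivalent class (coupling with P1 allele)
      out <- ifelse(x == "sterile", 2L, 3L)
      attr(out, "type") <- "marker"
    } else {
      out <- ifelse(x == "sterile", 1L, 2L)
      attr(out, "type") <- "trait"
    }
  } else if (all(x %in% c("AA", "AB", "BB", NA))) {
    out <- match(x, c("AA", "AB", "BB"))
    attr(out, "type") <- "marker"
  } else stop("unknown genotype/phenotype codes in column")
  out
}

f2_loglik <- function(r, N, trait) {
  P <- f2_class_probs(r, trait)
  keep <- N > 0
  if (any(keep & P == 0)) return(-Inf)
  sum(N[keep] * log(P[keep]))
}

#' Two-point recombination fraction and LOD score
#'
#' BC1: the recombination fraction is the recombinant proportion among
#' informative individuals, with LOD = k log10(2r) + (n-k) log10(2(1-r))
#' (the r = 0 limit gives n log10 2). F2: maximum-likelihood r by bounded
#' 1-D optimisation of the multinomial class likelihood, whose class
#' probabilities come from gamete enumeration with phase known from the
#' founders; a marker x trait column (binary phenotype, sterile = homozygous
#' sterile-allele class) uses the corresponding 3 x 2 table likelihood.
#' LOD = log10 L(r-hat) - log10 L(0.5).
#'
#' @param x,y character columns: marker calls (AA/AB/BB; BC1 AB/BB) or
#'   phenotypes (sterile/fertile). Missing values are dropped pairwise.
#' @param cross_type "F2" or "BC1".
#' @return Object of class \code{pairwise_linkage}: list(r_hat, lod,
#'   n_informative, undefined). Non-segregating columns give an undefined
#'   (flagged) result; zero informative individuals is an error.
#' @examples
#' # 10 recombinants among 100 BC1 plants
#' x <- rep(c("AB", "BB"), 50)
#' y <- x; y[1:10] <- ifelse(x[1:10] == "AB", "BB", "AB")
#' estimate_rf(x, y, "BC1")   # r_hat 0.1, LOD about 15.98
#' @export
estimate_rf <- function(x, y, cross_type = c("F2", "BC1")) {
  cross_type <- match.arg(cross_type)
  cx <- code_column(x, cross_type); cy <- code_column(y, cross_type)
  tx <- attr(cx, "type"); ty <- attr(cy, "type")
  keep <- !is.na(cx) & !is.na(cy)
  cx <- cx[keep]; cy <- cy[keep]
  n <- length(cx)
  if (n == 0) stop("zero informative individuals")
  res <- list(r_hat = NA_real_, lod = NA_real_, n_informative = n,
              undefined = FALSE, cross_type = cross_type)
  if (length(unique(cx)) < 2L || length(unique(cy)) < 2L) {
    # a non-segregating column carries no linkage information
    res$undefined <- TRUE
    class(res) <- "pairwise_linkage"
    return(res)
  }
  if (cross_type == "BC1") {
    k <- sum(cx != cy)
    r <- min(k / n, 0.5)
    lod <- if (k == 0) n * log10(2)
           else k * log10(2 * r) + (n - k) * log10(2 * (1 - r))
    res$r_hat <- r; res$lod <- max(lod, 0)
  } else {
    trait <- tx == "trait" || ty == "trait"
    if (tx == "trait" && ty == "trait")
      stop("cannot estimate linkage between two trait columns")
    if (tx == "trait") { tmp <- cx; cx <- cy; cy <- tmp }
    N <- matrix(0, 3, if (trait) 2 else 3)
    for (i in seq_len(n)) N[cx[i], cy[i]] <- N[cx[i], cy[i]] + 1
    opt <- stats::optimize(f2_loglik, c(1e-9, 0.5 - 1e-9), N = N,
                           trait = trait, maximum = TRUE, tol = 1e-10)
    r <- opt$maximum; ll <- opt$objective
    ll0 <- f2_loglik(0, N, trait)
    if (ll0 >= ll) { r <- 0; ll <- ll0 }
    if (r < 1e-8) r <- 0
    res$r_hat <- r
    res$lod <- max((ll - f2_loglik(0.5, N, trait)) / log(10), 0)
  }
  class(res) <- "pairwise_linkage"
  res
}

#' @export
print.pairwise_linkage <- function(x, ...) {
  if (x$undefined)
    cat("<linkage undefined (non-segregating column); n =",
        x$n_informative, ">\n")
  else
    cat(sprintf("<linkage r = %.4f, LOD = %.2f, n = %d>\n",
                x$r_hat, x$lod, x$n_informative))
  invisible(x)
}

#' Kosambi map function and its inverse
#'
#' Converts a recombination fraction to genetic distance,
#' d = 25 ln((1+2r)/(1-2r)) cM, and back, r = (e^(4d/100)-1) / (2(e^(4d/100)+1)).
#' The round trip is an identity to better than 1e-10.
#'
#' @param r recombination fraction(s) in [0, 0.5).
#' @return distance in cM.
#' @export
kosambi_cM <- function(r) {
  if (any(r < 0 | r >= 0.5)) stop("r must be in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi_cM
#' @param d_cM genetic distance(s) in cM (>= 0).
#' @export
kosambi_r <- function(d_cM) {
  if (any(d_cM < 0)) stop("distance must be >= 0")
  e <- exp(4 * d_cM / 100)
  (e - 1) / (2 * (e + 1))
}

#' All-pairs recombination fractions and LOD scores
#'
#' Vectorised two-point scan over every marker pair, used for linkage
#' grouping and ordering. F2 likelihoods are maximised on a fixed grid of r
#' values (step \code{grid_step}), which is ample for thresholding at the
#' grouping gates; the two-column \code{\link{estimate_rf}} is the precise
#' estimator. Missing calls are dropped pairwise via the count matrices.
#'
#' @param mat a \code{gms_geno}.
#' @param markers optional subset of marker ids.
#' @param grid_step grid resolution for the F2 likelihood scan.
#' @return list of m x m matrices: \code{r_hat}, \code{lod},
#'   \code{n_informative} (diagonals NA).
#' @export
pairwise_rf <- function(mat, markers = colnames(mat$calls),
                        grid_step = 1e-3) {
  stopifnot(inherits(mat, "gms_geno"))
  X <- mat$calls[, markers, drop = FALSE]
  m <- ncol(X)
  if (mat$cross_type == "BC1") {
    I1 <- (!is.na(X) & X == "AB") + 0; I2 <- (!is.na(X) & X == "BB") + 0
    K <- crossprod(I1, I2) + crossprod(I2, I1)            # recombinant pairs
    n <- crossprod(I1 + I2)
    r <- pmin(K / n, 0.5)
    lod <- ifelse(K == 0, n * log10(2),
                  K * log10(pmax(2 * r, 1e-300)) +
                    (n - K) * log10(2 * (1 - r)))
    lod <- pmax(lod, 0)
  } else {
    Ind <- lapply(c("AA", "AB", "BB"),
                  function(cc) (!is.na(X) & X == cc) + 0)
    N <- vector("list", 9L)   # N[[3*(a-1)+b]] = counts of class (a, b)
    for (a in 1:3) for (b in 1:3)
      N[[3L * (a - 1L) + b]] <- crossprod(Ind[[a]], Ind[[b]])
    n <- Reduce(`+`, N)
    grid <- seq(grid_step, 0.5 - grid_step, by = grid_step)
    bestLL <- matrix(-Inf, m, m); bestR <- matrix(NA_real_, m, m)
    ll_at <- function(rv) {
      P <- f2_class_probs(rv)
      LL <- matrix(0, m, m)
      for (a in 1:3) for (b in 1:3) {
        p <- P[a, b]
        if (p > 0) LL <- LL + N[[3L * (a - 1L) + b]] * log(p)
      }
      LL
    }
    for (rv in grid) {
      LL <- ll_at(rv)
      better <- LL > bestLL
      bestLL[better] <- LL[better]; bestR[better] <- rv
    }
    # r = 0 boundary (perfect cosegregation)
    P0 <- f2_class_probs(0)
    LL0 <- matrix(0, m, m); ok0 <- matrix(TRUE, m, m)
    for (a in 1:3) for (b in 1:3) {
      p <- P0[a, b]; Nc <- N[[3L * (a - 1L) + b]]
      if (p > 0) LL0 <- LL0 + Nc * log(p) else ok0 <- ok0 & (Nc == 0)
    }
    hit0 <- ok0 & LL0 >= bestLL
    bestLL[hit0] <- LL0[hit0]; bestR[hit0] <- 0
    r <- bestR
    lod <- pmax((bestLL - ll_at(0.5)) / log(10), 0)
  }
  dimnames(r) <- dimnames(lod) <- dimnames(n) <- list(markers, markers)
  diag(r) <- NA; diag(lod) <- NA
  list(r_hat = r, lod = lod, n_informative = n)
}
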