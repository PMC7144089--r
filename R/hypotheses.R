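#' Build a hypothesis: a model plus parental line genotypes
#'
#' A hypothesis assigns a genotype under one genetic model to each of the
#' three lines used in the crossing scheme: the male sterile line (default
#' name "NH80-A"), the restorer line ("TA95", whose F1 with the sterile line
#' is fertile) and the maintainer line ("WH606", whose F1 with the sterile
#' line is sterile).
#'
#' @param model a \code{gms_model}.
#' @param line_genotypes named list of \code{gms_genotype}s; names are line
#'   names and must include sterile, restorer and maintainer lines.
#' @param sterile_line,restorer_line,maintainer_line line names.
#' @return Object of class \code{gms_hypothesis}.
#' @export
gms_hypothesis <- function(model, line_genotypes,
                           sterile_line = "NH80-A",
                           restorer_line = "TA95",
                           maintainer_line = "WH606") {
  stopifnot(inherits(model, "gms_model"))
  need <- c(sterile_line, restorer_line, maintainer_line)
  if (!all(need %in% names(line_genotypes)))
    stop("line_genotypes must name the sterile, restorer and maintainer lines")
  if (phenotype_of(line_genotypes[[sterile_line]], model) != "sterile")
    stop("the sterile line's genotype must phenotype as sterile under the model")
  structure(list(model = model, line_genotypes = line_genotypes,
                 sterile_line = sterile_line, restorer_line = restorer_line,
                 maintainer_line = maintainer_line),
            class = "gms_hypothesis")
}

hyp_label <- function(h) {
  gk <- vapply(h$line_genotypes, geno_key, "")
  paste0(h$model$model_id, ": ",
         paste(names(gk), gk, sep = "=", collapse = ", "))
}

#' @export
print.gms_hypothesis <- function(x, ...) {
  cat("<hypothesis ", hyp_label(x), ">\n", sep = "")
  invisible(x)
}

#' Default cross-outcome constraints of the three-line scheme
#'
#' The deterministic observations used to enumerate candidate hypotheses:
#' the sterile line is sterile; restorer and maintainer are fertile; their
#' selfs do not segregate; F1(sterile x restorer) is all fertile;
#' F1(sterile x maintainer) is all sterile; F1(restorer x maintainer) is all
#' fertile.
#'
#' @return data.frame with columns type ("phenotype", "self", "f1"),
#'   line1, line2, outcome.
#' @export
table1_constraints <- function() {
  data.frame(
    type = c("phenotype", "phenotype", "phenotype", "self", "self",
             "f1", "f1", "f1"),
    line1 = c("NH80-A", "TA95", "WH606", "TA95", "WH606",
              "NH80-A", "NH80-A", "TA95"),
    line2 = c(NA, NA, NA, NA, NA, "TA95", "WH606", "WH606"),
    outcome = c("sterile", "fertile", "fertile", "all_fertile", "all_fertile",
                "all_fertile", "all_sterile", "all_fertile"),
    stringsAsFactors = FALSE
  )
}

all_genotypes <- function(model, homozygous_only = FALSE) {
  # all unordered haplotype pairs (phase-distinct for two-locus heterozygotes)
  haps <- expand.grid(lapply(model$loci, identity), stringsAsFactors = FALSE)
  haps <- lapply(seq_len(nrow(haps)), function(i) as.character(haps[i, ]))
  out <- list()
  for (i in seq_along(haps)) for (j in i:length(haps)) {
    if (homozygous_only && i != j) next
    out[[length(out) + 1L]] <- genotype(model, haps[[i]], haps[[j]])
  }
  out
}

check_constraints <- function(model, gens, constraints, tol = 1e-12) {
  # gens: named list of genotypes for the three lines
  for (k in seq_len(nrow(constraints))) {
    row <- constraints[k, ]
    if (row$type == "phenotype") {
      if (phenotype_of(gens[[row$line1]], model) != row$outcome) return(FALSE)
    } else {
      p1 <- gens[[row$line1]]
      p2 <- if (row$type == "self") p1 else gens[[row$line2]]
      sf <- sterile_fraction(cross_genotypes(p1, p2, model), model)
      ok <- switch(row$outcome,
                   all_fertile = sf < tol,
                   all_sterile = sf > 1 - tol,
                   segregating = sf > tol && sf < 1 - tol,
                   stop("unknown constraint outcome: ", row$outcome))
      if (!ok) return(FALSE)
    }
  }
  TRUE
}

#' Enumerate hypotheses consistent with the observed cross outcomes
#'
#' Exhaustively assigns genotypes to the three lines under each candidate
#' model and keeps assignments consistent with all deterministic constraints
#' (line phenotypes, non-segregating selfs, all-fertile / all-sterile F1s).
#' Under the multi-allelic model exactly one assignment survives the default
#' constraints (sterile line b/b, restorer a/a, maintainer c/c); under the
#' two-gene model the surviving restorer genotypes are homozygous RfRf
#' carriers (MsMs RfRf, msms RfRf; plus Msms RfRf when
#' \code{inbred_homozygous = FALSE}).
#'
#' @param constraints data.frame as \code{\link{table1_constraints}}.
#' @param models list of candidate \code{gms_model}s.
#' @param inbred_homozygous if TRUE (default) restorer and maintainer lines,
#'   being advanced inbreds, are restricted to fully homozygous genotypes.
#' @return list of \code{gms_hypothesis} (possibly empty; contradictory
#'   constraints yield an empty list, not an error).
#' @export
enumerate_hypotheses <- function(constraints = table1_constraints(),
                                 models = list(gms_model("multi_allelic"),
                                               gms_model("two_gene")),
                                 inbred_homozygous = TRUE) {
  out <- list()
  lines <- c("NH80-A", "TA95", "WH606")
  for (model in models) {
    gA <- all_genotypes(model, homozygous_only = FALSE)
    gI <- all_genotypes(model, homozygous_only = inbred_homozygous)
    for (a in gA) {
      if (phenotype_of(a, model) != "sterile") next
      for (t in gI) for (w in gI) {
        gens <- list(a, t, w); names(gens) <- lines
        if (check_constraints(model, gens, constraints))
          out[[length(out) + 1L]] <- gms_hypothesis(model, gens)
      }
    }
  }
  out
}

#' Progeny test design
#'
#' Test A: F2 subpopulations from selfed (sterile x restorer) F1 plants,
#' scored for segregation. Test B: testcrosses of sterile F2 plants (from
#' test A's families) to the maintainer. Test C: F2 subpopulations from
#' selfed (restorer x maintainer) F1 plants. A family "segregates" iff it
#' contains at least one sterile and at least one fertile plant.
#'
#' @param test_id "A", "B" or "C".
#' @param n_families number of families scored.
#' @param n_per_family plants scored per family.
#' @return Object of class \code{progeny_test_design}.
#' @export
progeny_test_design <- function(test_id = c("A", "B", "C"), n_families,
                                n_per_family) {
  test_id <- match.arg(test_id)
  if (n_families < 1L || n_per_family < 1L)
    stop("n_families and n_per_family must be >= 1")
  structure(list(test_id = test_id, n_families = as.integer(n_families),
                 n_per_family = as.integer(n_per_family)),
            class = "progeny_test_design")
}

#' The three progeny-test designs used in the study
#'
#' 64 F2 subpopulations of 60 plants (test A), 40 testcross families of 20
#' plants (test B), 25 F2 subpopulations of 60 plants (test C).
#' @return named list of \code{progeny_test_design}s.
#' @export
study_designs <- function() {
  list(A = progeny_test_design("A", 64, 60),
       B = progeny_test_design("B", 40, 20),
       C = progeny_test_design("C", 25, 60))
}

# Per-family sterile-fraction mixture for a test under a hypothesis:
# a list with weights w and sterile fractions p, one entry per possible
# family-parent genotype (weight = probability that a family has that parent).
family_mixture <- function(h, test_id) {
  model <- h$model
  A <- h$line_genotypes[[h$sterile_line]]
  Tt <- h$line_genotypes[[h$restorer_line]]
  W <- h$line_genotypes[[h$maintainer_line]]
  if (test_id == "A") {
    f1 <- cross_genotypes(A, Tt, model)
    w <- as.numeric(f1)
    p <- vapply(names(f1), function(k) {
      g <- geno_from_key(k, model)
      sterile_fraction(cross_genotypes(g, g, model), model)
    }, 0)
  } else if (test_id == "B") {
    f1 <- cross_genotypes(A, Tt, model)
    # F2 distribution marginalised over F1 parents, conditioned on sterility
    f2 <- numeric(0)
    for (k in names(f1)) {
      g <- geno_from_key(k, model)
      d <- cross_genotypes(g, g, model) * f1[[k]]
      f2 <- new_dist(c(f2, d))
    }
    ph <- vapply(names(f2), phenotype_of, "", model = model)
    st <- f2[ph == "sterile"]
    if (sum(st) == 0) return(list(w = numeric(0), p = numeric(0)))
    w <- as.numeric(st / sum(st))
    p <- vapply(names(st), function(k) {
      g <- geno_from_key(k, model)
      sterile_fraction(cross_genotypes(g, W, model), model)
    }, 0)
  } else if (test_id == "C") {
    f1 <- cross_genotypes(Tt, W, model)
    w <- as.numeric(f1)
    p <- vapply(names(f1), function(k) {
      g <- geno_from_key(k, model)
      sterile_fraction(cross_genotypes(g, g, model), model)
    }, 0)
  } else stop("unknown test_id: ", test_id)
  list(w = w, p = p)
}

outcome_prob <- function(outcome, mix, n) {
  # marginalise family outcome probability over the parent-genotype mixture
  f <- switch(outcome,
              all_sterile = function(p) p^n,
              all_fertile = function(p) (1 - p)^n,
              segregating = function(p) 1 - p^n - (1 - p)^n,
              stop("unknown outcome: ", outcome))
  sum(mix$w * f(mix$p))
}

#' Log-likelihood of progeny-test observations under a hypothesis
#'
#' Each family's outcome probability follows from its sterile fraction p and
#' family size n: P(all fertile) = (1-p)^n, P(all sterile) = p^n,
#' P(segregating) = 1 - p^n - (1-p)^n. For test B the family parent is a
#' sterile F2 plant, so p is marginalised over the conditional genotype
#' distribution of a sterile F2 individual. Families multiply (log-sum).
#' An impossible observation set returns the -1e9 sentinel so that rankings
#' over hypotheses remain total.
#'
#' @param h a \code{gms_hypothesis}.
#' @param design a \code{progeny_test_design}.
#' @param obs a \code{progeny_test_observation} (see
#'   \code{\link{progeny_test_observation}}) for the same test.
#' @return total natural-log likelihood (scalar).
#' @export
progeny_test_loglik <- function(h, design, obs) {
  stopifnot(inherits(h, "gms_hypothesis"),
            inherits(design, "progeny_test_design"))
  if (obs$test_id != design$test_id)
    stop("observation test_id does not match design")
  if (length(obs$outcomes) != design$n_families)
    stop("family count does not match design")
  if (design$n_per_family < 1L) stop("family size must be >= 1")
  mix <- family_mixture(h, design$test_id)
  if (length(mix$w) == 0) return(-1e9)
  ll <- 0
  for (o in unique(obs$outcomes)) {
    k <- sum(obs$outcomes == o)
    pr <- outcome_prob(o, mix, design$n_per_family)
    if (pr <= 0) return(-1e9)
    ll <- ll + k * log(pr)
  }
  ll
}

#' Construct a set of per-family progeny-test outcomes
#'
#' @param test_id "A", "B" or "C".
#' @param outcomes character vector, one of "segregating", "all_sterile",
#'   "all_fertile" per family.
#' @return Object of class \code{progeny_test_observation}.
#' @export
progeny_test_observation <- function(test_id, outcomes) {
  ok <- outcomes %in% c("segregating", "all_sterile", "all_fertile")
  if (!all(ok)) stop("unknown outcome: ", outcomes[!ok][1])
  structure(list(test_id = test_id, outcomes = outcomes),
            class = "progeny_test_observation")
}

#' The study's observed progeny-test outcomes
#'
#' All 64 test-A families segregated, all 40 test-B families were entirely
#' sterile, and all 25 test-C families were entirely fertile.
#' @return named list of \code{progeny_test_observation}s.
#' @export
study_observations <- function() {
  list(A = progeny_test_observation("A", rep("segregating", 64)),
       B = progeny_test_observation("B", rep("all_sterile", 40)),
       C = progeny_test_observation("C", rep("all_fertile", 25)))
}

#' Rank hypotheses by total progeny-test log-likelihood
#'
#' Sums \code{\link{progeny_test_loglik}} over the three tests for each
#' hypothesis and ranks. Ties are broken by input order, and the result is
#' invariant to the order of hypotheses (up to ties) and of families.
#'
#' @param hypotheses non-empty list of \code{gms_hypothesis}.
#' @param designs,observations named lists keyed by test id.
#' @return data.frame (ranked): hypothesis label, model, logLik, delta to the
#'   best; the hypothesis list (ranked) is attached as attribute
#'   \code{"hypotheses"}.
#' @export
discriminate <- function(hypotheses, designs, observations) {
  if (length(hypotheses) == 0) stop("empty hypothesis list")
  ll <- vapply(hypotheses, function(h) {
    sum(vapply(names(observations), function(tid)
      progeny_test_loglik(h, designs[[tid]], observations[[tid]]), 0))
  }, 0)
  ord <- order(-ll)  # stable: ties keep enumeration order
  res <- data.frame(
    hypothesis = vapply(hypotheses, hyp_label, "")[ord],
    model = vapply(hypotheses, function(h) h$model$model_id, "")[ord],
    logLik = ll[ord],
    delta = ll[ord] - max(ll),
    stringsAsFactors = FALSE
  )
  attr(res, "hypotheses") <- hypotheses[ord]
  res
}

#' Fit GMS genetic models to progeny-test data
#'
#' The package's model-fitting front end: enumerates every hypothesis (model
#' plus line-genotype assignment) consistent with the deterministic cross
#' outcomes, evaluates each against the progeny-test observations by
#' likelihood, and returns the ranked fit.
#'
#' @param observations named list of \code{progeny_test_observation}s
#'   (default: the study's outcomes).
#' @param designs named list of \code{progeny_test_design}s.
#' @param constraints deterministic cross-outcome constraints used for
#'   hypothesis enumeration.
#' @param models candidate \code{gms_model}s.
#' @param inbred_homozygous restrict inbred lines to homozygous genotypes.
#' @return Object of class \code{gms_fit} with the ranking, the best
#'   hypothesis, and the inputs; methods: \code{print}, \code{summary},
#'   \code{logLik}, \code{simulate}.
#' @examples
#' fit <- gms_fit()
#' fit$best$model$model_id   # "multi_allelic"
#' @export
gms_fit <- function(observations = study_observations(),
                    designs = study_designs(),
                    constraints = table1_constraints(),
                    models = list(gms_model("multi_allelic"),
                                  gms_model("two_gene")),
                    inbred_homozygous = TRUE) {
  hyps <- enumerate_hypotheses(constraints, models, inbred_homozygous)
  if (length(hyps) == 0)
    stop("no hypothesis is consistent with the supplied constraints")
  ranking <- discriminate(hyps, designs, observations)
  structure(list(ranking = ranking,
                 best = attr(ranking, "hypotheses")[[1]],
                 hypotheses = attr(ranking, "hypotheses"),
                 designs = designs, observations = observations),
            class = "gms_fit")
}

#' @export
print.gms_fit <- function(x, ...) {
  cat("GMS model discrimination (", nrow(x$ranking), " hypotheses)\n", sep = "")
  cat("Best:", x$ranking$hypothesis[1], "\n")
  if (nrow(x$ranking) > 1)
    cat("Log-likelihood advantage over runner-up:",
        format(x$ranking$logLik[1] - x$ranking$logLik[2], digits = 4), "\n")
  invisible(x)
}

#' @export
summary.gms_fit <- function(object, ...) {
  cat("Ranked hypotheses by total progeny-test log-likelihood:\n")
  print(object$ranking[, c("hypothesis", "logLik", "delta")],
        row.names = FALSE)
  invisible(object$ranking)
}

#' @export
logLik.gms_fit <- function(object, ...) {
  structure(object$ranking$logLik[1], class = "logLik",
            df = 0, nobs = sum(vapply(object$designs,
                                      function(d) d$n_families, 0L)))
}

#' Simulate progeny-test observations from a fitted hypothesis
#'
#' @param object a \code{gms_fit}.
#' @param nsim number of replicate observation sets.
#' @param seed RNG seed (required for reproducibility).
#' @param hypothesis which hypothesis to simulate under (default the best).
#' @param ... unused.
#' @return list of length \code{nsim}; each element a named list of
#'   \code{progeny_test_observation}s.
#' @export
simulate.gms_fit <- function(object, nsim = 1, seed = NULL,
                             hypothesis = object$best, ...) {
  if (is.null(seed)) stop("seed is required")
  set.seed(seed)
  replicate(nsim, simulate_progeny_tests(hypothesis, object$designs),
            simplify = FALSE)
}

#' Simulate progeny-test outcomes under a hypothesis
#'
#' Families are drawn by sampling the family parent from the test's parent
#' mixture (for test B, the conditional genotype distribution of a sterile F2
#' plant), then sampling the family's sterile count binomially at that
#' parent's sterile fraction, and classifying the family outcome.
#'
#' @param h a \code{gms_hypothesis}.
#' @param designs named list of \code{progeny_test_design}s.
#' @param seed optional RNG seed; if NULL the current RNG stream is used.
#' @return named list of \code{progeny_test_observation}s, with the simulated
#'   sterile counts attached as attribute \code{"n_sterile"}.
#' @export
simulate_progeny_tests <- function(h, designs = study_designs(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (tid in names(designs)) {
    d <- designs[[tid]]
    mix <- family_mixture(h, d$test_id)
    if (length(mix$w) == 0)
      stop("no possible family parent for test ", tid, " under this hypothesis")
    parent <- sample.int(length(mix$w), d$n_families, replace = TRUE,
                         prob = mix$w)
    ns <- stats::rbinom(d$n_families, d$n_per_family, mix$p[parent])
    outc <- ifelse(ns == 0L, "all_fertile",
                   ifelse(ns == d$n_per_family, "all_sterile", "segregating"))
    ob <- progeny_test_observation(d$test_id, outc)
    attr(ob, "n_sterile") <- ns
    out[[tid]] <- ob
  }
  out
}
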