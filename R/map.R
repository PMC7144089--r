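# Linkage grouping, marker ordering, bin construction, trait placement and
# map summaries.

#' Form linkage groups by thresholded single linkage
#'
#' Markers are joined when their pairwise recombination fraction is strictly
#' below \code{rf_max} and the LOD score strictly above \code{lod_min}
#' (defaults r < 0.3, LOD > 7); groups are the connected components of that
#' graph (transitive closure). Groups are numbered by decreasing size, ties
#' by lexicographically smallest member id; singleton markers form singleton
#' groups.
#'
#' @param mat a \code{gms_geno}.
#' @param rf_max,lod_min grouping gates (strict).
#' @param pw optional precomputed \code{\link{pairwise_rf}} result.
#' @return named list ("LG1", "LG2", ...) of character vectors of marker ids.
#' @export
form_groups <- function(mat, rf_max = 0.3, lod_min = 7, pw = NULL) {
  markers <- colnames(mat$calls)
  m <- length(markers)
  if (is.null(pw)) pw <- pairwise_rf(mat)
  adj <- !is.na(pw$r_hat) & pw$r_hat < rf_max & pw$lod > lod_min
  # union-find over markers
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(m)) {
    js <- which(adj[i, ])
    for (j in js[js > i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  root <- vapply(seq_len(m), find, 0L)
  comps <- split(markers, root)
  first <- vapply(comps, min, "")
  comps <- comps[order(-lengths(comps), first)]
  names(comps) <- paste0("LG", seq_along(comps))
  lapply(comps, unname)
}

#' Order markers within a linkage group
#'
#' Greedy chain construction (seeded at the most distant marker pair,
#' repeatedly appending the unplaced marker closest to either chain end)
#' followed by 2-opt refinement, minimising the sum of adjacent
#' recombination fractions. Deterministic for a given input. Alternatively
#' order by supplied physical position (\code{by = "bp"}).
#'
#' @param markers character vector of marker ids (a linkage group).
#' @param mat a \code{gms_geno}.
#' @param by "rf" (likelihood-based seriation) or "bp" (physical order).
#' @param pw optional precomputed \code{\link{pairwise_rf}} over at least
#'   these markers.
#' @return markers in map order.
#' @export
order_markers <- function(markers, mat, by = c("rf", "bp"), pw = NULL) {
  by <- match.arg(by)
  if (length(markers) <= 2L && by == "rf") return(markers)
  if (by == "bp") {
    meta <- mat$markers[match(markers, mat$markers$marker), ]
    return(markers[order(meta$bp)])
  }
  if (is.null(pw)) pw <- pairwise_rf(mat, markers)
  D <- pw$r_hat[markers, markers]
  D[is.na(D)] <- 0.5
  diag(D) <- 0
  m <- length(markers)
  # seed: most distant pair (ties: first in marker order)
  Doff <- D; diag(Doff) <- -1
  far <- which(Doff == max(Doff), arr.ind = TRUE)[1, ]
  chain <- c(far[1], far[2])
  left <- setdiff(seq_len(m), chain)
  while (length(left)) {
    dl <- D[chain[1], left]; dr <- D[chain[length(chain)], left]
    if (min(dl) <= min(dr)) {
      k <- left[which.min(dl)]; chain <- c(k, chain)
    } else {
      k <- left[which.min(dr)]; chain <- c(chain, k)
    }
    left <- setdiff(left, k)
  }
  chain <- two_opt(chain, D)
  markers[chain]
}

two_opt <- function(ord, D) {
  path_len <- function(o) sum(D[cbind(o[-length(o)], o[-1])])
  best <- path_len(ord)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    m <- length(ord)
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      cand <- ord
      cand[i:j] <- rev(cand[i:j])
      l <- path_len(cand)
      if (l < best - 1e-12) { ord <- cand; best <- l; improved <- TRUE }
    }
  }
  ord
}

#' Merge closely linked markers into recombination bins
#'
#' Scans adjacent markers in map order, merging a marker into the current
#' bin while the adjacent genetic distance is below \code{merge_below_cM}
#' and zero recombination events are observed between them (identical
#' non-missing call patterns); adjacent bins are therefore separated by at
#' least one observed recombination event. One member per bin is chosen as
#' the bin representative, uniformly at random under a dedicated seeded RNG
#' stream, and map distances are recalculated between representatives.
#'
#' @param markers_ordered markers in map order (see
#'   \code{\link{order_markers}}).
#' @param mat a \code{gms_geno}.
#' @param merge_below_cM merge threshold (strict; default 0.5 cM).
#' @param rep_seed seed of the representative-selection RNG stream.
#' @return Object of class \code{gms_binned}: list with \code{bins} (each:
#'   members, representative, n_markers), and \code{map} (data.frame: marker
#'   = representative, cM, bp, n_markers).
#' @export
make_bins <- function(markers_ordered, mat, merge_below_cM = 0.5,
                      rep_seed = 1L) {
  stopifnot(inherits(mat, "gms_geno"))
  if (!all(markers_ordered %in% colnames(mat$calls)))
    stop("unknown markers in ordered list")
  X <- mat$calls[, markers_ordered, drop = FALSE]
  m <- ncol(X)
  n_events <- function(i, j) {
    ok <- !is.na(X[, i]) & !is.na(X[, j])
    sum(X[ok, i] != X[ok, j])
  }
  groups <- list(); cur <- 1L
  if (m > 1) for (k in 2:m) {
    # zero observed recombination against every current member (missing
    # calls make the adjacent-only check non-transitive)
    ev <- vapply(cur, n_events, 0L, j = k)
    est <- estimate_rf(X[, k - 1L], X[, k], mat$cross_type)
    d <- if (isTRUE(est$undefined) || est$r_hat >= 0.5) Inf
         else kosambi_cM(est$r_hat)
    if (all(ev == 0L) && d < merge_below_cM) cur <- c(cur, k)
    else { groups[[length(groups) + 1L]] <- cur; cur <- k }
  }
  groups[[length(groups) + 1L]] <- cur

  reps <- with_seed(rep_seed, vapply(groups, function(g)
    g[sample.int(length(g), 1L)], 0L))
  bins <- lapply(seq_along(groups), function(b) list(
    members = markers_ordered[groups[[b]]],
    representative = markers_ordered[reps[b]],
    n_markers = length(groups[[b]])))

  rep_ids <- vapply(bins, `[[`, "", "representative")
  cM <- numeric(length(rep_ids))
  if (length(rep_ids) > 1) for (k in 2:length(rep_ids)) {
    est <- estimate_rf(X[, reps[k - 1L]], X[, reps[k]], mat$cross_type)
    r <- if (isTRUE(est$undefined)) 0.5 - 1e-9 else min(est$r_hat, 0.5 - 1e-9)
    cM[k] <- cM[k - 1L] + kosambi_cM(r)
  }
  meta <- mat$markers[match(rep_ids, mat$markers$marker), ]
  map <- data.frame(marker = rep_ids, cM = cM, bp = meta$bp,
                    n_markers = vapply(bins, `[[`, 0L, "n_markers"),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(bins = bins, map = map), class = "gms_binned")
}

with_seed <- function(seed, expr) {
  # evaluate expr under a private RNG stream, restoring global state
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.gms_binned <- function(x, ...) {
  cat("Binned map:", length(x$bins), "bins over",
      sum(x$map$n_markers), "markers; length",
      round(max(x$map$cM), 1), "cM\n")
  invisible(x)
}

#' Place the sterility trait on a marker map
#'
#' The phenotype is treated as a morphological marker: recessive-classified
#' in an F2 (sterile plants are the homozygous sterile-allele class) and
#' codominant-equivalent in a BC1. The trait is inserted into the map at the
#' position minimising the recombination fraction to its neighbours, with
#' its position interpolated by Kosambi distance from the nearest marker;
#' markers with zero recombination to the trait are reported as
#' cosegregating. If no marker reaches \code{lod_min} the trait is reported
#' unplaced for that map.
#'
#' @param map data.frame with columns marker and cM, in map order (e.g. the
#'   \code{map} element of \code{\link{make_bins}}).
#' @param mat a \code{gms_geno} containing those markers and a non-constant
#'   phenotype.
#' @param lod_min minimum LOD linking the trait to the group (default 3).
#' @return list: \code{map} (with a "TRAIT" row inserted when placed),
#'   \code{placed}, \code{position_cM}, \code{nearest_marker}, \code{r_hat},
#'   \code{lod}, \code{cosegregating} (marker ids with r = 0).
#' @export
place_trait <- function(map, mat, lod_min = 3) {
  if (length(unique(mat$phenotype)) < 2L)
    stop("constant phenotype: trait cannot be placed")
  trait <- mat$phenotype
  ests <- lapply(map$marker, function(mk)
    estimate_rf(mat$calls[, mk], trait, mat$cross_type))
  r <- vapply(ests, function(e) if (isTRUE(e$undefined)) NA_real_ else e$r_hat, 0)
  lod <- vapply(ests, function(e) if (isTRUE(e$undefined)) 0 else e$lod, 0)
  if (all(is.na(r)) || max(lod, na.rm = TRUE) <= lod_min)
    return(list(map = map, placed = FALSE, position_cM = NA_real_,
                nearest_marker = NA_character_, r_hat = NA_real_,
                lod = max(lod, na.rm = TRUE),
                cosegregating = character(0)))
  best <- which.min(ifelse(is.na(r), Inf, r))
  rb <- r[best]
  d <- kosambi_cM(min(rb, 0.5 - 1e-9))
  # choose the side of the nearest marker by the neighbour with smaller r
  m <- nrow(map)
  left_r <- if (best > 1) r[best - 1] else Inf
  right_r <- if (best < m) r[best + 1] else Inf
  pos <- if (rb == 0) map$cM[best]
         else if (left_r <= right_r) map$cM[best] - d else map$cM[best] + d
  pos <- min(max(pos, min(map$cM)), max(map$cM))
  trait_row <- data.frame(marker = "TRAIT", cM = pos,
                          stringsAsFactors = FALSE)
  for (cc in setdiff(names(map), names(trait_row))) trait_row[[cc]] <- NA
  out <- rbind(map, trait_row[, names(map)])
  out <- out[order(out$cM, out$marker != "TRAIT"), ]
  rownames(out) <- NULL
  list(map = out, placed = TRUE, position_cM = pos,
       nearest_marker = map$marker[best], r_hat = rb, lod = lod[best],
       cosegregating = map$marker[!is.na(r) & r == 0])
}

#' Linkage-map summary table
#'
#' Per linkage group: map length, SNP / polymorphic-tag / bin counts, and
#' the derived ratios SNPs per tag, tags per bin and mean inter-bin interval
#' (cM per bin), each reported to one decimal; plus a totals row whose
#' ratios are quotients of the summed counts.
#'
#' @param groups data.frame with columns group, length_cM, n_snp, n_tags,
#'   n_bins (one row per linkage group).
#' @return data.frame with the input columns plus snps_per_tag,
#'   tags_per_bin, cM_per_bin, and a final "Total" row.
#' @examples
#' map_summary(data.frame(group = "A01", length_cM = 107.8, n_snp = 384,
#'                        n_tags = 206, n_bins = 58))
#' @export
map_summary <- function(groups) {
  need <- c("group", "length_cM", "n_snp", "n_tags", "n_bins")
  stopifnot(all(need %in% names(groups)))
  if (nrow(groups) == 0 || any(groups$n_bins < 1) || any(groups$n_tags < 1))
    stop("each group needs at least one tag and one bin")
  tot <- data.frame(group = "Total",
                    length_cM = sum(groups$length_cM),
                    n_snp = sum(groups$n_snp),
                    n_tags = sum(groups$n_tags),
                    n_bins = sum(groups$n_bins),
                    stringsAsFactors = FALSE)
  out <- rbind(groups[, need], tot)
  out$snps_per_tag <- round(out$n_snp / out$n_tags, 1)
  out$tags_per_bin <- round(out$n_tags / out$n_bins, 1)
  out$cM_per_bin <- round(out$length_cM / out$n_bins, 1)
  rownames(out) <- NULL
  out
}
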