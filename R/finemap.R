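# Recombinant screening between flanking markers and the sterility locus in
# large F2 panels, plus cosegregation testing of candidate-gene markers.
#
# Under the recessive trait classification of an F2 (sterile plants are the
# homozygous sterile-parent class), an individual is recombinant on one side
# when its marker genotype class is impossible without at least one crossover
# in the marker-trait interval: a sterile plant not homozygous for the
# sterile-parent allele (AA), or a fertile plant that is AA. Fertile
# heterozygotes are NOT recombinant evidence (their phenotype class is
# compatible with multiple trait genotypes at zero crossovers).

side_recombinant <- function(call, phen) {
  ifelse(is.na(call), NA,
         ifelse(phen == "sterile", call != "AA", call == "AA"))
}

#' Screen an F2 panel for recombinants between flanking markers and the trait
#'
#' @param mat a \code{gms_geno} (F2, phenotype present, phase known from
#'   founders: AA = sterile-parent homozygote).
#' @param left_marker,right_marker flanking marker ids.
#' @return Object of class \code{recombinant_records}: data.frame of flagged
#'   plants (individual, left_call, right_call, phenotype, side in
#'   left/right/double). Individuals missing both flanking genotypes are
#'   skipped; their ids are attached as attribute \code{"skipped"}. The
#'   total screened is attribute \code{"n_screened"}.
#' @export
find_recombinants <- function(mat, left_marker, right_marker) {
  stopifnot(inherits(mat, "gms_geno"))
  if (mat$cross_type != "F2")
    stop("recombinant screening expects an F2 panel")
  gl <- mat$calls[, left_marker]
  gr <- mat$calls[, right_marker]
  phen <- mat$phenotype
  skipped <- rownames(mat$calls)[is.na(gl) & is.na(gr)]
  rl <- side_recombinant(gl, phen)
  rr <- side_recombinant(gr, phen)
  is_rec <- (!is.na(rl) & rl) | (!is.na(rr) & rr)
  side <- ifelse(!is.na(rl) & rl & !is.na(rr) & rr, "double",
                 ifelse(!is.na(rl) & rl, "left", "right"))
  out <- data.frame(individual = rownames(mat$calls)[is_rec],
                    left_call = gl[is_rec], right_call = gr[is_rec],
                    phenotype = phen[is_rec], side = side[is_rec],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  attr(out, "n_screened") <- nrow(mat$calls) - length(skipped)
  class(out) <- c("recombinant_records", "data.frame")
  out
}

#' Percentage of recombinant plants
#'
#' Each plant counts once, however many crossover events it carries.
#'
#' @param records a \code{recombinant_records} (or anything with
#'   \code{nrow}).
#' @param n number of plants screened (> 0).
#' @return 100 * n_recombinant / n, rounded (half to even) to 2 decimals.
#' @examples
#' recombinant_percentage(data.frame(id = 1:3), 1590)  # 0.19
#' @export
recombinant_percentage <- function(records, n) {
  if (n <= 0) stop("n must be > 0")
  round(100 * nrow(records) / n, 2)
}

#' Marker-trait genetic distance
#'
#' Maximum-likelihood recombination fraction between a marker and the
#' sterility trait (via \code{\link{estimate_rf}}) converted to cM with the
#' Kosambi function. A marker whose LOD falls below \code{lod_min} is
#' reported unlinked.
#'
#' @param mat a \code{gms_geno}.
#' @param marker marker id.
#' @param lod_min LOD below which the marker is flagged unlinked (default 3).
#' @return list: r_hat, lod, cM (NA when unlinked), unlinked.
#' @export
marker_trait_distance <- function(mat, marker, lod_min = 3) {
  est <- estimate_rf(mat$calls[, marker], mat$phenotype, mat$cross_type)
  if (isTRUE(est$undefined))
    return(list(r_hat = NA_real_, lod = NA_real_, cM = NA_real_,
                unlinked = TRUE))
  unlinked <- est$lod < lod_min
  cM <- if (unlinked || est$r_hat >= 0.5) NA_real_ else kosambi_cM(est$r_hat)
  list(r_hat = est$r_hat, lod = est$lod, cM = cM, unlinked = unlinked)
}

#' Cosegregation test of a codominant marker with the sterility trait
#'
#' Expected mapping (phase known): the sterile-parent homozygote class (AA)
#' is sterile; heterozygotes and the other homozygote class are fertile.
#' Counts the individuals violating that mapping; the marker cosegregates
#' iff there are none.
#'
#' @param mat a \code{gms_geno}.
#' @param marker marker id.
#' @param sterile_class the marker class expected in sterile plants, i.e.
#'   the phase map ("AA" unless allele codes were relabelled).
#' @return Object of class \code{cosegregation_result}: list(n_individuals,
#'   n_discordant, verdict in {"cosegregating", "discordant"}).
#' @export
cosegregation_test <- function(mat, marker, sterile_class = "AA") {
  g <- mat$calls[, marker]
  keep <- !is.na(g)
  if (!any(keep)) stop("all calls missing for marker ", marker)
  g <- g[keep]; phen <- mat$phenotype[keep]
  discord <- (phen == "sterile" & g != sterile_class) |
    (phen == "fertile" & g == sterile_class)
  res <- list(n_individuals = length(g), n_discordant = sum(discord),
              verdict = if (sum(discord) == 0) "cosegregating" else "discordant")
  class(res) <- "cosegregation_result"
  res
}

#' @export
print.cosegregation_result <- function(x, ...) {
  cat("Cosegregation:", x$verdict, "(", x$n_discordant, "discordant of",
      x$n_individuals, ")\n")
  invisible(x)
}

#' Fine-mapping interval summary
#'
#' Marker-trait distances on each side of the locus, their sum (the mapped
#' interval, distances taken additive), and the physical span between the
#' flanking markers when positions are available.
#'
#' @param mat a \code{gms_geno}.
#' @param left,right flanking marker ids.
#' @return list: left_cM, right_cM, total_cM, left_marker, right_marker,
#'   bp_span (NA without positions), plus the underlying r/LOD estimates.
#' @export
interval_report <- function(mat, left, right) {
  dl <- marker_trait_distance(mat, left)
  dr <- marker_trait_distance(mat, right)
  meta <- mat$markers
  bpl <- meta$bp[match(left, meta$marker)]
  bpr <- meta$bp[match(right, meta$marker)]
  list(left_marker = left, right_marker = right,
       left_cM = dl$cM, right_cM = dr$cM,
       total_cM = dl$cM + dr$cM,
       bp_span = if (length(bpl) && length(bpr) && !is.na(bpl) && !is.na(bpr))
         abs(bpr - bpl) else NA_real_,
       left = dl, right = dr)
}
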