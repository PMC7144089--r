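# File formats: tab-separated genotype / map / observation tables, a YAML
# run configuration and a JSON run manifest. No binary formats.

#' Write a genotype matrix to TSV
#'
#' One row per individual: an \code{individual} id column, one column per
#' marker (codes AA/AB/BB, empty for missing) and a final \code{phenotype}
#' column (sterile/fertile).
#'
#' @param mat a \code{gms_geno}.
#' @param path output file.
#' @param map_path optional path for a companion marker-map TSV (marker,
#'   chrom, bp, true_cM).
#' @return \code{path}, invisibly.
#' @export
write_genotype_tsv <- function(mat, path, map_path = NULL) {
  df <- data.frame(individual = rownames(mat$calls), mat$calls,
                   phenotype = mat$phenotype,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  if (!is.null(map_path)) {
    mp <- mat$markers
    names(mp)[names(mp) == "cM"] <- "true_cM"
    utils::write.table(mp, map_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a genotype matrix from TSV
#'
#' Inverse of \code{\link{write_genotype_tsv}}; validates genotype codes and
#' reports the offending row and column on a parse error.
#'
#' @param path genotype TSV.
#' @param cross_type "F2" or "BC1".
#' @param map_path optional marker-map TSV giving chrom/bp/true_cM metadata.
#' @return a \code{gms_geno} (without simulation truth).
#' @export
read_genotype_tsv <- function(path, cross_type = c("F2", "BC1"),
                              map_path = NULL) {
  cross_type <- match.arg(cross_type)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  if (nrow(df) == 0 || ncol(df) < 3)
    stop("empty or malformed genotype file: ", path)
  if (!"individual" %in% names(df) || !"phenotype" %in% names(df))
    stop("genotype TSV needs 'individual' and 'phenotype' columns")
  marker_cols <- names(df)[!names(df) %in% c("individual", "phenotype")]
  if (anyDuplicated(marker_cols)) stop("duplicate marker id in header")
  calls <- as.matrix(df[, marker_cols, drop = FALSE])
  calls[calls == "NA" | calls == ""] <- NA_character_
  bad <- which(matrix(!(calls %in% c("AA", "AB", "BB", NA)), nrow(calls)),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("unknown genotype code '%s' at row %d, marker '%s'",
                 calls[bad[1, 1], bad[1, 2]], bad[1, 1],
                 marker_cols[bad[1, 2]]))
  phen <- df$phenotype
  if (!all(phen %in% c("sterile", "fertile", NA)))
    stop("phenotype column must be sterile/fertile/NA")
  rownames(calls) <- df$individual
  markers <- data.frame(marker = marker_cols, chrom = NA_character_,
                        bp = NA_real_, cM = NA_real_,
                        stringsAsFactors = FALSE)
  if (!is.null(map_path)) {
    mp <- utils::read.delim(map_path, stringsAsFactors = FALSE)
    i <- match(marker_cols, mp$marker)
    markers$chrom <- mp$chrom[i]
    markers$bp <- mp$bp[i]
    if ("true_cM" %in% names(mp)) markers$cM <- mp$true_cM[i]
  }
  structure(list(calls = calls, markers = markers, phenotype = phen,
                 cross_type = cross_type, trait = NULL, design = NULL,
                 truth = NULL),
            class = "gms_geno")
}

#' Read progeny-test observations from TSV
#'
#' Columns: family_id, test_id, n, n_sterile. Family outcomes are derived
#' (all sterile / all fertile / segregating).
#'
#' @param path observations TSV.
#' @return named list of \code{progeny_test_observation} by test id, each
#'   with attribute \code{"n_per_family"}.
#' @export
read_observations_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("family_id", "test_id", "n", "n_sterile")
  if (!all(need %in% names(df)))
    stop("observations TSV needs columns: ", paste(need, collapse = ", "))
  if (any(df$n_sterile > df$n) || any(df$n < 1))
    stop("invalid family counts")
  out <- list()
  for (tid in unique(df$test_id)) {
    sub <- df[df$test_id == tid, ]
    outc <- ifelse(sub$n_sterile == 0, "all_fertile",
                   ifelse(sub$n_sterile == sub$n, "all_sterile",
                          "segregating"))
    ob <- progeny_test_observation(tid, outc)
    attr(ob, "n_per_family") <- sub$n
    out[[tid]] <- ob
  }
  out
}

#' Read a pipeline run configuration (YAML)
#'
#' Fields: seed (required); model (multi_allelic/two_gene, inter_locus_rf);
#' population (cross_type, n_individuals, recurrent_parent); trait (chrom, bp,
#' founder alleles); noise (mean_depth, depth_min, missing_max); thresholds
#' (rf_max, lod_min, bin_merge_cM); markers_per_chrom; out_dir.
#'
#' @param path YAML file.
#' @return validated config list of class \code{gms_config}.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must set a seed")
  defaults <- list(
    model = list(model_id = "multi_allelic"),
    population = list(cross_type = "F2", n_individuals = 88, recurrent_parent = "P2"),
    trait = list(chrom = "A07", bp = 6.8e6,
                 founder_alleles = list(P1 = "b", P2 = "a")),
    noise = list(mean_depth = 10, depth_min = 5, missing_max = 0.20),
    thresholds = list(rf_max = 0.3, lod_min = 7, bin_merge_cM = 0.5),
    markers_per_chrom = 40,
    out_dir = "."
  )
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
    else if (is.list(defaults[[nm]]))
      for (k in names(defaults[[nm]]))
        if (is.null(cfg[[nm]][[k]])) cfg[[nm]][[k]] <- defaults[[nm]][[k]]
  }
  th <- cfg$thresholds
  if (any(unlist(th) <= 0)) stop("thresholds must be positive")
  class(cfg) <- "gms_config"
  cfg
}

#' Run the pipeline stages and write artifacts with a manifest
#'
#' Stages: \code{"simulate"} (population + genotype/map TSVs),
#' \code{"models"} (progeny-test model discrimination report),
#' \code{"map"} (grouping, bp ordering, trait placement),
#' \code{"bins"} (recombination bins), \code{"finemap"} (recombinant screen
#' between the markers flanking the trait), or \code{"all"}. Every run
#' writes a JSON manifest (seed, config, package version, per-stage counts)
#' so outputs are regenerable from the manifest alone. Identical config and
#' seed give byte-identical outputs.
#'
#' @param config a \code{gms_config} (see \code{\link{read_run_config}}) or
#'   path to a YAML config.
#' @param stage one of simulate, models, map, bins, finemap, all.
#' @param out_dir output directory (default from config).
#' @return named list of written file paths, invisibly.
#' @export
gms_run <- function(config, stage = c("all", "simulate", "models", "map",
                                      "bins", "finemap"),
                    out_dir = NULL) {
  stage <- match.arg(stage)
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(out_dir)) out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  log <- list(seed = config$seed, stage = stage,
              package = as.character(utils::packageVersion("gmsmap")),
              thresholds = config$thresholds)

  model <- gms_model(config$model$model_id,
                     inter_locus_rf = config$model$inter_locus_rf %||% 0.5)
  genome <- genome_model(markers_per_chrom = config$markers_per_chrom)
  trait <- trait_locus_spec(config$trait$chrom, config$trait$bp, model,
                            config$trait$founder_alleles, genome)
  noise <- noise_model(mean_depth = config$noise$mean_depth,
                       depth_min = config$noise$depth_min,
                       marker_missing_max = config$noise$missing_max)
  design <- population_design(config$population$cross_type,
                              config$population$n_individuals,
                              config$population$recurrent_parent,
                              seed = config$seed)

  run_sim <- stage %in% c("simulate", "all")
  need_mat <- stage %in% c("map", "bins", "finemap", "all", "simulate")
  mat <- NULL
  if (need_mat) {
    mat <- simulate_population(design, genome, trait, noise)
    filt <- apply_marker_filters(mat, noise)
    log$simulate <- list(n = design$n, markers_simulated = ncol(mat$calls),
                         markers_kept = filt$n_kept,
                         markers_dropped = filt$n_dropped)
    mat <- filt$matrix
    if (run_sim) {
      paths$genotypes <- file.path(out_dir, "genotypes.tsv")
      paths$marker_map <- file.path(out_dir, "marker_map.tsv")
      write_genotype_tsv(mat, paths$genotypes, paths$marker_map)
    }
  }

  if (stage %in% c("models", "all")) {
    fit <- gms_fit()
    paths$models <- file.path(out_dir, "model_ranking.tsv")
    utils::write.table(fit$ranking, paths$models, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    log$models <- list(n_hypotheses = nrow(fit$ranking),
                       best = fit$ranking$hypothesis[1])
  }

  if (stage %in% c("map", "bins", "finemap", "all")) {
    pw <- pairwise_rf(mat)
    groups <- form_groups(mat, config$thresholds$rf_max,
                          config$thresholds$lod_min, pw = pw)
    ordered <- lapply(groups, order_markers, mat = mat, by = "bp")
    map_df <- do.call(rbind, lapply(names(ordered), function(g) {
      mk <- ordered[[g]]
      cM <- 0
      if (length(mk) > 1) for (k in 2:length(mk)) {
        est <- estimate_rf(mat$calls[, mk[k - 1]], mat$calls[, mk[k]],
                           mat$cross_type)
        r <- if (isTRUE(est$undefined)) 0.5 - 1e-9 else min(est$r_hat, 0.5 - 1e-9)
        cM[k] <- cM[k - 1] + kosambi_cM(r)
      }
      data.frame(group = g, marker = mk, cM = round(cM, 2),
                 bp = mat$markers$bp[match(mk, mat$markers$marker)],
                 stringsAsFactors = FALSE)
    }))
    log$map <- list(n_groups = length(groups),
                    group_sizes = unname(lengths(groups)))
    if (stage %in% c("map", "all")) {
      paths$map <- file.path(out_dir, "map.tsv")
      utils::write.table(map_df, paths$map, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    if (stage %in% c("bins", "finemap", "all")) {
      binned <- lapply(names(ordered), function(g)
        make_bins(ordered[[g]], mat, config$thresholds$bin_merge_cM,
                  rep_seed = config$seed))
      names(binned) <- names(ordered)
      bins_df <- do.call(rbind, lapply(names(binned), function(g) {
        b <- binned[[g]]
        data.frame(group = g,
                   bin = seq_along(b$bins),
                   representative = vapply(b$bins, `[[`, "", "representative"),
                   members = vapply(b$bins, function(x)
                     paste(x$members, collapse = ","), ""),
                   cM = round(b$map$cM, 2), stringsAsFactors = FALSE)
      }))
      log$bins <- list(n_bins = nrow(bins_df))
      if (stage %in% c("bins", "all")) {
        paths$bins <- file.path(out_dir, "bins.tsv")
        utils::write.table(bins_df, paths$bins, sep = "\t", quote = FALSE,
                           row.names = FALSE)
      }
    }
    if (stage %in% c("finemap", "all")) {
      # screen against the markers flanking the trait's true position
      chr <- config$trait$chrom
      mk <- mat$markers[mat$markers$chrom == chr, ]
      left <- mk$marker[max(which(mk$bp <= config$trait$bp[1]))]
      right <- mk$marker[min(which(mk$bp > config$trait$bp[1]))]
      rec <- find_recombinants(mat, left, right)
      iv <- interval_report(mat, left, right)
      paths$recombinants <- file.path(out_dir, "recombinants.tsv")
      utils::write.table(as.data.frame(rec), paths$recombinants, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      paths$interval <- file.path(out_dir, "interval.json")
      jsonlite::write_json(iv[c("left_marker", "right_marker", "left_cM",
                                "right_cM", "total_cM", "bp_span")],
                           paths$interval, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      log$finemap <- list(n_recombinants = nrow(rec),
                          pct = recombinant_percentage(rec,
                                                       attr(rec, "n_screened")))
    }
  }

  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(c(log, list(config = unclass(config),
                                   files = lapply(paths[names(paths) != "manifest"],
                                                  basename))),
                       paths$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
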