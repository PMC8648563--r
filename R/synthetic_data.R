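# Seeded synthetic clustered count data: negative-binomial counts with
# log-normal per-cell library sizes and per-cluster depth multipliers,
# planted cluster markers, planted ligand-receptor pairs (optionally with
# multi-subunit complexes), and a matching interaction database with decoys.
# This is the test bed for every downstream stage: the generator emits the
# same formats the readers consume plus ground-truth tables.

#' Simulation configuration
#'
#' Counts for gene g in cell c are drawn from a negative binomial with mean
#' `s_c * mu_g * fold(cluster(c), g)` and dispersion `phi`
#' (variance `m + phi m^2`), where `s_c` is a log-normal library-size factor
#' times the cell's cluster depth multiplier. Planted markers multiply the
#' mean of one gene in one cluster; planted interactions multiply the ligand
#' members in the source cluster and the receptor members in the target
#' cluster. Gene names are `g0001, g0002, ...`; clusters `C1, C2, ...`.
#'
#' @param n_clusters number of clusters.
#' @param cells_per_cluster cells per cluster (scalar or per-cluster vector).
#' @param n_genes number of genes.
#' @param baseline_mean per-gene negative-binomial mean before library-size
#'   scaling (scalar or length-`n_genes` vector).
#' @param dispersion negative-binomial dispersion `phi > 0`
#'   (`size = 1/phi`).
#' @param libsize_sigma sdlog of the log-normal per-cell library factor.
#' @param depth_multipliers per-cluster multiplicative depth factors.
#' @param markers data frame `gene, cluster, fold` of planted markers.
#' @param interactions data frame `ligand, receptor, source, target, fold`
#'   of planted ligand-receptor pairs; `ligand`/`receptor` are gene names,
#'   or several joined by `+` to plant a heteromeric complex.
#' @param decoys_per_planted decoy interactions (random non-planted gene
#'   pairs at baseline) per planted one.
#' @param n_decoys explicit decoy count, overriding `decoys_per_planted`.
#' @param n_donors donors assigned round-robin (no donor effect simulated).
#' @param seed integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_clusters = 3L, cells_per_cluster = 100L,
                       n_genes = 500L, baseline_mean = 1,
                       dispersion = 0.5, libsize_sigma = 0.35,
                       depth_multipliers = rep(1, n_clusters),
                       markers = NULL, interactions = NULL,
                       decoys_per_planted = 5L, n_decoys = NULL,
                       n_donors = 2L, seed = 1L) {
  cfg <- list(n_clusters = as.integer(n_clusters),
              cells_per_cluster = rep_len(as.integer(cells_per_cluster),
                                          n_clusters),
              n_genes = as.integer(n_genes),
              baseline_mean = rep_len(baseline_mean, n_genes),
              dispersion = dispersion,
              libsize_sigma = libsize_sigma,
              depth_multipliers = rep_len(depth_multipliers, n_clusters),
              markers = markers, interactions = interactions,
              decoys_per_planted = as.integer(decoys_per_planted),
              n_decoys = n_decoys, n_donors = as.integer(n_donors),
              seed = as.integer(seed))
  if (any(cfg$cells_per_cluster <= 0) || cfg$n_genes <= 0 ||
      cfg$n_clusters <= 0) {
    abort("all sizes must be positive", "envcci_config_error")
  }
  if (cfg$dispersion <= 0 || any(cfg$baseline_mean <= 0) ||
      any(cfg$depth_multipliers <= 0)) {
    abort("baseline means, dispersion and depth multipliers must be positive",
          "envcci_config_error")
  }
  structure(cfg, class = "sim_config")
}

split_partner_spec <- function(spec) strsplit(spec, "+", fixed = TRUE)[[1]]

#' Simulate a clustered dataset with planted signal
#'
#' @param cfg a [sim_config()].
#' @return List of class `ccc_sim` with elements `counts` (cells x genes),
#'   `annot` (cell, cluster, donor, total_counts), `truth` (marker and
#'   interaction ground-truth tables), and `db` (an `lr_database` holding
#'   the planted interactions plus baseline decoys).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  clusters <- paste0("C", seq_len(cfg$n_clusters))
  cl <- rep(clusters, cfg$cells_per_cluster)
  n_cells <- length(cl)
  cells <- sprintf("cell%05d", seq_len(n_cells))

  check_genes <- function(g, what) {
    bad <- setdiff(g, genes)
    if (length(bad)) {
      abort(sprintf("%s references unknown gene(s): %s", what,
                    paste(bad, collapse = ", ")),
            "envcci_config_error")
    }
  }
  check_clusters <- function(x, what) {
    bad <- setdiff(x, clusters)
    if (length(bad)) {
      abort(sprintf("%s references unknown cluster(s): %s", what,
                    paste(bad, collapse = ", ")),
            "envcci_config_error")
    }
  }

  fold <- matrix(1, nrow = cfg$n_clusters, ncol = cfg$n_genes,
                 dimnames = list(clusters, genes))
  mk <- cfg$markers
  if (!is.null(mk) && nrow(mk)) {
    require_columns(mk, c("gene", "cluster", "fold"), "marker spec")
    check_genes(mk$gene, "marker spec")
    check_clusters(mk$cluster, "marker spec")
    if (any(mk$fold <= 0)) abort("marker folds must be > 0",
                                 "envcci_config_error")
    for (i in seq_len(nrow(mk))) {
      fold[mk$cluster[i], mk$gene[i]] <- fold[mk$cluster[i], mk$gene[i]] * mk$fold[i]
    }
  }

  planted_genes <- character()
  complexes <- list()
  ia_rows <- list()
  it <- cfg$interactions
  if (!is.null(it) && nrow(it)) {
    require_columns(it, c("ligand", "receptor", "source", "target", "fold"),
                    "interaction spec")
    check_clusters(c(it$source, it$target), "interaction spec")
    if (any(it$fold <= 0)) abort("interaction folds must be > 0",
                                 "envcci_config_error")
    for (i in seq_len(nrow(it))) {
      lg <- split_partner_spec(it$ligand[i])
      rg <- split_partner_spec(it$receptor[i])
      check_genes(c(lg, rg), "interaction spec")
      for (g in lg) fold[it$source[i], g] <- fold[it$source[i], g] * it$fold[i]
      for (g in rg) fold[it$target[i], g] <- fold[it$target[i], g] * it$fold[i]
      pa <- if (length(lg) > 1L) {
        id <- sprintf("CPX_L%02d", i); complexes[[id]] <- lg; id
      } else lg
      pb <- if (length(rg) > 1L) {
        id <- sprintf("CPX_R%02d", i); complexes[[id]] <- rg; id
      } else rg
      ia_rows[[i]] <- data.frame(interaction_id = sprintf("planted_%02d", i),
                                 partner_a = pa, partner_b = pb,
                                 annotation = "planted",
                                 stringsAsFactors = FALSE)
      planted_genes <- c(planted_genes, lg, rg)
    }
  }
  planted_genes <- unique(c(planted_genes,
                            if (!is.null(mk) && nrow(mk)) mk$gene))

  # decoys: simple-simple interactions among untouched baseline genes
  n_planted <- length(ia_rows)
  n_decoys <- cfg$n_decoys %||% (cfg$decoys_per_planted * n_planted)
  decoy_rows <- list()
  if (n_decoys > 0L) {
    pool <- setdiff(genes, planted_genes)
    if (length(pool) < 2L * n_decoys) {
      abort("not enough non-planted genes to draw decoy interactions",
            "envcci_config_error")
    }
    picked <- matrix(sample(pool, 2L * n_decoys), ncol = 2L)
    decoy_rows <- list(data.frame(interaction_id = sprintf("decoy_%03d",
                                                           seq_len(n_decoys)),
                                  partner_a = picked[, 1],
                                  partner_b = picked[, 2],
                                  annotation = "decoy",
                                  stringsAsFactors = FALSE))
  }
  interactions <- do.call(rbind, c(ia_rows, decoy_rows))
  if (is.null(interactions)) {
    interactions <- data.frame(interaction_id = character(),
                               partner_a = character(),
                               partner_b = character(),
                               annotation = character(),
                               stringsAsFactors = FALSE)
  }
  db <- lr_database(genes, complexes, interactions,
                    version = sprintf("sim-seed%d", cfg$seed))

  s <- stats::rlnorm(n_cells, meanlog = 0, sdlog = cfg$libsize_sigma) *
    cfg$depth_multipliers[match(cl, clusters)]
  mu <- s %o% cfg$baseline_mean * fold[cl, , drop = FALSE]
  counts <- matrix(stats::rnbinom(n_cells * cfg$n_genes,
                                  mu = as.vector(mu),
                                  size = 1 / cfg$dispersion),
                   nrow = n_cells, dimnames = list(cells, genes))
  storage.mode(counts) <- "double"

  annot <- data.frame(cell = cells, cluster = cl,
                      donor = paste0("donor",
                                     rep_len(seq_len(cfg$n_donors), n_cells)),
                      total_counts = unname(rowSums(counts)),
                      stringsAsFactors = FALSE)
  truth <- list(
    markers = if (!is.null(mk) && nrow(mk)) mk else
      data.frame(gene = character(), cluster = character(), fold = numeric()),
    interactions = data.frame(
      interaction_id = interactions$interaction_id,
      source = c(if (n_planted) it$source, rep(NA_character_,
                                               nrow(interactions) - n_planted)),
      target = c(if (n_planted) it$target, rep(NA_character_,
                                               nrow(interactions) - n_planted)),
      planted = interactions$annotation == "planted",
      stringsAsFactors = FALSE)
  )
  structure(list(counts = counts, annot = annot, truth = truth, db = db,
                 config = cfg),
            class = "ccc_sim")
}

#' @method print ccc_sim
#' @export
print.ccc_sim <- function(x, ...) {
  cat(sprintf("ccc_sim: %d cells x %d genes, %d clusters, %d planted / %d decoy interactions\n",
              nrow(x$counts), ncol(x$counts), x$config$n_clusters,
              sum(x$truth$interactions$planted),
              sum(!x$truth$interactions$planted)))
  invisible(x)
}

#' Depth-confounded null dataset
#'
#' Two clusters drawn from one and the same expression model but with
#' different sequencing-depth multipliers: the failure mode that inflates
#' false positives in a naive rank test and that depth stratification is
#' designed to absorb. No markers or interactions are planted, so every
#' positive DE call is a false positive.
#'
#' @param n_genes number of genes.
#' @param cells_per_cluster cells in each of the two clusters.
#' @param depth_ratio library-size multiplier of cluster C2 relative to C1.
#' @param baseline_mean,dispersion,libsize_sigma,seed,... passed to
#'   [sim_config()].
#' @return A `ccc_sim` (see [simulate_dataset()]).
#' @export
depth_confounded_null <- function(n_genes = 2000L, cells_per_cluster = 300L,
                                  depth_ratio = 2, baseline_mean = 1,
                                  dispersion = 0.5, libsize_sigma = 0.35,
                                  seed = 1L, ...) {
  cfg <- sim_config(n_clusters = 2L, cells_per_cluster = cells_per_cluster,
                    n_genes = n_genes, baseline_mean = baseline_mean,
                    dispersion = dispersion, libsize_sigma = libsize_sigma,
                    depth_multipliers = c(1, depth_ratio),
                    n_decoys = 0L, seed = seed, ...)
  simulate_dataset(cfg)
}

#' Write a simulated dataset in the pipeline's input formats
#'
#' MTX + name files for the counts, TSV annotation, CSV database tables and
#' TSV ground truth — everything the readers consume.
#'
#' @param sim a `ccc_sim`.
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts_mtx(sim$counts, dir)
  write_ccc_tsv(sim$annot, file.path(dir, "annotation.tsv"))
  write_lr_database(sim$db, dir)
  write_ccc_tsv(sim$truth$markers, file.path(dir, "truth_markers.tsv"))
  write_ccc_tsv(sim$truth$interactions, file.path(dir, "truth_interactions.tsv"))
  invisible(dir)
}
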