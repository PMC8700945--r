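#' Simulation configuration
#'
#' Describes a synthetic log2 expression study with the structure the
#' pipeline assumes: DS and euploid control groups sampled across brain
#' regions and developmental ages, Gaussian gene baselines and residual
#' noise on the log2 scale, and planted trisomy-like fold changes that
#' can be restricted to particular strata (a region, an age rank, or the
#' whole brain). The defaults emulate the design of a two-group postmortem
#' brain study: all 11 regions with 5 samples per group per region (55 per
#' karyotype group), gene baselines Normal(8, 1.5) log2 units and residual
#' noise sd 0.2 log2 units.
#'
#' @param n_genes number of genes.
#' @param n_per_group samples per karyotype group within each region.
#' @param regions region codes to simulate (subset of [region_codes()]).
#' @param age_ranks age-rank bin definitions ([default_age_ranks()]).
#' @param age_rank_props sampling proportions over `age_ranks` rows
#'   (uniform by default); each sample draws its rank, then a uniform age
#'   inside the bin.
#' @param baseline_mean,gene_sd per-gene baseline log2 mean drawn once per
#'   gene from Normal(`baseline_mean`, `gene_sd`).
#' @param noise_sd residual log2 noise sd per measurement.
#' @param planted `NULL` or a data frame with columns `gene_id`,
#'   `fold_change` (> 0, linear scale) and `stratum` (`"whole_brain"`, a
#'   region code, or an age-rank label): DS samples belonging to the
#'   stratum get `log2(fold_change)` added for that gene.
#' @param seed integer seed governing the entire output stream.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 500, n_per_group = 5, regions = region_codes(),
                       age_ranks = default_age_ranks(), age_rank_props = NULL,
                       baseline_mean = 8, gene_sd = 1.5, noise_sd = 0.2,
                       planted = NULL, seed = 1L) {
  if (gene_sd < 0 || noise_sd < 0) stop("standard deviations must be >= 0", call. = FALSE)
  if (!all(regions %in% region_codes())) {
    stop("regions must be a subset of region_codes()", call. = FALSE)
  }
  if (is.null(age_rank_props)) {
    age_rank_props <- rep(1 / nrow(age_ranks), nrow(age_ranks))
  }
  if (length(age_rank_props) != nrow(age_ranks)) {
    stop("age_rank_props must have one entry per age rank", call. = FALSE)
  }
  if (!is.null(planted)) {
    stopifnot(all(c("gene_id", "fold_change", "stratum") %in% names(planted)))
    if (any(planted$fold_change <= 0)) {
      stop("planted fold_change must be > 0", call. = FALSE)
    }
  }
  structure(list(
    n_genes = n_genes, n_per_group = n_per_group, regions = regions,
    age_ranks = age_ranks, age_rank_props = age_rank_props / sum(age_rank_props),
    baseline_mean = baseline_mean, gene_sd = gene_sd, noise_sd = noise_sd,
    planted = planted, seed = as.integer(seed)
  ), class = "sim_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a stratified two-group expression dataset
#'
#' Generates log2 intensities `x_gs = mu_g + delta_gs + e_gs` with
#' `mu_g ~ Normal(baseline_mean, gene_sd)` drawn once per gene,
#' `delta_gs = log2(fold_change)` when sample s is DS and gene g is
#' planted in a stratum containing s (0 otherwise), and
#' `e_gs ~ Normal(0, noise_sd)`. The same seed reproduces the output
#' bitwise.
#'
#' @param cfg a [sim_config()].
#' @return List with `matrix` (log2 [expr_matrix()], genes named
#'   `G0001...`), `metadata` (sample metadata data frame with an
#'   `age_rank` column), and `truth` (the planted-effect table, zero rows
#'   when nothing was planted).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  if (!is.null(cfg$planted)) {
    missing <- setdiff(cfg$planted$gene_id, gene_ids)
    if (length(missing)) {
      stop("planted gene(s) not in simulated gene set: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  grid <- expand.grid(idx = seq_len(cfg$n_per_group), group = c("DS", "control"),
                      region = cfg$regions, stringsAsFactors = FALSE)
  n_samples <- nrow(grid)
  with_seed(cfg$seed, {
    rank_idx <- sample.int(nrow(cfg$age_ranks), n_samples, replace = TRUE,
                           prob = cfg$age_rank_props)
    rk <- cfg$age_ranks[rank_idx, , drop = FALSE]
    age_value <- round(stats::runif(n_samples, rk$low, rk$high), 1)
    age_value <- pmax(age_value, 0.1)  # age must be positive even in a 0-low bin
    sex <- sample(c("F", "M"), n_samples, replace = TRUE)
    metadata <- data.frame(
      sample_id = sprintf("S_%s_%s_%02d", grid$region, grid$group, grid$idx),
      group = grid$group, region = grid$region,
      age_value = age_value, age_unit = rk$unit, sex = sex,
      stringsAsFactors = FALSE
    )
    metadata <- suppressWarnings(assign_age_rank(metadata, cfg$age_ranks))
    mu <- stats::rnorm(cfg$n_genes, cfg$baseline_mean, cfg$gene_sd)
    values <- mu + matrix(stats::rnorm(cfg$n_genes * n_samples, 0, cfg$noise_sd),
                          cfg$n_genes, n_samples)
    dimnames(values) <- list(gene_ids, metadata$sample_id)
    if (!is.null(cfg$planted)) {
      for (k in seq_len(nrow(cfg$planted))) {
        p <- cfg$planted[k, ]
        hit <- metadata$group == "DS" & sample_in_stratum(metadata, p$stratum)
        values[p$gene_id, hit] <- values[p$gene_id, hit] + log2(p$fold_change)
      }
    }
    truth <- if (is.null(cfg$planted)) {
      data.frame(gene_id = character(), stratum = character(),
                 fold_change = numeric(), stringsAsFactors = FALSE)
    } else {
      cfg$planted[c("gene_id", "stratum", "fold_change")]
    }
    list(matrix = expr_matrix(values, scale_tag = "log2"),
         metadata = metadata, truth = truth)
  })
}

sample_in_stratum <- function(metadata, stratum_label) {
  if (stratum_label %in% c("whole_brain", "Brain", "all")) {
    rep(TRUE, nrow(metadata))
  } else if (stratum_label %in% region_codes()) {
    metadata$region == stratum_label
  } else {
    !is.na(metadata$age_rank) & metadata$age_rank == stratum_label
  }
}

#' Write the small fixed-seed fixture files used in examples and tests
#'
#' Produces, under `outdir`: a 6-probe x 4-sample series-matrix file
#' (`series_matrix.txt`) whose probes map onto the five HMGN genes (two
#' probes for HMGN1, exercising probe collapse), the matching sample
#' metadata (`sample_metadata.tsv`), the probe annotation
#' (`probe_annotation.tsv`), the five-gene HMGN annotation
#' (`hmgn_annotation.tsv`), and the planted-effect truth table
#' (`truth.tsv`; HMGN1 carries a 1.5-fold trisomic dose in all samples).
#' Regeneration with the same seed is byte-identical.
#'
#' @param outdir writable output directory (created if absent).
#' @param seed integer seed.
#' @return Named character vector of the file paths, invisibly.
#' @export
make_fixture_files <- function(outdir, seed = 20211L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ann <- hmgn_annotation()
  probe_ann <- data.frame(
    probe_id = sprintf("P%06d", 1:6),
    gene_symbol = c("HMGN1", "HMGN1", "HMGN2", "HMGN3", "HMGN4", "HMGN5"),
    stringsAsFactors = FALSE
  )
  probe_ann <- merge(probe_ann, ann, by = "gene_symbol", sort = FALSE)
  probe_ann <- probe_ann[order(probe_ann$probe_id),
                         c("probe_id", "gene_symbol", "entrez_id", "locus")]
  cfg <- sim_config(n_genes = 6, n_per_group = 2, regions = "HIP",
                    planted = data.frame(gene_id = "G0001", fold_change = 1.5,
                                         stratum = "whole_brain",
                                         stringsAsFactors = FALSE),
                    seed = seed)
  sim <- simulate_dataset(cfg)
  mat <- sim$matrix
  # probes in order map to HMGN1, HMGN1, HMGN2..HMGN5; the planted gene
  # G0001 becomes the first HMGN1 probe
  rownames(mat) <- probe_ann$probe_id
  paths <- c(
    series_matrix = file.path(outdir, "series_matrix.txt"),
    metadata = file.path(outdir, "sample_metadata.tsv"),
    probe_annotation = file.path(outdir, "probe_annotation.tsv"),
    hmgn_annotation = file.path(outdir, "hmgn_annotation.tsv"),
    truth = file.path(outdir, "truth.tsv")
  )
  write_series_matrix(mat, sim$metadata, paths["series_matrix"])
  write_sample_metadata(sim$metadata[c("sample_id", "group", "region",
                                       "age_value", "age_unit", "sex")],
                        paths["metadata"])
  utils::write.table(probe_ann, paths["probe_annotation"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ann, paths["hmgn_annotation"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$gene_id <- "HMGN1"
  utils::write.table(truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
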