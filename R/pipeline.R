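#' Pipeline configuration
#'
#' Bundles every tunable threshold of the analysis with its default: depth
#' floor 1000 reads, rarefaction depth 1000, prevalence 10%, CLR pseudocount
#' 1, FDR 0.05, network edge thresholds |r| >= 0.1 and p < 0.05, rewiring
#' flag 0.12, 999 PERMANOVA permutations, 5 CV folds, 500 trees. A global
#' seed is expanded into per-stage seeds by a fixed counter scheme
#' (`stage_seed = seed * 131 + stage_index`) so any stage can be re-run in
#' isolation reproducibly.
#'
#' @param sim a [paired_sim_config()] for the intervention cohorts (or NULL
#'   when supplying data directly to [run_pipeline()]).
#' @param ibd_sim optional [cross_sectional_sim_config()] for the
#'   cross-sectional validation stage.
#' @param stages character vector of stages to run, a subset of
#'   `c("diversity", "permanova", "diffab", "network", "ml", "ibd")`.
#' @param min_depth,rarefaction_depth,prevalence,pseudocount,fdr_alpha
#'   core thresholds (see above).
#' @param edge_min_r,edge_max_p,rewiring_high,sparcc_resamples,network_perm
#'   network thresholds.
#' @param n_perm,cv_k,n_trees PERMANOVA permutations, CV folds, forest size.
#' @param seed global integer seed.
#' @param out_dir output directory for stage artifacts and the manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = NULL, ibd_sim = NULL,
                            stages = c("diversity", "permanova", "diffab",
                                       "network", "ml", "ibd"),
                            min_depth = 1000, rarefaction_depth = 1000,
                            prevalence = 0.10, pseudocount = 1,
                            fdr_alpha = 0.05, edge_min_r = 0.1,
                            edge_max_p = 0.05, rewiring_high = 0.12,
                            sparcc_resamples = 20, network_perm = 100,
                            n_perm = 999, cv_k = 5, n_trees = 500,
                            seed = 1, out_dir = tempfile("rsmeta_run_")) {
  stopifnot(min_depth >= 0, rarefaction_depth >= 1,
            prevalence >= 0, prevalence <= 1, pseudocount > 0,
            fdr_alpha >= 0, fdr_alpha <= 1, edge_min_r >= 0,
            edge_max_p > 0, edge_max_p <= 1, n_perm >= 1, cv_k >= 2,
            n_trees >= 1)
  bad <- setdiff(stages, c("diversity", "permanova", "diffab", "network",
                           "ml", "ibd"))
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(as.list(environment()), class = "pipeline_config")
}

.stage_seed <- function(cfg, i) (cfg$seed * 131 + i) %% 2147483647L

# pooled prevalence filter: features detected in >= fraction of all samples
.pooled_prevalence_filter <- function(c, min_fraction) {
  shared <- Reduce(intersect, lapply(c$tables, colnames))
  pooled <- do.call(rbind, lapply(c$tables, function(t)
    unclass(t)[, shared, drop = FALSE]))
  keep <- colMeans(pooled > 0) >= min_fraction
  keep_feats <- shared[keep]
  tabs <- lapply(c$tables, function(t)
    feature_table(unclass(t)[, keep_feats, drop = FALSE]))
  cohort_set(tabs, c$metadata, c$tree)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on simulated or supplied
#' cohorts, writes each stage's tabular outputs under `cfg$out_dir`, and
#' returns (and writes) a JSON manifest with the configuration, per-stage
#' seeds and per-file MD5 checksums.
#'
#' @param cfg a [pipeline_config()].
#' @param cohorts optional paired [cohort_set()] (otherwise simulated from
#'   `cfg$sim`).
#' @param ibd_cohorts optional cross-sectional [cohort_set()] for the `ibd`
#'   stage (otherwise simulated from `cfg$ibd_sim` when present).
#' @param module feature ids for the `ibd` module score; defaults to the
#'   significant set of the `diffab` stage (or the simulation's planted
#'   module if `diffab` is disabled).
#' @return The manifest, invisibly a list with per-stage results under
#'   `$results`.
#' @export
run_pipeline <- function(cfg, cohorts = NULL, ibd_cohorts = NULL,
                         module = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list(); truth <- NULL
  if (is.null(cohorts)) {
    if (is.null(cfg$sim) && length(cfg$stages) > 0)
      stop("no cohorts supplied and no simulation config in cfg$sim")
    if (!is.null(cfg$sim)) {
      sim <- simulate_paired_cohorts(cfg$sim)
      cohorts <- sim$cohorts; truth <- sim$truth
    }
  }
  emit <- function(df, name) {
    f <- file.path(cfg$out_dir, name)
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  }
  files <- character(0)
  if (!is.null(cohorts)) {
    cohorts <- cohort_set(lapply(cohorts$tables, filter_min_depth,
                                 min_total = cfg$min_depth),
                          cohorts$metadata, cohorts$tree)
  }
  tree <- if (!is.null(cohorts)) cohorts$tree else NULL
  if (is.null(tree) && !is.null(cfg$sim))
    tree <- simulate_tree(cfg$sim$n_features, .stage_seed(cfg, 0))

  rarefied <- NULL
  if (any(c("diversity", "permanova") %in% cfg$stages)) {
    rarefied <- lapply(cohorts$tables, function(t)
      rarefy(filter_min_depth(t, cfg$rarefaction_depth),
             cfg$rarefaction_depth, .stage_seed(cfg, 1)))
  }
  if ("diversity" %in% cfg$stages) {
    rc <- cohort_set(rarefied, cohorts$metadata, tree)
    metrics <- c("shannon", "observed_features",
                 if (!is.null(tree)) "faith_pd")
    alpha <- lapply(metrics, function(mm) pool_alpha_diversity(rc, mm, tree))
    names(alpha) <- metrics
    long <- do.call(rbind, lapply(metrics, function(mm) {
      ps <- alpha[[mm]]$per_study
      po <- alpha[[mm]]$pooled
      rbind(ps, data.frame(study_id = "Combined", metric = mm, g = po$mu,
                           var_g = po$se_mu^2, n = sum(ps$n), t = po$z,
                           p = po$p))
    }))
    # pooled p-values are reported unadjusted; q adjusts them across the
    # alpha metrics for readers who want that multiplicity handled
    long$q <- NA_real_
    comb <- long$study_id == "Combined"
    long$q[comb] <- bh_fdr(long$p[comb])
    files <- c(files, emit(long, "alpha_meta.tsv"))
    results$diversity <- alpha
  }
  if ("permanova" %in% cfg$stages) {
    rows <- list()
    for (sid in study_ids(cohorts)) {
      m <- cohorts$metadata[[sid]]
      pr <- suppressMessages(pair_samples(m))
      samp <- c(pr$baseline, pr$endpoint)
      D <- beta_distance(feature_table(unclass(rarefied[[sid]])[samp, ,
                                                                drop = FALSE]),
                         "bray_curtis")
      grp <- rep(c("baseline", "endpoint"), each = nrow(pr))
      subj <- rep(pr$subject_id, 2)
      pm <- rm_permanova(D, grp, subj, cfg$n_perm, .stage_seed(cfg, 2))
      rows[[sid]] <- data.frame(study_id = sid, R2 = pm$R2, p = pm$p,
                                pseudo_F = pm$pseudo_F)
    }
    # study-level clustering of baseline samples, pooled over cohorts
    shared <- Reduce(intersect, lapply(rarefied, colnames))
    base_list <- lapply(study_ids(cohorts), function(sid) {
      pr <- suppressMessages(pair_samples(cohorts$metadata[[sid]]))
      unclass(rarefied[[sid]])[pr$baseline, shared, drop = FALSE]
    })
    pooled <- do.call(rbind, base_list)
    labs <- rep(study_ids(cohorts), vapply(base_list, nrow, 0L))
    sv <- study_variance(beta_distance(feature_table(pooled), "bray_curtis"),
                         labs, cfg$n_perm, .stage_seed(cfg, 3))
    per <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    files <- c(files, emit(per, "rm_permanova.tsv"))
    results$permanova <- list(per_study = per, study_variance = sv)
  }
  dres <- NULL
  if ("diffab" %in% cfg$stages) {
    filt <- .pooled_prevalence_filter(cohorts, cfg$prevalence)
    dt <- delta_clr(filt, cfg$pseudocount)
    dres <- run_differential_abundance(dt, cfg$fdr_alpha)
    files <- c(files, emit(dres$results, "diffab.tsv"),
               emit(consistency_table(dres, dt), "diffab_consistency.tsv"))
    results$diffab <- dres
  }
  if ("network" %in% cfg$stages) {
    filt <- .pooled_prevalence_filter(cohorts, cfg$prevalence)
    scores <- list(); sizes <- numeric(0)
    for (sid in study_ids(filt)) {
      pr <- suppressMessages(pair_samples(filt$metadata[[sid]]))
      nets <- lapply(c(baseline = "baseline", endpoint = "endpoint"),
                     function(tp) {
        samp <- if (tp == "baseline") pr$baseline else pr$endpoint
        tt <- feature_table(unclass(filt$tables[[sid]])[samp, , drop = FALSE])
        net <- sparcc(tt, cfg$sparcc_resamples, seed = .stage_seed(cfg, 4))
        net <- permutation_pvalues(tt, net, cfg$network_perm,
                                   .stage_seed(cfg, 5))
        filter_edges(net, cfg$edge_min_r, cfg$edge_max_p)
      })
      union_edges <- unique(rbind(nets$baseline, nets$endpoint))
      feats <- Reduce(intersect, lapply(filt$tables, colnames))
      part <- detect_modules(union_edges, feats)
      scores[[sid]] <- rewiring_score(nets$baseline, nets$endpoint, part)
      sizes[sid] <- nrow(filt$tables[[sid]])
    }
    rw <- combine_rewiring(scores, sizes, cfg$rewiring_high)
    files <- c(files, emit(rw, "rewiring.tsv"))
    results$network <- rw
  }
  if ("ml" %in% cfg$stages) {
    ml <- rbind(within_study_cv(cohorts, cfg$cv_k, .stage_seed(cfg, 6),
                                n_trees = cfg$n_trees),
                cross_study_validation(cohorts, .stage_seed(cfg, 6),
                                       n_trees = cfg$n_trees),
                loso(cohorts, .stage_seed(cfg, 6), n_trees = cfg$n_trees))
    files <- c(files, emit(ml, "ml_auc.tsv"))
    results$ml <- ml
  }
  if ("ibd" %in% cfg$stages) {
    if (is.null(ibd_cohorts)) {
      if (is.null(cfg$ibd_sim)) {
        message("ibd stage skipped: no cross-sectional cohorts or ibd_sim")
      } else {
        ibd_cohorts <- simulate_ibd_cohorts(cfg$ibd_sim)$cohorts
      }
    }
    if (!is.null(ibd_cohorts)) {
      if (is.null(module)) {
        module <- if (!is.null(dres)) dres$significant
                  else if (!is.null(truth)) truth$module_features
        if (is.null(module) || length(module) == 0)
          stop("ibd stage needs a module (none significant and no truth)")
      }
      ra <- do.call(rbind, lapply(ibd_cohorts$tables, relative_abundance))
      md <- do.call(rbind, lapply(ibd_cohorts$metadata, as.data.frame))
      sc <- module_score(ra[md$sample_id, , drop = FALSE], module)
      lmm <- fit_diagnosis_lmm(sc, md$diagnosis, md$study_id)
      files <- c(files, emit(lmm$contrasts, "ibd_contrasts.tsv"))
      results$ibd <- list(lmm = lmm, module = module)
    }
  }
  manifest <- list(
    package = "rsmeta",
    r_version = as.character(getRversion()),
    seed = cfg$seed,
    stages = cfg$stages,
    thresholds = cfg[c("min_depth", "rarefaction_depth", "prevalence",
                       "pseudocount", "fdr_alpha", "edge_min_r", "edge_max_p",
                       "rewiring_high", "n_perm", "cv_k", "n_trees")],
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest$results <- results
  invisible(manifest)
}

#' Bookkeeping fixture: the intervention cohort panel
#'
#' Expands the packaged study-level subject counts of the seven-cohort
#' intervention panel into per-sample paired metadata (two samples per
#' subject) with unit placeholder count tables, for cohort accounting.
#'
#' @return A paired-mode [cohort_set()].
#' @export
intervention_cohort_fixture <- function() {
  tab <- utils::read.table(system.file("extdata", "intervention_cohorts.tsv",
                                       package = "rsmeta"),
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  tables <- list(); metadata <- list()
  for (i in seq_len(nrow(tab))) {
    sid <- tab$study_id[i]; ns <- tab$subjects[i]
    subj <- sprintf("%s_subj%03d", sid, seq_len(ns))
    md <- data.frame(
      sample_id = c(paste0(subj, "_t0"), paste0(subj, "_t1")),
      study_id = sid, subject_id = rep(subj, 2),
      timepoint = rep(c("baseline", "endpoint"), each = ns),
      stringsAsFactors = FALSE)
    counts <- matrix(1000, nrow(md), 1,
                     dimnames = list(md$sample_id, "F001"))
    tables[[sid]] <- feature_table(counts)
    metadata[[sid]] <- sample_metadata(md, "paired")
  }
  cohort_set(tables, metadata)
}

#' Bookkeeping fixture: the IBD validation cohort panel
#'
#' Expands the packaged per-diagnosis sample counts of the eight-cohort IBD
#' panel into per-sample cross-sectional metadata with unit placeholder
#' count tables.
#'
#' @return A cross-sectional [cohort_set()].
#' @export
ibd_cohort_fixture <- function() {
  tab <- utils::read.table(system.file("extdata", "ibd_cohorts.tsv",
                                       package = "rsmeta"),
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  tables <- list(); metadata <- list()
  for (i in seq_len(nrow(tab))) {
    sid <- tab$study_id[i]
    md <- do.call(rbind, lapply(c("HC", "CD", "UC"), function(dg) {
      n <- tab[[paste0("n_", dg)]][i]
      if (n == 0) return(NULL)
      data.frame(sample_id = sprintf("%s_%s_%03d", sid, dg, seq_len(n)),
                 study_id = sid,
                 subject_id = sprintf("%s_%s_%03d", sid, dg, seq_len(n)),
                 diagnosis = dg, stringsAsFactors = FALSE)
    }))
    counts <- matrix(1000, nrow(md), 1,
                     dimnames = list(md$sample_id, "F001"))
    tables[[sid]] <- feature_table(counts)
    metadata[[sid]] <- sample_metadata(md, "cross_sectional")
  }
  cohort_set(tables, metadata)
}

#' Write the small demonstration fixture bundle
#'
#' Materializes a tiny simulated paired panel (TSV tables and metadata, a
#' newick tree, a JSON ground-truth sidecar) plus the two packaged cohort
#' bookkeeping fixtures, all readable by the package's own readers.
#'
#' @param dir output directory.
#' @param seed integer seed for the simulated part.
#' @return Character vector of written file paths, invisibly.
#' @export
make_fixtures <- function(dir = tempfile("rsmeta_fixtures_"), seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- paired_sim_config(n_studies = 2, subjects_per_study = c(4, 5),
                           n_features = 12, module_features = 1:3,
                           delta = -1, depth_range = c(2000, 4000),
                           seed = seed)
  sim <- simulate_paired_cohorts(cfg)
  files <- character(0)
  for (sid in study_ids(sim$cohorts)) {
    f1 <- file.path(dir, paste0(sid, "_counts.tsv"))
    f2 <- file.path(dir, paste0(sid, "_metadata.tsv"))
    write_feature_table(sim$cohorts$tables[[sid]], f1)
    write_metadata(sim$cohorts$metadata[[sid]], f2)
    files <- c(files, f1, f2)
  }
  ftree <- file.path(dir, "tree.nwk")
  write_tree(simulate_tree(cfg$n_features, seed), ftree)
  ftruth <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth[c("module_features", "delta")], ftruth,
                       auto_unbox = FALSE, digits = NA)
  for (nm in c("intervention_cohorts.tsv", "ibd_cohorts.tsv")) {
    f <- file.path(dir, nm)
    file.copy(system.file("extdata", nm, package = "rsmeta"), f,
              overwrite = TRUE)
    files <- c(files, f)
  }
  invisible(c(files, ftree, ftruth))
}
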