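#' Construct a feature count table
#'
#' The universal data container of the pipeline: a samples x features matrix of
#' non-negative integer counts (OTUs, KOs, CAZymes -- the pipeline is
#' feature-type agnostic). Row names are sample identifiers, column names are
#' feature identifiers; both must be unique.
#'
#' @param counts numeric matrix of non-negative integers with unique row and
#'   column names.
#' @return An object of class `feature_table` (a validated integer matrix).
#' @export
feature_table <- function(counts) {
  counts <- as.matrix(counts)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts))))
    stop("feature_table requires sample (row) and feature (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample identifier: ",
         rownames(counts)[duplicated(rownames(counts))][1])
  if (anyDuplicated(colnames(counts)))
    stop("duplicate feature identifier: ",
         colnames(counts)[duplicated(colnames(counts))][1])
  if (!is.numeric(counts)) stop("counts must be numeric")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("negative or non-integral count at sample '%s', feature '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  storage.mode(counts) <- "double"
  structure(counts, class = c("feature_table", class(unclass(counts))))
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features, total count %s\n",
              nrow(x), ncol(x), format(sum(x), big.mark = ",")))
  invisible(x)
}

#' Read a feature table from a TSV file
#'
#' Expects a header row of feature identifiers and a first column of sample
#' identifiers. Row and column order are preserved exactly.
#'
#' @param path path to a tab-separated file.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE, comment.char = "",
                          quote = "", stringsAsFactors = FALSE)
  feature_table(as.matrix(df))
}

#' Write a feature table to a TSV file
#'
#' Inverse of [read_feature_table()]; round-trips exactly.
#'
#' @param x a `feature_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), unclass(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct sample metadata
#'
#' Per-sample bookkeeping for either of the pipeline's two designs:
#' `paired` (longitudinal intervention; `timepoint` is `baseline` or
#' `endpoint`) or `cross_sectional` (disease cohorts; `diagnosis` is `HC`,
#' `CD` or `UC`). A "complete pair" is a subject with exactly one baseline and
#' one endpoint sample.
#'
#' @param df data.frame with columns `sample_id`, `study_id`, `subject_id`,
#'   and `timepoint` or `diagnosis` depending on `mode`.
#' @param mode `"paired"` or `"cross_sectional"`.
#' @return A `sample_metadata` data.frame with a `mode` attribute.
#' @export
sample_metadata <- function(df, mode = c("paired", "cross_sectional")) {
  mode <- match.arg(mode)
  cond_col <- if (mode == "paired") "timepoint" else "diagnosis"
  need <- c("sample_id", "study_id", "subject_id", cond_col)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("metadata missing column(s): ",
                             paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, need, drop = FALSE]
  for (cc in need) df[[cc]] <- as.character(df[[cc]])
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ", df$sample_id[duplicated(df$sample_id)][1])
  allowed <- if (mode == "paired") c("baseline", "endpoint") else
    c("HC", "CD", "UC")
  bad <- setdiff(unique(df[[cond_col]]), allowed)
  if (length(bad) > 0)
    stop(sprintf("unknown %s label(s): %s (allowed: %s)", cond_col,
                 paste(bad, collapse = ", "), paste(allowed, collapse = ", ")))
  if (mode == "paired") {
    key <- paste(df$study_id, df$subject_id, df$timepoint, sep = "\r")
    if (anyDuplicated(key))
      stop("duplicated (subject_id, timepoint): ",
           gsub("\r", " / ", key[duplicated(key)][1]))
  }
  structure(df, class = c("sample_metadata", "data.frame"), mode = mode)
}

#' Read sample metadata from a TSV file
#'
#' @param path path to a tab-separated file with a header.
#' @inheritParams sample_metadata
#' @return A `sample_metadata` data.frame.
#' @export
read_metadata <- function(path, mode = c("paired", "cross_sectional")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "",
                          quote = "", stringsAsFactors = FALSE)
  sample_metadata(df, mode)
}

#' Write sample metadata to a TSV file
#' @param m a `sample_metadata` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(m, path) {
  utils::write.table(as.data.frame(m), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny with branch lengths from a newick file
#'
#' The tree drives Faith's PD and the UniFrac metrics; it must be rooted
#' (bifurcating at the root) and carry a non-negative length on every branch.
#'
#' @param path newick file.
#' @return An [ape::read.tree()] `phylo` object, validated.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- ape::read.tree(path)
  validate_tree(tr)
}

validate_tree <- function(tr) {
  if (is.null(tr)) stop("could not parse newick tree")
  if (is.null(tr$edge.length))
    stop("tree has no branch lengths; a rooted tree with lengths is required")
  if (anyNA(tr$edge.length) || any(tr$edge.length < 0))
    stop("tree has missing or negative branch lengths")
  if (!ape::is.rooted(tr))
    stop("tree is unrooted (trifurcating root); root it first, e.g. with ",
         "ape::root() on an outgroup or ape::midpoint from phangorn")
  if (anyDuplicated(tr$tip.label)) stop("duplicate leaf labels in tree")
  tr
}

#' Write a phylogeny to a newick file
#' @param tr a `phylo` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tr, path) {
  ape::write.tree(tr, file = path)
  invisible(path)
}

#' Drop samples below a minimum sequencing depth
#'
#' Samples with fewer than `min_total` reads are excluded before any
#' downstream analysis (default 1,000, the pipeline-wide depth floor).
#'
#' @param t a `feature_table`.
#' @param min_total minimum row sum to retain a sample.
#' @return Filtered `feature_table`; warns if no sample survives.
#' @export
filter_min_depth <- function(t, min_total = 1000) {
  stopifnot(min_total >= 0)
  keep <- rowSums(t) >= min_total
  if (!any(keep)) warning("no sample reaches depth ", min_total)
  feature_table(unclass(t)[keep, , drop = FALSE])
}

#' Drop features below a prevalence threshold
#'
#' A feature is "detected" in a sample when its count is > 0; features
#' detected in fewer than `ceiling(min_fraction * n_samples)` samples are
#' removed (default 10% of samples).
#'
#' @param t a `feature_table`.
#' @param min_fraction fraction of samples in which a feature must be detected.
#' @return Filtered `feature_table`.
#' @export
filter_prevalence <- function(t, min_fraction = 0.10) {
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  need <- ceiling(min_fraction * nrow(t))
  keep <- colSums(unclass(t) > 0) >= need
  feature_table(unclass(t)[, keep, drop = FALSE])
}

#' Rarefy all samples to a common depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) to exactly `depth` reads, via [vegan::rrarefy()]. Used for
#' alpha and beta diversity only; differential abundance works on raw counts.
#'
#' @param t a `feature_table` in which every sample has at least `depth` reads.
#' @param depth target reads per sample.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return Rarefied `feature_table` with every row summing to `depth`.
#' @export
rarefy <- function(t, depth = 1000, seed) {
  if (missing(seed)) stop("rarefy requires an explicit seed")
  low <- rowSums(t) < depth
  if (any(low))
    stop("sample(s) below rarefaction depth ", depth, ": ",
         paste(utils::head(rownames(t)[low], 5), collapse = ", "),
         "; run filter_min_depth() first")
  counts <- unclass(t)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  # rrarefy warns when the smallest positive count exceeds 1, which is a
  # legitimate state for simulated tables; the check is not relevant here
  out <- withCallingHandlers(
    vegan::rrarefy(counts, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  dimnames(out) <- dimnames(counts)
  feature_table(out)
}

# save/restore .Random.seed so seeded helpers do not disturb the caller's RNG
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Match baseline and endpoint samples within subjects
#'
#' Retains only strictly paired subjects: exactly one baseline and one
#' endpoint sample. Pairing is within study (a subject id appearing in two
#' studies is two distinct subjects). Incomplete subjects are dropped with a
#' message.
#'
#' @param m paired-mode `sample_metadata`.
#' @return data.frame with columns `study_id`, `subject_id`, `baseline`,
#'   `endpoint` (sample ids), one row per complete pair. The number of dropped
#'   subjects is in attribute `n_dropped`.
#' @export
pair_samples <- function(m) {
  if (!identical(attr(m, "mode"), "paired"))
    stop("pair_samples requires paired-mode metadata")
  if (nrow(m) == 0)
    return(structure(data.frame(study_id = character(), subject_id = character(),
                                baseline = character(), endpoint = character(),
                                stringsAsFactors = FALSE), n_dropped = 0L))
  key <- paste(m$study_id, m$subject_id, sep = "\r")
  out <- lapply(split(seq_len(nrow(m)), key), function(idx) {
    sub <- m[idx, , drop = FALSE]
    b <- sub$sample_id[sub$timepoint == "baseline"]
    e <- sub$sample_id[sub$timepoint == "endpoint"]
    if (length(b) == 1 && length(e) == 1)
      data.frame(study_id = sub$study_id[1], subject_id = sub$subject_id[1],
                 baseline = b, endpoint = e, stringsAsFactors = FALSE)
    else NULL
  })
  dropped <- sum(vapply(out, is.null, logical(1)))
  pairs <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(pairs))
    pairs <- data.frame(study_id = character(), subject_id = character(),
                        baseline = character(), endpoint = character(),
                        stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$study_id, pairs$subject_id), , drop = FALSE]
  rownames(pairs) <- NULL
  if (dropped > 0)
    message(dropped, " subject(s) without a complete baseline/endpoint pair dropped")
  structure(pairs, n_dropped = as.integer(dropped))
}

#' Convert counts to relative abundances
#'
#' @param t a `feature_table` with strictly positive row sums.
#' @return Numeric matrix; each row sums to 1.
#' @export
relative_abundance <- function(t) {
  counts <- unclass(t)
  rs <- rowSums(counts)
  if (any(rs == 0))
    stop("zero-sum sample(s): ",
         paste(utils::head(rownames(counts)[rs == 0], 5), collapse = ", "))
  counts / rs
}

#' Centered log-ratio transform
#'
#' `clr(x)_k = ln(x_k + pseudocount) - mean_k ln(x_k + pseudocount)`, applied
#' per sample. A pseudocount of 1 (the default) handles structural zeros.
#' Every output row sums to zero.
#'
#' @param t a `feature_table` (or bare count matrix).
#' @param pseudocount positive offset added to every count.
#' @return Numeric matrix of CLR values, same dimnames as `t`.
#' @export
clr_transform <- function(t, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  lg <- log(unclass(t) + pseudocount)
  lg - rowMeans(lg)
}

#' Bundle per-study tables and metadata
#'
#' @param tables named list (by study id) of `feature_table`s.
#' @param metadata named list (by study id) of `sample_metadata`, sample ids
#'   coinciding with the corresponding table's rows.
#' @param tree optional shared `phylo` tree over the feature universe.
#' @return A `cohort_set` object.
#' @export
cohort_set <- function(tables, metadata, tree = NULL) {
  if (!identical(sort(names(tables)), sort(names(metadata))))
    stop("tables and metadata must be named by the same study ids")
  if (anyDuplicated(names(tables))) stop("duplicate study ids")
  for (sid in names(tables)) {
    if (!setequal(rownames(tables[[sid]]), metadata[[sid]]$sample_id))
      stop("study '", sid, "': table and metadata sample ids differ")
    if (!all(metadata[[sid]]$study_id == sid))
      stop("study '", sid, "': metadata study_id column disagrees with key")
  }
  if (!is.null(tree)) validate_tree(tree)
  structure(list(tables = tables[sort(names(tables))],
                 metadata = metadata[sort(names(tables))], tree = tree),
            class = "cohort_set")
}

#' @export
print.cohort_set <- function(x, ...) {
  cat(sprintf("cohort_set: %d studies (%s), %d samples%s\n",
              length(x$tables), paste(names(x$tables), collapse = ", "),
              sum(vapply(x$tables, nrow, 0L)),
              if (is.null(x$tree)) "" else ", with tree"))
  invisible(x)
}

#' Study identifiers of a cohort set
#' @param c a `cohort_set`.
#' @return Character vector of study ids.
#' @export
study_ids <- function(c) names(c$tables)

#' Per-study and total sample bookkeeping
#'
#' For paired cohorts: subjects, complete pairs and paired samples per study;
#' for cross-sectional cohorts: per-diagnosis sample counts. The final row
#' (`study_id = "Total"`) holds column totals.
#'
#' @param c a `cohort_set`.
#' @return data.frame of counts; columns depend on the metadata mode.
#' @export
cohort_summary <- function(c) {
  if (length(c$tables) == 0)
    return(data.frame(study_id = "Total", n_samples = 0L, n_subjects = 0L))
  mode <- attr(c$metadata[[1]], "mode")
  rows <- lapply(study_ids(c), function(sid) {
    m <- c$metadata[[sid]]
    if (mode == "paired") {
      pr <- suppressMessages(pair_samples(m))
      data.frame(study_id = sid, n_subjects = nrow(pr),
                 n_pairs = nrow(pr), n_paired_samples = 2L * nrow(pr),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(study_id = sid,
                 n_samples = nrow(m),
                 n_HC = sum(m$diagnosis == "HC"),
                 n_CD = sum(m$diagnosis == "CD"),
                 n_UC = sum(m$diagnosis == "UC"),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  tot <- out[1, , drop = FALSE]
  tot$study_id <- "Total"
  for (cc in names(out)[-1]) tot[[cc]] <- sum(out[[cc]])
  rbind(out, tot)
}
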