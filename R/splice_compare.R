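#' Cross-experiment splicing-profile comparison
#'
#' Loads a directory of rMATS JCEC files named
#' `"<experiment>_<TYPE>.MATS.JCEC.txt"`, intersects significant event
#' sets between every pair of experiments per splicing type and
#' inclusion-difference sign, and scores each overlap with an exact
#' upper-tail hypergeometric test, using all events detected across the
#' two experiments as the population. Raw p-value matrices, their
#' -log10 transforms and an average-linkage clustered heatmap are
#' emitted; no multiple-testing correction is applied by default so the
#' matrices remain amenable to any downstream adjustment.
#'
#' @name splice_compare
NULL

#' Load a directory of experiments
#'
#' @param dir directory containing suffix-conforming JCEC files; other
#'   files are ignored. Unparseable files are skipped with a warning and
#'   listed in the `skipped` element.
#' @param fdr_threshold significance threshold (strict `<`).
#' @param types splicing types to load.
#' @return list of class `experiment_sets`: `experiments` (named list;
#'   per experiment, per type: `all_keys`, `sig_pos`, `sig_neg`),
#'   `summary` (per experiment x type significant-event counts),
#'   `skipped` (file names that failed to parse).
#' @export
load_experiment_dir <- function(dir, fdr_threshold = 0.0005,
                                types = c("SE", "RI", "A5SS", "A3SS",
                                          "MXE")) {
  if (!dir.exists(dir)) stop_fmt("no such directory: %s", dir)
  exps <- list()
  skipped <- character(0)
  for (ty in types) {
    suffix <- sprintf("_%s.MATS.JCEC.txt", ty)
    files <- list.files(dir, pattern = paste0(gsub(".", "\\.", suffix,
                                                   fixed = TRUE), "$"),
                        full.names = TRUE)
    names_seen <- character(0)
    for (f in files) {
      name <- sub(paste0(suffix, "$"), "", basename(f))
      if (name %in% names_seen)
        stop_fmt("duplicate experiment name '%s' for type %s", name, ty)
      names_seen <- c(names_seen, name)
      ev <- tryCatch(read_rmats(f, ty), error = function(e) {
        warn_fmt("skipping %s: %s", basename(f), conditionMessage(e))
        NULL
      })
      if (is.null(ev)) {
        skipped <- c(skipped, basename(f))
        next
      }
      keys <- event_key(ev)
      sig <- ev$fdr < fdr_threshold
      if (is.null(exps[[name]])) exps[[name]] <- list()
      exps[[name]][[ty]] <- list(
        all_keys = unique(keys),
        sig_pos = unique(keys[sig & ev$inc_diff > 0]),
        sig_neg = unique(keys[sig & ev$inc_diff < 0]))
    }
  }
  if (length(exps) == 0L)
    stop_fmt("%s: no parseable experiment files found", dir)
  summary <- do.call(rbind, unlist(lapply(names(exps), function(nm)
    lapply(names(exps[[nm]]), function(ty) {
      s <- exps[[nm]][[ty]]
      data.frame(experiment = nm, as_type = ty,
                 n_tested = length(s$all_keys),
                 n_sig_positive = length(s$sig_pos),
                 n_sig_negative = length(s$sig_neg),
                 n_sig_total = length(s$sig_pos) + length(s$sig_neg))
    })), recursive = FALSE))
  out <- list(experiments = exps, summary = summary, skipped = skipped)
  class(out) <- "experiment_sets"
  out
}

#' Upper-tail hypergeometric probability
#'
#' Exact `P(X >= k)` for the overlap of a size-`K` and a size-`n` set
#' drawn from a population of `N`, evaluated in log space.
#'
#' @param k observed overlap.
#' @param K,n sizes of the two sets.
#' @param N population size.
#' @return probability in (0, 1].
#' @export
hypergeom_upper <- function(k, K, n, N) {
  if (k < 0 || K < 0 || n < 0 || N < 0 || k > min(K, n) || K > N || n > N)
    stop_fmt("invalid hypergeometric bounds: k=%d K=%d n=%d N=%d",
             k, K, n, N)
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

sig_set <- function(s, sign) {
  switch(sign, pos = s$sig_pos, neg = s$sig_neg,
         total = union(s$sig_pos, s$sig_neg))
}

#' Pairwise experiment overlap
#'
#' @param A,B per-type experiment entries (elements of an
#'   `experiment_sets` object).
#' @param sign `"pos"`, `"neg"` or `"total"` (union of both signs).
#' @return list of class `overlap_result` with `k`, `K`, `n`, `N`, `p`
#'   and `common` (the shared significant event keys).
#' @export
pairwise_compare <- function(A, B, sign = c("neg", "pos", "total")) {
  sign <- match.arg(sign)
  a <- sig_set(A, sign); b <- sig_set(B, sign)
  common <- intersect(a, b)
  N <- length(union(A$all_keys, B$all_keys))
  res <- list(k = length(common), K = length(a), n = length(b), N = N,
              p = hypergeom_upper(length(common), length(a), length(b), N),
              common = common)
  class(res) <- "overlap_result"
  res
}

#' All-pairs comparison with matrices and clustering
#'
#' @param sets an `experiment_sets` object, or a directory path to load.
#' @param types splicing types to compare (those present are used).
#' @param signs sign classes to compare.
#' @param outdir optional output directory for matrix TSVs, heatmap PNGs
#'   and the per-experiment summary.
#' @param emit_event_lists also write one TSV of common significant
#'   events per pair (file count grows quadratically; off by default).
#' @param fdr_threshold used only when `sets` is a directory path.
#' @return list of class `compare_result`; per type x sign: `p` (square
#'   matrix, diagonal = minimal attainable tail probability),
#'   `neg_log10` (p floored at 1e-300), `hclust` (average-linkage tree
#'   on Euclidean distances of the -log10 rows, diagonal masked to 0),
#'   plus the run `summary`.
#' @export
compare_all <- function(sets, types = c("SE", "RI", "A5SS", "A3SS", "MXE"),
                        signs = c("neg", "pos", "total"), outdir = NULL,
                        emit_event_lists = FALSE, fdr_threshold = 0.0005) {
  if (is.character(sets))
    sets <- load_experiment_dir(sets, fdr_threshold, types)
  exps <- sets$experiments
  if (length(exps) < 2L)
    stop_fmt("need at least 2 experiments, found %d", length(exps))
  if (!is.null(outdir))
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  nms <- names(exps)
  matrices <- list()
  for (ty in types) {
    have <- nms[vapply(exps, function(e) !is.null(e[[ty]]), logical(1))]
    if (length(have) < 2L) next
    for (sg in signs) {
      M <- matrix(NA_real_, length(have), length(have),
                  dimnames = list(have, have))
      for (i in seq_along(have)) for (j in seq_along(have)) {
        if (j < i) next
        A <- exps[[have[i]]][[ty]]; B <- exps[[have[j]]][[ty]]
        if (i == j) {
          K <- length(sig_set(A, sg))
          N <- length(A$all_keys)
          M[i, i] <- hypergeom_upper(K, K, K, N)
        } else {
          r <- pairwise_compare(A, B, sg)
          M[i, j] <- M[j, i] <- r$p
          if (emit_event_lists && !is.null(outdir)) {
            fn <- sprintf("common_%s_%s_%s_vs_%s.tsv", ty, sg, have[i],
                          have[j])
            write_tsv(data.frame(event_key = r$common),
                      file.path(outdir, fn))
          }
        }
      }
      L <- -log10(pmax(M, 1e-300))
      Lmask <- L; diag(Lmask) <- 0
      hc <- stats::hclust(stats::dist(Lmask, method = "euclidean"),
                          method = "average")
      key <- sprintf("%s_%s", ty, sg)
      matrices[[key]] <- list(p = M, neg_log10 = L, hclust = hc)
      if (!is.null(outdir)) {
        write_matrix <- function(mat, fn) {
          df <- cbind(data.frame(experiment = rownames(mat)),
                      as.data.frame(mat))
          write_tsv(df, file.path(outdir, fn))
        }
        write_matrix(M, sprintf("pvalues_%s.tsv", key))
        write_matrix(L, sprintf("neg_log10_pvalues_%s.tsv", key))
        grDevices::png(file.path(outdir, sprintf("heatmap_%s.png", key)),
                       width = 900, height = 800)
        pheatmap::pheatmap(Lmask, clustering_method = "average",
                           clustering_distance_rows = "euclidean",
                           clustering_distance_cols = "euclidean",
                           main = sprintf("-log10(p) overlap, %s %s",
                                          ty, sg))
        grDevices::dev.off()
      }
    }
  }
  if (length(matrices) == 0L)
    stop_fmt("no splicing type present in at least 2 experiments")
  if (!is.null(outdir))
    write_tsv(sets$summary, file.path(outdir, "experiment_summary.tsv"))
  out <- list(matrices = matrices, summary = sets$summary,
              clustering = "average-linkage hclust on Euclidean distance of -log10(p), diagonal masked")
  class(out) <- "compare_result"
  out
}

#' Cut a comparison clustering into groups
#'
#' @param result a `compare_result`.
#' @param key which type/sign matrix, e.g. `"SE_neg"`.
#' @param k number of groups.
#' @return named integer vector of group labels.
#' @export
compare_groups <- function(result, key, k) {
  stats::cutree(result$matrices[[key]]$hclust, k = k)
}
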