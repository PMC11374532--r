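#' Tree-ensemble regulatory edge inference
#'
#' For each target gene, a seeded random-forest regression of its
#' expression on all TFs (excluding itself); variance-reduction
#' importances are normalized to sum 1 per target, and edges are kept iff
#' their weight exceeds `weight_min` (default 0.1, the published cutoff
#' convention for this estimator family).
#'
#' @param expr gene x sample expression matrix, typically log2(TPM + 1).
#' @param tfs candidate regulator genes (rows of `expr`).
#' @param targets target genes (rows of `expr`).
#' @param n_trees trees per forest (default 1000).
#' @param seed root seed; each target gets a derived substream.
#' @param weight_min edge weight threshold (default 0.1).
#' @param mtry predictors per split; default floor(sqrt(#TFs)).
#' @return list: `edges` (data.frame tf, target, weight; weight >
#'   weight_min only), `weights` (tf x target matrix of all normalized
#'   importances).
#' @export
infer_edges <- function(expr, tfs, targets, n_trees = 1000, seed = 1,
                        weight_min = 0.1, mtry = NULL) {
  if (ncol(expr) < 8) stop("need >= 8 samples for edge inference")
  if (!all(tfs %in% rownames(expr)))
    stop("TFs missing from expression matrix")
  if (!all(targets %in% rownames(expr)))
    stop("targets missing from expression matrix")
  z <- t(scale(t(expr[unique(c(tfs, targets)), , drop = FALSE])))
  W <- matrix(0, length(tfs), length(targets),
              dimnames = list(tfs, targets))
  for (tg in targets) {
    if (is.na(stats::sd(expr[tg, ])) || stats::sd(expr[tg, ]) == 0) {
      warning("target ", tg, " has zero variance; skipped")
      next
    }
    preds <- setdiff(tfs, tg)
    X <- t(z[preds, , drop = FALSE])
    y <- z[tg, ]
    m <- if (is.null(mtry)) max(1L, floor(sqrt(length(preds)))) else mtry
    set.seed(stage_seed(seed, paste0("rf:", tg)))
    rf <- randomForest::randomForest(x = X, y = y, ntree = n_trees,
                                     mtry = m, importance = FALSE)
    imp <- pmax(rf$importance[, "IncNodePurity"], 0)
    tot <- sum(imp)
    if (tot > 0) W[preds, tg] <- imp / tot
  }
  idx <- which(W > weight_min, arr.ind = TRUE)
  edges <- data.frame(tf = rownames(W)[idx[, 1]],
                      target = colnames(W)[idx[, 2]],
                      weight = W[idx], stringsAsFactors = FALSE)
  edges <- edges[order(-edges$weight, edges$tf, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  list(edges = edges, weights = W)
}

#' Attach motif-evidence tiers to expression edges
#'
#' Tier semantics: tier 1 = expression edge only; tier 2 = edge plus a hit
#' of one of the TF's motifs in the target's promoter in exactly one
#' library; tier 3 = hits in both libraries. Edges below the weight
#' threshold never enter.
#'
#' @param edges data.frame(tf, target, weight) from [infer_edges()].
#' @param hits motif hit table from [scan_motifs()].
#' @param motif_map data.frame(id, tf, library) mapping motifs to TFs
#'   (e.g. the simulated motif library, or a curated table).
#' @return data.frame(tf, target, weight, hits_libA-style per-library hit
#'   counts, n_libs, tier), one row per edge.
#' @export
tier_edges <- function(edges, hits, motif_map) {
  libs <- sort(unique(motif_map$library))
  rows <- lapply(seq_len(nrow(edges)), function(i) {
    tf <- edges$tf[i]; tg <- edges$target[i]
    own <- motif_map$id[motif_map$tf == tf]
    h <- hits[hits$gene == tg & hits$motif %in% own, , drop = FALSE]
    per_lib <- vapply(libs, function(lb) sum(h$library == lb), integer(1))
    n_libs <- sum(per_lib > 0)
    cbind(data.frame(tf = tf, target = tg, weight = edges$weight[i],
                     stringsAsFactors = FALSE),
          stats::setNames(as.data.frame(t(per_lib)),
                          paste0("hits_", libs)),
          data.frame(n_libs = n_libs, tier = 1L + min(n_libs, 2L)))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(tf = character(0), target = character(0),
                      weight = numeric(0), n_libs = integer(0),
                      tier = integer(0))
  rownames(out) <- NULL
  out
}

#' Rank candidate targets by treatment fold change
#'
#' The rank score of a gene is the mean of its per-day log2 fold changes
#' across the same-day treatment (TC) and treatment-course (TS) contrasts
#' (eight values for a four-day course); candidates are ordered by
#' descending score, ties broken by the maximum single-day log2FC. Genes
#' missing from any table are flagged and ranked last.
#'
#' @param targets character vector of candidate genes.
#' @param tc_tables,ts_tables named lists (by day) of `deg_table`s.
#' @return data.frame(gene, rank_score, max_lfc, missing, rank) in rank
#'   order.
#' @export
rank_candidates <- function(targets, tc_tables, ts_tables) {
  tabs <- c(tc_tables, ts_tables)
  rows <- lapply(targets, function(g) {
    lfc <- vapply(tabs, function(tb) {
      i <- match(g, tb$gene)
      if (is.na(i)) NA_real_ else tb$log2FC[i]
    }, numeric(1))
    missing <- anyNA(lfc)
    data.frame(gene = g,
               rank_score = if (missing) NA_real_ else mean(lfc),
               max_lfc = if (missing) NA_real_ else max(lfc),
               missing = missing, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(out$missing, -out$rank_score, -out$max_lfc, out$gene,
               na.last = TRUE)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
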