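#' Hypergeometric over-representation test
#'
#' For each term with K annotated genes in a population of size M, the
#' enrichment p of a study set of size n with k annotated members is the
#' upper tail `P(X >= k)` of Hypergeometric(M, K, n). Adjustment is BH
#' across terms (within namespace by default, mirroring grouped GO
#' reporting) or none (raw-p convention used for BIN categories).
#'
#' @param study character vector, a subset of `population`.
#' @param population character vector, the background gene set
#'   (typically the globally expressed genes).
#' @param annotation data.frame(gene, term) with optional `namespace`.
#' @param adjust `"BH"` or `"none"`.
#' @param by_namespace adjust within namespace (default TRUE).
#' @return data.frame(term, namespace, k, n, K, M, pvalue, padj) sorted by
#'   padj then pvalue.
#' @export
hypergeom_enrich <- function(study, population, annotation, adjust = "BH",
                             by_namespace = TRUE) {
  study <- unique(study); population <- unique(population)
  bad <- setdiff(study, population)
  if (length(bad))
    stop("study genes outside population: ", paste(bad, collapse = ", "))
  if (!"namespace" %in% names(annotation)) annotation$namespace <- "default"
  annotation <- annotation[annotation$gene %in% population, , drop = FALSE]
  M <- length(population); n <- length(study)
  terms <- unique(annotation[, c("term", "namespace")])
  res <- lapply(seq_len(nrow(terms)), function(i) {
    memb <- unique(annotation$gene[annotation$term == terms$term[i]])
    K <- length(memb)
    k <- length(intersect(memb, study))
    p <- stats::phyper(k - 1, K, M - K, n, lower.tail = FALSE)
    data.frame(term = terms$term[i], namespace = terms$namespace[i],
               k = k, n = n, K = K, M = M, pvalue = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(term = character(0), namespace = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      M = integer(0), pvalue = numeric(0), padj = numeric(0)))
  out$padj <- if (identical(adjust, "BH")) {
    if (by_namespace) {
      stats::ave(out$pvalue, out$namespace,
                 FUN = function(p) adjust_bh(p))
    } else adjust_bh(out$pvalue)
  } else out$pvalue
  out[order(out$padj, out$pvalue), , drop = FALSE]
}

#' TF-family enrichment per expression profile
#'
#' The same hypergeometric machinery with families as pseudo-terms and the
#' TF universe as population, applied to each profile's member set.
#'
#' @param profile_members named list: profile id -> character vector of TF
#'   genes assigned to it.
#' @param tf_families data.frame(gene, family) covering the TF universe.
#' @param p_max raw-p reporting threshold for the `enriched` flag
#'   (default 0.05).
#' @return data.frame(profile, term = family, k, n, K, M, pvalue,
#'   enriched).
#' @export
tf_family_enrich <- function(profile_members, tf_families, p_max = 0.05) {
  universe <- unique(tf_families$gene)
  anno <- data.frame(gene = tf_families$gene, term = tf_families$family,
                     stringsAsFactors = FALSE)
  res <- lapply(names(profile_members), function(pid) {
    memb <- intersect(profile_members[[pid]], universe)
    if (!length(memb)) return(NULL)
    r <- hypergeom_enrich(memb, universe, anno, adjust = "none")
    r$profile <- pid
    r
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(profile = character(0), term = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      M = integer(0), pvalue = numeric(0),
                      enriched = logical(0)))
  out$enriched <- out$pvalue < p_max
  out$padj <- NULL
  out[, c("profile", "term", "k", "n", "K", "M", "pvalue", "enriched")]
}
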