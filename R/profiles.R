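#' Build log2FC trajectories for one contrast strategy
#'
#' A gene's trajectory is `(0, log2FC_d1, ..., log2FC_d4)` in day order,
#' taken from the strategy's per-day DEG tables whether or not the gene is
#' significant there. Genes absent from any table are excluded with a
#' warning.
#'
#' @param tables named list (by day) of `deg_table`s for one strategy.
#' @param genes gene subset (e.g. the DETFs of the strategy).
#' @return gene x (1 + n_days) numeric matrix, first column 0.
#' @export
build_trajectories <- function(tables, genes) {
  days <- names(tables)
  keep <- genes
  for (d in days) keep <- keep[keep %in% tables[[d]]$gene]
  dropped <- setdiff(genes, keep)
  if (length(dropped))
    warning("excluded ", length(dropped),
            " gene(s) absent from some contrast table")
  traj <- vapply(days, function(d) {
    tab <- tables[[d]]
    tab$log2FC[match(keep, tab$gene)]
  }, numeric(length(keep)))
  if (length(keep) == 1) traj <- matrix(traj, nrow = 1)
  out <- cbind(0, traj)
  dimnames(out) <- list(keep, c("0", days))
  out
}

#' Enumerate and select STEM-style model profiles
#'
#' Candidate templates start at 0 and move by an integer in `-c..c` at
#' each of `n_transitions` steps, giving `(2c+1)^n_transitions` candidates
#' in enumeration order. `m` profiles are selected greedily to maximize
#' the minimum pairwise distance `1 - cor` (the flat profile, whose
#' correlation is undefined, is scored 0 against everything and seeds the
#' selection). Selected profiles are renumbered `0..m-1` in enumeration
#' order.
#'
#' @param c unit change per step (default 1).
#' @param n_transitions number of post-baseline steps (default 4).
#' @param m number of profiles to select (default 26).
#' @return a `profile_models` list: `templates` (m x (n+1) matrix,
#'   rownames the profile ids), `c`, `candidates` (count).
#' @export
generate_model_profiles <- function(c = 1, n_transitions = 4, m = 26) {
  if (c < 1) stop("c >= 1 required")
  n_cand <- (2 * c + 1)^n_transitions
  if (m > n_cand) stop("m exceeds the ", n_cand, " candidates")
  steps <- expand.grid(rep(list(seq(-c, c)), n_transitions))[, n_transitions:1,
                                                             drop = FALSE]
  ## enumeration order: first transition varies slowest
  cand <- t(apply(as.matrix(steps), 1, cumsum))
  cand <- cbind(0, cand)
  flat_idx <- which(rowSums(abs(cand)) == 0)

  D <- 1 - suppressWarnings(stats::cor(t(cand)))
  zero_var <- apply(cand, 1, stats::sd) == 0
  D[zero_var, ] <- 1; D[, zero_var] <- 1
  diag(D) <- 0

  selected <- flat_idx
  while (length(selected) < m) {
    mind <- apply(D[, selected, drop = FALSE], 1, min)
    mind[selected] <- -Inf
    selected <- c(selected, which.max(mind))
  }
  selected <- sort(selected)
  templates <- cand[selected, , drop = FALSE]
  dimnames(templates) <- list(as.character(seq_len(length(selected)) - 1),
                              c("t0", paste0("t", seq_len(n_transitions))))
  structure(list(templates = templates, c = c, candidates = n_cand),
            class = "profile_models")
}

## row-wise Pearson correlation of X against templates, with the
## convention that any zero-variance row (either side) correlates 0
cor_rows <- function(X, tmpl) {
  Xc <- X - rowMeans(X)
  Tc <- tmpl - rowMeans(tmpl)
  xn <- sqrt(rowSums(Xc^2)); tn <- sqrt(rowSums(Tc^2))
  R <- tcrossprod(Xc, Tc) / outer(pmax(xn, 1e-300), pmax(tn, 1e-300))
  R[xn == 0, ] <- 0
  R[, tn == 0] <- 0
  R
}

#' Assign trajectories to model profiles
#'
#' Each gene goes to the profile with the highest Pearson correlation to
#' its trajectory; ties break toward the lowest profile id; zero-variance
#' trajectories go to the flat profile.
#'
#' @param trajectories gene x timepoint matrix from [build_trajectories()].
#' @param profiles a `profile_models`.
#' @return data.frame(gene, profile, correlation).
#' @export
assign_genes <- function(trajectories, profiles) {
  tmpl <- profiles$templates
  flat <- which(apply(tmpl, 1, stats::sd) == 0)[1]
  R <- cor_rows(trajectories, tmpl)
  best <- max.col(R, ties.method = "first")  # rows ordered by id
  zero_var <- apply(trajectories, 1, stats::sd) == 0
  if (!is.na(flat)) best[zero_var] <- flat
  out <- data.frame(gene = rownames(trajectories),
                    profile = rownames(tmpl)[best],
                    correlation = R[cbind(seq_len(nrow(R)), best)],
                    stringsAsFactors = FALSE)
  out$correlation[zero_var] <- 0
  out
}

#' Permutation significance of profile sizes
#'
#' The expected size of profile m is `N * mean_g P(gene g assigned to m)`
#' under exhaustive permutation of each gene's post-baseline values (all
#' 4! = 24 orderings for the standard five-point trajectory). The p value
#' is the binomial upper tail `P(X >= observed | N, E_m / N)`, Bonferroni
#' corrected across profiles; a profile is significant iff the adjusted p
#' is at most `alpha`.
#'
#' @param trajectories gene x timepoint matrix (first column baseline 0).
#' @param profiles a `profile_models`.
#' @param assignment output of [assign_genes()]; recomputed when NULL.
#' @param alpha significance level (default 0.05).
#' @return data.frame(profile, observed, expected, pvalue, padj,
#'   significant), with attribute `scheme = "exhaustive"`.
#' @export
profile_significance <- function(trajectories, profiles, assignment = NULL,
                                 alpha = 0.05) {
  if (is.null(assignment)) assignment <- assign_genes(trajectories, profiles)
  tmpl <- profiles$templates
  ids <- rownames(tmpl)
  m <- nrow(tmpl)
  N <- nrow(trajectories)
  nt <- ncol(trajectories) - 1
  perms <- perm_matrix(nt)

  expected <- stats::setNames(numeric(m), ids)
  flat_idx <- which(apply(tmpl, 1, stats::sd) == 0)[1]
  for (g in seq_len(N)) {
    x <- trajectories[g, ]
    if (stats::sd(x) == 0 && !is.na(flat_idx)) {
      expected[flat_idx] <- expected[flat_idx] + 1
      next
    }
    X <- cbind(x[1], matrix(x[-1][perms], nrow(perms), nt))
    best <- max.col(cor_rows(X, tmpl), ties.method = "first")
    tb <- tabulate(best, nbins = m)
    expected <- expected + tb / nrow(perms)
  }

  observed <- stats::setNames(integer(m), ids)
  tb <- table(assignment$profile)
  observed[names(tb)] <- as.integer(tb)
  pvals <- vapply(ids, function(id) {
    q <- min(max(expected[id] / N, 0), 1)
    stats::pbinom(observed[id] - 1, N, q, lower.tail = FALSE)
  }, numeric(1))
  padj <- pmin(pvals * m, 1)
  out <- data.frame(profile = ids, observed = unname(observed),
                    expected = unname(expected), pvalue = unname(pvals),
                    padj = unname(padj),
                    significant = unname(padj) <= alpha,
                    stringsAsFactors = FALSE)
  attr(out, "scheme") <- "exhaustive"
  out
}

## all permutations of 1..n, in a fixed deterministic order
perm_matrix <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- perm_matrix(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1)))
  }
  unname(out)
}
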