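#' Configuration for the synthetic two-arm time-course generator
#'
#' The generator emulates a shared-baseline fruit-set style design: one
#' control day-0 baseline (C0) and two arms (control C, treatment T) sampled
#' on the later days, three replicates per cell, negative-binomial counts.
#' Gene classes are planted to land in specific regions of the per-day
#' three-contrast Venn used by the VDEG classifier:
#'
#' * `null` — flat mean everywhere;
#' * `ns_equal` — identical time effect in both arms (Venn overlap d; must
#'   never be called a VDEG);
#' * `cppu_only` — effect only in the treatment arm vs day 0 (overlap f);
#' * `both_diff` — same-sign effects in both arms whose log2 fold changes
#'   differ by `effect_lfc` (overlap g);
#' * `ns_suppressed` — effect in the control arm only, treatment held at
#'   baseline (overlap e).
#'
#' @param n_genes number of non-regulator genes.
#' @param n_reps replicates per (condition, day) cell (>= 2).
#' @param days ordered day vector; must start at 0.
#' @param baseline_meanlog,baseline_sdlog lognormal parameters for gene base
#'   mean counts.
#' @param dispersion NB dispersion alpha (Var = mu + alpha mu^2), recycled
#'   per gene.
#' @param effect_lfc planted effect size, log2 units.
#' @param class_fractions named proportions over the five gene classes;
#'   must sum to 1.
#' @param libsize_sdlog sdlog of the lognormal per-sample library factor.
#' @param promoter_length promoter length in bp.
#' @param n_tfs number of regulator (TF) genes appended to the matrix.
#' @param n_edges number of planted TF -> target edges.
#' @param edge_coef regression coefficient of target log-mean on
#'   standardized TF log-expression.
#' @param edge_noise_sd sd of the per-cell gaussian noise on target
#'   log2-means.
#' @param tf_pattern_sd sd of each TF's per-day log2 temporal effect.
#' @param gene_length_meanlog,gene_length_sdlog lognormal parameters for
#'   gene lengths (bp).
#' @param seed root RNG seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000, n_reps = 3, days = c(0, 1, 2, 4, 8),
                       baseline_meanlog = log(100), baseline_sdlog = 1,
                       dispersion = 0.1, effect_lfc = 2.0,
                       class_fractions = c(null = 0.6, ns_equal = 0.1,
                                           cppu_only = 0.1, both_diff = 0.1,
                                           ns_suppressed = 0.1),
                       libsize_sdlog = 0.15, promoter_length = 2000,
                       n_tfs = 20, n_edges = 10, edge_coef = 2.0,
                       edge_noise_sd = 0.25, tf_pattern_sd = 1.5,
                       gene_length_meanlog = log(1500),
                       gene_length_sdlog = 0.4, seed = 1) {
  cfg <- list(n_genes = n_genes, n_reps = n_reps, days = days,
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog, dispersion = dispersion,
              effect_lfc = effect_lfc, class_fractions = class_fractions,
              libsize_sdlog = libsize_sdlog,
              promoter_length = promoter_length, n_tfs = n_tfs,
              n_edges = n_edges, edge_coef = edge_coef,
              edge_noise_sd = edge_noise_sd, tf_pattern_sd = tf_pattern_sd,
              gene_length_meanlog = gene_length_meanlog,
              gene_length_sdlog = gene_length_sdlog, seed = seed)
  validate_sim_config(cfg)
}

GENE_CLASSES <- c("null", "ns_equal", "cppu_only", "both_diff", "ns_suppressed")

validate_sim_config <- function(cfg) {
  if (cfg$n_genes <= 0 || cfg$n_reps <= 0)
    stop("config error: n_genes and n_reps must be positive")
  if (cfg$n_reps < 2) stop("config error: n_reps >= 2 required")
  if (cfg$days[1] != 0 || any(diff(cfg$days) <= 0))
    stop("config error: days must be strictly increasing and start at 0")
  fr <- cfg$class_fractions
  if (!setequal(names(fr), GENE_CLASSES))
    stop("config error: class_fractions must name exactly: ",
         paste(GENE_CLASSES, collapse = ", "))
  if (abs(sum(fr) - 1) > 1e-9) stop("config error: class_fractions must sum to 1")
  if (any(fr < 0)) stop("config error: negative class fraction")
  if (cfg$dispersion < 0) stop("config error: dispersion must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

#' Build the sample design for a configuration
#'
#' Day 0 is a single shared baseline under condition C; every later day has
#' both a C and a T cell.
#' @param config a `sim_config`.
#' @return a `sample_design` data.frame.
#' @export
make_design <- function(config) {
  later <- config$days[-1]
  rows <- list(data.frame(condition = "C", day = 0,
                          replicate = seq_len(config$n_reps)))
  for (d in later) for (cond in c("C", "T"))
    rows[[length(rows) + 1L]] <- data.frame(condition = cond, day = d,
                                            replicate = seq_len(config$n_reps))
  df <- do.call(rbind, rows)
  df$sample <- sprintf("%s%d_%d", df$condition, df$day, df$replicate)
  validate_design(df[, c("sample", "condition", "day", "replicate")])
}

## Per-(condition, day) generative log2 effect for a gene class.
## L is the planted effect size in log2 units; s is the gene's sign.
class_effects <- function(class, s, L, days) {
  later <- days[-1]
  eff <- function(cval, tval) {
    cells <- c("C0", paste0("C", later), paste0("T", later))
    v <- c(0, rep(cval, length(later)), rep(tval, length(later)))
    names(v) <- cells
    v
  }
  switch(class,
    null          = eff(0, 0),
    ns_equal      = eff(s * L, s * L),
    cppu_only     = eff(0, s * L),
    both_diff     = eff(s * L, s * 2 * L),
    ns_suppressed = eff(s * L, 0),
    stop("unknown gene class: ", class))
}

#' Overlay planted TF -> target dependencies onto generative means
#'
#' For each edge, the target's per-sample log2 mean becomes
#' `intercept + coefficient * z_s + noise_s`, where `z_s` is the TF's
#' realized log2 expression standardized across all samples and the
#' intercept is the target's baseline log2 mean. Working at sample level
#' (the TF's realized expression, replicate noise included) is what makes
#' the dependency recoverable by expression-based network inference.
#'
#' @param tf_expr TF x sample matrix of realized log2 expression.
#' @param intercepts named vector of target baseline log2 means.
#' @param edges data.frame(tf, target, coefficient).
#' @param noise_sd sd of the per-sample gaussian noise term.
#' @return target x sample matrix of log2 means.
#' @export
simulate_tf_targets <- function(tf_expr, intercepts, edges,
                                noise_sd = 0.25) {
  out <- matrix(NA_real_, nrow(edges), ncol(tf_expr),
                dimnames = list(edges$target, colnames(tf_expr)))
  for (i in seq_len(nrow(edges))) {
    x <- tf_expr[edges$tf[i], ]
    z <- if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
    out[i, ] <- intercepts[edges$target[i]] + edges$coefficient[i] * z +
      stats::rnorm(length(z), 0, noise_sd)
  }
  out
}

#' Simulate a two-arm time-course count matrix with truth labels
#'
#' Draws gene classes, generative per-cell log2 means, TF regulators with
#' day-driven temporal patterns, planted TF -> target dependencies, library
#' size factors and negative-binomial counts. Deterministic given the
#' config seed.
#'
#' @param config a `sim_config`.
#' @return a `vdeg_sim` list: `counts` (integer gene x sample matrix),
#'   `design`, `gene_lengths`, and `truth` (classes, signs, generative
#'   `cell_log2` means, library factors, TF ids, planted edges).
#' @export
simulate_counts <- function(config) {
  config <- validate_sim_config(unclass(config))
  design <- make_design(config)
  cells <- unique(paste0(design$condition, design$day))
  genes <- sprintf("G%05d", seq_len(config$n_genes))

  sim <- with_seed(stage_seed(config$seed, "counts"), {
    classes <- sample(GENE_CLASSES, config$n_genes, replace = TRUE,
                      prob = config$class_fractions[GENE_CLASSES])
    names(classes) <- genes
    signs <- sample(c(-1, 1), config$n_genes, replace = TRUE)
    names(signs) <- genes
    base <- stats::rlnorm(config$n_genes, config$baseline_meanlog,
                          config$baseline_sdlog)
    names(base) <- genes

    cell_log2 <- t(vapply(genes, function(g) {
      log2(base[g]) + class_effects(classes[g], signs[g],
                                    config$effect_lfc, config$days)[cells]
    }, stats::setNames(numeric(length(cells)), cells)))

    ## regulator genes: day-only temporal pattern shared by both arms
    tf_genes <- character(0); edges <- NULL
    if (config$n_tfs > 0) {
      tf_genes <- sprintf("TF%03d", seq_len(config$n_tfs))
      tf_base <- stats::rlnorm(config$n_tfs, config$baseline_meanlog,
                               config$baseline_sdlog)
      tf_rows <- t(vapply(seq_len(config$n_tfs), function(i) {
        day_eff <- stats::setNames(
          c(0, stats::rnorm(length(config$days) - 1, 0, config$tf_pattern_sd)),
          as.character(config$days))
        d_of_cell <- sub("^[CT]", "", cells)
        log2(tf_base[i]) + day_eff[d_of_cell]
      }, stats::setNames(numeric(length(cells)), cells)))
      rownames(tf_rows) <- tf_genes
      cell_log2 <- rbind(cell_log2, tf_rows)

      n_edges <- min(config$n_edges, config$n_tfs)
      if (n_edges > 0) {
        null_genes <- genes[classes == "null"]
        if (length(null_genes) < n_edges)
          stop("not enough null-class genes to host planted edges")
        targets <- sample(null_genes, n_edges)
        edges <- data.frame(tf = tf_genes[seq_len(n_edges)], target = targets,
                            coefficient = config$edge_coef,
                            stringsAsFactors = FALSE)
      }
    }

    all_genes <- rownames(cell_log2)
    lib <- stats::rlnorm(nrow(design), 0, config$libsize_sdlog)
    names(lib) <- design$sample
    mu <- 2^cell_log2[, paste0(design$condition, design$day), drop = FALSE]
    colnames(mu) <- design$sample
    mu <- sweep(mu, 2, lib, `*`)
    disp <- rep_len(config$dispersion, length(all_genes))
    counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                    size = 1 / pmax(disp[row(mu)], 1e-12)),
                     nrow = nrow(mu), dimnames = dimnames(mu))

    ## planted edges: target means track the TF's realized per-sample
    ## expression, so the dependency is visible at sample level
    target_log2 <- NULL
    if (!is.null(edges)) {
      tf_norm <- log2(sweep(counts[edges$tf, , drop = FALSE], 2, lib, `/`) + 1)
      intercepts <- stats::setNames(cell_log2[edges$target, "C0"],
                                    edges$target)
      target_log2 <- simulate_tf_targets(tf_norm, intercepts, edges,
                                         config$edge_noise_sd)
      mu_t <- sweep(2^target_log2, 2, lib, `*`)
      d_t <- rep_len(config$dispersion, nrow(mu_t))
      counts[edges$target, ] <-
        matrix(stats::rnbinom(length(mu_t), mu = as.vector(mu_t),
                              size = 1 / pmax(d_t[row(mu_t)], 1e-12)),
               nrow = nrow(mu_t))
    }
    storage.mode(counts) <- "integer"
    lens <- round(stats::rlnorm(length(all_genes), config$gene_length_meanlog,
                                config$gene_length_sdlog))
    lens <- pmax(lens, 200)
    names(lens) <- all_genes

    list(counts = counts, gene_lengths = lens,
         truth = list(classes = classes, signs = signs,
                      cell_log2 = cell_log2, target_log2 = target_log2,
                      lib_factors = lib, tf_genes = tf_genes,
                      edges = edges))
  })
  structure(c(sim, list(design = design, config = config)),
            class = "vdeg_sim")
}

#' @export
print.vdeg_sim <- function(x, ...) {
  cat("Synthetic two-arm time-course bundle\n")
  cat(sprintf("  %d genes x %d samples (days %s, %d reps/cell)\n",
              nrow(x$counts), ncol(x$counts),
              paste(x$config$days, collapse = ","), x$config$n_reps))
  cat("  gene classes:",
      paste(sprintf("%s=%d", names(table(x$truth$classes)),
                    table(x$truth$classes)), collapse = " "), "\n")
  if (!is.null(x$truth$edges))
    cat(sprintf("  %d planted TF->target edges, %d TF genes\n",
                nrow(x$truth$edges), length(x$truth$tf_genes)))
  invisible(x)
}

#' Generate a consensus motif library pair for the simulated TFs
#'
#' Each TF receives one motif per library (tags `libA`, `libB`), a random
#' exact consensus over ACGT. These stand in for externally curated motif
#' collections; real analyses supply their own tables.
#'
#' @param tf_genes character vector of TF ids.
#' @param width motif width in bp.
#' @param seed RNG seed.
#' @return data.frame(id, library, tf, consensus).
#' @export
simulate_motif_library <- function(tf_genes, width = 7, seed = 1) {
  with_seed(stage_seed(seed, "motifs"), {
    ## rejection-sample so no consensus equals (or reverse-complements)
    ## another: colliding motifs would make planted sites ambiguous
    seen <- character(0)
    draw <- function() {
      repeat {
        cons <- paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
                      collapse = "")
        if (!cons %in% seen && !revcomp(cons) %in% seen &&
            cons != revcomp(cons)) {
          seen <<- c(seen, cons)
          return(cons)
        }
      }
    }
    rows <- lapply(tf_genes, function(tf) {
      data.frame(id = paste0("M_", tf, "_", c("A", "B")),
                 library = c("libA", "libB"), tf = tf,
                 consensus = c(draw(), draw()), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Simulate promoter sequences with planted motif occurrences
#'
#' Backgrounds are i.i.d. uniform ACGT. Planted motifs are written at
#' recorded ATG-relative coordinates (start -L..-w so the whole motif lies
#' upstream of the ATG); minus-strand plants write the reverse complement
#' into the forward string. Any chance background occurrence of a library
#' consensus outside the recorded sites is scrubbed by locally resampling
#' the window, so planted-hit counts are exact.
#'
#' @param config a `sim_config` (promoter_length, seed).
#' @param motifs consensus motif table as from [simulate_motif_library()].
#' @param genes genes to build promoters for.
#' @param plant optional data.frame(gene, motif, start, strand) of explicit
#'   placements; when NULL a default plan derived from `edges` is used.
#' @param edges planted edge table (used for the default plan: the first
#'   half of edges get both-library support, the next quarter libA only,
#'   the rest none).
#' @return list: `promoters` (named character vector) and `motif_truth`
#'   data.frame(gene, motif, library, start, end, strand).
#' @export
simulate_promoters <- function(config, motifs, genes = NULL, plant = NULL,
                               edges = NULL) {
  L <- config$promoter_length
  if (any(nchar(motifs$consensus) > L))
    stop("config error: motif longer than promoter")
  if (is.null(genes)) {
    if (is.null(edges)) stop("supply `genes` or `edges`")
    genes <- unique(edges$target)
  }

  with_seed(stage_seed(config$seed, "promoters"), {
    if (is.null(plant)) plant <- default_plant_plan(motifs, edges, L)
    if (nrow(plant) > 0 && !all(plant$gene %in% genes))
      genes <- union(genes, plant$gene)

    proms <- vapply(genes, function(g)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1))

    truth_rows <- list()
    for (i in seq_len(nrow(plant))) {
      m <- motifs[motifs$id == plant$motif[i], ]
      w <- nchar(m$consensus)
      start <- plant$start[i]
      if (start < -L || start > -w)
        stop("planted motif coordinate out of range for ", plant$gene[i])
      pos <- start + L + 1  # 1-based forward-string position
      ins <- if (plant$strand[i] == "+") m$consensus else revcomp(m$consensus)
      s <- proms[[plant$gene[i]]]
      substr(s, pos, pos + w - 1) <- ins
      proms[[plant$gene[i]]] <- s
      truth_rows[[length(truth_rows) + 1L]] <-
        data.frame(gene = plant$gene[i], motif = m$id, library = m$library,
                   start = start, end = start + w - 1,
                   strand = plant$strand[i], stringsAsFactors = FALSE)
    }
    motif_truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
      data.frame(gene = character(0), motif = character(0),
                 library = character(0), start = integer(0), end = integer(0),
                 strand = character(0))

    proms <- scrub_background(proms, motifs, motif_truth, L)
    list(promoters = proms, motif_truth = motif_truth)
  })
}

default_plant_plan <- function(motifs, edges, L) {
  if (is.null(edges) || nrow(edges) == 0)
    return(data.frame(gene = character(0), motif = character(0),
                      start = integer(0), strand = character(0)))
  n <- nrow(edges)
  n3 <- ceiling(n / 2); n2 <- ceiling(n / 4)
  rows <- list()
  for (i in seq_len(n)) {
    libs <- if (i <= n3) c("libA", "libB") else if (i <= n3 + n2) "libA"
            else character(0)
    for (lb in libs) {
      m <- motifs[motifs$tf == edges$tf[i] & motifs$library == lb, ]
      w <- nchar(m$consensus)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = edges$target[i], motif = m$id,
        start = sample(seq(-L, -w), 1),
        strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), motif = character(0),
               start = integer(0), strand = character(0))
}

## Resample background windows until no library consensus occurs outside
## its recorded planted sites. Converges quickly at uniform background.
scrub_background <- function(proms, motifs, motif_truth, L) {
  for (g in names(proms)) {
    planted <- motif_truth[motif_truth$gene == g, , drop = FALSE]
    for (iter in 1:50) {
      hits <- consensus_hits_one(proms[[g]], motifs, L)
      if (nrow(hits) > 0) {
        key_p <- paste(planted$motif, planted$start, planted$strand)
        spur <- hits[!paste(hits$motif, hits$start, hits$strand) %in% key_p, ,
                     drop = FALSE]
      } else spur <- hits
      if (nrow(spur) == 0) break
      s <- proms[[g]]
      ## never resample bases inside a planted span
      prot <- rep(FALSE, L)
      for (j in seq_len(nrow(planted))) {
        p0 <- planted$start[j] + L + 1
        prot[p0:(p0 + (planted$end[j] - planted$start[j]))] <- TRUE
      }
      for (j in seq_len(nrow(spur))) {
        p0 <- spur$start[j] + L + 1
        idx <- p0:(p0 + (spur$end[j] - spur$start[j]))
        idx <- idx[!prot[idx]]
        for (p in idx)
          substr(s, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      proms[[g]] <- s
    }
  }
  proms
}

## exact-consensus scan of a single promoter (both strands), internal to
## the generator's scrubbing loop; the user-facing scanner lives in regnet.
consensus_hits_one <- function(seq, motifs, L) {
  rows <- list()
  for (i in seq_len(nrow(motifs))) {
    cons <- motifs$consensus[i]
    for (pat in list(c(cons, "+"), c(revcomp(cons), "-"))) {
      p <- gregexpr(paste0("(?=", pat[1], ")"), seq, perl = TRUE)[[1]]
      p <- p[p > 0]
      for (pos in p)
        rows[[length(rows) + 1L]] <- data.frame(
          motif = motifs$id[i], start = pos - 1 - L,
          end = pos - 1 - L + nchar(cons) - 1, strand = pat[2],
          stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(motif = character(0), start = integer(0), end = integer(0),
               strand = character(0))
}

#' Simulate a functional annotation table
#'
#' Plants one term (`CK_PROCESS`, namespace BP) enriched among the
#' `cppu_only` gene class, plus uniform background terms across the three
#' GO-style namespaces.
#'
#' @param config a `sim_config`.
#' @param truth truth labels from [simulate_counts()].
#' @param n_background number of background terms.
#' @param planted_rate membership probability of the planted term within
#'   the cppu_only class (background rate 0.02).
#' @return data.frame(gene, term, namespace).
#' @export
simulate_annotation <- function(config, truth, n_background = 20,
                                planted_rate = 0.8) {
  genes <- names(truth$classes)
  with_seed(stage_seed(config$seed, "annotation"), {
    rows <- list()
    is_cppu <- truth$classes == "cppu_only"
    keep <- stats::runif(length(genes)) <
      ifelse(is_cppu, planted_rate, 0.02)
    if (any(keep))
      rows[[1]] <- data.frame(gene = genes[keep], term = "CK_PROCESS",
                              namespace = "BP", stringsAsFactors = FALSE)
    ns <- c("BP", "MF", "CC")
    for (i in seq_len(n_background)) {
      memb <- genes[stats::runif(length(genes)) < 0.05]
      if (length(memb))
        rows[[length(rows) + 1L]] <- data.frame(
          gene = memb, term = sprintf("TERM%02d", i),
          namespace = ns[(i - 1) %% 3 + 1], stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

#' Simulate the TF-family annotation for regulator genes
#' @param truth truth labels from [simulate_counts()].
#' @return data.frame(gene, family).
#' @export
simulate_tf_families <- function(truth) {
  fams <- c("MYB", "bZIP", "bHLH", "WRKY", "NAC", "AP2", "HB")
  tf <- truth$tf_genes
  data.frame(gene = tf, family = fams[(seq_along(tf) - 1) %% length(fams) + 1],
             stringsAsFactors = FALSE)
}

#' Write a complete synthetic input bundle to disk
#'
#' Emits counts, sample sheet, gene lengths, promoters (FASTA), consensus
#' motif table, annotation, TF families and truth labels (JSON), plus a
#' MANIFEST of the files written.
#'
#' @param config a `sim_config`.
#' @param dir output directory (created if absent).
#' @return invisibly, a list with the in-memory objects and file paths.
#' @export
simulate_inputs <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_counts(config)
  motifs <- simulate_motif_library(sim$truth$tf_genes, seed = config$seed)
  prom <- simulate_promoters(config, motifs, edges = sim$truth$edges)
  anno <- simulate_annotation(config, sim$truth)
  fams <- simulate_tf_families(sim$truth)

  paths <- list(
    counts = file.path(dir, "counts.tsv"),
    design = file.path(dir, "design.tsv"),
    lengths = file.path(dir, "gene_lengths.tsv"),
    promoters = file.path(dir, "promoters.fa"),
    motifs = file.path(dir, "motifs.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    tf_families = file.path(dir, "tf_families.tsv"),
    truth = file.path(dir, "truth.json"))
  write_matrix_tsv(sim$counts, paths$counts)
  utils::write.table(sim$design, paths$design, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(gene = names(sim$gene_lengths), length = sim$gene_lengths),
    paths$lengths, sep = "\t", quote = FALSE, row.names = FALSE)
  write_promoters(prom$promoters, paths$promoters)
  utils::write.table(motifs, paths$motifs, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(anno, paths$annotation, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(fams, paths$tf_families, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_out <- list(classes = as.list(sim$truth$classes),
                    edges = sim$truth$edges,
                    motif_truth = prom$motif_truth,
                    lib_factors = as.list(sim$truth$lib_factors))
  jsonlite::write_json(truth_out, paths$truth, auto_unbox = TRUE, digits = NA)
  manifest <- list(files = lapply(paths, basename), seed = config$seed,
                   n_genes = config$n_genes, complete = TRUE)
  jsonlite::write_json(manifest, file.path(dir, "MANIFEST.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(sim = sim, motifs = motifs, promoters = prom$promoters,
                 motif_truth = prom$motif_truth, annotation = anno,
                 tf_families = fams, paths = paths))
}
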