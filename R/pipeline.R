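#' Pipeline configuration
#'
#' Collects all stage parameters with their defaults. Inputs come either
#' from `input_dir` (a bundle as written by [simulate_inputs()], or
#' equivalently-shaped real data) or from `sim` (a [sim_config()] to
#' generate in memory). Unknown keys are rejected.
#'
#' @param input_dir directory with counts.tsv, design.tsv,
#'   gene_lengths.tsv, promoters.fa, motifs.tsv, annotation.tsv,
#'   tf_families.tsv.
#' @param sim a `sim_config` used when `input_dir` is NULL.
#' @param out_dir output directory for stage artifacts.
#' @param seed root seed for every stochastic stage.
#' @param expressed_min_tpm expressed-gene TPM threshold.
#' @param lfc_min,padj_max DEG thresholds.
#' @param prior_n dispersion-shrinkage prior sample size.
#' @param shared_k minimum periods for the shared VDEG sets.
#' @param profile_strategy contrast strategy for trajectory clustering
#'   (`"TS"`, `"NS"` or `"TC"`).
#' @param profile_c,profile_m model-profile unit change and count.
#' @param profile_alpha profile significance level.
#' @param enrich_adjust `"BH"` or `"none"` for the GO-style enrichment.
#' @param n_trees,weight_min network forest size and edge threshold.
#' @param motif_threshold PWM score-tail threshold.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir = NULL, sim = NULL, out_dir = tempfile("vdegrun"),
                            seed = 1, expressed_min_tpm = 1.0, lfc_min = 1.0,
                            padj_max = 0.05, prior_n = 5, shared_k = 3,
                            profile_strategy = "TS", profile_c = 1,
                            profile_m = 26, profile_alpha = 0.05,
                            enrich_adjust = "BH", n_trees = 1000,
                            weight_min = 0.1, motif_threshold = 1e-5) {
  cfg <- as.list(environment())
  if (is.null(cfg$input_dir) && is.null(cfg$sim))
    stop("config error: provide input_dir or sim")
  structure(cfg, class = "pipeline_config")
}

load_inputs <- function(config) {
  if (!is.null(config$input_dir)) {
    p <- function(f) {
      path <- file.path(config$input_dir, f)
      if (!file.exists(path)) stop("data error: missing input file ", path)
      path
    }
    list(counts = read_counts(p("counts.tsv")),
         design = read_design(p("design.tsv")),
         gene_lengths = read_gene_lengths(p("gene_lengths.tsv")),
         promoters = read_promoters(p("promoters.fa")),
         motifs = read_motifs(p("motifs.tsv")),
         annotation = read_annotation(p("annotation.tsv")),
         tf_families = utils::read.delim(p("tf_families.tsv"),
                                         stringsAsFactors = FALSE),
         truth = NULL)
  } else {
    sim <- simulate_counts(config$sim)
    motifs <- simulate_motif_library(sim$truth$tf_genes,
                                     seed = config$sim$seed)
    prom <- simulate_promoters(config$sim, motifs, edges = sim$truth$edges)
    list(counts = sim$counts, design = sim$design,
         gene_lengths = sim$gene_lengths, promoters = prom$promoters,
         motifs = motifs,
         annotation = simulate_annotation(config$sim, sim$truth),
         tf_families = simulate_tf_families(sim$truth),
         truth = c(sim$truth, list(motif_truth = prom$motif_truth)))
  }
}

#' Run the complete screening pipeline
#'
#' Stage order: quantification -> per-strategy differential expression ->
#' VDEG classification -> profile clustering of DETFs -> enrichment of the
#' shared VDEG sets -> regulatory-network inference with motif tiers ->
#' candidate ranking. Deterministic given the config seed; artifacts and a
#' summary JSON are written under `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_result` list (invisibly also written to disk):
#'   inputs, per-stage results and the `summary` list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name) message("[vdegscreen] stage: ", name)

  stage("load")
  inputs <- load_inputs(config)
  counts <- inputs$counts; design <- inputs$design

  stage("quantify")
  tpm <- compute_tpm(counts, inputs$gene_lengths)
  means <- period_means(tpm, design)
  expr_flags <- filter_expressed(means, config$expressed_min_tpm)
  pca <- pca_qc(tpm, design, expressed = expr_flags$expressed)

  stage("differential expression")
  factors <- size_factors(counts)
  disp <- estimate_dispersion(counts, design, factors,
                              n_prior = config$prior_n)
  strategies <- c("TC", "NS", "TS")
  tables <- list(); sets <- list()
  for (st in strategies) {
    specs <- build_contrasts(design, st)
    tables[[st]] <- lapply(specs, function(sp)
      wald_test(counts, design, sp, factors, disp$dispersion))
    sets[[st]] <- lapply(tables[[st]], call_degs,
                         lfc_min = config$lfc_min,
                         padj_max = config$padj_max)
  }

  stage("vdeg")
  vdeg <- vdeg_screen(sets$NS, sets$TS, sets$TC, tables$TC,
                      k = config$shared_k)

  stage("profiles")
  fam <- inputs$tf_families
  st <- config$profile_strategy
  detf <- fam$gene[fam$gene %in%
                     unique(unlist(lapply(sets[[st]], `[[`, "genes")))]
  prof <- NULL
  if (length(detf) >= 2) {
    traj <- build_trajectories(tables[[st]], detf)
    models <- generate_model_profiles(c = config$profile_c,
                                      m = config$profile_m)
    assign <- assign_genes(traj, models)
    signif <- profile_significance(traj, models, assign,
                                   alpha = config$profile_alpha)
    members <- split(assign$gene, assign$profile)
    fam_enrich <- tf_family_enrich(members, fam)
    prof <- list(trajectories = traj, models = models, assignment = assign,
                 significance = signif, family_enrichment = fam_enrich)
  }

  stage("enrichment")
  population <- expr_flags$expressed
  enr <- lapply(c(up = "up", down = "down"), function(dir) {
    study <- intersect(vdeg$shared[[dir]], population)
    if (!length(study)) return(NULL)
    hypergeom_enrich(study, population, inputs$annotation,
                     adjust = config$enrich_adjust)
  })

  stage("network")
  expr <- log2(tpm + 1)
  tfs <- intersect(fam$gene, rownames(expr))
  net_targets <- intersect(names(inputs$promoters), rownames(expr))
  net <- NULL; tiers <- NULL; hits <- NULL
  if (length(tfs) >= 2 && length(net_targets) >= 1) {
    net <- infer_edges(expr, tfs, net_targets, n_trees = config$n_trees,
                       seed = config$seed, weight_min = config$weight_min)
    hits <- scan_motifs(inputs$promoters, inputs$motifs,
                        threshold = config$motif_threshold)
    motif_map <- inputs$motifs[, intersect(c("id", "tf", "library"),
                                           names(inputs$motifs))]
    if ("tf" %in% names(motif_map))
      tiers <- tier_edges(net$edges, hits, motif_map)
  }

  stage("rank")
  ranked <- if (length(net_targets))
    rank_candidates(net_targets, tables$TC, tables$TS) else NULL

  summary <- list(
    n_genes = nrow(counts), n_samples = ncol(counts),
    seed = config$seed,
    deg_counts = lapply(sets, function(s)
      lapply(s, function(x) length(x$genes))),
    vdeg_counts = vdeg$counts,
    shared_up = length(vdeg$shared$up),
    shared_down = length(vdeg$shared$down),
    significant_profiles = if (!is.null(prof))
      prof$significance$profile[prof$significance$significant] else character(0),
    enriched_terms = lapply(enr, function(e)
      if (is.null(e)) character(0) else e$term[e$padj < 0.05]),
    tier_table = if (!is.null(tiers)) as.list(table(tiers$tier)) else list(),
    n_edges = if (!is.null(net)) nrow(net$edges) else 0,
    top_candidates = if (!is.null(ranked)) utils::head(ranked$gene, 5)
      else character(0))

  write_artifacts(config$out_dir, vdeg, prof, enr, net, tiers, hits,
                  ranked, pca, summary)
  invisible(structure(list(inputs = inputs, tpm = tpm, means = means,
                           expressed = expr_flags, pca = pca,
                           factors = factors, dispersion = disp,
                           tables = tables, sets = sets, vdeg = vdeg,
                           profiles = prof, enrichment = enr, network = net,
                           tiers = tiers, hits = hits, ranked = ranked,
                           summary = summary, config = config),
                      class = "pipeline_result"))
}

write_artifacts <- function(dir, vdeg, prof, enr, net, tiers, hits, ranked,
                            pca, summary) {
  wt <- function(df, f) if (!is.null(df))
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wt(vdeg$records, "vdeg_records.tsv")
  wt(vdeg$counts, "vdeg_counts.tsv")
  if (!is.null(prof)) {
    wt(prof$significance, "profiles.tsv")
    wt(prof$assignment, "profile_assignment.tsv")
    wt(prof$family_enrichment, "tf_family_enrichment.tsv")
  }
  wt(enr$up, "enrichment_up.tsv")
  wt(enr$down, "enrichment_down.tsv")
  if (!is.null(net)) wt(net$edges, "edges.tsv")
  wt(tiers, "edge_tiers.tsv")
  wt(hits, "motif_hits.tsv")
  wt(ranked, "ranked_candidates.tsv")
  co <- data.frame(sample = rownames(pca$coords), pca$coords)
  wt(co, "pca_coords.tsv")
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  jsonlite::write_json(list(complete = TRUE,
                            files = list.files(dir)),
                       file.path(dir, "MANIFEST.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("vdegscreen pipeline result\n")
  cat(sprintf("  %d genes x %d samples; seed %s\n", x$summary$n_genes,
              x$summary$n_samples, x$summary$seed))
  print(x$vdeg)
  if (!is.null(x$network))
    cat(sprintf("  network: %d edges above threshold\n",
                nrow(x$network$edges)))
  if (!is.null(x$ranked))
    cat("  top candidate:", x$ranked$gene[1], "\n")
  invisible(x)
}
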