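# Independent brute-force oracles used to check the implementation.

# BH step-up from the definition: sort p ascending, padj_(i) =
# min over j >= i of p_(j) * n / j, capped at 1, mapped back.
bh_step_up <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  run <- Inf
  for (i in n:1) {
    run <- min(run, ps[i] * n / i)
    adj[i] <- min(run, 1)
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

# exact hypergeometric upper tail from binomial coefficients
hyper_tail_exact <- function(k, M, K, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(M - K, n - kk)) / choose(M, n)
}

# per-gene membership-pattern enumeration for the VDEG classes
vdeg_brute <- function(A, B, X) {
  genes <- unique(c(A, B, X))
  cls <- character(0); who <- character(0)
  for (g in genes) {
    a <- g %in% A; b <- g %in% B; x <- g %in% X
    lab <- if (a && b && x) "g" else if (!a && b && x) "f"
      else if (a && !b && x) "e" else NA
    if (!is.na(lab)) { cls <- c(cls, lab); who <- c(who, g) }
  }
  data.frame(gene = who, class = cls, stringsAsFactors = FALSE)
}

# per-element membership tally for Venn regions
venn_brute <- function(sets) {
  universe <- unique(unlist(sets))
  pat <- vapply(universe, function(g)
    paste(as.integer(vapply(sets, function(s) g %in% s, logical(1))),
          collapse = ""), character(1))
  table(pat)
}

# tiny two-group NB count fixture; the effect is planted in the first
# `frac_de` fraction of genes so size factors stay estimable from the rest
nb_two_group <- function(G = 200, n = 3, mu = 100, disp = 0.1, lfc = 0,
                         frac_de = 0.3, seed = 1) {
  set.seed(seed)
  mu_g <- rlnorm(G, log(mu), 0.5)
  de_idx <- seq_len(round(G * frac_de))
  ## balanced signs keep the median-of-ratios reference composition-free
  de_sign <- rep_len(c(1, -1), length(de_idx))
  mu_t <- mu_g
  if (lfc != 0) mu_t[de_idx] <- mu_g[de_idx] * 2^(lfc * de_sign)
  m <- cbind(matrix(rnbinom(G * n, mu = rep(mu_g, n), size = 1 / disp), G, n),
             matrix(rnbinom(G * n, mu = rep(mu_t, n),
                            size = 1 / disp), G, n))
  dimnames(m) <- list(sprintf("g%04d", seq_len(G)),
                      c(paste0("C4_", 1:n), paste0("T4_", 1:n)))
  storage.mode(m) <- "integer"
  design <- validate_design(data.frame(
    sample = colnames(m), condition = rep(c("C", "T"), each = n),
    day = 4, replicate = rep(seq_len(n), 2)))
  has_de <- lfc != 0
  list(counts = m, design = design,
       de_genes = rownames(m)[if (has_de) de_idx else integer(0)],
       de_sign = if (has_de) setNames(de_sign, rownames(m)[de_idx])
                 else numeric(0))
}

# run the three contrast strategies end to end on a simulated bundle
run_strategies <- function(sim, lfc_min = 1.0, padj_max = 0.05) {
  f <- size_factors(sim$counts)
  disp <- estimate_dispersion(sim$counts, sim$design, f)
  tables <- list(); sets <- list()
  for (st in c("TC", "NS", "TS")) {
    specs <- build_contrasts(sim$design, st)
    tables[[st]] <- lapply(specs, function(sp)
      wald_test(sim$counts, sim$design, sp, f, disp$dispersion))
    sets[[st]] <- lapply(tables[[st]], call_degs, lfc_min = lfc_min,
                         padj_max = padj_max)
  }
  list(tables = tables, sets = sets, factors = f, dispersion = disp)
}
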