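#' Build the contrast family for a strategy
#'
#' Three contrast strategies over a shared-baseline two-arm time course:
#' * `TC` — treatment vs control at the same day: (T_d, C_d) for d > 0;
#' * `NS` — the natural course: (C_d, C_0);
#' * `TS` — the treatment course: (T_d, C_0).
#' The numerator is listed first in every pair.
#'
#' @param design sample design.
#' @param strategy one of `"TC"`, `"NS"`, `"TS"`.
#' @return named list of `contrast_spec` (one per post-baseline day).
#' @export
build_contrasts <- function(design, strategy) {
  days <- sort(unique(design$day))
  later <- days[days > 0]
  check_cell <- function(cond, d) {
    if (!any(design$condition == cond & design$day == d))
      stop("design missing cell (", cond, ", ", d, ")")
  }
  check_cell("C", 0)
  specs <- lapply(later, function(d) {
    switch(strategy,
      TC = { check_cell("T", d); check_cell("C", d)
             contrast_spec(sprintf("C%d_T%d", d, d),
                           c("T", d), c("C", d)) },
      NS = { check_cell("C", d)
             contrast_spec(sprintf("C0_C%d", d), c("C", d), c("C", 0)) },
      TS = { check_cell("T", d)
             contrast_spec(sprintf("C0_T%d", d), c("T", d), c("C", 0)) },
      stop("unknown strategy: ", strategy))
  })
  names(specs) <- as.character(later)
  specs
}

#' Classify VDEGs for one day from the three-contrast Venn
#'
#' With A = DEGs of C0-vs-Cd (natural course), B = DEGs of C0-vs-Td
#' (treatment course) and X = DEGs of Cd-vs-Td (same-day treatment
#' contrast), the value-DEG classes are the Venn regions
#'
#' * `g` = A int B int X — responds to both courses, at different levels;
#' * `f` = (B int X) minus A — treatment-only response;
#' * `e` = (A int X) minus B — natural response suppressed by treatment;
#'
#' and the VDEG set is their union. Genes in (A int B) minus X (overlap d)
#' are excluded: their levels do not differ between arms at day d.
#'
#' @param A,B,X `deg_set` objects (or character vectors) for the same day.
#' @param day the day, attached to the records.
#' @return data.frame(gene, day, class) with class in e/f/g.
#' @export
vdeg_classify <- function(A, B, X, day = NA) {
  gs <- function(s) if (inherits(s, "deg_set")) s$genes else as.character(s)
  a <- gs(A); b <- gs(B); x <- gs(X)
  g <- intersect(intersect(a, b), x)
  f <- setdiff(intersect(b, x), a)
  e <- setdiff(intersect(a, x), b)
  genes <- c(g, f, e)
  out <- data.frame(
    gene = genes, day = rep(day, length(genes)),
    class = rep(c("g", "f", "e"), c(length(g), length(f), length(e))),
    stringsAsFactors = FALSE)
  out[order(out$gene), , drop = FALSE]
}

#' Attach up/down direction to VDEG records
#'
#' Direction comes from the sign of the same-day treatment-vs-control
#' log2 fold change (numerator T): positive means the gene is higher under
#' treatment (`up`), negative means higher in the control arm (`down`).
#' Every VDEG is a member of that contrast's DEG set, so the sign is
#' always defined and its magnitude at least the DEG threshold.
#'
#' @param records data.frame from [vdeg_classify()].
#' @param tc_table the day's Cd-vs-Td `deg_table` (numerator T).
#' @return records with `direction`, `log2FC_TC` and `padj_TC` columns.
#' @export
vdeg_direction <- function(records, tc_table) {
  idx <- match(records$gene, tc_table$gene)
  if (anyNA(idx))
    stop("genes missing from the day's T-vs-C table: ",
         paste(records$gene[is.na(idx)], collapse = ", "))
  records$log2FC_TC <- tc_table$log2FC[idx]
  records$padj_TC <- tc_table$padj[idx]
  records$direction <- ifelse(records$log2FC_TC > 0, "up", "down")
  records
}

#' Genes shared across at least k periods, by direction
#'
#' Up and down memberships are tallied independently per day: a gene
#' counts toward the shared-up list if it is an up-regulated VDEG on at
#' least `k` of the days, and analogously for down. A direction-flipping
#' gene can in principle enter both lists.
#'
#' @param per_day named list (by day) of direction-annotated VDEG record
#'   data.frames.
#' @param k minimum number of periods (default 3).
#' @return list: `up` and `down` character vectors.
#' @export
shared_across_periods <- function(per_day, k = 3) {
  if (k > length(per_day))
    stop("k exceeds the number of periods (", length(per_day), ")")
  tally <- function(dir) {
    sets <- lapply(per_day, function(df) df$gene[df$direction == dir])
    tab <- table(unlist(sets))
    sort(names(tab)[tab >= k])
  }
  list(up = tally("up"), down = tally("down"))
}

#' Exact Venn region counts for 2-5 sets
#'
#' Counts every non-empty membership pattern, plus the union size and the
#' all-way intersection.
#'
#' @param sets named list of 2-5 character vectors (or `deg_set`s).
#' @param upset if TRUE, more than 5 sets are allowed and results are
#'   returned as an upset-style pattern table only.
#' @return list: `regions` (data.frame pattern/count, patterns as binary
#'   strings in set order), `union`, `all_intersection`.
#' @export
venn_summary <- function(sets, upset = FALSE) {
  sets <- lapply(sets, function(s)
    if (inherits(s, "deg_set")) s$genes else as.character(s))
  n <- length(sets)
  if (n < 2) stop("need >= 2 sets")
  if (n > 5 && !upset)
    stop("more than 5 sets: set upset = TRUE for a pattern table")
  universe <- unique(unlist(sets))
  memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) memb <- matrix(memb, nrow = 1)
  pat <- apply(memb, 1, function(b) paste(as.integer(b), collapse = ""))
  all_pats <- apply(expand.grid(rep(list(0:1), n))[-1, n:1, drop = FALSE],
                    1, paste, collapse = "")
  counts <- stats::setNames(integer(length(all_pats)), sort(all_pats))
  tb <- table(pat)
  counts[names(tb)] <- as.integer(tb)
  regions <- data.frame(pattern = names(counts), count = unname(counts),
                        stringsAsFactors = FALSE)
  list(regions = regions, union = length(universe),
       all_intersection = unname(counts[paste(rep(1, n), collapse = "")]))
}

#' Run the full VDEG screen across all days
#'
#' Convenience wrapper: classifies, directs and tallies VDEGs for every
#' post-baseline day from per-strategy DEG results.
#'
#' @param ns_sets,ts_sets,tc_sets named lists (by day) of `deg_set`s for
#'   the NS (C0 vs Cd), TS (C0 vs Td) and TC (Cd vs Td) contrasts.
#' @param tc_tables named list (by day) of the TC `deg_table`s.
#' @param k sharing threshold for [shared_across_periods()].
#' @return a `vdeg_result` list: `records` (one data.frame over all days),
#'   `per_day` (list of per-day record frames), `shared` (up/down),
#'   `counts` (per-day totals by class and direction).
#' @export
vdeg_screen <- function(ns_sets, ts_sets, tc_sets, tc_tables, k = 3) {
  days <- names(tc_sets)
  per_day <- lapply(days, function(d) {
    rec <- vdeg_classify(ns_sets[[d]], ts_sets[[d]], tc_sets[[d]],
                         day = as.numeric(d))
    vdeg_direction(rec, tc_tables[[d]])
  })
  names(per_day) <- days
  records <- do.call(rbind, per_day)
  rownames(records) <- NULL
  counts <- do.call(rbind, lapply(days, function(d) {
    df <- per_day[[d]]
    data.frame(day = as.numeric(d), total = nrow(df),
               up = sum(df$direction == "up"),
               down = sum(df$direction == "down"),
               e = sum(df$class == "e"), f = sum(df$class == "f"),
               g = sum(df$class == "g"))
  }))
  structure(list(records = records, per_day = per_day,
                 shared = shared_across_periods(per_day, k = k),
                 counts = counts),
            class = "vdeg_result")
}

#' @export
print.vdeg_result <- function(x, ...) {
  cat("VDEG screen\n")
  for (i in seq_len(nrow(x$counts)))
    cat(sprintf("  day %g: %d VDEGs (%d up, %d down; e=%d f=%d g=%d)\n",
                x$counts$day[i], x$counts$total[i], x$counts$up[i],
                x$counts$down[i], x$counts$e[i], x$counts$f[i],
                x$counts$g[i]))
  cat(sprintf("  shared (>=3 periods): %d up, %d down\n",
              length(x$shared$up), length(x$shared$down)))
  invisible(x)
}
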