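#' Scan promoters for motif occurrences
#'
#' Consensus motifs (IUPAC strings) are matched exactly on both strands;
#' `N` in a promoter never matches. Position-weight-matrix motifs are
#' scored by log-odds against a 0-order background at every offset on both
#' strands, and an offset is a hit iff the exact score-tail probability
#' (computed by dynamic programming over the PWM score distribution under
#' the background) is at most `threshold`.
#'
#' Coordinates are ATG-relative: the base immediately 5' of the ATG is -1,
#' a forward-strand match beginning at 1-based string position p of a
#' promoter of length L has `start = p - 1 - L` and
#' `end = start + width - 1` (inclusive). A minus-strand hit is reported
#' on the same forward-string span.
#'
#' @param promoters named character vector of promoter sequences (ACGTN),
#'   or a FASTA path.
#' @param motifs a consensus table (data.frame with columns id, library,
#'   consensus) and/or a list of PWM motifs as from [read_meme()].
#' @param threshold score-tail probability threshold for PWM hits
#'   (default 1e-5).
#' @return data.frame(gene, motif, library, start, end, strand, score,
#'   pvalue). Consensus hits have score = width and pvalue NA.
#' @export
scan_motifs <- function(promoters, motifs, threshold = 1e-5) {
  if (is.character(promoters) && length(promoters) == 1 &&
      file.exists(promoters))
    promoters <- read_promoters(promoters)
  promoters <- toupper(promoters)
  bad <- vapply(promoters, function(s)
    grepl("[^ACGTN]", s), logical(1))
  if (any(bad))
    stop("character outside ACGTN in record(s): ",
         paste(names(promoters)[bad], collapse = ", "))
  mlist <- normalize_motifs(motifs)
  rows <- list()
  chars <- lapply(promoters, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  for (g in names(promoters)) {
    v <- chars[[g]]; L <- length(v)
    for (m in mlist) {
      if (!is.null(m$consensus)) {
        w <- nchar(m$consensus)
        if (w > L) next
        for (pat in list(list(m$consensus, "+"),
                         list(revcomp(m$consensus), "-"))) {
          pos <- consensus_match_pos(v, pat[[1]])
          for (p in pos)
            rows[[length(rows) + 1L]] <- data.frame(
              gene = g, motif = m$id, library = m$library,
              start = p - 1L - L, end = p - 1L - L + w - 1L,
              strand = pat[[2]], score = w, pvalue = NA_real_,
              stringsAsFactors = FALSE)
        }
      } else {
        hits <- pwm_scan_one(v, m, threshold)
        if (nrow(hits)) {
          hits$gene <- g; hits$motif <- m$id; hits$library <- m$library
          hits$start <- hits$pos - 1L - L
          hits$end <- hits$start + ncol(m$pwm) - 1L
          rows[[length(rows) + 1L]] <-
            hits[, c("gene", "motif", "library", "start", "end", "strand",
                     "score", "pvalue")]
        }
      }
    }
  }
  if (length(rows)) {
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  } else
    data.frame(gene = character(0), motif = character(0),
               library = character(0), start = integer(0), end = integer(0),
               strand = character(0), score = numeric(0),
               pvalue = numeric(0))
}

## 1-based forward-string start positions of exact IUPAC matches
consensus_match_pos <- function(chars, cons) {
  w <- nchar(cons)
  L <- length(chars)
  if (w > L) return(integer(0))
  cs <- strsplit(toupper(cons), "", fixed = TRUE)[[1]]
  ok <- rep(TRUE, L - w + 1)
  for (j in seq_len(w)) {
    allowed <- IUPAC_SETS[[cs[j]]]
    if (is.null(allowed)) stop("invalid consensus code: ", cs[j])
    ok <- ok & chars[seq(j, L - w + j)] %in% allowed
  }
  which(ok)
}

normalize_motifs <- function(motifs) {
  out <- list()
  add_consensus_df <- function(df) {
    for (i in seq_len(nrow(df)))
      out[[length(out) + 1L]] <<- list(id = df$id[i], library = df$library[i],
                                       consensus = toupper(df$consensus[i]))
  }
  if (is.data.frame(motifs)) add_consensus_df(motifs)
  else if (is.list(motifs)) {
    for (m in motifs) {
      if (is.data.frame(m)) add_consensus_df(m)
      else if (!is.null(m$pwm) || !is.null(m$consensus))
        out[[length(out) + 1L]] <- m
      else stop("unrecognized motif entry")
    }
  } else stop("motifs must be a data.frame or list")
  for (m in out) {
    if (!is.null(m$consensus) && nchar(m$consensus) < 4)
      stop("consensus length >= 4 required: ", m$id)
    if (!is.null(m$pwm) && any(abs(colSums(m$pwm) - 1) > 1e-6))
      stop("PWM columns must sum to 1: ", m$id)
  }
  out
}

## Exact PWM score-tail p values via DP over the integer-discretized
## log-odds score distribution under the 0-order background.
pwm_score_dist <- function(int_scores, bg) {
  ## int_scores: 4 x w integer matrix; returns named numeric vector:
  ## names = achievable total integer scores, values = probabilities
  dist <- c(`0` = 1)
  for (j in seq_len(ncol(int_scores))) {
    nd <- new.env()
    for (k in seq_along(dist)) {
      s0 <- as.integer(names(dist)[k]); p0 <- dist[[k]]
      for (b in 1:4) {
        key <- as.character(s0 + int_scores[b, j])
        nd[[key]] <- (if (is.null(nd[[key]])) 0 else nd[[key]]) + p0 * bg[b]
      }
    }
    dist <- unlist(as.list(nd))
  }
  dist[order(as.integer(names(dist)))]
}

pwm_scan_one <- function(chars, m, threshold, eps = 1e-3) {
  bg <- m$bg
  if (is.null(bg)) bg <- rep(0.25, 4)
  pwm <- m$pwm
  w <- ncol(pwm)
  L <- length(chars)
  if (w > L)
    return(data.frame(pos = integer(0), strand = character(0),
                      score = numeric(0), pvalue = numeric(0)))
  lo <- log2(pmax(pwm, 1e-10) / bg)
  int_scores <- round(lo / eps)
  storage.mode(int_scores) <- "integer"
  dist <- pwm_score_dist(int_scores, bg)
  supp <- as.integer(names(dist))
  tail_p <- rev(cumsum(rev(dist)))  # P(S >= supp[i])
  pass <- supp[tail_p <= threshold]
  if (!length(pass))
    return(data.frame(pos = integer(0), strand = character(0),
                      score = numeric(0), pvalue = numeric(0)))
  min_int <- min(pass)  # smallest passing integer score

  base_idx <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  idx <- unname(base_idx[chars])           # NA for N
  rows <- list()
  for (strand in c("+", "-")) {
    sc_mat <- if (strand == "+") int_scores else
      int_scores[4:1, w:1, drop = FALSE]   # reverse complement PWM
    lo_mat <- if (strand == "+") lo else lo[4:1, w:1, drop = FALSE]
    total <- rep(0L, L - w + 1)
    real <- rep(0, L - w + 1)
    valid <- rep(TRUE, L - w + 1)
    for (j in seq_len(w)) {
      bj <- idx[seq(j, L - w + j)]
      valid <- valid & !is.na(bj)
      bj[is.na(bj)] <- 1L
      total <- total + sc_mat[cbind(bj, j)]
      real <- real + lo_mat[cbind(bj, j)]
    }
    hit <- valid & total >= min_int
    for (p in which(hit)) {
      pv <- sum(dist[supp >= total[p]])
      rows[[length(rows) + 1L]] <- data.frame(
        pos = p, strand = strand, score = real[p], pvalue = pv,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(pos = integer(0), strand = character(0),
               score = numeric(0), pvalue = numeric(0))
}

#' Read a consensus motif table
#' @param path TSV with columns id, library, consensus (optional tf).
#' @return data.frame usable by [scan_motifs()].
#' @export
read_motifs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "library", "consensus")
  if (!all(need %in% names(df)))
    stop("motif table needs columns: ", paste(need, collapse = ", "))
  df
}

#' Read a minimal MEME-format PWM file
#'
#' Supports the `MOTIF` / `letter-probability matrix` subset of MEME text
#' format, with an optional `Background letter frequencies` line.
#'
#' @param path MEME text file.
#' @param library library tag to attach to every motif.
#' @return list of PWM motif objects (id, library, pwm 4 x w with rows
#'   A,C,G,T, bg).
#' @export
read_meme <- function(path, library = "meme") {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bgl <- grep("^Background letter frequencies", lines)
  if (length(bgl) && bgl[1] < length(lines)) {
    toks <- strsplit(trimws(lines[bgl[1] + 1]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    nums <- vals[!is.na(vals)]
    if (length(nums) == 4) bg <- nums
  }
  starts <- grep("^MOTIF\\s", lines)
  out <- list()
  for (s in starts) {
    id <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    h <- grep("letter-probability matrix", lines[s:length(lines)])[1] + s - 1
    wm <- regmatches(lines[h], regexpr("w=\\s*\\d+", lines[h]))
    w <- as.integer(sub("w=\\s*", "", wm))
    rows <- lines[(h + 1):(h + w)]
    pwm <- vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]]), numeric(4))
    dimnames(pwm) <- list(c("A", "C", "G", "T"), NULL)  # 4 x w
    out[[length(out) + 1L]] <- list(id = id, library = library, pwm = pwm,
                                    bg = bg)
  }
  out
}
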