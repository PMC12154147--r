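#' Filter single cells on quality-control metrics
#'
#' Keeps a cell iff detected genes > 200, 1000 < total molecules < 50000,
#' and mitochondrial percentage < 20 (all inequalities strict, as the
#' thresholds are printed). Rejected cells list every violated rule.
#'
#' @param records Data frame with columns `cell_id`, `n_genes`,
#'   `n_molecules`, `percent_mito`.
#' @return List with `kept` (character ids) and `rejected` (data frame
#'   `cell_id`, `reasons`; reasons comma-separated among
#'   "genes", "molecules_low", "molecules_high", "mito").
#' @export
filter_cells_qc <- function(records) {
  need <- c("cell_id", "n_genes", "n_molecules", "percent_mito")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "), call. = FALSE)
  if (any(records$n_genes < 0) || any(records$n_molecules < 0))
    stop("counts must be >= 0", call. = FALSE)
  if (any(records$percent_mito < 0 | records$percent_mito > 100))
    stop("percent_mito must be in [0, 100]", call. = FALSE)
  viol <- cbind(
    genes = !(records$n_genes > 200),
    molecules_low = !(records$n_molecules > 1000),
    molecules_high = !(records$n_molecules < 50000),
    mito = !(records$percent_mito < 20))
  keep <- rowSums(viol) == 0
  rejected <- data.frame(
    cell_id = records$cell_id[!keep],
    reasons = apply(viol[!keep, , drop = FALSE], 1, function(v)
      paste(colnames(viol)[v], collapse = ",")),
    stringsAsFactors = FALSE)
  rownames(rejected) <- NULL
  list(kept = records$cell_id[keep], rejected = rejected)
}

#' Signed gene score from a DE result
#'
#' `score = -log10(p) * sign(log2fc)`; genes with log2fc exactly 0 score 0,
#' and high p-values give correspondingly low scores. Zero p-values are
#' clamped to `p_floor` (with a warning) so the score stays finite.
#'
#' @param p P-values in `[0, 1]`.
#' @param log2fc Signed log2 fold changes.
#' @param p_floor Clamp for p = 0 (default 1e-300).
#' @return Numeric scores.
#' @export
gene_score <- function(p, log2fc, p_floor = 1e-300) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]", call. = FALSE)
  if (any(p == 0)) {
    warning("p-value(s) of 0 clamped to ", p_floor)
    p[p == 0] <- p_floor
  }
  -log10(p) * sign(log2fc)
}

#' Rank genes by signed score into a preranked list
#'
#' Scores are sorted in descending order; ties are broken by gene symbol
#' (lexicographic), making the ranking deterministic.
#'
#' @param de Data frame with columns `gene`, `pval`, `log2fc`; gene symbols
#'   must be unique.
#' @param p_floor Passed to [gene_score()].
#' @return An object of class `ranked_gene_list`: data frame `gene`,
#'   `score`, ordered.
#' @export
rank_genes <- function(de, p_floor = 1e-300) {
  dup <- unique(de$gene[duplicated(de$gene)])
  if (length(dup))
    stop("duplicate gene symbols: ", paste(head(dup, 10), collapse = ", "), call. = FALSE)
  score <- gene_score(de$pval, de$log2fc, p_floor)
  ord <- order(-score, de$gene)
  out <- data.frame(gene = de$gene[ord], score = score[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_gene_list", "data.frame")
  out
}

#' Write a ranked list as a two-column RNK file
#'
#' @param ranked A [rank_genes()] result.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_rnk <- function(ranked, path) {
  utils::write.table(ranked[, c("gene", "score")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an RNK file into a ranked list
#'
#' @param path Two-column tab-separated file (gene, score).
#' @return A `ranked_gene_list`.
#' @export
read_rnk <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(d) <- c("gene", "score")
  d <- d[order(-d$score, d$gene), ]
  rownames(d) <- NULL
  class(d) <- c("ranked_gene_list", "data.frame")
  d
}

#' Preranked enrichment score (weighted Kolmogorov-Smirnov running sum)
#'
#' Walking down the ranked list, set members ("hits") increment the running
#' sum by `|score|^w` normalized by the total hit weight, and non-members
#' decrement it by `1/(N - N_hits)`. The enrichment score is the signed
#' extremum of the running sum. Weight exponent `w = 1` is the classic
#' weighted statistic.
#'
#' @param ranked A [rank_genes()] result.
#' @param gene_set Character vector of member genes.
#' @param w Weight exponent.
#' @param return_curve Also return the full running sum.
#' @return List with `es`, `n_hits`, `undefined` (TRUE when the set does
#'   not intersect the universe; `es` is then NA), and optionally `curve`.
#' @export
preranked_es <- function(ranked, gene_set, w = 1, return_curve = FALSE) {
  hit <- ranked$gene %in% gene_set
  n_hits <- sum(hit)
  N <- nrow(ranked)
  if (n_hits == 0)
    return(list(es = NA_real_, n_hits = 0L, undefined = TRUE))
  if (n_hits == N)
    stop("gene set covers the whole universe; no misses to walk", call. = FALSE)
  wts <- abs(ranked$score)^w
  hit_total <- sum(wts[hit])
  step <- ifelse(hit, if (hit_total > 0) wts / hit_total else 1 / n_hits,
                 -1 / (N - n_hits))
  # all-zero hit weights degenerate to equal hit increments
  if (hit_total == 0) step[hit] <- 1 / n_hits
  curve <- cumsum(step)
  es <- curve[which.max(abs(curve))]
  out <- list(es = es, n_hits = as.integer(n_hits), undefined = FALSE)
  if (return_curve) out$curve <- curve
  out
}

# ES from sorted hit positions only, O(k): running-sum value just after
# each hit and just before each hit. Used inside the permutation loop.
es_from_positions <- function(abs_scores_w, pos, N, hit_total = NULL) {
  k <- length(pos)
  pos <- sort.int(pos)
  w <- abs_scores_w[pos]
  tot <- if (is.null(hit_total)) sum(w) else hit_total
  if (tot == 0) {
    inc <- rep(1 / k, k)
  } else {
    inc <- w / tot
  }
  miss <- 1 / (N - k)
  cum_hit <- cumsum(inc)
  # extrema occur just after a hit (all hits so far minus misses passed) or
  # just before one (same, without the current hit's increment)
  after <- cum_hit - (pos - seq_len(k)) * miss
  before <- c(0, cum_hit[-k]) - (pos - seq_len(k)) * miss
  vals <- c(after, before)
  vals[which.max(abs(vals))]
}

#' Preranked GSEA with gene-label permutation FDR
#'
#' For each admissible gene set (size within `[min_size, max_size]` after
#' intersection with the universe), the observed enrichment score is
#' compared against a null built by re-drawing the set's positions
#' uniformly from the ranked list (`n_perm` gene-label permutations).
#' Nominal p is the fraction of same-sign null scores at least as extreme;
#' NES divides the ES by the mean magnitude of the same-sign null scores;
#' FDR q uses the standard NES-ratio estimator (fraction of all pooled
#' same-sign null NES at least as extreme divided by the fraction of
#' observed same-sign NES at least as extreme, clipped to [0, 1]). Sets
#' with FDR q <= `q_cutoff` are flagged significant.
#'
#' @param ranked A [rank_genes()] result.
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param n_perm Number of permutations (>= 10).
#' @param min_size,max_size Admissible set-size range (sets larger than
#'   `max_size` are excluded and reported).
#' @param w Weight exponent of the running-sum statistic.
#' @param q_cutoff Significance flag threshold on FDR q.
#' @param seed Integer seed for the permutation RNG.
#' @return Data frame: `set`, `size`, `es`, `nes`, `pval`, `fdr_q`,
#'   `significant`; excluded sets (with reasons) in `attr(, "excluded")`.
#' @export
permutation_fdr <- function(ranked, sets, n_perm = 1000, min_size = 5,
                            max_size = 1500, w = 1, q_cutoff = 0.3,
                            seed = 1L) {
  if (n_perm < 10) stop("n_perm must be >= 10", call. = FALSE)
  N <- nrow(ranked)
  wts <- abs(ranked$score)^w
  sizes <- vapply(sets, function(s) sum(ranked$gene %in% s), integer(1))
  admissible <- sizes >= min_size & sizes <= max_size
  excluded <- data.frame(set = names(sets)[!admissible], size = sizes[!admissible],
                         reason = ifelse(sizes[!admissible] > max_size,
                                         "larger than max_size", "smaller than min_size"),
                         stringsAsFactors = FALSE)
  if (!any(admissible)) stop("no admissible gene set", call. = FALSE)
  use <- which(admissible)

  set.seed(seed)
  res <- vector("list", length(use))
  null_nes_pos <- list(); null_nes_neg <- list()
  for (i in seq_along(use)) {
    s <- sets[[use[i]]]
    pos <- which(ranked$gene %in% s)
    k <- length(pos)
    es <- es_from_positions(wts, pos, N)
    null_es <- vapply(seq_len(n_perm), function(j)
      es_from_positions(wts, sample.int(N, k), N), numeric(1))
    same <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
    # fraction of same-sign null scores at least as extreme, the standard
    # preranked convention
    pval <- if (length(same)) sum(abs(same) >= abs(es)) / length(same) else 0
    mean_same <- if (length(same)) mean(abs(same)) else NA_real_
    nes <- if (is.na(mean_same) || mean_same == 0) NA_real_ else es / mean_same
    null_nes <- null_es
    pos_null <- null_es[null_es >= 0]
    neg_null <- null_es[null_es < 0]
    null_nes_pos[[i]] <- if (length(pos_null)) pos_null / mean(abs(pos_null)) else numeric(0)
    null_nes_neg[[i]] <- if (length(neg_null)) neg_null / mean(abs(neg_null)) else numeric(0)
    res[[i]] <- data.frame(set = names(sets)[use[i]], size = k, es = es,
                           nes = nes, pval = pval, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  pool_pos <- unlist(null_nes_pos); pool_neg <- unlist(null_nes_neg)
  obs_pos <- out$nes[!is.na(out$nes) & out$nes >= 0]
  obs_neg <- out$nes[!is.na(out$nes) & out$nes < 0]
  out$fdr_q <- vapply(seq_len(nrow(out)), function(i) {
    nes <- out$nes[i]
    if (is.na(nes)) return(NA_real_)
    if (nes >= 0) {
      num <- if (length(pool_pos)) mean(pool_pos >= nes) else 0
      den <- if (length(obs_pos)) mean(obs_pos >= nes) else 1
    } else {
      num <- if (length(pool_neg)) mean(pool_neg <= nes) else 0
      den <- if (length(obs_neg)) mean(obs_neg <= nes) else 1
    }
    if (den == 0) return(0)
    min(1, num / den)
  }, numeric(1))
  out$significant <- !is.na(out$fdr_q) & out$fdr_q <= q_cutoff
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
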