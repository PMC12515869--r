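#' Hypergeometric over-representation analysis
#'
#' For each gene set, computes the exact hypergeometric upper-tail
#' probability of observing at least the seen overlap between the hit list
#' and the set within the universe, with BH correction across sets. Sets are
#' intersected with the universe first.
#'
#' @param hits Character vector of significant ids; must be a subset of
#'   `universe`.
#' @param universe Character vector of all tested ids (non-empty).
#' @param sets Named list of character vectors.
#' @return data.frame `set`, `set_size` (within universe), `overlap`,
#'   `expected`, `p`, `q`, sorted by increasing `p` (ties by set name).
#' @export
ora_hypergeometric <- function(hits, universe, sets) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop_validation("'universe' is empty")
  hits <- unique(hits)
  if (!all(hits %in% universe)) {
    stop_validation("'hits' must be a subset of 'universe'")
  }
  N <- length(universe)
  n <- length(hits)
  rows <- lapply(names(sets), function(nm) {
    set <- intersect(unique(sets[[nm]]), universe)
    K <- length(set)
    k <- length(intersect(hits, set))
    data.frame(set = nm, set_size = K, overlap = k, expected = n * K / N,
               p = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(set = character(0), set_size = integer(0),
                      overlap = integer(0), expected = numeric(0),
                      p = numeric(0), q = numeric(0)))
  }
  out$q <- adjust_bh(out$p)
  out <- out[order(out$p, out$set), ]
  rownames(out) <- NULL
  out
}

## Sort a named metric vector into ranked order: decreasing metric,
## ties broken by id for determinism.
rank_metric <- function(metric) {
  if (is.null(names(metric)) || anyDuplicated(names(metric))) {
    stop_validation("'metric' must be named with unique ids")
  }
  metric[order(-metric, names(metric))]
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Classic GSEA running sum over a ranked list: positions in the set add
#' `|metric|^weight / sum(|metric|^weight over hits)`, positions outside
#' subtract `1 / (N - N_hits)`. The enrichment score is the running sum's
#' maximum deviation from zero (signed).
#'
#' @param metric Named numeric vector (id -> ranking metric); sorted
#'   internally in decreasing order with ties broken by id.
#' @param set Character vector; must intersect the ranked ids and must not
#'   cover all of them.
#' @param weight Exponent on the metric. Default 1; 0 gives the unweighted
#'   (equal-step) statistic.
#' @return List: `es`, `running` (running sum along the ranked list),
#'   `peak` (index of the extreme).
#' @export
gsea_enrichment_score <- function(metric, set, weight = 1) {
  ranked <- rank_metric(metric)
  ids <- names(ranked)
  hit <- ids %in% set
  n_hit <- sum(hit)
  if (n_hit == 0L) stop_validation("'set' does not intersect the ranked list")
  if (n_hit == length(ids)) {
    stop_validation("'set' covers the whole ranked list (no misses)")
  }
  wts <- abs(ranked)^weight
  denom <- sum(wts[hit])
  step_hit <- if (denom > 0) wts / denom else
    rep(1 / n_hit, length(ids))  # all-zero metric: equal hit steps
  step <- ifelse(hit, step_hit, -1 / (length(ids) - n_hit))
  running <- cumsum(step)
  ## signed extreme; an exact tie between the positive and negative
  ## deviations resolves to the positive one
  mx <- max(running)
  mn <- min(running)
  if (mx + mn >= -1e-12) {
    peak <- which.max(running)
    es <- mx
  } else {
    peak <- which.min(running)
    es <- mn
  }
  list(es = es, running = unname(running), peak = peak)
}

#' Preranked gene-set enrichment analysis
#'
#' Computes the enrichment score of each set on the ranked list, builds a
#' null by gene-label permutation (random sets of the same size), and
#' reports the normalized enrichment score (ES divided by the mean |null
#' ES| of matching sign), a permutation p-value, and an FDR q-value from
#' the standard signed pooling of normalized null scores across sets.
#' Deterministic for a fixed seed.
#'
#' @param metric Named numeric vector (id -> ranking metric), e.g. `log2fc`
#'   from [run_differential()].
#' @param sets Named list of character vectors; sets with no overlap or
#'   full overlap with the ranked ids are dropped with a message.
#' @param n_permutations Number of label permutations (>= 100). Default
#'   1000.
#' @param weight Metric exponent. Default 1.
#' @param seed Integer seed.
#' @return data.frame `set`, `size` (ids in list), `es`, `nes`, `p`,
#'   `fdr_q`, sorted by `p` then set name.
#' @export
gsea_preranked <- function(metric, sets, n_permutations = 1000L, weight = 1,
                           seed = 1L) {
  n_permutations <- assert_count(n_permutations, "n_permutations", min = 100L)
  ranked <- rank_metric(metric)
  ids <- names(ranked)
  sizes <- vapply(sets, function(s) length(intersect(s, ids)), integer(1))
  drop <- sizes == 0L | sizes == length(ids)
  if (any(drop)) {
    message(sprintf("dropping %d set(s) with empty or full overlap", sum(drop)))
    sets <- sets[!drop]
    sizes <- sizes[!drop]
  }
  if (length(sets) == 0L) {
    return(data.frame(set = character(0), size = integer(0), es = numeric(0),
                      nes = numeric(0), p = numeric(0), fdr_q = numeric(0)))
  }
  es_obs <- vapply(names(sets), function(nm)
    gsea_enrichment_score(ranked, sets[[nm]], weight)$es, numeric(1))

  with_seed(seed, {
    uniq_sizes <- sort(unique(sizes))
    null_by_size <- lapply(uniq_sizes, function(k) {
      vapply(seq_len(n_permutations), function(b) {
        gsea_enrichment_score(ranked, sample(ids, k), weight)$es
      }, numeric(1))
    })
    names(null_by_size) <- as.character(uniq_sizes)

    norm_one <- function(es, null) {
      pos_mean <- mean(null[null >= 0])
      neg_mean <- mean(abs(null[null < 0]))
      ## signed permutation tail (GSEA convention): fraction of same-sign
      ## null ES at least as extreme; 0 when nothing in the null reaches it
      if (es >= 0) {
        list(nes = if (is.nan(pos_mean) || pos_mean == 0) NA_real_
                   else es / pos_mean,
             p = sum(null >= es) / max(1L, sum(null >= 0)),
             null_nes = c(null[null >= 0] / pos_mean,
                          if (!is.nan(neg_mean) && neg_mean > 0)
                            null[null < 0] / neg_mean))
      } else {
        list(nes = if (is.nan(neg_mean) || neg_mean == 0) NA_real_
                   else es / neg_mean,
             p = sum(null <= es) / max(1L, sum(null < 0)),
             null_nes = c(null[null < 0] / neg_mean,
                          if (!is.nan(pos_mean) && pos_mean > 0)
                            null[null >= 0] / pos_mean))
      }
    }
    per_set <- lapply(names(sets), function(nm) {
      norm_one(es_obs[[nm]], null_by_size[[as.character(
        length(intersect(sets[[nm]], ids)))]])
    })
    nes <- vapply(per_set, function(x) x$nes, numeric(1))
    pval <- vapply(per_set, function(x) x$p, numeric(1))
    pooled_null <- unlist(lapply(per_set, function(x) x$null_nes))

    fdr_q <- vapply(seq_along(nes), function(i) {
      s <- nes[i]
      if (is.na(s)) return(NA_real_)
      if (s >= 0) {
        num <- mean(pooled_null[pooled_null >= 0] >= s)
        den <- sum(nes >= s, na.rm = TRUE) / max(1, sum(nes >= 0, na.rm = TRUE))
      } else {
        num <- mean(pooled_null[pooled_null < 0] <= s)
        den <- sum(nes <= s, na.rm = TRUE) / max(1, sum(nes < 0, na.rm = TRUE))
      }
      if (is.nan(num) || den == 0) return(NA_real_)
      min(1, num / den)
    }, numeric(1))

    out <- data.frame(set = names(sets),
                      size = as.integer(sizes[names(sets)]),
                      es = unname(es_obs), nes = nes, p = pval,
                      fdr_q = fdr_q, stringsAsFactors = FALSE)
    out <- out[order(out$p, out$set), ]
    rownames(out) <- NULL
    out
  })
}
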