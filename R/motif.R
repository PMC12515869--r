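#' Positional amino-acid frequency matrix of flanking windows
#'
#' Counts residues at each offset around the central lysine of a set of
#' `2*w + 1`-residue windows. The terminus-padding character `_` is counted
#' in its own bucket, so per-position counts (including padding) sum to the
#' number of windows and frequencies (counts / n_windows) sum to 1.
#'
#' @param windows Character vector of windows, all of length `2*w + 1` with
#'   `K` at the center.
#' @param w Half-window width.
#' @return Object of class `pfm`: list with `counts` and `freq` (matrices,
#'   rows = 20 residues + `_`, columns = offsets `-w..-1, +1..+w`),
#'   `n_windows`, `w`, `offsets`.
#' @export
position_frequency_matrix <- function(windows, w) {
  w <- assert_count(w, "w", min = 1L)
  width <- 2L * w + 1L
  bad <- nchar(windows) != width | substr(windows, w + 1L, w + 1L) != "K"
  if (any(bad)) {
    stop_validation("malformed window(s): ",
                    paste(utils::head(windows[bad], 5), collapse = ", "))
  }
  offsets <- setdiff(seq(-w, w), 0L)
  rows <- c(AA_ALPHABET, "_")
  counts <- matrix(0L, nrow = length(rows), ncol = length(offsets),
                   dimnames = list(rows, sprintf("%+d", offsets)))
  n <- length(windows)
  if (n > 0L) {
    chars <- matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
                    nrow = width)
    for (j in seq_along(offsets)) {
      col <- chars[offsets[j] + w + 1L, ]
      tb <- table(factor(col, levels = rows))
      if (sum(tb) != n) {
        stop_validation("window(s) contain characters outside the amino-acid alphabet")
      }
      counts[, j] <- as.integer(tb)
    }
  }
  structure(list(counts = counts,
                 freq = if (n > 0L) counts / n else counts * 0,
                 n_windows = n, w = w, offsets = offsets),
            class = "pfm")
}

#' Positional enrichment of foreground versus background windows
#'
#' For every (offset, residue) cell, compares the foreground frequency with
#' the background frequency: the reported ratio adds a pseudo-frequency of
#' `0.5 / n` to each side to stay finite at zero background counts, while
#' the p-value is the exact binomial upper tail of the raw foreground count
#' at the raw background frequency.
#'
#' @param fg,bg `pfm` objects with the same `w`.
#' @return data.frame with `offset`, `residue`, `fg_count`, `fg_freq`,
#'   `bg_freq`, `log2_ratio`, `p`, `bg_zero` (flag: background frequency was
#'   zero with a positive foreground count).
#' @export
positional_enrichment <- function(fg, bg) {
  stopifnot(inherits(fg, "pfm"), inherits(bg, "pfm"))
  if (fg$w != bg$w) stop_validation("'fg' and 'bg' must share the same w")
  if (fg$n_windows == 0L || bg$n_windows == 0L) {
    stop_validation("both window sets must be non-empty")
  }
  grid <- expand.grid(residue = AA_ALPHABET,
                      offset = sprintf("%+d", fg$offsets),
                      stringsAsFactors = FALSE)
  k <- mapply(function(r, o) fg$counts[r, o], grid$residue, grid$offset)
  fg_freq <- k / fg$n_windows
  bg_freq <- mapply(function(r, o) bg$freq[r, o], grid$residue, grid$offset)
  ratio <- (fg_freq + 0.5 / fg$n_windows) / (bg_freq + 0.5 / bg$n_windows)
  p <- pbinom(k - 1L, fg$n_windows, bg_freq, lower.tail = FALSE)
  data.frame(offset = grid$offset, residue = grid$residue,
             fg_count = as.integer(k), fg_freq = fg_freq, bg_freq = bg_freq,
             log2_ratio = log2(ratio), p = p,
             bg_zero = bg_freq == 0 & k > 0, row.names = NULL,
             stringsAsFactors = FALSE)
}

## Windows matching a motif pattern (named character vector offset -> residue,
## names like "-1", "+3"). '_' never matches.
motif_matches <- function(windows, pattern, w) {
  if (length(pattern) == 0L) return(rep(TRUE, length(windows)))
  keep <- rep(TRUE, length(windows))
  for (off in names(pattern)) {
    idx <- as.integer(off) + w + 1L
    keep <- keep & substr(windows, idx, idx) == pattern[[off]]
  }
  keep
}

#' Greedy motif-x style motif search
#'
#' Iteratively extracts sequence motifs around the central lysine. At each
#' step the (offset, residue) cell with the smallest binomial upper-tail
#' p-value of the foreground count at the background frequency is fixed,
#' provided `p < p_threshold` and the foreground support is at least
#' `min_occurrences`; both window sets are then restricted to matching
#' windows and the search recurses. When no further cell qualifies, the
#' accumulated pattern is emitted as a motif, its foreground matches are
#' removed, and the search restarts against the full background. Ties in p
#' are broken by offset then residue, so results are deterministic.
#'
#' @param fg_windows Foreground windows (modified-site flanks).
#' @param bg_windows Background windows (all K-centered windows of the
#'   proteome; see [proteome_k_windows()]).
#' @param w Half-window width.
#' @param p_threshold Binomial significance threshold per fixed cell.
#'   Default 1e-6 (motif-x convention).
#' @param min_occurrences Minimum foreground support per motif. Default 20.
#' @param max_depth Maximum number of fixed positions per motif. Default
#'   `2 * w`.
#' @return data.frame with one row per motif: `motif` (dot pattern like
#'   `.......A..K..........`), `n_fixed`, `fg_matches`, `bg_matches`,
#'   `fold_enrichment`, `p` (binomial tail of the full pattern against the
#'   full background). Zero rows when nothing qualifies.
#' @export
motif_x_search <- function(fg_windows, bg_windows, w, p_threshold = 1e-6,
                           min_occurrences = 20L, max_depth = 2L * w) {
  w <- assert_count(w, "w", min = 1L)
  if (length(fg_windows) == 0L || length(bg_windows) == 0L) {
    return(empty_motif_result())
  }
  position_frequency_matrix(fg_windows, w)  # validates fg
  position_frequency_matrix(bg_windows, w)
  offsets <- setdiff(seq(-w, w), 0L)
  results <- list()
  fg_pool <- fg_windows
  repeat {
    if (length(fg_pool) == 0L) break
    pattern <- grow_motif(fg_pool, bg_windows, w, offsets, p_threshold,
                          min_occurrences, max_depth)
    if (length(pattern) == 0L) break
    hit_fg <- motif_matches(fg_pool, pattern, w)
    hit_bg <- motif_matches(bg_windows, pattern, w)
    k_fg <- sum(hit_fg)
    k_bg <- sum(hit_bg)
    bg_freq <- k_bg / length(bg_windows)
    fold <- (k_fg / length(fg_pool)) /
      ((k_bg + 0.5) / (length(bg_windows) + 0.5))
    results[[length(results) + 1L]] <- data.frame(
      motif = pattern_string(pattern, w), n_fixed = length(pattern),
      fg_matches = k_fg, bg_matches = k_bg, fold_enrichment = fold,
      p = pbinom(k_fg - 1L, length(fg_pool), bg_freq, lower.tail = FALSE),
      stringsAsFactors = FALSE)
    fg_pool <- fg_pool[!hit_fg]
  }
  if (length(results) == 0L) return(empty_motif_result())
  out <- do.call(rbind, results)
  rownames(out) <- NULL
  out
}

empty_motif_result <- function() {
  data.frame(motif = character(0), n_fixed = integer(0),
             fg_matches = integer(0), bg_matches = integer(0),
             fold_enrichment = numeric(0), p = numeric(0))
}

## One greedy descent: returns the fixed pattern (possibly empty).
grow_motif <- function(fg, bg, w, offsets, p_threshold, min_occurrences,
                       max_depth) {
  pattern <- character(0)
  repeat {
    if (length(pattern) >= max_depth) break
    free <- setdiff(sprintf("%+d", offsets), names(pattern))
    if (length(free) == 0L || length(fg) == 0L || length(bg) == 0L) break
    fg_pfm <- position_frequency_matrix(fg, w)
    bg_pfm <- position_frequency_matrix(bg, w)
    best <- NULL
    for (off in free) {
      for (res in AA_ALPHABET) {
        k <- fg_pfm$counts[res, off]
        if (k < min_occurrences) next
        p <- pbinom(k - 1L, length(fg), bg_pfm$freq[res, off],
                    lower.tail = FALSE)
        if (is.null(best) || p < best$p) {
          best <- list(off = off, res = res, p = p)
        }
      }
    }
    if (is.null(best) || best$p >= p_threshold) break
    pattern[[best$off]] <- best$res
    idx <- as.integer(best$off) + w + 1L
    fg <- fg[substr(fg, idx, idx) == best$res]
    bg <- bg[substr(bg, idx, idx) == best$res]
  }
  pattern
}

pattern_string <- function(pattern, w) {
  chars <- rep(".", 2L * w + 1L)
  chars[w + 1L] <- "K"
  for (off in names(pattern)) chars[as.integer(off) + w + 1L] <- pattern[[off]]
  paste(chars, collapse = "")
}

#' All lysine-centered windows of a proteome
#'
#' Extracts the `2*w + 1` window around every K residue of every protein —
#' the motif-x background matching the central residue.
#'
#' @param proteome data.frame with `accession`, `sequence`.
#' @param w Half-window width. Default 10.
#' @return Character vector of windows.
#' @export
proteome_k_windows <- function(proteome, w = 10L) {
  unlist(lapply(seq_len(nrow(proteome)), function(i) {
    s <- proteome$sequence[i]
    pos <- which(strsplit(s, "", fixed = TRUE)[[1]] == "K")
    vapply(pos, function(p) extract_flank(s, p, w = w), character(1))
  }), use.names = FALSE)
}
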