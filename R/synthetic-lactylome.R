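#' Generate a synthetic lactylome on a proteome
#'
#' Selects a fraction of proteins as lactylated and places lysine-lactylation
#' sites on their K residues. Per-protein site counts follow a mixture: with
#' probability `design$single_site_frac` a protein carries exactly one site;
#' otherwise it carries `2 + NB(size, mu)` sites with `mu` proportional to
#' the protein's lysine count, producing the heavy right tail seen in real
#' lactylomes (a few K-rich giants carrying tens of sites). The negative
#' binomial mean is calibrated so the overall mean sites-per-protein matches
#' `design$mean_sites_per_protein`.
#'
#' Selected proteins containing no lysine are skipped with a warning; site
#' counts are capped at the number of available K residues.
#'
#' @param proteome data.frame with `accession`, `sequence` columns (e.g. from
#'   [generate_proteome()]).
#' @param design A [synthetic_design()].
#' @param w Flanking half-window recorded per site. Default 10.
#' @param nb_size Negative-binomial dispersion of the multi-site branch
#'   (smaller = heavier tail). Default 0.5.
#' @return A site catalog data.frame: `site`, `accession`, `position`
#'   (1-based), `flank` (width `2*w + 1`, `_`-padded at termini).
#' @export
generate_lactylome <- function(proteome, design = synthetic_design(),
                               w = 10L, nb_size = 0.5) {
  if (nrow(proteome) == 0L) stop_validation("'proteome' must be non-empty")
  stopifnot(inherits(design, "synthetic_design"))
  with_seed(design$seed + 1L, {
    n_mod <- round(design$frac_modified_proteins * nrow(proteome))
    idx <- sample.int(nrow(proteome), n_mod)
    k_pos <- lapply(proteome$sequence[idx], function(s) {
      which(strsplit(s, "", fixed = TRUE)[[1]] == "K")
    })
    n_k <- lengths(k_pos)
    if (any(n_k == 0L)) {
      warning(sprintf("%d selected protein(s) contain no lysine; skipped",
                      sum(n_k == 0L)))
      idx <- idx[n_k > 0L]
      k_pos <- k_pos[n_k > 0L]
      n_k <- n_k[n_k > 0L]
    }
    if (length(idx) == 0L) {
      return(data.frame(site = character(), accession = character(),
                        position = integer(), flank = character(),
                        stringsAsFactors = FALSE))
    }
    p1 <- design$single_site_frac
    ## Mean of the NB branch so that E[sites/protein] hits the target:
    ## target = p1 * 1 + (1 - p1) * (2 + mu_bar)
    mu_bar <- if (p1 >= 1) 0 else
      max(0, (design$mean_sites_per_protein - p1 - 2 * (1 - p1)) / (1 - p1))
    mu_i <- if (mean(n_k) > 0) mu_bar * n_k / mean(n_k) else rep(0, length(n_k))
    single <- runif(length(idx)) < p1
    counts <- ifelse(single, 1L,
                     2L + rnbinom(length(idx), size = nb_size, mu = mu_i))
    counts <- pmin(counts, n_k)
    recs <- lapply(seq_along(idx), function(i) {
      pos <- sort(k_pos[[i]][sample.int(length(k_pos[[i]]), counts[i])])
      acc <- proteome$accession[idx[i]]
      data.frame(site = paste0(acc, "_K", pos), accession = acc,
                 position = pos, stringsAsFactors = FALSE)
    })
    catalog <- do.call(rbind, recs)
    catalog <- catalog[order(catalog$accession, catalog$position), ]
    rownames(catalog) <- NULL
    seqs <- setNames(proteome$sequence, proteome$accession)
    catalog$flank <- vapply(seq_len(nrow(catalog)), function(i) {
      extract_flank(seqs[[catalog$accession[i]]], catalog$position[i], w = w)
    }, character(1))
    catalog
  })
}
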