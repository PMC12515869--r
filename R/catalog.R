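#' Sites-per-protein counts and histogram
#'
#' @param catalog Site catalog data.frame (`site`, `accession`, `position`).
#' @return List: `counts` (named integer vector, sites per protein) and
#'   `histogram` (data.frame `bin` / `n_proteins`, bins `1`..`20` and
#'   `">20"`).
#' @export
sites_per_protein <- function(catalog) {
  if (nrow(catalog) == 0L) {
    return(list(counts = integer(0),
                histogram = data.frame(bin = character(0),
                                       n_proteins = integer(0))))
  }
  counts <- table(catalog$accession)
  counts <- setNames(as.integer(counts), names(counts))
  bins <- c(as.character(1:20), ">20")
  binned <- ifelse(counts > 20L, ">20", as.character(counts))
  hist <- data.frame(bin = bins,
                     n_proteins = as.integer(table(factor(binned,
                                                          levels = bins))),
                     stringsAsFactors = FALSE)
  list(counts = counts, histogram = hist)
}

#' Percentage of modified proteins carrying exactly one site
#'
#' @param catalog Non-empty site catalog.
#' @return Percentage (0-100), rounded to 2 decimals.
#' @export
fraction_single_site <- function(catalog) {
  if (nrow(catalog) == 0L) stop_validation("'catalog' is empty")
  counts <- table(catalog$accession)
  round(100 * sum(counts == 1L) / length(counts), 2)
}

#' Most heavily modified proteins
#'
#' Ranked descending by site count; ties broken lexicographically by
#' accession.
#'
#' @param catalog Site catalog.
#' @param k Number of proteins to return (>= 1).
#' @return data.frame `accession`, `n_sites` (at most `k` rows).
#' @export
top_modified_proteins <- function(catalog, k) {
  k <- assert_count(k, "k", min = 1L)
  counts <- table(catalog$accession)
  ord <- order(-as.integer(counts), names(counts))
  data.frame(accession = names(counts)[ord],
             n_sites = as.integer(counts)[ord],
             stringsAsFactors = FALSE)[seq_len(min(k, length(counts))), ,
                                       drop = FALSE]
}

#' Overlap of modification-changed and content-changed proteins
#'
#' Set arithmetic behind the Venn comparison of proteins with changed
#' modification levels versus proteins with changed abundance.
#'
#' @param kla_changed,content_changed Character vectors of accessions.
#' @return List: `n_kla`, `n_content`, `n_overlap`, `n_kla_only`,
#'   `percent_kla_only` (2 decimals; share of `kla_changed` outside
#'   `content_changed`).
#' @export
overlap_changed <- function(kla_changed, content_changed) {
  kla <- unique(kla_changed)
  content <- unique(content_changed)
  n_overlap <- length(intersect(kla, content))
  n_only <- length(kla) - n_overlap
  list(n_kla = length(kla), n_content = length(content),
       n_overlap = n_overlap, n_kla_only = n_only,
       percent_kla_only = if (length(kla)) round(100 * n_only / length(kla), 2)
                          else NA_real_)
}

#' Extract the flanking window around a modified lysine
#'
#' Returns the `2*w + 1` residue window centered on a lysine, padded with
#' `_` beyond the protein termini (motif-tool convention).
#'
#' @param sequence Protein sequence (single string) or a proteome data.frame
#'   with `accession`/`sequence` columns, in which case `accession` selects
#'   the protein.
#' @param position 1-based residue index; must hold a `K`.
#' @param w Half-window in residues. Default 10.
#' @param accession Accession to look up when `sequence` is a proteome.
#' @return Window string of length `2*w + 1` with `K` at the center.
#' @examples
#' extract_flank("MKT", 2, w = 2)  # "_MKT_"
#' @export
extract_flank <- function(sequence, position, w = 10L, accession = NULL) {
  if (is.data.frame(sequence)) {
    stopifnot(!is.null(accession))
    hit <- match(accession, sequence$accession)
    if (is.na(hit)) stop_validation("accession not found in proteome")
    sequence <- sequence$sequence[hit]
  }
  w <- assert_count(w, "w", min = 1L)
  n <- nchar(sequence)
  if (position < 1L || position > n) {
    stop_validation("'position' outside the protein")
  }
  if (substr(sequence, position, position) != "K") {
    stop_validation(sprintf("residue at position %d is not K", position))
  }
  lo <- position - w
  hi <- position + w
  core <- substr(sequence, max(1L, lo), min(n, hi))
  paste0(strrep("_", max(0L, 1L - lo)), core, strrep("_", max(0L, hi - n)))
}

#' Tally proteins and sites per cellular compartment
#'
#' A multi-localized protein contributes once to each of its compartments.
#' Queried proteins missing from the annotation fall into an
#' `"unannotated"` bucket. When a site catalog is supplied, sites are
#' counted per compartment through their parent protein.
#'
#' @param proteins Character vector of accessions.
#' @param annotation Named list: accession -> character vector of
#'   compartment labels (each annotated protein needs >= 1 label).
#' @param sites Optional site catalog restricted to `proteins` for the site
#'   tally.
#' @return data.frame `compartment`, `n_proteins`, `n_sites`, sorted by
#'   descending protein count then name.
#' @export
tally_compartments <- function(proteins, annotation, sites = NULL) {
  proteins <- unique(proteins)
  labels_of <- function(acc) {
    lab <- annotation[[acc]]
    if (is.null(lab) || length(lab) == 0L) "unannotated" else unique(lab)
  }
  site_counts <- if (is.null(sites)) integer(0) else table(sites$accession)
  rows <- lapply(proteins, function(acc) {
    ns <- if (acc %in% names(site_counts)) as.integer(site_counts[[acc]]) else 0L
    data.frame(compartment = labels_of(acc), n_proteins = 1L, n_sites = ns,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(compartment = character(0), n_proteins = integer(0),
                      n_sites = integer(0)))
  }
  all_rows <- do.call(rbind, rows)
  agg <- aggregate(cbind(n_proteins, n_sites) ~ compartment, data = all_rows,
                   FUN = sum)
  agg <- agg[order(-agg$n_proteins, agg$compartment), ]
  rownames(agg) <- NULL
  agg
}
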