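#' Configuration for an end-to-end pipeline run
#'
#' Collects every stage parameter with the calling thresholds used
#' throughout (fold change above 1.5 or below 1/1.5 with raw p < 0.05), the
#' motif and network settings, and the simulation design.
#'
#' @param design A [synthetic_design()] describing the simulated experiment.
#' @param n_proteins Proteome size for simulation. Default 1000 (so the
#'   default design yields ~477 modified proteins).
#' @param up_threshold,down_threshold,alpha,gate_alpha Differential calling
#'   thresholds; see [run_differential()].
#' @param w Motif half-window. Default 10.
#' @param motif_p_threshold,motif_min_occurrences motif-x settings.
#' @param node_score_cutoff,haircut,fluff MCODE settings.
#' @param n_permutations,gene_sets GSEA settings: permutation count and an
#'   optional named list of gene sets (protein accessions); `NULL` simulates
#'   sets with [generate_gene_sets()].
#' @param seed Master seed for the run.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(design = synthetic_design(seed = seed),
                            n_proteins = 1000L,
                            up_threshold = 1.5,
                            down_threshold = 1 / up_threshold,
                            alpha = 0.05, gate_alpha = 0.05, w = 10L,
                            motif_p_threshold = 1e-6,
                            motif_min_occurrences = 20L,
                            node_score_cutoff = 0.2, haircut = TRUE,
                            fluff = FALSE, n_permutations = 1000L,
                            gene_sets = NULL, seed = 1L) {
  stopifnot(down_threshold > 0, up_threshold > down_threshold)
  structure(list(design = design, n_proteins = n_proteins,
                 up_threshold = up_threshold,
                 down_threshold = down_threshold, alpha = alpha,
                 gate_alpha = gate_alpha, w = w,
                 motif_p_threshold = motif_p_threshold,
                 motif_min_occurrences = motif_min_occurrences,
                 node_score_cutoff = node_score_cutoff, haircut = haircut,
                 fluff = fluff, n_permutations = n_permutations,
                 gene_sets = gene_sets, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full synthetic-to-report pipeline
#'
#' Chains every stage at desk scale: simulate a proteome, lactylome,
#' intensity tables, PPI graph and gene sets; normalize, center and
#' protein-correct the site table; run the gated differential analysis on
#' sites and proteins; summarize the site catalog; search motifs against
#' the proteome background; detect MCODE complexes on the PPI graph of
#' modified proteins; and run ORA plus preranked GSEA on the differential
#' results. Identical `config` (including its seeds) reproduces identical
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional directory; when given, every stage output is
#'   written there as TSV (with `#` metadata headers echoing thresholds and
#'   seed).
#' @return List of class `pipeline_run`: `report` (named counts), plus all
#'   intermediate objects (`proteome`, `catalog`, `tables`, `corrected`,
#'   `diff_sites`, `diff_proteins`, `catalog_summary`, `motifs`,
#'   `complexes`, `ora`, `gsea`).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  design <- config$design
  proteome <- generate_proteome(config$n_proteins, seed = config$seed)
  catalog <- generate_lactylome(proteome, design, w = config$w)
  report <- c(n_proteins = nrow(proteome), n_modified_proteins = 0L,
              n_sites = 0L)
  if (nrow(catalog) == 0L) {
    return(structure(list(report = report, proteome = proteome,
                          catalog = catalog), class = "pipeline_run"))
  }
  tables <- generate_intensities(catalog, design)
  map <- setNames(catalog$accession, catalog$site)
  orphans <- sum(!(map %in% rownames(tables$proteins$values)))
  quant <- quantify_sites(tables$sites, tables$proteins, map)

  diff_sites <- run_differential(quant$sites,
                                 up_threshold = config$up_threshold,
                                 down_threshold = config$down_threshold,
                                 alpha = config$alpha,
                                 gate_alpha = config$gate_alpha)
  diff_proteins <- run_differential(quant$proteins,
                                    up_threshold = config$up_threshold,
                                    down_threshold = config$down_threshold,
                                    alpha = config$alpha,
                                    gate_alpha = config$gate_alpha)

  spp <- sites_per_protein(catalog)
  changed_sites <- diff_sites$feature[diff_sites$call != "ns"]
  kla_changed <- unique(catalog$accession[match(changed_sites, catalog$site)])
  content_changed <- diff_proteins$feature[diff_proteins$call != "ns"]
  venn <- overlap_changed(kla_changed, content_changed)
  catalog_summary <- list(
    histogram = spp$histogram,
    single_site_pct = fraction_single_site(catalog),
    top_proteins = top_modified_proteins(catalog, 10L),
    venn = venn)

  bg_windows <- proteome_k_windows(proteome, w = config$w)
  motifs <- motif_x_search(catalog$flank, bg_windows, w = config$w,
                           p_threshold = config$motif_p_threshold,
                           min_occurrences = config$motif_min_occurrences)

  accs <- sort(unique(catalog$accession))
  n_planted <- min(3L, length(accs) %/% 15L)
  graph <- generate_ppi_graph(length(accs),
                              clusters = rep(list(c(15L, 0.9)), n_planted),
                              p_out = 0.01, seed = config$seed + 3L)
  graph <- igraph::set_vertex_attr(graph, "name", value = accs)
  complexes <- mcode_find_complexes(graph,
                                    node_score_cutoff = config$node_score_cutoff,
                                    haircut = config$haircut,
                                    fluff = config$fluff)

  sets <- config$gene_sets %||%
    generate_gene_sets(accs, n_sets = 20L,
                       size_range = c(10L, min(50L, length(accs))),
                       seed = config$seed + 4L)
  ora <- ora_hypergeometric(kla_changed, accs, sets)
  site_metric <- setNames(diff_sites$log2fc, diff_sites$feature)
  site_metric <- site_metric[is.finite(site_metric)]
  prot_metric <- tapply(site_metric,
                        catalog$accession[match(names(site_metric),
                                                catalog$site)], mean)
  prot_metric <- setNames(as.numeric(prot_metric), names(prot_metric))
  gsea <- gsea_preranked(prot_metric, sets,
                         n_permutations = config$n_permutations,
                         seed = config$seed + 5L)

  s_sum <- summarize_differential(diff_sites)
  p_sum <- summarize_differential(diff_proteins)
  report <- c(n_proteins = nrow(proteome),
              n_modified_proteins = length(unique(catalog$accession)),
              n_sites = nrow(catalog), n_orphan_sites = orphans,
              n_sites_untestable = unname(s_sum["n_untestable"]),
              n_sites_up = unname(s_sum["n_up"]),
              n_sites_down = unname(s_sum["n_down"]),
              n_sites_ns = unname(s_sum["n_ns"]),
              n_proteins_up = unname(p_sum["n_up"]),
              n_proteins_down = unname(p_sum["n_down"]),
              n_clusters = nrow(complexes), n_motifs = nrow(motifs),
              seed = config$seed)

  run <- structure(list(report = report, proteome = proteome,
                        catalog = catalog, tables = tables,
                        corrected = quant$sites, diff_sites = diff_sites,
                        diff_proteins = diff_proteins,
                        catalog_summary = catalog_summary, motifs = motifs,
                        graph = graph, complexes = complexes, ora = ora,
                        gsea = gsea), class = "pipeline_run")
  if (!is.null(outdir)) write_pipeline_outputs(run, config, outdir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline_run\n")
  for (nm in names(x$report)) {
    cat(sprintf("  %-22s %s\n", nm, format(x$report[[nm]])))
  }
  invisible(x)
}

write_pipeline_outputs <- function(run, config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  meta <- c(sprintf("lactylomics %s",
                    as.character(utils::packageVersion("lactylomics"))),
            sprintf("seed: %d", config$seed),
            sprintf("thresholds: up=%g down=%g alpha=%g gate_alpha=%g",
                    config$up_threshold, config$down_threshold,
                    config$alpha, config$gate_alpha))
  p <- function(f) file.path(outdir, f)
  write_fasta(run$proteome, p("proteome.fasta"))
  write_site_tsv(run$catalog, p("sites.tsv"), comments = meta)
  write_intensity_tsv(run$tables$sites, p("site_intensities.tsv"), meta)
  write_intensity_tsv(run$tables$proteins, p("protein_intensities.tsv"), meta)
  write_tsv(run$tables$truth, p("truth.tsv"), meta)
  write_intensity_tsv(run$corrected, p("corrected.tsv"), meta)
  write_tsv(run$diff_sites, p("diff_sites.tsv"), meta)
  write_tsv(run$diff_sites[, c("feature", "log2fc", "neg_log10_p")],
            p("volcano.tsv"), meta)
  write_tsv(run$diff_proteins, p("diff_proteins.tsv"), meta)
  write_tsv(run$catalog_summary$histogram, p("sites_per_protein.tsv"), meta)
  write_tsv(run$motifs, p("motifs.tsv"), meta)
  write_edge_list(run$graph, p("ppi_edges.tsv"))
  write_tsv(run$complexes, p("complexes.tsv"), meta)
  write_tsv(run$ora, p("ora.tsv"), meta)
  write_tsv(run$gsea, p("gsea.tsv"), meta)
  write_tsv(data.frame(key = names(run$report),
                       value = unname(run$report)),
            p("report.tsv"), meta)
  invisible(outdir)
}
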