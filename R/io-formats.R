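#' Read a proteome from FASTA
#'
#' The accession is the header token before the first whitespace; sequences
#' are upper-cased and a trailing `*` is stripped.
#'
#' @param path FASTA file.
#' @return data.frame `accession`, `sequence`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) {
    warning("empty FASTA file: ", path)
    return(data.frame(accession = character(0), sequence = character(0)))
  }
  acc <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(acc)) {
    stop_validation("duplicate accession(s) in FASTA: ",
                    paste(unique(acc[duplicated(acc)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  data.frame(accession = acc, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write a proteome to FASTA
#'
#' @param proteome data.frame with `accession`, `sequence`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteome, path) {
  set <- Biostrings::AAStringSet(setNames(proteome$sequence,
                                          proteome$accession))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

## Shared TSV dialect: '#'-prefixed metadata lines, header row, empty cell
## (or "NA") = missing, '.' decimal separator.

write_tsv <- function(df, path, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

#' Write an intensity table to TSV
#'
#' First column `feature`, remaining columns sample ids; a `# group:` header
#' comment records the design; missing values are written as empty cells.
#'
#' @param tab An [intensity_table()].
#' @param path Output file.
#' @param comments Extra `#` metadata lines.
#' @return `path`, invisibly.
#' @export
write_intensity_tsv <- function(tab, path, comments = character(0)) {
  df <- data.frame(feature = rownames(tab$values), tab$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path,
            comments = c(paste0("group: ",
                                paste(sprintf("%s=%s", names(tab$group),
                                              tab$group), collapse = ",")),
                         comments))
}

#' Read an intensity table from TSV
#'
#' Accepts the dialect of [write_intensity_tsv()]: first column feature id,
#' then one column per sample; empty cells and `NA` are missing. Ragged rows
#' and non-positive values are rejected with the offending location.
#'
#' @param path TSV file.
#' @param group Character vector of group labels per sample column, or
#'   `NULL` to read them from the `# group:` header comment.
#' @return An [intensity_table()].
#' @export
read_intensity_tsv <- function(path, group = NULL) {
  lines <- readLines(path)
  body <- grep("^#", lines, invert = TRUE, value = FALSE)
  fields <- count.fields(textConnection(lines[body]), sep = "\t",
                         blank.lines.skip = FALSE)
  if (length(unique(fields)) > 1L) {
    stop_validation("ragged row at line ",
                    body[which(fields != fields[1])[1]], " of ", path)
  }
  if (is.null(group)) {
    gl <- grep("^# group:", lines, value = TRUE)
    if (length(gl) != 1L) {
      stop_validation("no 'group' argument and no '# group:' header in ", path)
    }
    pairs <- strsplit(strsplit(sub("^# group:\\s*", "", gl), ",")[[1]], "=")
    group <- setNames(vapply(pairs, `[[`, character(1), 2L),
                      vapply(pairs, `[[`, character(1), 1L))
  }
  df <- read_tsv(path, na.strings = c("", "NA"))
  mat <- as.matrix(df[, -1, drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- df[[1]]
  bad <- which(!is.na(mat) & mat <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop_validation(sprintf("non-positive intensity at feature '%s', sample '%s'",
                            rownames(mat)[bad[1, 1]], colnames(mat)[bad[1, 2]]))
  }
  if (!is.null(names(group))) group <- group[colnames(mat)]
  intensity_table(mat, unname(group))
}

#' Read/write gene sets in GMT format
#'
#' Standard GMT dialect: one set per line — name, description, then
#' tab-separated member ids.
#'
#' @param sets Named list of character vectors.
#' @param path File path.
#' @param descriptions Optional character vector of descriptions (recycled
#'   `"na"`).
#' @return `read_gmt`: named list of character vectors; `write_gmt`:
#'   `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  desc <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  setNames(sets, vapply(parts, `[[`, character(1), 1L))
}

#' Read/write an undirected edge list TSV
#'
#' Two required columns (`from`, `to`) and an optional numeric `score`;
#' self-loops and duplicates are rejected by [ppi_graph()].
#'
#' @param path TSV file.
#' @param graph An [igraph::igraph].
#' @param min_score Optional score filter applied on read.
#' @return `read_edge_list`: an [igraph::igraph]; `write_edge_list`:
#'   `path`, invisibly.
#' @export
read_edge_list <- function(path, min_score = NULL) {
  df <- read_tsv(path)
  ppi_graph(df, min_score = min_score)
}

#' @rdname read_edge_list
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_edgelist(ensure_named(graph))
  write_tsv(data.frame(from = el[, 1], to = el[, 2]), path)
}

#' Write a site catalog to TSV
#'
#' @param catalog Site catalog data.frame.
#' @param path Output file.
#' @param comments Extra `#` metadata lines.
#' @return `path`, invisibly.
#' @export
write_site_tsv <- function(catalog, path, comments = character(0)) {
  write_tsv(catalog, path, comments = comments)
}

#' @rdname write_site_tsv
#' @param path TSV file.
#' @export
read_site_tsv <- function(path) {
  df <- read_tsv(path)
  df$position <- as.integer(df$position)
  df
}
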