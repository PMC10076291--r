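#' Read scaffold sequences from a FASTA file
#'
#' Loads a multi-FASTA of host or viral scaffolds, uppercases the sequence,
#' validates the alphabet (A, C, G, T, N) and applies the global scaffold
#' length floor. Scaffolds shorter than 2.5 kbp are excluded from all
#' downstream analyses by default; the floor is configurable so that small
#' synthetic fixtures can pass through.
#'
#' @param path Path to a FASTA file.
#' @param min_len Minimum scaffold length in bp (default 2500). Records
#'   shorter than this are dropped; input order is otherwise preserved.
#' @param source_sample,year Optional annotations attached to every scaffold.
#' @return A `data.frame` with columns `id`, `seq`, `length`,
#'   `source_sample`, `year`.
#' @export
read_sequences <- function(path, min_len = 2500, source_sample = NA_character_,
                           year = NA_integer_) {
  if (!file.exists(path)) sl_error("sl_io_error", paste0("no such file: ", path))
  if (file.size(path) == 0L) {
    return(data.frame(id = character(0), seq = character(0),
                      length = integer(0), source_sample = character(0),
                      year = integer(0), stringsAsFactors = FALSE))
  }
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) sl_error("sl_parse_error",
      paste0("malformed FASTA in ", path, ": ", conditionMessage(e)))
  )
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, "", 1L)
  if (anyDuplicated(ids)) {
    sl_error("sl_parse_error", paste0(
      "duplicate sequence id in ", path, ": ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    sl_error("sl_parse_error", paste0(
      "record ", ids[which(bad)[1]], " in ", path,
      " contains characters outside {A,C,G,T,N}"))
  }
  keep <- nchar(seqs) >= min_len & nchar(seqs) >= 1L
  data.frame(id = ids[keep], seq = unname(seqs[keep]),
             length = nchar(seqs[keep]),
             source_sample = source_sample, year = year,
             stringsAsFactors = FALSE)
}

#' Write scaffold sequences to FASTA
#'
#' @param scaffolds A `data.frame` with `id` and `seq` columns (as returned
#'   by [read_sequences()]) or a named character vector.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(scaffolds, path) {
  if (is.data.frame(scaffolds)) {
    seqs <- scaffolds$seq
    names(seqs) <- scaffolds$id
  } else {
    seqs <- scaffolds
  }
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

# GTDB-style 7-rank lineage -> matrix of rank values with prefixes stripped.
LINEAGE_RANKS <- c("domain", "phylum", "class", "order", "family", "genus",
                   "species")

split_lineage <- function(lineage) {
  parts <- strsplit(lineage, ";", fixed = TRUE)
  out <- matrix("", nrow = length(lineage), ncol = 7L,
                dimnames = list(NULL, LINEAGE_RANKS))
  for (i in seq_along(parts)) {
    p <- sub("^[a-z]__", "", trimws(parts[[i]]))
    p <- p[seq_len(min(length(p), 7L))]
    out[i, seq_along(p)] <- p
  }
  out
}

#' Read a MAG metadata table
#'
#' The table mirrors standard bin quality + taxonomy outputs: one row per
#' metagenome-assembled genome with CheckM-style completeness/contamination
#' percentages and a GTDB-style 7-rank lineage string.
#'
#' @param path TSV with required columns `mag_id`, `completeness`,
#'   `contamination`, `lineage`, `site`, `year`; an optional `scaffolds`
#'   column holds comma-separated member scaffold ids.
#' @return A `data.frame` with the input columns plus one column per rank
#'   (`domain` .. `species`; empty string for unassigned ranks) and a
#'   `scaffolds` list-column.
#' @export
read_mag_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("mag_id", "completeness", "contamination", "lineage", "site", "year")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    sl_error("sl_schema_error",
             paste0("MAG table ", path, " is missing column(s): ",
                    paste(missing, collapse = ", ")))
  }
  for (col in c("completeness", "contamination")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v) || any(v < 0 | v > 100)) {
      sl_error("sl_value_error",
               paste0(col, " must be numeric within [0, 100] in ", path))
    }
    df[[col]] <- v
  }
  ranks <- split_lineage(df$lineage)
  for (r in LINEAGE_RANKS) df[[r]] <- ranks[, r]
  if (!is.null(df$scaffolds)) {
    df$scaffolds <- lapply(strsplit(as.character(df$scaffolds), ",", fixed = TRUE),
                           trimws)
  } else {
    df$scaffolds <- replicate(nrow(df), character(0), simplify = FALSE)
  }
  df
}

#' Read a viral element metadata table
#'
#' @param path TSV with required columns `viral_id`, `site`, `year`,
#'   `category` (`nonintegrated` or `provirus` as labelled upstream);
#'   optional `length` and logical `dgr` columns.
#' @return A `data.frame`.
#' @export
read_viral_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("viral_id", "site", "year", "category")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    sl_error("sl_schema_error",
             paste0("viral table ", path, " is missing column(s): ",
                    paste(missing, collapse = ", ")))
  }
  if (is.null(df$dgr)) df$dgr <- FALSE
  df$dgr <- as.logical(df$dgr)
  df
}

#' Export a virus-host network
#'
#' Writes three companion files for downstream visualization (e.g. in
#' Cytoscape): an edge TSV (`<prefix>.edges.tsv` with columns `host_id`,
#' `viral_id`, `n_matches`, `host_site`, `viral_site`), a GraphML file with
#' site/year/taxonomy node attributes (`<prefix>.graphml`), and a SIF file
#' (`<prefix>.sif`).
#'
#' @param net A `vh_network` (see [build_network()]).
#' @param prefix Output path prefix.
#' @return Character vector of the three paths written, invisibly.
#' @export
write_network <- function(net, prefix) {
  stopifnot(inherits(net, "vh_network"))
  edge_path <- paste0(prefix, ".edges.tsv")
  gml_path <- paste0(prefix, ".graphml")
  sif_path <- paste0(prefix, ".sif")

  hsite <- stats::setNames(net$hosts$site, net$hosts$mag_id)
  vsite <- stats::setNames(net$virals$site, net$virals$viral_id)
  ed <- net$edges
  out <- data.frame(host_id = ed$host_id, viral_id = ed$viral_id,
                    n_matches = ed$weight,
                    host_site = unname(hsite[ed$host_id]),
                    viral_site = unname(vsite[ed$viral_id]),
                    stringsAsFactors = FALSE)
  utils::write.table(out, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  g <- network_to_igraph(net)
  igraph::write_graph(g, gml_path, format = "graphml")

  if (nrow(ed)) {
    sif <- paste(ed$host_id, "targets", ed$viral_id)
  } else {
    sif <- character(0)
  }
  writeLines(sif, sif_path)
  invisible(c(edges = edge_path, graphml = gml_path, sif = sif_path))
}

#' @importFrom igraph graph_from_data_frame
network_to_igraph <- function(net) {
  hosts <- net$hosts
  virals <- net$virals
  nodes <- data.frame(
    name = c(hosts$mag_id, virals$viral_id),
    type = c(rep("host", nrow(hosts)), rep("virus", nrow(virals))),
    site = c(hosts$site, virals$site),
    year = c(hosts$year, virals$year),
    taxonomy = c(if (!is.null(hosts$lineage)) hosts$lineage else rep("", nrow(hosts)),
                 rep("", nrow(virals))),
    stringsAsFactors = FALSE)
  edges <- data.frame(from = net$edges$host_id, to = net$edges$viral_id,
                      weight = net$edges$weight, stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

#' Read a network edge TSV written by [write_network()]
#'
#' @param path Path to a `.edges.tsv` file.
#' @return A `data.frame` with columns `host_id`, `viral_id`, `n_matches`,
#'   `host_site`, `viral_site`.
#' @export
read_network_edges <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
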