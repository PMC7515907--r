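#' Write an interactome to disk
#'
#' Three text formats are supported. `tsv` writes `gene_a  gene_b  provenance
#' source` with a `# seeds:` header comment so that seeds (including isolated
#' ones) survive a round trip. `sif` writes the Cytoscape simple-interaction
#' format `geneA  known|novel  geneB`, again with a `# seeds:` header. `graphml`
#' writes GraphML with node attribute `role` and edge attributes `provenance`
#' and `source`; seeds are recovered from the role attribute on read.
#'
#' A write/read round trip in any format preserves seeds, edges and
#' provenance exactly.
#'
#' @param net an `interactome`.
#' @param path output file path.
#' @param format one of `"tsv"`, `"sif"`, `"graphml"`; defaults to the file
#'   extension.
#' @return `path`, invisibly.
#' @export
write_interactome <- function(net, path,
                              format = c("tsv", "sif", "graphml")) {
  stopifnot(inherits(net, "interactome"))
  if (missing(format)) {
    format <- tolower(tools::file_ext(path))
  }
  format <- match.arg(format)
  e <- net$edges
  if (format == "graphml") {
    g <- interactome_graph(net)
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# name: ", net$name), con)
  writeLines(paste0("# seeds: ", paste(net$seeds, collapse = ",")), con)
  if (format == "tsv") {
    writeLines("gene_a\tgene_b\tprovenance\tsource", con)
    if (nrow(e) > 0L) {
      writeLines(paste(e$a, e$b, e$provenance, e$source, sep = "\t"), con)
    }
  } else {
    if (nrow(e) > 0L) {
      writeLines(paste(e$a, e$provenance, e$b, sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Read an interactome written by [write_interactome()]
#'
#' @param path input file.
#' @param format one of `"tsv"`, `"sif"`, `"graphml"`; defaults to the file
#'   extension.
#' @param name network label; defaults to the stored name (tsv/sif header or
#'   GraphML graph attribute) or the file name.
#' @return an `interactome`.
#' @export
read_interactome <- function(path, format = c("tsv", "sif", "graphml"),
                             name = NULL) {
  if (missing(format)) {
    format <- tolower(tools::file_ext(path))
  }
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    role <- igraph::vertex_attr(g, "role")
    vnames <- igraph::vertex_attr(g, "name")
    if (is.null(role)) {
      stop("GraphML file lacks the 'role' node attribute: ", path)
    }
    ed <- igraph::as_data_frame(g, what = "edges")
    if (is.null(ed$source)) ed$source <- ""
    if (is.null(ed$provenance)) {
      stop("GraphML file lacks the 'provenance' edge attribute: ", path)
    }
    seeds <- vnames[role == "seed"]
    gname <- igraph::graph_attr(g, "name")
    known <- ed[ed$provenance == "known", , drop = FALSE]
    novel <- ed[ed$provenance == "novel", , drop = FALSE]
    return(assemble_interactome(
      seeds,
      known = ppi_edges(known$from, known$to, source = known$source),
      novel = ppi_edges(novel$from, novel$to, source = novel$source),
      name = if (!is.null(name)) name else
        if (!is.null(gname)) gname else basename(path)
    ))
  }

  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, invert = TRUE, value = TRUE)
  body_ln <- grep("^#", lines, invert = TRUE)
  seeds_line <- grep("^# seeds:", hdr, value = TRUE)
  if (length(seeds_line) == 0L) {
    stop("missing '# seeds:' header in ", path)
  }
  seeds <- strsplit(sub("^# seeds:\\s*", "", seeds_line[1L]), ",")[[1L]]
  seeds <- trimws(seeds[nzchar(trimws(seeds))])
  name_line <- grep("^# name:", hdr, value = TRUE)
  if (is.null(name)) {
    name <- if (length(name_line) > 0L) {
      sub("^# name:\\s*", "", name_line[1L])
    } else {
      basename(path)
    }
  }

  if (format == "tsv") {
    if (length(body) == 0L || body[1L] != "gene_a\tgene_b\tprovenance\tsource") {
      stop("bad or missing TSV header in ", path)
    }
    data_idx <- seq_along(body)[-1L]
  } else {
    data_idx <- seq_along(body)
  }
  fields <- strsplit(body[data_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  want <- if (format == "tsv") 4L else 3L
  bad <- which(nf != want)
  if (length(bad) > 0L) {
    stop("malformed line ", body_ln[data_idx[bad[1L]]], " in ", path, ": ",
         body[data_idx[bad[1L]]])
  }
  m <- do.call(rbind, fields)
  if (is.null(m)) {
    m <- matrix(character(), ncol = want)
  }
  if (format == "tsv") {
    ed <- data.frame(a = m[, 1L], b = m[, 2L], provenance = m[, 3L],
                     source = m[, 4L], stringsAsFactors = FALSE)
  } else {
    ed <- data.frame(a = m[, 1L], b = m[, 3L], provenance = m[, 2L],
                     source = "", stringsAsFactors = FALSE)
  }
  badp <- !ed$provenance %in% c("known", "novel")
  if (any(badp)) {
    stop("malformed line ", body_ln[data_idx[which(badp)[1L]]], " in ", path,
         ": provenance must be 'known' or 'novel'")
  }
  known <- ed[ed$provenance == "known", , drop = FALSE]
  novel <- ed[ed$provenance == "novel", , drop = FALSE]
  assemble_interactome(
    seeds,
    known = ppi_edges(known$a, known$b, source = known$source),
    novel = ppi_edges(novel$a, novel$b, source = novel$source),
    name = name
  )
}

#' Read a seed gene list
#'
#' One symbol per line; blank lines and `#` comments are ignored.
#'
#' @param path input file.
#' @return normalized character vector.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(character())
  }
  unique(normalize_symbols(lines))
}
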