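#' Read a per-seed summary table (known/novel PPI counts plus partner lists)
#'
#' Reads a tab-separated table with columns `seed`, `k_known`, `n_novel`,
#' `novel_partners` (comma-separated symbols, or `None` for an empty list).
#' This is the format of the packaged cilia table; see [cilia_table1()].
#'
#' The partner-list length is authoritative: when a row's stated `n_novel`
#' disagrees with the number of listed partners, a warning reports the row and
#' `n_novel` is replaced by the list length. Partner tokens that look like
#' plain numbers (a known failure mode of spreadsheet-mangled gene symbols)
#' are flagged in a warning but retained verbatim.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `seed`, `k_known`, `n_novel` and a
#'   list-column `novel_partners` (one row per seed). An empty file yields a
#'   zero-row table with a warning.
#' @export
read_seed_summary_table <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           stringsAsFactors = FALSE)
  required <- c("seed", "k_known", "n_novel", "novel_partners")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("seed summary table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    warning("seed summary table ", path, " has no data rows")
    out <- data.frame(seed = character(), k_known = integer(),
                      n_novel = integer(), stringsAsFactors = FALSE)
    out$novel_partners <- list()
    return(out)
  }
  seeds <- normalize_symbols(raw$seed)
  dup <- duplicated(seeds)
  if (any(dup)) {
    stop("duplicate seed row(s): ",
         paste(unique(seeds[dup]), collapse = ", "))
  }
  partners <- lapply(raw$novel_partners, function(p) {
    p <- trimws(p)
    if (!nzchar(p) || identical(toupper(p), "NONE")) {
      return(character())
    }
    toks <- trimws(strsplit(p, ",", fixed = TRUE)[[1L]])
    toks <- toks[nzchar(toks)]
    sort(unique(normalize_symbols(toks)))
  })
  numericish <- unique(unlist(lapply(partners, function(p) {
    p[looks_numeric_symbol(p)]
  })))
  if (length(numericish) > 0L) {
    warning("partner symbol(s) look numeric (possible spreadsheet ",
            "corruption), retained verbatim: ",
            paste(numericish, collapse = ", "))
  }
  n_stated <- as.integer(raw$n_novel)
  n_actual <- lengths(partners)
  mism <- which(!is.na(n_stated) & n_stated != n_actual)
  if (length(mism) > 0L) {
    warning("stated n_novel disagrees with partner-list length for: ",
            paste(sprintf("%s (%d vs %d)", seeds[mism], n_stated[mism],
                          n_actual[mism]), collapse = ", "),
            "; using the list length")
  }
  out <- data.frame(seed = seeds,
                    k_known = as.integer(raw$k_known),
                    n_novel = as.integer(n_actual),
                    stringsAsFactors = FALSE)
  out$novel_partners <- partners
  out
}

#' The packaged cilia interaction table
#'
#' Loads the transcription of the published table of 165 cilia genes with
#' their known-PPI counts, novel-PPI counts and novel interactor lists that
#' ships with the package (`inst/extdata/cilia_table1.tsv`). The transcription
#' follows the printed table verbatim, including one spreadsheet-corrupted
#' partner symbol (`"42435"` under ROPN1L).
#'
#' @param quiet suppress the transcription warnings (numeric-looking
#'   symbols)? Default `TRUE`.
#' @return see [read_seed_summary_table()].
#' @examples
#' t1 <- cilia_table1()
#' nrow(t1)                      # 165 cilia genes
#' sum(t1$n_novel)               # total predicted novel PPIs
#' @export
cilia_table1 <- function(quiet = TRUE) {
  path <- system.file("extdata", "cilia_table1.tsv", package = "ciliome",
                      mustWork = TRUE)
  if (quiet) {
    suppressWarnings(read_seed_summary_table(path))
  } else {
    read_seed_summary_table(path)
  }
}

#' Novel edges implied by a per-seed summary table
#'
#' Expands the partner lists of a seed summary table into a seed-partner edge
#' table, suitable as the `novel` input of [assemble_interactome()].
#'
#' @param summary a table from [read_seed_summary_table()].
#' @param source source tag for the edges.
#' @return edge data.frame as from [ppi_edges()].
#' @export
seed_summary_edges <- function(summary, source = "predicted") {
  n <- lengths(summary$novel_partners)
  ppi_edges(rep(summary$seed, n), unlist(summary$novel_partners),
            source = source)
}
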