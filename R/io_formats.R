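#' @importFrom data.table data.table as.data.table fread fwrite setnames setkey
#'   foverlaps setcolorder copy := .N .SD rbindlist
#' @importFrom stats lm AIC ks.test quantile rbeta runif setNames
#' @importFrom utils head
NULL

# quiet R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  "pvalue", "pos", "chrom", "snp_id", "gene_id", "start", "end", "protein_id",
  "best_snp_p", "n_snps", "gene_size_kb", "snps_per_kb", "corrected_p",
  "neg_log10_p", "win_start", "win_end", "i.snp_id", "i.pos", "i.pvalue",
  "best_snp_id", "score", "in_replication_lcc", "n_unrelated_lccs", "."
))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_io <- function(fmt, ..., path = NULL) {
  msg <- sprintf(fmt, ...)
  if (!is.null(path)) msg <- sprintf("%s [file: %s]", msg, path)
  stop(msg, call. = FALSE)
}

#' Strip an optional "chr" prefix from chromosome names
#'
#' Chromosome labels are normalized so that "chr1", "Chr1" and "1" compare
#' equal across association tables and gene annotation.
#'
#' @param x character vector of chromosome labels.
#' @return character vector without the "chr" prefix.
#' @export
normalize_chrom <- function(x) sub("^[Cc][Hh][Rr]", "", as.character(x))

#' Read a PLINK-style SNP association table
#'
#' Reads a whitespace/tab-delimited association results file (one row per
#' SNP) into a validated SNP table. Rows with missing or non-numeric
#' p-values are dropped and counted; p-values outside (0, 1] or positions
#' < 1 are invalid and also dropped with a count. Column names are
#' configurable to accommodate PLINK (`SNP`/`CHR`/`BP`/`P`) and variants.
#'
#' @param path path to the TSV file.
#' @param columns named character vector mapping the roles `snp`, `chrom`,
#'   `pos`, `p` to column names in the file.
#' @return a `data.table` with columns `snp_id`, `chrom`, `pos`, `pvalue`,
#'   carrying a `load_report` attribute (named integer vector with counts of
#'   rows read, kept, and dropped by reason).
#' @export
read_association_table <- function(path,
                                   columns = c(snp = "SNP", chrom = "CHR",
                                               pos = "BP", p = "P")) {
  if (!file.exists(path)) stop_io("association file not found", path = path)
  required <- c("snp", "chrom", "pos", "p")
  missing_roles <- setdiff(required, names(columns))
  if (length(missing_roles))
    stop_io("column_config missing roles: %s", paste(missing_roles, collapse = ", "))
  if (file.size(path) == 0) stop_io("association file is empty", path = path)
  dt <- fread(path, header = TRUE)
  if (nrow(dt) == 0L) stop_io("association file is empty", path = path)
  # resolve each role to the configured name, falling back to the
  # package's canonical column names (as written by write_tsv)
  canonical <- c(snp = "snp_id", chrom = "chrom", pos = "pos", p = "pvalue")
  resolved <- vapply(required, function(role) {
    cand <- c(columns[[role]], canonical[[role]])
    hit <- cand[cand %in% names(dt)]
    if (!length(hit)) NA_character_ else hit[1L]
  }, character(1))
  if (anyNA(resolved))
    stop_io("association file lacks required column(s): %s",
            paste(columns[required][is.na(resolved)], collapse = ", "),
            path = path)
  out <- dt[, .(snp_id = as.character(get(resolved[["snp"]])),
                chrom  = normalize_chrom(get(resolved[["chrom"]])),
                pos    = suppressWarnings(as.integer(get(resolved[["pos"]]))),
                pvalue = suppressWarnings(as.numeric(get(resolved[["p"]]))))]
  n_read <- nrow(out)
  bad_p  <- is.na(out$pvalue)
  out    <- out[!bad_p]
  inv_p  <- out$pvalue <= 0 | out$pvalue > 1
  inv_pos <- is.na(out$pos) | out$pos < 1L
  invalid <- inv_p | inv_pos
  out    <- out[!invalid]
  if (anyDuplicated(out$snp_id))
    stop_io("duplicate snp_id values in association table", path = path)
  attr(out, "load_report") <- c(n_read = n_read, n_kept = nrow(out),
                                n_dropped_missing_p = sum(bad_p),
                                n_dropped_invalid = sum(invalid))
  out[]
}

#' Read gene annotation (1-based TSV or BED)
#'
#' The pipeline uses 1-based inclusive coordinates throughout (the GWAS
#' convention). BED input (0-based, half-open) is converted at this
#' boundary: `start <- start + 1`. Strand is ignored; the SNP assignment
#' window is symmetric.
#'
#' @param path path to the annotation file. TSV dialect expects a header
#'   with columns `gene_id`, `chrom`, `start`, `end`; BED dialect expects
#'   headerless `chrom`, `start`, `end`, `name`.
#' @param format `"tsv"` (1-based inclusive, default) or `"bed"`.
#' @return a `data.table` with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
read_gene_annotation <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_io("gene annotation file not found", path = path)
  if (format == "bed") {
    dt <- fread(path, header = FALSE)
    if (ncol(dt) < 4L) stop_io("BED annotation needs >= 4 columns", path = path)
    dt <- dt[, 1:4]
    setnames(dt, c("chrom", "start", "end", "gene_id"))
    dt[, start := as.integer(start) + 1L]   # 0-based half-open -> 1-based inclusive
    dt[, end := as.integer(end)]
  } else {
    dt <- fread(path, header = TRUE)
    need <- c("gene_id", "chrom", "start", "end")
    absent <- setdiff(need, names(dt))
    if (length(absent))
      stop_io("annotation lacks column(s): %s", paste(absent, collapse = ", "),
              path = path)
    dt <- dt[, .(gene_id, chrom, start = as.integer(start), end = as.integer(end))]
  }
  dt[, gene_id := as.character(gene_id)]
  dt[, chrom := normalize_chrom(chrom)]
  setcolorder(dt, c("gene_id", "chrom", "start", "end"))
  if (any(dt$start > dt$end)) stop_io("gene annotation has start > end", path = path)
  if (any(dt$start < 1L)) stop_io("gene annotation has start < 1", path = path)
  if (anyDuplicated(dt$gene_id)) stop_io("duplicate gene_id in annotation", path = path)
  dt[]
}

#' Read a protein-protein interaction edge list
#'
#' Reads a two-column TSV of interacting protein identifiers into an
#' undirected simple [igraph][igraph::graph] object. Self-loops are removed
#' and duplicate edges (including reversed duplicates) collapsed, because
#' the coherence metrics are defined on distinct interacting partners; the
#' counts of removed records are attached as a `load_report` attribute.
#' Nodes only ever seen in self-loops are retained as isolated nodes.
#'
#' @param path path to the edge list (2 columns, with or without header;
#'   a header is assumed when the first line repeats no identifier pattern
#'   seen below — pass `header` explicitly to override).
#' @param header logical; does the file carry a header line? Default FALSE.
#' @return an undirected simple `igraph` graph with a `load_report`
#'   attribute (`n_rows`, `n_self_loops_removed`, `n_duplicates_removed`).
#' @export
read_edge_list <- function(path, header = FALSE) {
  if (!file.exists(path)) stop_io("edge list not found", path = path)
  if (file.size(path) == 0) {
    warning(sprintf("edge list '%s' is empty; returning empty graph", path))
    g <- igraph::make_empty_graph(0, directed = FALSE)
    attr(g, "load_report") <- c(n_rows = 0L, n_self_loops_removed = 0L,
                                n_duplicates_removed = 0L)
    return(g)
  }
  dt <- tryCatch(
    fread(path, header = header, colClasses = "character", fill = FALSE),
    error = function(e) stop_io("malformed edge list (%s)", conditionMessage(e),
                                path = path))
  if (nrow(dt) == 0L) {
    warning(sprintf("edge list '%s' is empty; returning empty graph", path))
    g <- igraph::make_empty_graph(0, directed = FALSE)
    attr(g, "load_report") <- c(n_rows = 0L, n_self_loops_removed = 0L,
                                n_duplicates_removed = 0L)
    return(g)
  }
  if (ncol(dt) != 2L)
    stop_io("edge list must have exactly 2 columns, found %d", ncol(dt), path = path)
  bad <- which(is.na(dt[[1]]) | is.na(dt[[2]]) | dt[[1]] == "" | dt[[2]] == "")
  if (length(bad))
    stop_io("malformed edge list line %d (empty endpoint)", bad[1] + as.integer(header),
            path = path)
  ppi_from_edges(dt[[1]], dt[[2]])
}

#' Build a PPI graph from endpoint vectors
#'
#' Internal constructor shared by file readers and the synthetic generator:
#' enforces the simple undirected graph invariants (no self-loops, no
#' parallel or reversed-duplicate edges).
#'
#' @param from,to character vectors of endpoints (equal length).
#' @param nodes optional character vector of all node names, to retain
#'   isolated nodes that appear in no edge.
#' @return undirected simple `igraph` with a `load_report` attribute.
#' @export
ppi_from_edges <- function(from, to, nodes = NULL) {
  stopifnot(length(from) == length(to))
  n_rows <- length(from)
  self <- from == to
  a <- pmin(from[!self], to[!self])
  b <- pmax(from[!self], to[!self])
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  all_nodes <- unique(c(nodes, from, to))
  g <- igraph::graph_from_data_frame(
    data.frame(from = a[!dup], to = b[!dup], stringsAsFactors = FALSE),
    directed = FALSE, vertices = sort(all_nodes))
  attr(g, "load_report") <- c(n_rows = n_rows,
                              n_self_loops_removed = sum(self),
                              n_duplicates_removed = sum(dup))
  g
}

#' Read a gene-to-protein identifier map
#'
#' @param path 2-column TSV (`gene_id`, `protein_id`), header optional via
#'   `header`. Duplicate pairs are collapsed; one gene may map to several
#'   proteins and vice versa.
#' @param header logical, or `"auto"` (default) to treat a first line of
#'   `gene_id<TAB>protein_id` as a header.
#' @return `data.table` with columns `gene_id`, `protein_id`.
#' @export
read_gene_map <- function(path, header = "auto") {
  if (!file.exists(path)) stop_io("gene-protein map not found", path = path)
  if (identical(header, "auto")) {
    first <- readLines(path, n = 1L, warn = FALSE)
    header <- length(first) == 1L &&
      identical(tolower(strsplit(first, "\t", fixed = TRUE)[[1]]),
                c("gene_id", "protein_id"))
  }
  dt <- fread(path, header = header, colClasses = "character")
  if (ncol(dt) != 2L) stop_io("gene-protein map must have 2 columns", path = path)
  setnames(dt, c("gene_id", "protein_id"))
  if (any(dt$gene_id == "" | dt$protein_id == ""))
    stop_io("gene-protein map contains empty identifiers", path = path)
  unique(dt)
}

#' Read a candidate gene list
#'
#' One gene identifier per line; blank lines and lines starting with `#`
#' are ignored; duplicates are removed (the number removed is attached as
#' attribute `n_duplicates`).
#'
#' @param path path to the list file.
#' @return character vector of unique gene ids.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop_io("gene list not found", path = path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  out <- unique(lines)
  attr(out, "n_duplicates") <- length(lines) - length(out)
  out
}

#' Write a table or gene list as TSV
#'
#' Tables are written with a header; character vectors are written one id
#' per line (readable back with [read_gene_list()]). Reading a written file
#' reproduces the value.
#'
#' @param x data.frame/data.table or character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  if (is.character(x)) {
    writeLines(x, path)
  } else {
    fwrite(as.data.table(x), path, sep = "\t")
  }
  invisible(path)
}
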