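## seqio: sequence / annotation I/O and the scaffold -> ordered-gene model.
##
## Proteins travel as a `protein_set`: a data.frame with columns id, desc,
## seq (upper-case residues over the 20 standard letters plus X; a trailing
## "*" stop is stripped on load). Gene calls travel as a `gene_calls`
## data.frame with 1-based inclusive coordinates and a 0-based per-scaffold
## ordinal assigned by ascending start.

#' Construct a protein set
#'
#' @param seqs named character vector of residue strings (names are ids), or
#'   an unnamed character vector plus `ids`.
#' @param ids,desc optional ids and descriptions.
#' @return a `protein_set` data.frame with columns `id`, `desc`, `seq`.
#' @export
protein_set <- function(seqs, ids = names(seqs), desc = NULL) {
  ids <- as.character(ids)
  if (length(ids) != length(seqs) || anyNA(ids) || any(ids == ""))
    stop("every protein needs a non-empty id")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate protein id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(seqs))
  seqs <- sub("\\*$", "", seqs)
  if (any(!nzchar(seqs))) stop("empty residue string for: ",
                               paste(ids[!nzchar(seqs)], collapse = ", "))
  bad <- regexpr("[^ACDEFGHIKLMNPQRSTVWYX]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("illegal residue '%s' in record '%s' at position %d",
                 substr(seqs[i], bad[i], bad[i]), ids[i], bad[i]))
  }
  desc <- if (is.null(desc)) rep("", length(ids)) else as.character(desc)
  out <- data.frame(id = ids, desc = desc,
                    seq = unname(seqs), stringsAsFactors = FALSE)
  class(out) <- c("protein_set", "data.frame")
  out
}

#' @export
print.protein_set <- function(x, ...) {
  cat(sprintf("protein_set with %d sequences (lengths %d-%d)\n",
              nrow(x), if (nrow(x)) min(nchar(x$seq)) else 0L,
              if (nrow(x)) max(nchar(x$seq)) else 0L))
  if (nrow(x)) print(utils::head(data.frame(id = x$id, length = nchar(x$seq)), 6))
  invisible(x)
}

#' Read protein FASTA
#'
#' Reads a protein FASTA file into a [protein_set()]. Residues are
#' upper-cased; a trailing stop symbol is stripped; duplicate ids and
#' letters outside the 20-residue + X alphabet are hard errors.
#'
#' @param path FASTA file.
#' @return a `protein_set`.
#' @export
read_proteins <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  full <- names(ss)
  ids <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  protein_set(as.character(ss), ids = ids, desc = desc)
}

#' Read nucleotide FASTA
#'
#' @param path FASTA file.
#' @return named character vector of upper-case nucleotide sequences.
#' @export
read_nucleotides <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  stats::setNames(toupper(as.character(ss)), ids)
}

#' Write sequences as FASTA
#'
#' @param seqs a `protein_set` or named character vector.
#' @param path output file.
#' @param width line width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "protein_set")) seqs <- stats::setNames(seqs$seq, seqs$id)
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

assign_ordinals <- function(genes) {
  ord <- order(genes$scaffold_id, genes$start, genes$end, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  genes$ordinal <- stats::ave(genes$start, genes$scaffold_id,
                              FUN = function(x) seq_along(x) - 1L)
  genes$ordinal <- as.integer(genes$ordinal)
  rownames(genes) <- NULL
  genes
}

new_gene_calls <- function(df) {
  need <- c("gene_id", "scaffold_id", "start", "end", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene table missing column(s): ", paste(miss, collapse = ", "))
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (any(df$start > df$end))
    stop("start > end for gene(s): ",
         paste(df$gene_id[df$start > df$end], collapse = ", "))
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup)) stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  df <- assign_ordinals(df[need])
  class(df) <- c("gene_calls", "data.frame")
  df
}

#' Read gene calls
#'
#' Reads gene coordinates from GFF3 (CDS features), a gene-table TSV
#' (columns gene_id, scaffold_id, start, end, strand), or Prodigal-style
#' protein-FASTA headers (`id # start # end # strand # ...`). Coordinates
#' are 1-based inclusive; 0-based ordinals are assigned per scaffold by
#' ascending start, so ordinals depend only on coordinates, not file order.
#'
#' When `proteins` is supplied, calls without a matching protein record are
#' skipped with a warning; the count is available as `attr(x, "load_report")`.
#'
#' @param path input file (ignored for dialect `"prodigal"` when `proteins`
#'   carries coordinates in its descriptions).
#' @param dialect one of `"auto"`, `"gff3"`, `"table"`, `"prodigal"`.
#' @param proteins optional [protein_set()] to cross-check ids against.
#' @return a `gene_calls` data.frame (gene_id, scaffold_id, start, end,
#'   strand, ordinal).
#' @export
read_gene_calls <- function(path = NULL, dialect = c("auto", "gff3", "table", "prodigal"),
                            proteins = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    if (is.null(path)) dialect <- "prodigal"
    else if (grepl("\\.gff3?$", path, ignore.case = TRUE)) dialect <- "gff3"
    else dialect <- "table"
  }
  df <- switch(dialect,
    gff3 = read_gff3_cds(path),
    table = {
      tab <- utils::read.delim(path, stringsAsFactors = FALSE)
      tab
    },
    prodigal = {
      if (is.null(proteins)) stop("prodigal dialect needs a protein_set")
      parse_prodigal_headers(proteins)
    })
  skipped <- 0L
  if (!is.null(proteins) && dialect != "prodigal") {
    keep <- df$gene_id %in% proteins$id
    skipped <- sum(!keep)
    if (skipped)
      warning(skipped, " gene call(s) without a matching protein record were skipped")
    df <- df[keep, , drop = FALSE]
  }
  out <- new_gene_calls(df)
  attr(out, "load_report") <- list(n_loaded = nrow(out), n_skipped = skipped)
  out
}

read_gff3_cds <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- as.data.frame(rtracklayer::import(path))
    gr <- gr[as.character(gr$type) == "CDS", , drop = FALSE]
    id <- as.character(gr$ID)
    if (all(is.na(id)) && !is.null(gr$Name)) id <- as.character(gr$Name)
    data.frame(gene_id = id,
               scaffold_id = as.character(gr$seqnames),
               start = gr$start, end = gr$end,
               strand = as.character(gr$strand),
               stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    f <- strsplit(lines, "\t", fixed = TRUE)
    f <- f[vapply(f, length, 1L) >= 9]
    f <- f[vapply(f, function(x) x[3] == "CDS", TRUE)]
    id <- vapply(f, function(x) sub("^.*ID=([^;]+).*$", "\\1", x[9]), "")
    data.frame(gene_id = id,
               scaffold_id = vapply(f, `[`, "", 1),
               start = as.integer(vapply(f, `[`, "", 4)),
               end = as.integer(vapply(f, `[`, "", 5)),
               strand = vapply(f, `[`, "", 7),
               stringsAsFactors = FALSE)
  }
}

parse_prodigal_headers <- function(proteins) {
  parts <- strsplit(proteins$desc, "\\s*#\\s*")
  ok <- vapply(parts, length, 1L) >= 4
  if (!all(ok))
    stop("record(s) without Prodigal-style '# start # end # strand' header: ",
         paste(proteins$id[!ok], collapse = ", "))
  scaf <- sub("_[0-9]+$", "", proteins$id)
  data.frame(gene_id = proteins$id, scaffold_id = scaf,
             start = as.integer(vapply(parts, function(p) p[2], "")),
             end = as.integer(vapply(parts, function(p) p[3], "")),
             strand = ifelse(vapply(parts, function(p) p[4], "") %in% c("-1", "-"), "-", "+"),
             stringsAsFactors = FALSE)
}

#' Write a typed TSV table
#'
#' Writes `rows` as a TSV with a header line, validating against a schema.
#' The schema is a named list mapping column name to `"character"`,
#' `"integer"`, `"logical"`, `"numeric"`, or `"numeric:<d>"` where `<d>`
#' gives the fixed number of decimals to render.
#'
#' @param rows data.frame.
#' @param path output path.
#' @param schema named list; must cover exactly the columns of `rows`.
#' @export
write_table <- function(rows, path, schema) {
  if (!setequal(names(schema), names(rows)))
    stop("schema/columns mismatch: ",
         paste(union(setdiff(names(schema), names(rows)),
                     setdiff(names(rows), names(schema))), collapse = ", "))
  rows <- rows[names(schema)]
  out <- rows
  for (col in names(schema)) {
    spec <- schema[[col]]
    type <- sub(":.*$", "", spec)
    v <- rows[[col]]
    ok <- switch(type,
      character = is.character(v), integer = is.numeric(v) && all(is.na(v) | v == floor(v)),
      numeric = is.numeric(v), logical = is.logical(v),
      stop("unknown schema type '", spec, "'"))
    if (!ok) stop("column '", col, "' does not conform to schema type '", spec, "'")
    if (grepl(":", spec)) {
      d <- as.integer(sub("^.*:", "", spec))
      out[[col]] <- ifelse(is.na(v), NA, formatC(v, format = "f", digits = d))
    } else if (type == "integer") {
      out[[col]] <- as.integer(v)
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a typed TSV table written by [write_table()]
#'
#' @param path file path.
#' @param schema same schema used to write.
#' @return data.frame with columns coerced to schema types.
#' @export
read_table <- function(path, schema) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = "NA")
  if (!setequal(names(df), names(schema)))
    stop("file columns do not match schema")
  df <- df[names(schema)]
  for (col in names(schema)) {
    type <- sub(":.*$", "", schema[[col]])
    df[[col]] <- switch(type,
      character = df[[col]], integer = as.integer(df[[col]]),
      numeric = as.numeric(df[[col]]), logical = as.logical(df[[col]]))
  }
  df
}
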