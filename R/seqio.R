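# On-disk formats: protein FASTA (Biostrings), BED6, GFF3 gene features,
# schema-checked TSV tables, Newick trees (ape).  All coordinates are
# normalised to BED convention: 0-based, half-open.

#' Write simulator output to disk
#'
#' One protein FASTA and one BED6 file per genome plus a single
#' ground-truth event table.  BED columns are chrom, start, end, name,
#' score (0), strand with 0-based half-open coordinates.
#'
#' @param genomes Named list of `AnnotatedGenome` objects.
#' @param log `EventLog` from [evolve()] (or `NULL` to skip).
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the character vector of files written.
#' @export
write_dataset <- function(genomes, log, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  files <- character()
  for (g in genomes) {
    fa <- file.path(outdir, paste0(g$genome_id, ".faa"))
    bed <- file.path(outdir, paste0(g$genome_id, ".bed"))
    write_fasta(setNames(g$genes$protein, g$genes$gene_id), fa)
    bed_df <- data.frame(chrom = g$genes$chrom, start = g$genes$start,
                         end = g$genes$end, name = g$genes$gene_id,
                         score = 0L, strand = g$genes$strand,
                         stringsAsFactors = FALSE)
    utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    files <- c(files, fa, bed)
  }
  if (!is.null(log)) {
    tf <- file.path(outdir, "truth_events.tsv")
    write_table(log$events, "events", tf)
    files <- c(files, tf)
  }
  invisible(files)
}

#' Write / read protein FASTA
#'
#' Thin wrappers over \pkg{Biostrings}.
#' @param seqs Named character vector of protein sequences.
#' @param path File path.
#' @return `read_fasta` returns a named character vector.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 70)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

read_bed6 <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand"))
  df
}

# GFF3 gene features -> BED-convention intervals.  Uses type == "gene"
# rows, falling back to mRNA; keyed by the ID attribute, then Name.
read_gff3_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(parts, length, 0L) >= 9
  parts <- parts[ok]
  type <- vapply(parts, `[`, "", 3)
  use <- type == "gene"
  if (!any(use)) use <- type == "mRNA"
  parts <- parts[use]
  if (!length(parts)) stop("no gene or mRNA features in ", path)
  attr_get <- function(s, key) {
    m <- regmatches(s, regexec(paste0("(?:^|;)", key, "=([^;]+)"), s))[[1]]
    if (length(m) == 2) m[2] else NA_character_
  }
  a9 <- vapply(parts, `[`, "", 9)
  ids <- vapply(a9, attr_get, "", key = "ID", USE.NAMES = FALSE)
  nms <- vapply(a9, attr_get, "", key = "Name", USE.NAMES = FALSE)
  name <- ifelse(is.na(ids), nms, ids)
  if (anyNA(name)) stop("GFF3 gene feature without ID or Name attribute")
  data.frame(chrom = vapply(parts, `[`, "", 1),
             # GFF3 is 1-based inclusive; convert to 0-based half-open
             start = as.integer(vapply(parts, `[`, "", 4)) - 1L,
             end = as.integer(vapply(parts, `[`, "", 5)),
             name = name, score = 0L,
             strand = vapply(parts, `[`, "", 7),
             stringsAsFactors = FALSE)
}

#' Load and reconcile one genome from FASTA + annotation
#'
#' Genes present in only one of the two files are dropped with a warning;
#' gene ordinals are recomputed as the rank of the start coordinate per
#' chromosome.
#'
#' @param fasta_path Protein FASTA.
#' @param annot_path BED6 or GFF3 (detected by extension `.gff`/`.gff3`,
#'   else BED).
#' @param genome_id Genome identifier.
#' @return An `AnnotatedGenome`; the number of dropped records is attached
#'   as attribute `"n_dropped"`.
#' @export
load_genome <- function(fasta_path, annot_path, genome_id) {
  prot <- read_fasta(fasta_path)
  if (anyDuplicated(names(prot)))
    stop("duplicated gene ids in ", fasta_path)
  ann <- if (grepl("\\.gff3?$", annot_path, ignore.case = TRUE))
    read_gff3_genes(annot_path) else read_bed6(annot_path)
  if (anyDuplicated(ann$name)) stop("duplicated gene ids in ", annot_path)
  shared <- intersect(names(prot), ann$name)
  n_drop <- (length(prot) - length(shared)) + (nrow(ann) - length(shared))
  if (!length(shared))
    stop("zero reconciled genes between ", fasta_path, " and ", annot_path)
  if (n_drop > 0)
    warning(sprintf("%d unmatched record(s) dropped while loading %s",
                    n_drop, genome_id))
  ann <- ann[ann$name %in% shared, , drop = FALSE]
  ann <- ann[radix_order(ann$chrom, ann$start), , drop = FALSE]
  ann$ordinal <- stats::ave(ann$start, ann$chrom,
                            FUN = function(x) seq_along(x) - 1L)
  genes <- data.frame(gene_id = ann$name, protein = unname(prot[ann$name]),
                      strand = ann$strand, chrom = ann$chrom,
                      ordinal = as.integer(ann$ordinal),
                      start = ann$start, end = ann$end,
                      stringsAsFactors = FALSE)
  if (any(genes$start >= genes$end)) stop("interval with start >= end")
  g <- list(genome_id = genome_id, genes = genes)
  class(g) <- "AnnotatedGenome"
  attr(g, "n_dropped") <- n_drop
  g
}

# ---------------------------------------------------------------- tables ----

table_schemas <- list(
  hits = c(query = "character", subject = "character",
           pct_identity = "numeric", aln_len = "integer",
           mismatch = "integer", gapopen = "integer", qstart = "integer",
           qend = "integer", sstart = "integer", send = "integer",
           evalue = "numeric", score = "numeric"),
  edges = c(from = "character", to = "character", blocks = "character"),
  communities = c(community_id = "character", gene = "character"),
  events = c(kind = "character", branch = "character",
             parent_ids = "character", child_ids = "character",
             breakpoints = "character", chrom = "character",
             position = "integer"),
  domains = c(gene_id = "character", domain = "character",
              start = "integer", end = "integer", score = "numeric",
              evalue = "numeric"),
  blocks = c(block_id = "character", genome_a = "character",
             chrom_a = "character", genome_b = "character",
             chrom_b = "character", orientation = "character",
             n_anchors = "integer", block_score = "numeric",
             anchors = "character"),
  calls = c(uid = "character", type = "character", evidence = "character"),
  profiles = c(genome_id = "character", community = "character",
               n_genes = "integer", n_ipms_like = "integer",
               n_mam_like = "integer"))

#' Schema-checked TSV round trip
#'
#' `write_table` writes a header + tab-separated rows; `read_table` reads
#' them back with the schema's column types.  Floating point columns are
#' written with full precision (`%.17g`) so values survive the round trip
#' exactly.
#'
#' @param rows data.frame matching the schema.
#' @param schema One of `names(syntegraph:::table_schemas)`.
#' @param path File path.
#' @return `read_table` returns the data.frame (0 rows for header-only).
#' @export
write_table <- function(rows, schema, path) {
  sch <- table_schemas[[schema]]
  if (is.null(sch)) stop("unknown schema: ", schema)
  missing <- setdiff(names(sch), names(rows))
  if (length(missing))
    stop("schema violation: missing column '", missing[1], "'")
  rows <- rows[, names(sch), drop = FALSE]
  fmt <- rows
  for (col in names(sch)) {
    if (sch[[col]] == "numeric") fmt[[col]] <- sprintf("%.17g", rows[[col]])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(sch), collapse = "\t"), con)
  if (nrow(fmt))
    utils::write.table(fmt, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path, schema) {
  sch <- table_schemas[[schema]]
  if (is.null(sch)) stop("unknown schema: ", schema)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = unname(sch),
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", na.strings = "NA")
  bad <- setdiff(names(sch), names(df))
  if (length(bad)) stop("schema violation: missing column '", bad[1], "'")
  df
}

# ---------------------------------------------------------------- newick ----

#' Newick tree IO
#'
#' Backed by \pkg{ape}; supports branch lengths and internal support
#' labels.  `read_newick` raises a parse error on unbalanced parentheses,
#' reporting the offending position.
#'
#' @param tree An [ape::read.tree()] `phylo` object.
#' @param path File path.
#' @return `read_newick` returns a `phylo` object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path), collapse = "")
  depth <- 0L
  chars <- strsplit(txt, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0)
      stop("unbalanced parentheses at position ", i, " of ", path)
  }
  if (depth != 0)
    stop("unbalanced parentheses at position ", length(chars), " of ", path)
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("could not parse newick in ", path)
  tr
}
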