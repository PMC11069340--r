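#' Read a protein FASTA file or literal FASTA text
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] that enforces the
#' panel contract: IDs must be unique, sequences non-empty. Sequences are
#' uppercased and whitespace-stripped; IDs are the header up to the first
#' whitespace. Returns an insertion-ordered named character vector so
#' downstream code can treat it as a plain id -> sequence map.
#'
#' @param path_or_text path to a FASTA file, or a character scalar containing
#'   FASTA text (detected by a leading `>`).
#' @return named character vector of uppercase protein sequences
#' @export
#' @examples
#' read_fasta(">a\nMKV\n>b\nGG")
read_fasta <- function(path_or_text) {
  if (!is.character(path_or_text) || length(path_or_text) != 1L)
    stop_input("read_fasta() expects a single path or FASTA text")
  if (startsWith(trimws(path_or_text), ">")) {
    path <- tempfile(fileext = ".fasta")
    on.exit(unlink(path), add = TRUE)
    writeLines(path_or_text, path)
  } else {
    path <- path_or_text
    if (!file.exists(path)) stop_input("FASTA file not found: %s", path)
  }
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop_input("duplicate ID %s in FASTA input", dup[[1]])
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  empty <- ids[nchar(seqs) == 0L]
  if (length(empty))
    stop_input("empty sequence for ID %s", empty[[1]])
  names(seqs) <- ids
  seqs
}

#' Write an id -> sequence map as FASTA
#'
#' @param seqs named character vector of sequences
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop_input("write_fasta() requires named sequences")
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

GENE_TABLE_COLS <- c("strain_id", "locus_id", "replicon_id",
                     "start", "end", "strand", "product")

validate_gene_table <- function(genes) {
  missing <- setdiff(GENE_TABLE_COLS, names(genes))
  if (length(missing))
    stop_input("gene table lacks column(s): %s", paste(missing, collapse = ", "))
  if (any(genes$start < 1L))
    stop_input("gene table has start < 1 (coordinates are 1-based)")
  bad <- genes$end < genes$start
  if (any(bad))
    stop_input("gene table has end < start for locus %s", genes$locus_id[bad][[1]])
  badstrand <- !genes$strand %in% c("+", "-")
  if (any(badstrand))
    stop_input("unknown strand symbol '%s' for locus %s",
               genes$strand[badstrand][[1]], genes$locus_id[badstrand][[1]])
  key <- paste(genes$strain_id, genes$locus_id)
  if (anyDuplicated(key))
    stop_input("duplicated (strain_id, locus_id): %s", key[duplicated(key)][[1]])
  genes
}

sort_gene_table <- function(genes) {
  genes[order(genes$strain_id, genes$replicon_id, genes$start), , drop = FALSE]
}

#' Read a gene-coordinate table (TSV or GFF3)
#'
#' TSV input needs columns `strain_id, locus_id, replicon_id, start, end,
#' strand, product` (`#` comment lines allowed). GFF3 input is parsed with
#' [rtracklayer::import()]; CDS features are kept, `locus_tag` (or `ID`)
#' becomes `locus_id`, and `strain_id` must be supplied since GFF3 carries no
#' strain column. Coordinates are 1-based inclusive on both ends in either
#' format. Records are returned sorted by (strain, replicon, start).
#'
#' @param path input file; `.gff`/`.gff3` extensions (or a `##gff-version`
#'   first line) select the GFF3 parser
#' @param strain_id strain label, required for GFF3 input
#' @return data.frame of gene records (one row per gene, no protein sequence;
#'   attach sequences with [build_panel()])
#' @export
read_gene_table <- function(path, strain_id = NULL) {
  if (!file.exists(path)) stop_input("gene table not found: %s", path)
  first <- readLines(path, n = 1L)
  is_gff <- grepl("\\.gff3?$", path, ignore.case = TRUE) ||
    grepl("^##gff-version", first)
  if (is_gff) {
    if (is.null(strain_id))
      stop_input("strain_id is required when reading GFF3")
    gr <- as.data.frame(rtracklayer::import(path))
    gr <- gr[gr$type == "CDS", , drop = FALSE]
    if (nrow(gr) == 0L) stop_input("no CDS features in %s", path)
    locus <- if ("locus_tag" %in% names(gr)) gr$locus_tag else gr$ID
    genes <- data.frame(
      strain_id = strain_id,
      locus_id = as.character(locus),
      replicon_id = as.character(gr$seqnames),
      start = as.integer(gr$start),
      end = as.integer(gr$end),
      strand = as.character(gr$strand),
      product = if ("product" %in% names(gr)) as.character(gr$product) else "",
      stringsAsFactors = FALSE
    )
  } else {
    genes <- read_tsv_plain(path, colClasses = c(
      strain_id = "character", locus_id = "character",
      replicon_id = "character", strand = "character",
      product = "character"))
    genes$start <- as.integer(genes$start)
    genes$end <- as.integer(genes$end)
    genes$locus_id <- as.character(genes$locus_id)
    genes$strain_id <- as.character(genes$strain_id)
  }
  genes <- validate_gene_table(genes)
  sort_gene_table(genes)
}

#' Read a strain phenotype table
#'
#' @param path TSV with columns `strain_id, degrader, isolation_source`
#' @return data.frame with logical `degrader`
#' @export
read_phenotypes <- function(path) {
  ph <- read_tsv_plain(path, colClasses = c(strain_id = "character",
                                            isolation_source = "character"))
  need <- c("strain_id", "degrader", "isolation_source")
  missing <- setdiff(need, names(ph))
  if (length(missing))
    stop_input("phenotype table lacks column(s): %s", paste(missing, collapse = ", "))
  ph$degrader <- as.logical(ph$degrader)
  if (anyNA(ph$degrader))
    stop_input("phenotype 'degrader' must be TRUE/FALSE for every strain")
  ph
}

#' Assemble a strain panel from genes, proteins and phenotypes
#'
#' The panel is the substrate of the comparative screen: per-strain gene
#' records with protein sequences, plus the degrader/non-degrader phenotype
#' labels that stratify the conservation matrix. Protein FASTA IDs must be
#' `strain|locus` (as written by [write_bundle()]) or plain locus IDs unique
#' across the panel.
#'
#' @param genes gene table (see [read_gene_table()]) covering all strains
#' @param proteins named character vector of protein sequences
#' @param phenotypes phenotype data.frame (see [read_phenotypes()])
#' @param reference_strain_id strain whose genes anchor the screen
#' @return an object of class `strain_panel`
#' @export
build_panel <- function(genes, proteins, phenotypes, reference_strain_id) {
  genes <- sort_gene_table(validate_gene_table(genes))
  key <- paste(genes$strain_id, genes$locus_id, sep = "|")
  idx <- match(key, names(proteins))
  idx[is.na(idx)] <- match(genes$locus_id, names(proteins))[is.na(idx)]
  if (anyNA(idx))
    stop_input("no protein sequence for %s", key[is.na(idx)][[1]])
  genes$protein_seq <- unname(proteins[idx])
  if (any(nchar(genes$protein_seq) == 0L))
    stop_input("empty protein sequence in panel")
  if (!reference_strain_id %in% genes$strain_id)
    stop_input("reference strain %s has no genes", reference_strain_id)
  orphan <- setdiff(phenotypes$strain_id, genes$strain_id)
  if (length(orphan))
    stop_input("phenotyped strain %s has no genes", orphan[[1]])
  # gene rank = position in coordinate order within the strain's replicon;
  # hotspot detection works on ranks, not bp
  genes$rank <- stats::ave(genes$start,
                           genes$strain_id, genes$replicon_id,
                           FUN = seq_along)
  structure(
    list(reference_strain_id = reference_strain_id,
         genes = genes,
         phenotypes = phenotypes),
    class = "strain_panel"
  )
}

#' @export
print.strain_panel <- function(x, ...) {
  ph <- x$phenotypes
  cat(sprintf(
    "strain_panel: %d strains (%d degraders / %d non-degraders), %d genes; reference: %s\n",
    length(unique(x$genes$strain_id)),
    sum(ph$degrader), sum(!ph$degrader),
    nrow(x$genes), x$reference_strain_id))
  invisible(x)
}

reference_genes <- function(panel) {
  panel$genes[panel$genes$strain_id == panel$reference_strain_id, , drop = FALSE]
}

strain_proteins <- function(panel, strain_id) {
  g <- panel$genes[panel$genes$strain_id == strain_id, , drop = FALSE]
  stats::setNames(g$protein_seq, g$locus_id)
}

#' Read a count matrix with its two-condition design
#'
#' @param path counts TSV: first column `gene_id`, remaining columns one per
#'   sample, non-negative integer counts
#' @param design_path design TSV with columns `sample_id, condition,
#'   replicate`; condition must be `treated` or `control`
#' @return object of class `count_matrix`: integer matrix plus design
#' @export
read_counts <- function(path, design_path) {
  tab <- read_tsv_plain(path, colClasses = c(gene_id = "character"))
  if (names(tab)[[1]] != "gene_id")
    stop_input("counts TSV must have 'gene_id' as its first column")
  design <- read_tsv_plain(design_path)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- as.character(tab$gene_id)
  count_matrix(counts, design)
}

#' Construct a validated count matrix
#'
#' @param counts gene x sample matrix of non-negative integers
#' @param design data.frame with `sample_id`, `condition` (`treated` /
#'   `control`) and `replicate`
#' @return object of class `count_matrix`
#' @export
count_matrix <- function(counts, design) {
  need <- c("sample_id", "condition", "replicate")
  missing <- setdiff(need, names(design))
  if (length(missing))
    stop_input("design lacks column(s): %s", paste(missing, collapse = ", "))
  undesigned <- setdiff(colnames(counts), design$sample_id)
  if (length(undesigned))
    stop_input("sample %s missing from design", undesigned[[1]])
  design <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
  bad <- setdiff(unique(design$condition), c("treated", "control"))
  if (length(bad))
    stop_input("unknown condition '%s' (expected treated/control)", bad[[1]])
  if (any(is.na(counts)) || any(counts < 0))
    stop_input("counts must be non-negative")
  if (any(counts != round(counts)))
    stop_input("counts must be integers")
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, design = design), class = "count_matrix")
}

#' Read long-format growth-curve plate reads
#'
#' @param path TSV with columns `strain_id, dose_uM, replicate, time_h, od600`
#' @return validated data.frame
#' @export
read_growth <- function(path) {
  g <- read_tsv_plain(path, colClasses = c(strain_id = "character"))
  need <- c("strain_id", "dose_uM", "replicate", "time_h", "od600")
  missing <- setdiff(need, names(g))
  if (length(missing))
    stop_input("growth table lacks column(s): %s", paste(missing, collapse = ", "))
  if (any(g$dose_uM < 0)) stop_input("negative dose in growth table")
  if (any(g$od600 < 0)) stop_input("negative OD600 in growth table")
  g
}

#' Read an observed MS peak list
#'
#' @param path TSV with columns `rt_min, mz, intensity`
#' @return validated data.frame
#' @export
read_peaks <- function(path) {
  p <- read_tsv_plain(path)
  need <- c("rt_min", "mz", "intensity")
  missing <- setdiff(need, names(p))
  if (length(missing))
    stop_input("peak list lacks column(s): %s", paste(missing, collapse = ", "))
  if (any(p$mz <= 0)) stop_input("peak m/z must be positive")
  if (any(p$rt_min < 0)) stop_input("peak retention time must be >= 0")
  if (any(p$intensity < 0)) stop_input("peak intensity must be >= 0")
  p
}
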