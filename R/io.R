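# File-format plumbing. FASTA through Biostrings, GFF3 through rtracklayer
# (1-based inclusive on disk), tab-separated tables through data.table.

#' Read chromosome sequences from FASTA
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta_seqs <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write chromosome sequences to FASTA
#' @param sequences Named character vector.
#' @param path Output file.
#' @export
write_fasta_seqs <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Write gene models to GFF3
#' @param genes `data.frame` with `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive), `strand`.
#' @param path Output file.
#' @export
write_gff_genes <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  S4Vectors::mcols(gr)$source <- "allopoly"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#' @param path GFF3 file.
#' @return `data.frame` with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gff_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  data.frame(gene_id = S4Vectors::mcols(gr)$ID,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

.write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t")
  invisible(path)
}

.read_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}

#' Read an FPKM matrix from TSV (first column gene id)
#' @param path TSV file.
#' @return Numeric matrix, genes x tissues.
#' @export
read_fpkm_tsv <- function(path) {
  d <- .read_tsv(path)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d[[1L]]
  m
}

#' Write an FPKM matrix to TSV
#' @param mat Numeric matrix with gene row names.
#' @param path Output file.
#' @export
write_fpkm_tsv <- function(mat, path) {
  .write_tsv(data.frame(gene_id = rownames(mat), mat, check.names = FALSE),
             path)
}

#' Write a full synthetic dataset to a directory
#'
#' Emits FASTA sequences, GFF3 gene models, the homoeolog table, depth and
#' identity tables, per-subgenome TE tables, FPKM matrices, the stress
#' table, one cytosine report per replicate, and the homoeologous CG site
#' map - all as plain text in the formats the package readers consume.
#'
#' @param dataset Dataset from [simulate_dataset()].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_fasta_seqs(dataset$sequences, p("sequences.fa"))
  write_gff_genes(dataset$genes, p("genes.gff3"))
  .write_tsv(dataset$pairs, p("pairs.tsv"))
  .write_tsv(dataset$depth, p("depth.tsv"))
  .write_tsv(dataset$identity, p("identity.tsv"))
  .write_tsv(dataset$te$A, p("te_A.tsv"))
  .write_tsv(dataset$te$B, p("te_B.tsv"))
  write_fpkm_tsv(dataset$expression$fpkm_a, p("fpkm_A.tsv"))
  write_fpkm_tsv(dataset$expression$fpkm_b, p("fpkm_B.tsv"))
  write_fpkm_tsv(dataset$expression$fpkm_diploid, p("fpkm_diploid.tsv"))
  s <- dataset$expression$stress
  .write_tsv(data.frame(pair_id = dataset$pairs$pair_id,
                        treatment_a = s$treatment_a,
                        treatment_b = s$treatment_b,
                        control_a = s$control_a, control_b = s$control_b),
             p("stress.tsv"))
  for (i in seq_along(dataset$methylation$replicates)) {
    .write_tsv(dataset$methylation$replicates[[i]],
               p(sprintf("cytosine_rep%d.tsv", i)))
  }
  .write_tsv(dataset$methylation$site_map, p("site_map.tsv"))
  invisible(dir)
}

#' Write the truth record as JSON
#' @param truth Truth object from [simulate_dataset()].
#' @param path Output file.
#' @export
write_truth <- function(truth, path) {
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a depth-window table
#' @param path TSV with `chrom`, `start`, `end`, `depth`.
#' @return `data.frame`.
#' @export
read_depth_tsv <- function(path) .read_tsv(path)

#' Read a homoeolog pair table
#' @param path TSV with at least `gene_a`, `gene_b`, `chrom_a`, `chrom_b`.
#' @return `data.frame`.
#' @export
read_pairs_tsv <- function(path) .read_tsv(path)

#' Read a TE table
#' @param path TSV with `chrom`, `start`, `end`, `family`, `class`,
#'   `perc_div`.
#' @return `data.frame`.
#' @export
read_te_tsv <- function(path) .read_tsv(path)

#' Read a Bismark-style cytosine report
#' @param path TSV with `chrom`, `pos`, `strand`, `context`,
#'   `count_methylated`, `count_unmethylated`.
#' @return `data.frame`.
#' @export
read_cytosine_tsv <- function(path) .read_tsv(path)
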