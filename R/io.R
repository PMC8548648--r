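#' Write a genome package to disk
#'
#' Writes `genome.fa`, `cds.fa`, `proteins.fa` (FASTA), `genes.gff3` (GFF3,
#' 1-based inclusive), `counts.tsv`, `samples.tsv` and the truth tables as
#' TSV. Output is byte-deterministic for a fixed simulation seed.
#'
#' @param pkg A `genome_package` from [simulate_family_genome()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genome_package <- function(pkg, dir) {
  stopifnot(inherits(pkg, "genome_package"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta <- function(x, file) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(x), file.path(dir, file))
  }
  write_fasta(pkg$chromosomes, "genome.fa")
  write_fasta(pkg$cds, "cds.fa")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(pkg$proteins),
                              file.path(dir, "proteins.fa"))
  gm <- pkg$gene_models %>% arrange(.data$chromosome, .data$start)
  gff <- c("##gff-version 3",
           sprintf("%s\tmybkit\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                   gm$chromosome, gm$start, gm$end, gm$strand, gm$gene_id))
  writeLines(gff, file.path(dir, "genes.gff3"))
  write_tsv0 <- function(df, file) {
    utils::write.table(df, file.path(dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  counts_df <- data.frame(gene_id = rownames(pkg$expression$counts),
                          pkg$expression$counts, check.names = FALSE)
  write_tsv0(counts_df, "counts.tsv")
  write_tsv0(as.data.frame(pkg$expression$samples), "samples.tsv")
  tr <- pkg$truth
  if (nrow(tr$planted_repeats) > 0) {
    write_tsv0(as.data.frame(tr$planted_repeats), "truth_repeats.tsv")
  }
  if (nrow(tr$duplicate_truth) > 0) {
    write_tsv0(as.data.frame(tr$duplicate_truth), "truth_duplicates.tsv")
  }
  if (nrow(tr$ssr_truth) > 0) {
    write_tsv0(as.data.frame(tr$ssr_truth), "truth_ssrs.tsv")
  }
  write_tsv0(as.data.frame(tr$de_truth), "truth_de.tsv")
  invisible(dir)
}
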