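#' Read an allc-style per-cytosine methylation table
#'
#' The on-disk format is a headerless TSV with columns chrom, pos
#' (1-based), strand, trinucleotide, mc, cov. Positions are converted to
#' the internal 0-based convention and the context class is derived from
#' the trinucleotide. Malformed rows fail with their line number.
#'
#' @param path file path.
#' @return data.table: chrom, pos (0-based), strand, tri, context, mc,
#'   cov. An empty file yields an empty table.
#' @export
read_allc <- function(path) {
  empty <- data.table(chrom = character(), pos = integer(),
                      strand = character(), tri = character(),
                      context = character(), mc = integer(),
                      cov = integer())
  if (file.size(path) == 0) return(empty)
  raw <- fread(path, header = FALSE, sep = "\t", fill = TRUE,
               colClasses = "character")
  if (ncol(raw) != 6L)
    stop("allc file must have 6 tab-separated columns, found ", ncol(raw))
  setnames(raw, c("chrom", "pos", "strand", "tri", "mc", "cov"))
  num_ok <- function(x) grepl("^[0-9]+$", x)
  bad <- which(!num_ok(raw$pos) | !num_ok(raw$mc) | !num_ok(raw$cov) |
                 !raw$strand %in% c("+", "-"))
  if (length(bad))
    stop("malformed allc row at line ", bad[1], " of ", path)
  out <- raw[, .(chrom, pos = as.integer(pos) - 1L, strand, tri,
                 mc = as.integer(mc), cov = as.integer(cov))]
  bad <- which(out$mc > out$cov | out$pos < 0L)
  if (length(bad))
    stop("invalid counts (mc > cov or pos < 1) at line ", bad[1],
         " of ", path)
  out[, context := context_class(substr(tri, 2, 2), substr(tri, 3, 3))]
  setcolorder(out, c("chrom", "pos", "strand", "tri", "context", "mc",
                     "cov"))
  out[]
}

#' Write an allc-style per-cytosine methylation table
#'
#' @param methylome data.table with chrom, pos (0-based), strand, tri,
#'   mc, cov.
#' @param path output path (headerless TSV, 1-based positions).
#' @return `path`, invisibly.
#' @export
write_allc <- function(methylome, path) {
  out <- methylome[, .(chrom, pos = pos + 1L, strand, tri, mc, cov)]
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write a genome model to FASTA
#' @param genome a `genome_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome$sequences, path, width = 80L)
  invisible(path)
}

#' Write genome annotations to GFF3
#'
#' Features are typed `gene`, `dispersed_repeat` (REs) and `pseudogene`;
#' coordinates are 1-based inclusive per the GFF3 convention.
#'
#' @param genome a `genome_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_gff3 <- function(genome, path) {
  type_map <- c(gene = "gene", RE = "dispersed_repeat",
                pseudogene = "pseudogene")
  f <- genome$features
  lines <- c("##gff-version 3",
             paste0("##sequence-region ", names(genome$chrom_lengths), " 1 ",
                    genome$chrom_lengths))
  if (nrow(f)) {
    rows <- sprintf("%s\tmethylscape\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                    f$chrom, type_map[f$type], f$start + 1L, f$end,
                    f$strand, f$feature_id)
    lines <- c(lines, rows)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a genome model from FASTA and GFF3
#'
#' GFF3 `type` values gene, dispersed_repeat / transposable_element
#' (mapped to RE) and pseudogene are recognized; other types are skipped
#' with a warning. Coordinates convert to internal 0-based half-open. A
#' feature extending beyond its sequence is an error.
#'
#' @param fasta_path genome FASTA.
#' @param gff3_path annotation GFF3.
#' @param control name of the unmethylated control contig.
#' @return a `genome_model`.
#' @export
read_genome <- function(fasta_path, gff3_path, control = "chloroplast") {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  lens <- stats::setNames(Biostrings::width(seqs), names(seqs))
  lines <- readLines(gff3_path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  feats <- if (length(lines)) {
    parts <- tstrsplit(lines, "\t", fixed = TRUE)
    if (length(parts) < 9L) stop("GFF3 rows must have 9 columns")
    type_map <- c(gene = "gene", dispersed_repeat = "RE",
                  transposable_element = "RE", pseudogene = "pseudogene")
    ty <- type_map[parts[[3]]]
    if (anyNA(ty)) {
      warning("skipping ", sum(is.na(ty)), " feature(s) of unknown type: ",
              paste(unique(parts[[3]][is.na(ty)]), collapse = ", "))
    }
    keep <- !is.na(ty)
    ids <- sub("^.*ID=([^;]+).*$", "\\1", parts[[9]][keep])
    dt <- data.table(chrom = parts[[1]][keep],
                     start = as.integer(parts[[4]][keep]) - 1L,
                     end = as.integer(parts[[5]][keep]),
                     strand = parts[[7]][keep],
                     type = unname(ty[keep]),
                     feature_id = ids)
    bad <- is.na(match(dt$chrom, names(lens))) | dt$end > lens[dt$chrom] |
      dt$start < 0L
    if (any(bad))
      stop("feature beyond sequence bounds: ",
           paste(dt$feature_id[bad], collapse = ", "))
    dt
  } else {
    data.table(chrom = character(), start = integer(), end = integer(),
               strand = character(), type = character(),
               feature_id = character())
  }
  gm <- list(sequences = seqs, features = feats, chrom_lengths = lens,
             control = control)
  class(gm) <- "genome_model"
  gm
}

#' Write DMRs as BED6+
#'
#' BED is 0-based half-open. Columns: chrom, start, end, name, score
#' (mean level difference x 1000, rounded), strand ("."), then context,
#' direction, n_dms, level_a, level_b.
#'
#' @param dmrs DMR table from [merge_dms()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  hdr <- "# DMR BED6+: 0-based half-open; score = mean level diff x 1000"
  rows <- if (nrow(dmrs)) {
    sprintf("%s\t%d\t%d\t%s\t%d\t.\t%s\t%s\t%d\t%.6g\t%.6g",
            dmrs$chrom, dmrs$start, dmrs$end,
            paste0("DMR_", seq_len(nrow(dmrs))),
            as.integer(round(dmrs$diff_level * 1000)),
            dmrs$context, dmrs$direction, dmrs$n_dms,
            dmrs$level_a, dmrs$level_b)
  } else character(0)
  writeLines(c(hdr, rows), path)
  invisible(path)
}
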