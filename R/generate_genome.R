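#' Generate a synthetic genome with typed annotations
#'
#' Draws random nucleotide sequences for each configured autosome plus
#' one chloroplast contig (the unmethylated conversion control), and
#' places non-overlapping genes, repetitive elements (REs) and
#' pseudogenes on each autosome. Placement uses stick-breaking of the
#' unoccupied space into random inter-feature gaps, so a feasible layout
#' is found deterministically; an infeasible request (features do not
#' fit) fails with an error naming the crowded chromosome.
#'
#' All coordinates are internal 0-based half-open; exported GFF3 is
#' 1-based inclusive (see [write_genome_gff3()]).
#'
#' @param scenario a [scenario_config()].
#' @return A `genome_model`: list with `sequences` (a
#'   [Biostrings::DNAStringSet]), `features` (data.table: chrom, start,
#'   end, strand, type, feature_id), `chrom_lengths` (including the
#'   chloroplast) and `control` (name of the control contig). Deterministic
#'   given the scenario master seed.
#' @export
generate_genome <- function(scenario) {
  validate_scenario(scenario)
  set.seed(derive_seed(scenario$seed, "genome"))
  chroms <- names(scenario$chrom_lengths)
  seqs <- character(length(chroms) + 1L)
  names(seqs) <- c(chroms, scenario$chloroplast)
  feats <- vector("list", length(chroms))

  for (i in seq_along(chroms)) {
    L <- scenario$chrom_lengths[[i]]
    seqs[i] <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                     collapse = "")
    feats[[i]] <- place_features(chroms[i], L, scenario)
  }
  seqs[length(seqs)] <- paste(
    sample(c("A", "C", "G", "T"), scenario$chloroplast_length, replace = TRUE),
    collapse = "")

  features <- data.table::rbindlist(feats)
  if (nrow(features)) {
    data.table::setorder(features, chrom, start)
    features[, feature_id := paste0(
      type, "_", chrom, "_", seq_len(.N)), by = .(type, chrom)]
  } else {
    features <- data.table::data.table(
      chrom = character(), start = integer(), end = integer(),
      strand = character(), type = character(), feature_id = character())
  }

  gm <- list(
    sequences = Biostrings::DNAStringSet(seqs),
    features = features,
    chrom_lengths = c(scenario$chrom_lengths,
                      stats::setNames(scenario$chloroplast_length,
                                      scenario$chloroplast)),
    control = scenario$chloroplast
  )
  class(gm) <- "genome_model"
  gm
}

# Draw feature lengths, then distribute the unoccupied space as random
# gaps (exponential stick-breaking), yielding a non-overlapping layout.
place_features <- function(chrom, L, scenario) {
  plan <- list(
    gene = list(n = scenario$n_genes, len = scenario$gene_length),
    RE = list(n = scenario$n_res, len = scenario$re_length),
    pseudogene = list(n = scenario$n_pseudo, len = scenario$pseudo_length)
  )
  types <- rep(names(plan), vapply(plan, `[[`, integer(1), "n"))
  if (!length(types)) {
    return(data.table::data.table(
      chrom = character(), start = integer(), end = integer(),
      strand = character(), type = character()))
  }
  lens <- unlist(lapply(plan, function(s) {
    if (s$n == 0L) return(integer(0))
    sample(seq(s$len[1], s$len[2]), s$n, replace = TRUE)
  }), use.names = FALSE)
  ord <- sample(seq_along(types))
  types <- types[ord]; lens <- lens[ord]
  n <- length(lens)
  free <- L - sum(lens) - n - 1L  # keep >= 1 bp between features
  if (free < 0L)
    stop("cannot place ", n, " features totalling ", sum(lens),
         " bp on ", chrom, " (", L, " bp): chromosome too crowded")
  w <- stats::rexp(n + 1L)
  gaps <- floor(w / sum(w) * free) + 1L
  starts <- cumsum(gaps)[seq_len(n)] + c(0L, cumsum(lens))[seq_len(n)]
  data.table::data.table(
    chrom = chrom,
    start = as.integer(starts),
    end = as.integer(starts + lens),
    strand = sample(c("+", "-"), n, replace = TRUE),
    type = types
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat("<genome_model>\n")
  cat("  contigs:", length(x$sequences), "(",
      sum(x$chrom_lengths), "bp ), control:", x$control, "\n")
  if (nrow(x$features)) {
    tab <- table(x$features$type)
    cat("  features:", paste(names(tab), tab, collapse = ", "), "\n")
  } else cat("  features: none\n")
  invisible(x)
}

#' Expand the scenario's planted differential intervals
#'
#' Combines explicitly listed planted DMR intervals with the clustered
#' intervals implied by the shared-peak fixture (per fixture window,
#' `peak_dmrs_per_window` CHG intervals of `peak_dmr_length` bp separated
#' by >250 bp so each merges into its own DMR downstream).
#'
#' @param scenario a [scenario_config()].
#' @return data.table with columns chrom, start, end, shift, context
#'   (0-based half-open), possibly empty.
#' @export
planted_intervals <- function(scenario) {
  out <- list()
  if (!is.null(scenario$planted_dmrs))
    out$explicit <- data.table::as.data.table(scenario$planted_dmrs)
  if (!is.null(scenario$peak_fixture)) {
    pf <- scenario$peak_fixture
    len <- scenario$peak_dmr_length
    k <- scenario$peak_dmrs_per_window
    spacing <- len + 300L  # > 250 bp merge gap: clusters stay separate DMRs
    rows <- lapply(seq_len(nrow(pf)), function(i) {
      w0 <- pf$window[i] * 50000L
      starts <- w0 + 1000L + (seq_len(k) - 1L) * spacing
      data.table::data.table(
        chrom = pf$chrom[i], start = starts, end = starts + len,
        shift = scenario$peak_dmr_shift, context = "CHG")
    })
    out$fixture <- data.table::rbindlist(rows)
  }
  if (!length(out)) {
    return(data.table::data.table(
      chrom = character(), start = integer(), end = integer(),
      shift = numeric(), context = character()))
  }
  data.table::rbindlist(out)
}
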