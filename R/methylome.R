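#' Classify the methylation context of a cytosine
#'
#' Plant methylomes distinguish CGN, CHG and CHH contexts (H = A, C or
#' T). Classification reads the trinucleotide 5'->3' on the cytosine's
#' own strand: if the next base is G the site is CGN; otherwise if the
#' base after that is G it is CHG; otherwise CHH.
#'
#' @param sequence a character string or [Biostrings::DNAString] (the
#'   plus-strand sequence of one contig).
#' @param position 1-based position of the cytosine on the plus strand
#'   (for minus-strand sites, the position of the plus-strand G).
#' @param strand "+" or "-".
#' @return list with `trinucleotide` (padded with N when truncated at a
#'   contig end), `context` (`NA` when the truncation makes the class
#'   ambiguous) and `truncated`.
#' @export
classify_context <- function(sequence, position, strand = "+") {
  s <- as.character(sequence)
  n <- nchar(s)
  stopifnot(position >= 1, position <= n, strand %in% c("+", "-"))
  base_at <- function(i) if (i >= 1 && i <= n) substr(s, i, i) else "N"
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  if (strand == "+") {
    if (base_at(position) != "C")
      stop("base at position ", position, " on + strand is not C")
    b1 <- base_at(position + 1L); b2 <- base_at(position + 2L)
    truncated <- position > n - 2L
  } else {
    if (base_at(position) != "G")
      stop("base at position ", position, " on - strand is not C")
    b1 <- comp[[base_at(position - 1L)]]
    b2 <- comp[[base_at(position - 2L)]]
    truncated <- position < 3L
  }
  context <- if (b1 == "G") "CGN"
  else if (b2 == "G") "CHG"
  else if (b1 == "N" || b2 == "N") NA_character_
  else "CHH"
  list(trinucleotide = paste0("C", b1, b2), context = context,
       truncated = truncated)
}

#' Enumerate all cytosine sites of a genome
#'
#' Scans both strands of every contig and returns one record per
#' cytosine: plus-strand C positions and minus-strand C positions (G on
#' the plus strand), each with its strand-oriented trinucleotide and
#' context class. Sites within 2 bp of a contig end carry a truncated
#' trinucleotide (N-padded) and are excluded from subcontext summaries;
#' their context is `NA` when undeterminable.
#'
#' @param genome a `genome_model` or [Biostrings::DNAStringSet].
#' @return data.table: chrom, pos (0-based), strand, tri, context,
#'   truncated; sorted by chrom, pos.
#' @export
find_cytosines <- function(genome) {
  seqs <- if (inherits(genome, "genome_model")) genome$sequences else genome
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    ch <- strsplit(as.character(seqs[[i]]), "")[[1]]
    n <- length(ch)
    pad <- c(ch, "N", "N")
    # plus strand: cytosines read left to right
    p <- which(ch == "C")
    dt_p <- if (length(p)) {
      b1 <- pad[p + 1L]; b2 <- pad[p + 2L]
      data.table(chrom = names(seqs)[i], pos = p - 1L, strand = "+",
                 tri = paste0("C", b1, b2),
                 context = context_class(b1, b2),
                 truncated = p > n - 2L)
    }
    # minus strand: plus-strand Gs, read right to left, complemented
    g <- which(ch == "G")
    dt_m <- if (length(g)) {
      padm <- c("N", "N", ch)
      b1 <- comp[padm[g + 1L]]; b2 <- comp[padm[g]]
      data.table(chrom = names(seqs)[i], pos = g - 1L, strand = "-",
                 tri = paste0("C", b1, b2),
                 context = context_class(b1, b2),
                 truncated = g < 3L)
    }
    out[[i]] <- rbindlist(list(dt_p, dt_m))
  }
  sites <- rbindlist(out)
  setorder(sites, chrom, pos, strand)
  sites[]
}

context_class <- function(b1, b2) {
  data.table::fifelse(
    b1 == "G", "CGN",
    data.table::fifelse(b2 == "G", "CHG",
      data.table::fifelse(b1 == "N" | b2 == "N", NA_character_, "CHH")))
}

#' Estimate the bisulfite non-conversion rate from the control contig
#'
#' The chloroplast genome is unmethylated, so any methylated calls on it
#' measure the non-conversion (false-methylation) rate epsilon:
#' pooled methylated reads / pooled total reads over all control sites
#' and contexts.
#'
#' @param methylome data.table of per-cytosine counts with columns
#'   `chrom`, `mc`, `cov` (any extra columns ignored; may span samples).
#' @param control name of the control contig.
#' @return epsilon in `[0, 1]`.
#' @export
estimate_nonconversion <- function(methylome, control = "chloroplast") {
  ctl <- methylome[chrom == control]
  if (nrow(ctl) == 0L)
    stop("control contig '", control, "' absent from the methylome table")
  cv <- sum(as.numeric(ctl$cov))
  if (cv == 0)
    stop("control contig '", control, "' present but has zero pooled coverage")
  sum(as.numeric(ctl$mc)) / cv
}

#' Per-site binomial methylation status calls
#'
#' Tests each covered site against the non-conversion background: the
#' one-sided binomial p-value P(X >= mc | cov, epsilon), adjusted with
#' Benjamini-Hochberg across covered sites, classifies each site as
#' methylated (adjusted p <= q), unmethylated, or uncovered (cov = 0).
#'
#' @param methylome data.table with `mc` and `cov` columns.
#' @param epsilon non-conversion rate in `[0, 1)`.
#' @param q BH level (default 0.01).
#' @return the input with added `p_value`, `padj` and `status` columns.
#' @export
call_sites <- function(methylome, epsilon, q = 0.01) {
  stopifnot(epsilon >= 0, epsilon < 1, q > 0, q < 1)
  out <- copy(methylome)
  out[, p_value := NA_real_]
  out[cov > 0, p_value := pbinom(mc - 1L, cov, epsilon, lower.tail = FALSE)]
  out[, padj := NA_real_]
  out[cov > 0, padj := p.adjust(p_value, method = "BH")]
  out[, status := fifelse(cov == 0L, "uncovered",
                          fifelse(padj <= q & mc > 0L, "methylated",
                                  "unmethylated"))]
  out[]
}

#' Weighted methylation level of a region set
#'
#' The weighted level pools reads: sum(mc) / sum(cov) over all sites of
#' the requested context inside the regions. This is the
#' methylated-reads-over-total-reads definition, not a mean of per-site
#' fractions. Zero pooled coverage (or an empty region) yields `NA`, the
#' undefined flag, never 0.
#'
#' @param methylome data.table with `chrom`, `pos`, `context`, `mc`, `cov`.
#' @param regions optional data.table (`chrom`, `start`, `end`, 0-based
#'   half-open); `NULL` means all sites.
#' @param context optional context class ("CGN", "CHG" or "CHH");
#'   `NULL` pools all contexts.
#' @return numeric scalar level in `[0,1]`, or `NA` when undefined.
#' @export
weighted_level <- function(methylome, regions = NULL, context = NULL) {
  tab <- methylome
  if (!is.null(context)) {
    ctx <- context
    tab <- tab[tab$context == ctx]
  }
  if (!is.null(regions)) {
    if (nrow(regions) == 0L) return(NA_real_)
    reg <- as.data.table(regions)[, .(chrom, start, end)]
    setkey(reg, chrom, start, end)
    pts <- tab[, .(chrom, start = pos, end = pos + 1L)]
    hit <- !is.na(foverlaps(pts, reg, type = "within", which = TRUE,
                            mult = "first"))
    tab <- tab[hit]
  }
  cv <- sum(as.numeric(tab$cov))
  if (cv == 0) return(NA_real_)
  sum(as.numeric(tab$mc)) / cv
}

#' Windowed methylation profile
#'
#' Tiles each chromosome into half-open windows `[i*w, (i+1)*w)` (the
#' last window truncated) and reports the pooled weighted level per
#' (chromosome, window, context). Windows with zero pooled coverage get
#' `NA` levels.
#'
#' @param methylome per-cytosine count table (may pool several samples).
#' @param chrom_lengths named vector of contig lengths, or a
#'   `genome_model`.
#' @param w window size in bp (default 50000).
#' @return data.table: chrom, window (0-based index), context, mc, cov,
#'   level.
#' @export
window_profile <- function(methylome, chrom_lengths, w = 50000L) {
  if (inherits(chrom_lengths, "genome_model"))
    chrom_lengths <- chrom_lengths$chrom_lengths
  if (w <= 0) stop("window size must be positive")
  grid <- rbindlist(lapply(names(chrom_lengths), function(cn) {
    data.table(chrom = cn,
               window = seq_len(ceiling(chrom_lengths[[cn]] / w)) - 1L)
  }))
  grid <- grid[CJ(chrom = unique(grid$chrom),
                  context = c("CGN", "CHG", "CHH")),
               on = "chrom", allow.cartesian = TRUE]
  obs <- methylome[!is.na(context),
                   .(mc = sum(as.numeric(mc)), cov = sum(as.numeric(cov))),
                   by = .(chrom, window = as.integer(pos %/% w), context)]
  out <- obs[grid, on = .(chrom, window, context)]
  out[is.na(mc), `:=`(mc = 0, cov = 0)]
  out[, level := fifelse(cov > 0, mc / cov, NA_real_)]
  setorder(out, chrom, window, context)
  out[]
}

#' Metagene methylation profile
#'
#' Averages methylation over scaled feature bodies plus fixed flanks:
#' feature bodies are divided into `body_bins` fractional bins and each
#' flank into `flank / flank_bin` fixed-width bins (defaults: 20 body
#' bins, 2-kb flanks in 100-bp pieces, 60 bins total). Minus-strand
#' features are orientation-flipped so bin 1 is always the far 5' flank.
#' Bin values pool reads across all features (weighted level).
#'
#' @param methylome per-cytosine count table.
#' @param features data.table with `chrom`, `start`, `end`, `strand`
#'   (0-based half-open).
#' @param body_bins number of body bins.
#' @param flank flank width in bp.
#' @param flank_bin flank bin width in bp (`flank` must be a multiple).
#' @return data.table: bin (1..total), zone ("upstream"/"body"/
#'   "downstream"), context, mc, cov, level.
#' @export
metaplot <- function(methylome, features, body_bins = 20L, flank = 2000L,
                     flank_bin = 100L) {
  if (nrow(features) == 0L) stop("empty feature set")
  if (flank %% flank_bin != 0) stop("flank must be a multiple of flank_bin")
  nf <- as.integer(flank / flank_bin)
  total <- 2L * nf + body_bins
  feat <- as.data.table(features)[, .(chrom, fstart = start, fend = end,
                                      fstrand = strand)]
  ext <- feat[, .(chrom, start = fstart - flank, end = fend + flank,
                  fstart, fend, fstrand)]
  setkey(ext, chrom, start, end)
  pts <- methylome[!is.na(context),
                   .(chrom, start = pos, end = pos + 1L, context, mc, cov)]
  ov <- foverlaps(pts, ext, type = "within", nomatch = NULL)
  if (nrow(ov) == 0L) stop("no cytosine falls within any feature or flank")
  ov[, bin := {
    p <- i.start  # site position (foverlaps prefixes the point columns)
    b <- integer(.N)
    up <- p < fstart
    dn <- p >= fend
    body <- !up & !dn
    b[up] <- 1L + as.integer((p[up] - (fstart[up] - flank)) %/% flank_bin)
    u <- (p[body] - fstart[body]) / (fend[body] - fstart[body])
    b[body] <- nf + 1L + pmin(as.integer(floor(u * body_bins)), body_bins - 1L)
    b[dn] <- nf + body_bins + 1L +
      as.integer((p[dn] - fend[dn]) %/% flank_bin)
    fifelse(fstrand == "-", total + 1L - b, b)
  }]
  prof <- ov[, .(mc = sum(as.numeric(mc)), cov = sum(as.numeric(cov))),
             by = .(bin, context)]
  grid <- CJ(bin = seq_len(total), context = c("CGN", "CHG", "CHH"))
  prof <- prof[grid, on = .(bin, context)]
  prof[is.na(mc), `:=`(mc = 0, cov = 0)]
  prof[, level := fifelse(cov > 0, mc / cov, NA_real_)]
  prof[, zone := fifelse(bin <= nf, "upstream",
                         fifelse(bin <= nf + body_bins, "body", "downstream"))]
  setorder(prof, context, bin)
  prof[]
}

#' Per-trinucleotide (subcontext) weighted levels
#'
#' Pools reads per trinucleotide: the 4 CGN, 3 CHG and 9 CHH
#' subcontexts. Sites with truncated (N-containing) trinucleotides are
#' excluded.
#'
#' @param methylome per-cytosine count table with `tri` and `context`.
#' @param by_chrom report per chromosome instead of genome-wide.
#' @return data.table: (chrom,) context, tri, mc, cov, level.
#' @export
subcontext_summary <- function(methylome, by_chrom = FALSE) {
  if (nrow(methylome) == 0L) stop("empty methylome table")
  tab <- methylome[!is.na(context) & !grepl("N", tri)]
  keys <- if (by_chrom) c("chrom", "context", "tri") else c("context", "tri")
  out <- tab[, .(mc = sum(as.numeric(mc)), cov = sum(as.numeric(cov))),
             by = keys]
  out[, level := fifelse(cov > 0, mc / cov, NA_real_)]
  setorderv(out, keys)
  out[]
}
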