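#' @useDynLib stopgainr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a transcript model
#'
#' A transcript model holds the exon/CDS structure of one transcript together
#' with precomputed strand-aware coordinate tables. All internal coordinates
#' are 0-based half-open; VCF-style 1-based positions are converted at the
#' input boundary, never inside.
#'
#' @param transcript_id,gene_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends Integer vectors of genomic exon bounds,
#'   0-based half-open, sorted by genomic start, pairwise non-overlapping.
#' @param cds_start,cds_end Genomic bounds of the coding region. Equal values
#'   mark a non-coding transcript.
#' @return An object of class `transcript_model`. Coding transcripts carry
#'   `cds_pos` (genomic position of each CDS base in 5'->3' coding order) and
#'   `exon_of_cds` (1-based exon index, transcription order, per CDS base).
#'   `cds_complete` is `TRUE` when the CDS length is a positive multiple of 3.
#' @export
new_transcript_model <- function(transcript_id, gene_id, chrom, strand,
                                 exon_starts, exon_ends, cds_start, cds_end) {
  stopifnot(strand %in% c("+", "-"),
            length(exon_starts) == length(exon_ends),
            all(exon_ends > exon_starts))
  o <- order(exon_starts)
  exon_starts <- as.integer(exon_starts[o])
  exon_ends <- as.integer(exon_ends[o])
  if (length(exon_starts) > 1L &&
      any(exon_starts[-1L] < exon_ends[-length(exon_ends)])) {
    stop("overlapping exons in transcript ", transcript_id)
  }
  coding <- cds_end > cds_start
  tx <- list(
    transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
    strand = strand, exon_starts = exon_starts, exon_ends = exon_ends,
    cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
    coding = coding, n_exons = length(exon_starts)
  )
  if (coding) {
    if (cds_start < exon_starts[1L] || cds_end > exon_ends[length(exon_ends)])
      stop("CDS outside exon span in transcript ", transcript_id)
    # coding sub-intervals per exon, genomic order
    cs <- pmax(exon_starts, cds_start)
    ce <- pmin(exon_ends, cds_end)
    keep <- ce > cs
    pos <- unlist(mapply(function(a, b) seq.int(a, b - 1L), cs[keep], ce[keep],
                         SIMPLIFY = FALSE), use.names = FALSE)
    exon_idx_genomic <- rep.int(which(keep), (ce - cs)[keep])
    if (strand == "-") {
      pos <- rev(pos)
      exon_idx_genomic <- rev(exon_idx_genomic)
      # exon index in transcription order counts from the 3'-most genomic exon
      exon_of_cds <- tx$n_exons + 1L - exon_idx_genomic
    } else {
      exon_of_cds <- exon_idx_genomic
    }
    tx$cds_pos <- as.integer(pos)
    tx$exon_of_cds <- as.integer(exon_of_cds)
    tx$cds_len <- length(pos)
    tx$cds_complete <- tx$cds_len > 0L && tx$cds_len %% 3L == 0L
  } else {
    tx$cds_len <- 0L
    tx$cds_complete <- FALSE
  }
  structure(tx, class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model %s (%s) %s:%s %d exon(s), CDS %d bp%s>\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand, x$n_exons,
              x$cds_len, if (x$coding && !x$cds_complete) ", incomplete" else ""))
  invisible(x)
}

chrom_class <- function(chrom) {
  c2 <- sub("^chr", "", chrom)
  ifelse(c2 == "X", "X", ifelse(c2 == "Y", "Y", "autosomal"))
}

read_genepred <- function(path) {
  gp <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = c(1:3, 9:10)))
  if (ncol(gp) < 10L) stop("not a genePred file (needs >= 10 columns): ", path)
  split_ints <- function(s) lapply(strsplit(s, ",", fixed = TRUE),
                                   function(x) as.integer(x[nzchar(x)]))
  list(
    transcript_id = gp[[1L]], chrom = gp[[2L]], strand = gp[[3L]],
    cds_start = as.integer(gp[[6L]]), cds_end = as.integer(gp[[7L]]),
    exon_starts = split_ints(gp[[9L]]), exon_ends = split_ints(gp[[10L]]),
    gene_id = if (ncol(gp) >= 12L) as.character(gp[[12L]]) else gp[[1L]]
  )
}

read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  txid <- as.character(md$transcript_id)
  gid <- if (!is.null(md$gene_id)) as.character(md$gene_id) else txid
  keep <- type %in% c("exon", "CDS") & !is.na(txid)
  gr <- gr[keep]; type <- type[keep]; txid <- txid[keep]; gid <- gid[keep]
  ids <- unique(txid)
  out <- list(transcript_id = ids, chrom = character(length(ids)),
              strand = character(length(ids)),
              cds_start = integer(length(ids)), cds_end = integer(length(ids)),
              exon_starts = vector("list", length(ids)),
              exon_ends = vector("list", length(ids)),
              gene_id = character(length(ids)))
  st <- GenomicRanges::start(gr) - 1L  # to 0-based half-open
  en <- GenomicRanges::end(gr)
  for (i in seq_along(ids)) {
    sel <- txid == ids[i]
    ex <- sel & type == "exon"
    cd <- sel & type == "CDS"
    if (!any(ex)) ex <- cd  # CDS-only GTFs
    o <- order(st[ex])
    out$chrom[i] <- as.character(GenomicRanges::seqnames(gr)[sel][1L])
    out$strand[i] <- as.character(GenomicRanges::strand(gr)[sel][1L])
    out$gene_id[i] <- gid[sel][1L]
    out$exon_starts[[i]] <- st[ex][o]
    out$exon_ends[[i]] <- en[ex][o]
    if (any(cd)) {
      out$cds_start[i] <- min(st[cd])
      out$cds_end[i] <- max(en[cd])
    } else {
      out$cds_start[i] <- out$cds_end[i] <- st[ex][o][1L]
    }
  }
  out
}

#' Load transcript annotations and reference sequence
#'
#' Reads a GenePred (UCSC, >= 10 columns; column 12 used as gene id when
#' present) or GTF annotation together with a reference FASTA and builds
#' gene models. Malformed records are skipped with a warning; coding
#' transcripts whose CDS length is not a multiple of 3 are retained but
#' flagged `cds_complete = FALSE` and excluded from feature averaging.
#'
#' @param annotation_file Path to GenePred or GTF.
#' @param fasta Path to the reference FASTA.
#' @param format `"auto"` (by extension), `"genepred"` or `"gtf"`.
#' @return A `gene_model_set`: named lists `$transcripts` and `$genes`, the
#'   reference `$genome` (a [Biostrings::DNAStringSet]), and an internal cache.
#' @export
load_annotations <- function(annotation_file, fasta,
                             format = c("auto", "genepred", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", annotation_file, ignore.case = TRUE))
      "gtf" else "genepred"
  }
  if (!file.exists(annotation_file)) stop("annotation file not found: ", annotation_file)
  if (!file.exists(fasta)) stop("FASTA not found: ", fasta)
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  raw <- if (format == "genepred") read_genepred(annotation_file) else read_gtf(annotation_file)

  transcripts <- list()
  for (i in seq_along(raw$transcript_id)) {
    tx <- tryCatch(
      new_transcript_model(raw$transcript_id[i], raw$gene_id[i], raw$chrom[i],
                           raw$strand[i], raw$exon_starts[[i]], raw$exon_ends[[i]],
                           raw$cds_start[i], raw$cds_end[i]),
      error = function(e) {
        warning("skipping malformed record ", raw$transcript_id[i], ": ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(tx)) next
    if (!tx$chrom %in% names(genome)) {
      warning("skipping ", tx$transcript_id, ": chromosome ", tx$chrom,
              " absent from FASTA", call. = FALSE)
      next
    }
    if (tx$coding && !tx$cds_complete)
      warning("transcript ", tx$transcript_id,
              " flagged incomplete (CDS length ", tx$cds_len,
              " not a multiple of 3)", call. = FALSE)
    transcripts[[tx$transcript_id]] <- tx
  }
  gene_ids <- unique(vapply(transcripts, `[[`, "", "gene_id"))
  genes <- lapply(gene_ids, function(g) {
    txs <- Filter(function(t) t$gene_id == g, transcripts)
    list(gene_id = g, chrom = txs[[1L]]$chrom,
         chrom_class = chrom_class(txs[[1L]]$chrom),
         transcript_ids = names(txs))
  })
  names(genes) <- gene_ids
  spans <- if (length(transcripts)) {
    GenomicRanges::GRanges(
      vapply(transcripts, `[[`, "", "chrom"),
      IRanges::IRanges(
        vapply(transcripts, function(t) t$exon_starts[1L] + 1L, 1L),
        vapply(transcripts, function(t) t$exon_ends[t$n_exons], 1L)),
      tx_id = names(transcripts))
  } else GenomicRanges::GRanges()
  structure(list(transcripts = transcripts, genes = genes, genome = genome,
                 tx_spans = spans, cache = new.env(parent = emptyenv())),
            class = "gene_model_set")
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat(sprintf("<gene_model_set: %d gene(s), %d transcript(s), %d sequence(s)>\n",
              length(x$genes), length(x$transcripts), length(x$genome)))
  invisible(x)
}

#' Map a genomic position to a CDS offset
#'
#' @param tx A `transcript_model`.
#' @param gpos Genomic position, 0-based.
#' @return 0-based offset into the spliced CDS (counted from the translation
#'   start, i.e. from the 3'-most genomic base on the minus strand), or
#'   `NA_integer_` for an intronic/UTR position inside the transcript span.
#'   Positions outside the transcript span are an error.
#' @export
genomic_to_cds <- function(tx, gpos) {
  stopifnot(inherits(tx, "transcript_model"), length(gpos) == 1L)
  if (gpos < tx$exon_starts[1L] || gpos >= tx$exon_ends[tx$n_exons])
    stop("position ", gpos, " outside span of transcript ", tx$transcript_id)
  if (!tx$coding) return(NA_integer_)
  m <- match(as.integer(gpos), tx$cds_pos)
  if (is.na(m)) NA_integer_ else m - 1L
}

#' Map CDS offsets back to genomic positions
#'
#' Inverse of [genomic_to_cds()]; vectorised over `offsets` (0-based).
#' @export
cds_to_genomic <- function(tx, offsets) {
  stopifnot(all(offsets >= 0L), all(offsets < tx$cds_len))
  tx$cds_pos[offsets + 1L]
}

#' Spliced CDS sequence of a transcript (coding strand)
#'
#' Cached per transcript inside the `gene_model_set`.
#' @param gms A `gene_model_set`.
#' @param tx_id Transcript identifier.
#' @return Character string of the CDS on the coding strand.
#' @export
transcript_cds_seq <- function(gms, tx_id) {
  key <- paste0("cds_seq:", tx_id)
  if (!is.null(gms$cache[[key]])) return(gms$cache[[key]])
  tx <- gms$transcripts[[tx_id]]
  if (is.null(tx) || !tx$coding) stop("no coding transcript ", tx_id)
  s <- gms$genome[[tx$chrom]]
  # cds_pos is in coding order; on "-" it is descending in genomic coords
  plus_pos <- if (tx$strand == "+") tx$cds_pos else rev(tx$cds_pos)
  runs <- cumsum(c(1L, diff(plus_pos) != 1L))
  starts <- plus_pos[!duplicated(runs)] + 1L
  ends <- plus_pos[!duplicated(runs, fromLast = TRUE)] + 1L
  seg <- paste(as.character(Biostrings::Views(s, start = starts, end = ends)),
               collapse = "")
  if (tx$strand == "-")
    seg <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seg)))
  gms$cache[[key]] <- seg
  seg
}

#' Codon containing a CDS offset
#'
#' @return List with `codon` (read on the coding strand) and `within`
#'   (`cds_offset %% 3`). A codon containing an `N` is returned as-is with
#'   `flagged = TRUE`.
#' @export
codon_at <- function(gms, tx_id, cds_offset) {
  tx <- gms$transcripts[[tx_id]]
  stopifnot(!is.null(tx), cds_offset >= 0L, cds_offset < tx$cds_len)
  seq <- transcript_cds_seq(gms, tx_id)
  ci <- cds_offset %/% 3L
  codon <- substr(seq, 3L * ci + 1L, 3L * ci + 3L)
  list(codon = codon, within = cds_offset %% 3L, flagged = grepl("N", codon))
}
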