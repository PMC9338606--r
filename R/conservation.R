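#' Read a per-base conservation track
#'
#' Accepts a 3-column TSV (`chrom`, `pos0`, `score`; 0-based positions, with
#' or without a header) or a bigWig file. Positions absent from the track are
#' missing (`NA`), never zero: sparse tracks must not bias regional means.
#'
#' @param path File path.
#' @param kind `"phyloP"` or `"phastCons"` (free-form label, kept for reports).
#' @param format `"auto"` (by extension), `"tsv"` or `"bigwig"`.
#' @return A `conservation_track`.
#' @export
read_conservation <- function(path, kind = "phyloP",
                              format = c("auto", "tsv", "bigwig")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(bw|bigwig)$", path, ignore.case = TRUE))
      "bigwig" else "tsv"
  }
  if (format == "tsv") {
    dt <- data.table::fread(path, header = "auto", sep = "\t",
                            col.names = c("chrom", "pos0", "score"))
    chroms <- as.character(dt$chrom); pos0 <- as.integer(dt$pos0)
    score <- as.numeric(dt$score)
  } else {
    gr <- rtracklayer::import(path, format = "BigWig")
    w <- GenomicRanges::width(gr)
    chroms <- rep(as.character(GenomicRanges::seqnames(gr)), w)
    pos0 <- unlist(lapply(seq_along(gr), function(i)
      seq.int(GenomicRanges::start(gr)[i] - 1L, GenomicRanges::end(gr)[i] - 1L)),
      use.names = FALSE)
    score <- rep(S4Vectors::mcols(gr)$score, w)
  }
  new_conservation_track(chroms, pos0, score, kind)
}

#' Build a conservation track from vectors
#'
#' @param chroms,pos0,score Parallel vectors (0-based positions).
#' @param kind Score label.
#' @export
new_conservation_track <- function(chroms, pos0, score, kind = "phyloP") {
  stopifnot(length(chroms) == length(pos0), length(pos0) == length(score))
  dense <- lapply(split(data.frame(pos0 = pos0, score = score), chroms),
                  function(d) {
                    v <- rep(NA_real_, max(d$pos0) + 1L)
                    v[d$pos0 + 1L] <- d$score
                    v
                  })
  structure(list(kind = kind, chroms = dense), class = "conservation_track")
}

#' @export
print.conservation_track <- function(x, ...) {
  n <- sum(vapply(x$chroms, function(v) sum(!is.na(v)), 0))
  cat(sprintf("<conservation_track %s: %d chromosome(s), %d scored base(s)>\n",
              x$kind, length(x$chroms), n))
  invisible(x)
}

#' Per-base track lookup
#'
#' Vectorised over `pos0`; positions outside the track return `NA`.
#' @export
track_values <- function(track, chrom, pos0) {
  v <- track$chroms[[chrom]]
  if (is.null(v)) return(rep(NA_real_, length(pos0)))
  out <- rep(NA_real_, length(pos0))
  inside <- pos0 >= 0L & pos0 < length(v)
  out[inside] <- v[pos0[inside] + 1L]
  out
}

#' Mean conservation over a variant-anchored region
#'
#' Regions are defined on the variant's codon: `upstream` covers CDS bases
#' strictly 5' of the first base of the variant codon, `downstream` the codon
#' and everything 3' of it (the portion of the protein lost to truncation),
#' and `overlapped_exon` every base of the genomic exon containing the
#' variant. Missing bases are ignored; an all-missing region yields `NA`.
#'
#' @param track A `conservation_track`.
#' @param tx A `transcript_model`.
#' @param region `"upstream"`, `"downstream"` or `"overlapped_exon"`.
#' @param cds_offset 0-based CDS offset of the variant.
#' @export
region_mean_conservation <- function(track, tx,
                                     region = c("upstream", "downstream",
                                                "overlapped_exon"),
                                     cds_offset) {
  region <- match.arg(region)
  stopifnot(tx$coding, cds_offset >= 0L, cds_offset < tx$cds_len)
  boundary <- 3L * (cds_offset %/% 3L)  # first base of the variant codon
  pos <- switch(region,
    upstream = if (boundary == 0L) integer(0)
               else tx$cds_pos[seq_len(boundary)],
    downstream = tx$cds_pos[seq.int(boundary + 1L, tx$cds_len)],
    overlapped_exon = {
      ex <- tx$exon_of_cds[cds_offset + 1L]
      gi <- if (tx$strand == "+") ex else tx$n_exons + 1L - ex
      seq.int(tx$exon_starts[gi], tx$exon_ends[gi] - 1L)
    })
  if (!length(pos)) return(NA_real_)
  v <- track_values(track, tx$chrom, pos)
  if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
}
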