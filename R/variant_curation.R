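# Variant parsing, stopgain consequence calling, and zygosity-aware dataset
# assembly. A variant's identity throughout the package is the full 5-tuple
# (chrom, pos, ref, alt, zygosity): the same locus may legitimately carry a
# benign label as a heterozygote and a pathogenic one as a homozygote.

variant_key4 <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
variant_key5 <- function(df) paste(df$chrom, df$pos, df$ref, df$alt,
                                   df$zygosity, sep = ":")

# Run expr with a private, restored RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

gt_to_zygosity <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  ifelse(gt %in% c("1/1"), "hom",
  ifelse(gt %in% c("0/1", "1/0"), "het",
  ifelse(gt == "1", "hemi", "unknown")))
}

#' Read single-nucleotide variants from a VCF
#'
#' Multi-allelic records are split into one row per alternate allele;
#' non-SNV alleles are dropped with a warning. Zygosity is derived from the
#' first sample's GT when a genotype column is present (`1/1` hom, `0/1`
#' het, haploid `1` hemi), otherwise `unknown`.
#'
#' @param path VCF 4.x file.
#' @return `data.frame` with `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `zygosity`, and `af` (from the INFO AF field when present, else `NA`).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path))
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  alt <- as.character(rr$ALT)
  zyg <- rep("unknown", length(rr))
  geno <- VariantAnnotation::geno(vcf)
  if ("GT" %in% names(geno) && ncol(geno$GT) >= 1L)
    zyg <- gt_to_zygosity(as.character(geno$GT[, 1L]))
  info <- VariantAnnotation::info(vcf)
  af <- if ("AF" %in% colnames(info)) {
    as.numeric(vapply(info$AF, function(a)
      if (length(a)) a[[1L]] else NA_real_, 0))
  } else rep(NA_real_, length(rr))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
                   pos = GenomicRanges::start(rr),
                   ref = ref, alt = alt, zygosity = zyg, af = af,
                   stringsAsFactors = FALSE)
  snv <- nchar(df$ref) == 1L & nchar(df$alt) == 1L &
    df$ref %in% c("A", "C", "G", "T") & df$alt %in% c("A", "C", "G", "T") &
    df$ref != df$alt
  if (any(!snv))
    warning(sum(!snv), " non-SNV allele(s) dropped from ", basename(path),
            call. = FALSE)
  df[snv, , drop = FALSE]
}

comp_base <- function(b) chartr("ACGT", "TGCA", b)

#' Call stopgain consequences of variants
#'
#' For every complete coding transcript whose CDS covers a variant, the
#' affected codon is substituted (strand-aware) and the variant is reported
#' as a stopgain when the new codon is TAG/TAA/TGA and the reference codon
#' is not already a stop. Vectorised over a variant table.
#'
#' @param variants `data.frame` with `chrom`, `pos` (1-based), `ref`, `alt`.
#' @param gms A `gene_model_set` from [load_annotations()].
#' @return `data.frame` with one row per (variant, transcript) stopgain call:
#'   `variant_row`, identity columns, `transcript_id`, `gene_id`,
#'   `cds_offset`, `new_stop_codon`, `exon_index` (1-based, transcription
#'   order), `dist_last_junction` (signed bp; positive = upstream of the last
#'   exon-exon junction, `NA` for single-coding-exon transcripts).
#' @export
annotate_stopgains <- function(variants, gms) {
  empty <- data.frame(variant_row = integer(0), chrom = character(0),
                      pos = integer(0), ref = character(0), alt = character(0),
                      transcript_id = character(0), gene_id = character(0),
                      cds_offset = integer(0), new_stop_codon = character(0),
                      exon_index = integer(0), dist_last_junction = integer(0),
                      stringsAsFactors = FALSE)
  if (!nrow(variants)) return(empty)
  vgr <- GenomicRanges::GRanges(variants$chrom,
                                IRanges::IRanges(variants$pos, variants$pos))
  hits <- GenomicRanges::findOverlaps(vgr, gms$tx_spans)
  if (!length(hits)) return(empty)
  out <- vector("list", 0L)
  qh <- S4Vectors::queryHits(hits)
  th <- S4Vectors::subjectHits(hits)
  tx_ids <- S4Vectors::mcols(gms$tx_spans)$tx_id
  for (tid in unique(tx_ids[th])) {
    tx <- gms$transcripts[[tid]]
    if (!tx$coding || !tx$cds_complete) next
    vi <- qh[tx_ids[th] == tid]
    pos0 <- variants$pos[vi] - 1L
    off <- match(pos0, tx$cds_pos) - 1L
    keep <- !is.na(off)
    if (!any(keep)) next
    vi <- vi[keep]; off <- off[keep]
    seq <- transcript_cds_seq(gms, tid)
    ref_coding <- if (tx$strand == "+") variants$ref[vi]
                  else comp_base(variants$ref[vi])
    alt_coding <- if (tx$strand == "+") variants$alt[vi]
                  else comp_base(variants$alt[vi])
    obs <- substring(seq, off + 1L, off + 1L)
    if (any(obs != ref_coding)) {
      warning("reference allele mismatch for ", sum(obs != ref_coding),
              " variant(s) on transcript ", tid, "; skipped", call. = FALSE)
      ok <- obs == ref_coding
      vi <- vi[ok]; off <- off[ok]; alt_coding <- alt_coding[ok]
      if (!length(vi)) next
    }
    ci <- off %/% 3L
    codon <- substring(seq, 3L * ci + 1L, 3L * ci + 3L)
    within <- off %% 3L
    new_codon <- codon
    substr(new_codon, within + 1L, within + 1L) <- alt_coding
    is_sg <- new_codon %in% STOP_CODONS & !(codon %in% STOP_CODONS)
    if (!any(is_sg)) next
    vi <- vi[is_sg]; off <- off[is_sg]; new_codon <- new_codon[is_sg]
    exon_idx <- tx$exon_of_cds[off + 1L]
    last_exon <- max(tx$exon_of_cds)
    junction_off <- if (last_exon > min(tx$exon_of_cds))
      min(which(tx$exon_of_cds == last_exon)) - 1L else NA_integer_
    out[[length(out) + 1L]] <- data.frame(
      variant_row = vi, chrom = variants$chrom[vi], pos = variants$pos[vi],
      ref = variants$ref[vi], alt = variants$alt[vi],
      transcript_id = tid, gene_id = tx$gene_id,
      cds_offset = off, new_stop_codon = new_codon, exon_index = exon_idx,
      dist_last_junction = if (is.na(junction_off)) NA_integer_
                           else junction_off - off,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$variant_row, res$transcript_id), , drop = FALSE]
}

#' @rdname annotate_stopgains
#' @param chrom,pos,ref,alt Single-variant form.
#' @export
call_stopgain <- function(chrom, pos, ref, alt, gms) {
  annotate_stopgains(data.frame(chrom = chrom, pos = pos, ref = ref,
                                alt = alt, stringsAsFactors = FALSE), gms)
}

#' Keep rare variants
#'
#' Retains variants with allele frequency strictly below the threshold;
#' variants without a recorded frequency are treated as rare (a variant
#' unseen in reference cohorts is rare by definition). Order preserved;
#' idempotent.
#'
#' @param variants `data.frame` with an `af` column.
#' @param af_threshold Default 0.01 (the clinical "common variant" cutoff).
#' @export
filter_rare <- function(variants, af_threshold = 0.01) {
  keep <- is.na(variants$af) | variants$af < af_threshold
  variants[keep, , drop = FALSE]
}

#' Assemble labelled train/test datasets
#'
#' Combines pathogenic and benign labelled variants, forces any variant whose
#' (chrom, pos, ref, alt) 4-tuple appears in an exclusion list into the
#' training split (leakage prevention against external tools' training data;
#' external lists lack zygosity, hence 4-tuple matching), and splits the rest
#' at random. Distinct 5-tuples at the same locus — e.g. a benign
#' heterozygote and a pathogenic homozygote — are retained as separate
#' records and always land in consistent splits because identity is the
#' 5-tuple.
#'
#' @param pathogenic,benign `data.frame`s with `chrom`, `pos`, `ref`, `alt`,
#'   `zygosity`, `af` (and optionally `source`); labels are attached here.
#' @param exclusion_lists Optional list of `data.frame`s with `chrom`, `pos`,
#'   `ref`, `alt`.
#' @param split_fraction Fraction of unconstrained variants routed to train
#'   (default 0.9).
#' @param seed RNG seed for the split.
#' @param by_gene Optional character vector of gene ids parallel to the
#'   combined rows; when supplied, splitting is done gene-wise (hold-out
#'   robustness mode) instead of variant-wise.
#' @return List with `train` and `test` `data.frame`s carrying a `label`
#'   column in `{pathogenic, benign}`.
#' @export
assemble_dataset <- function(pathogenic, benign, exclusion_lists = NULL,
                             split_fraction = 0.9, seed = 1L, by_gene = NULL) {
  pathogenic$label <- if (nrow(pathogenic)) "pathogenic" else character(0)
  benign$label <- if (nrow(benign)) "benign" else character(0)
  cols <- c("chrom", "pos", "ref", "alt", "zygosity", "af", "label")
  if ("source" %in% names(pathogenic) && "source" %in% names(benign))
    cols <- c(cols, "source")
  all <- rbind(pathogenic[, cols, drop = FALSE], benign[, cols, drop = FALSE])
  k5 <- variant_key5(all)
  dup <- duplicated(k5)
  if (any(dup)) {
    warning(sum(dup), " duplicated 5-tuple record(s) dropped", call. = FALSE)
    all <- all[!dup, , drop = FALSE]
    k5 <- k5[!dup]
  }
  excl_keys <- character(0)
  for (ex in exclusion_lists %||% list())
    excl_keys <- c(excl_keys, variant_key4(ex))
  forced <- variant_key4(all) %in% excl_keys
  free_idx <- which(!forced)
  train_free <- with_seed(seed, {
    if (!is.null(by_gene)) {
      genes <- unique(by_gene[free_idx])
      g_train <- sample(genes, round(length(genes) * split_fraction))
      free_idx[by_gene[free_idx] %in% g_train]
    } else {
      sample(free_idx, round(length(free_idx) * split_fraction))
    }
  })
  train <- all[sort(c(which(forced), train_free)), , drop = FALSE]
  test <- all[setdiff(free_idx, train_free), , drop = FALSE]
  if (length(intersect(variant_key5(train), variant_key5(test))))
    stop("internal error: 5-tuple present in both splits")
  if (!all(c("pathogenic", "benign") %in% train$label) ||
      !all(c("pathogenic", "benign") %in% test$label))
    stop("a split is missing one class; adjust split_fraction or inputs")
  rownames(train) <- rownames(test) <- NULL
  list(train = train, test = test)
}

#' Read / write labelled variant TSVs
#'
#' Columns: chrom, pos, ref, alt, zygosity, label, af, source.
#' @param path File path.
#' @export
read_labeled_tsv <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                        na.strings = c("NA", "")))
  df$chrom <- as.character(df$chrom)
  df
}

#' @rdname read_labeled_tsv
#' @param df Labelled variant table.
#' @export
write_labeled_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
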