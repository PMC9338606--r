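# Synthetic fixture generator: a toy genome with multi-exon, multi-isoform
# coding genes, conservation tracks, gene-level resource tables, and labeled
# stopgain variants whose pathogenicity is generated by a logistic model over
# the same biological mechanisms the feature library measures (truncation
# location, NMD, stop-codon identity, reinitiation, gene intolerance,
# zygosity, downstream conservation). Planted effects make end-to-end signal
# recovery a fair test without claiming population-genetic realism.

SENSE_CODONS <- setdiff(apply(expand.grid(c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T")),
                              1L, paste0, collapse = ""), STOP_CODONS)

#' Simulation configuration
#'
#' Defaults are the package's stated world: an exome-like toy cohort of
#' `n_variants` rare stopgains across `n_genes` multi-isoform genes with
#' effect weights large enough that the planted mechanisms dominate label
#' noise. Weights are on the logit scale; positive values push the stated
#' direction (earlier truncation, NMD, non-TGA stop, far reinitiation site,
#' intolerant gene, homozygosity in recessive genes, conserved downstream
#' region -> pathogenic).
#'
#' @param seed Master seed; fixed seed gives byte-identical outputs.
#' @param n_genes,transcripts_per_gene,exons_per_transcript,exon_codons,intron_length
#'   Genome shape (ranges are inclusive `c(min, max)`; exon lengths are
#'   `3 * exon_codons` so isoform exon-skipping preserves frame).
#' @param n_variants Number of labelled stopgain records.
#' @param class_prior Marginal pathogenic fraction before mechanisms.
#' @param w_location,w_nmd,w_stop_codon,w_reinit,w_oe,w_zygosity,w_conservation
#'   Mechanism weights.
#' @param label_noise Probability a generated label is flipped.
#' @param p_hom Probability a variant is homozygous (hemizygous on chrX).
#' @param hidden_zygosity_fraction Fraction of pathogenic records whose
#'   zygosity is masked to `unknown` (clinical databases omit zygosity).
#' @param het_twin_fraction Fraction of homozygous pathogenic variants in
#'   recessive genes that get a benign heterozygous twin at the same locus.
#' @param af_common_fraction Fraction of variants given a common (>= 1%)
#'   allele frequency to exercise rare-variant filtering.
#' @param exclusion_fraction Fraction of loci written to the external-tool
#'   overlap list (forced-to-train routing).
#' @param frac_rvis_missing,frac_explof_missing Fraction of genes absent
#'   from the RVIS / expected-LoF tables.
#' @export
sim_config <- function(seed = 1L, n_genes = 80L,
                       transcripts_per_gene = c(1L, 3L),
                       exons_per_transcript = c(2L, 10L),
                       exon_codons = c(30L, 80L),
                       intron_length = c(80L, 400L),
                       n_variants = 5000L, class_prior = 0.3,
                       w_location = 2.0, w_nmd = 2.0, w_stop_codon = 1.5,
                       w_reinit = 1.5, w_oe = 3.0, w_zygosity = 2.0,
                       w_conservation = 2.0,
                       label_noise = 0.02, p_hom = 0.3,
                       hidden_zygosity_fraction = 0.25,
                       het_twin_fraction = 0.05,
                       af_common_fraction = 0.04,
                       exclusion_fraction = 0.1,
                       frac_rvis_missing = 0.1,
                       frac_explof_missing = 0.05) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_genes >= 2L, cfg$n_variants >= 10L,
            all(is.finite(unlist(cfg[grep("^w_", names(cfg))]))))
  structure(cfg, class = "sim_config")
}

rint <- function(n, range) {
  if (range[1L] == range[2L]) rep(range[1L], n)
  else sample(seq.int(range[1L], range[2L]), n, replace = TRUE)
}

random_cds <- function(n_codons) {
  paste0("ATG",
         paste(sample(SENSE_CODONS, n_codons - 2L, replace = TRUE),
               collapse = ""),
         sample(STOP_CODONS, 1L))
}

revcomp_chr <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

#' Generate the synthetic genome and its side tables
#'
#' Writes `genome.fa`, `transcripts.genepred`, `phyloP.tsv`, `phastCons.tsv`,
#' the resource TSVs, and `gene_truth.tsv` (the synthetic per-gene latent
#' parameters: intolerance `u`, recessive flag, conservation level). All
#' transcripts are coding-complete (ATG start, stop end, CDS a multiple of
#' 3, no internal stop); additional isoforms skip one codon-aligned internal
#' exon so exon-skipping tests have real material. Per-base conservation is
#' drawn around a gene-level mean that tracks intolerance, so the
#' downstream-of-truncation mean correlates with pathogenicity.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created).
#' @return Invisible list with file `paths` and the `gene_params` table.
#' @export
simulate_genome <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(cfg$seed, simulate_genome_impl(cfg, out_dir))
}

simulate_genome_impl <- function(cfg, out_dir) {
  ng <- cfg$n_genes
  chrom_pool <- c("chr1", "chr2", "chr3", "chr4", "chrX", "chrY")
  chrom_w <- c(0.24, 0.24, 0.22, 0.18, 0.10, 0.02)
  genes <- data.frame(
    gene_id = sprintf("GENE%03d", seq_len(ng)),
    chrom = sample(chrom_pool, ng, replace = TRUE, prob = chrom_w),
    strand = sample(c("+", "-"), ng, replace = TRUE),
    u = stats::runif(ng),                      # intolerance, 1 = intolerant
    recessive = stats::rbinom(ng, 1L, 0.4),
    stringsAsFactors = FALSE)
  genes$cons_level <- pmax(0.5 + 2.5 * genes$u + stats::rnorm(ng, sd = 0.3), -0.5)

  chrom_seq <- stats::setNames(vector("list", length(chrom_pool)), chrom_pool)
  for (ch in chrom_pool) chrom_seq[[ch]] <- character(0)
  chrom_len <- stats::setNames(rep(0L, length(chrom_pool)), chrom_pool)
  gp_rows <- character(0)
  cons_rows <- vector("list", 0L)
  tx_meta <- vector("list", 0L)

  for (gi in seq_len(ng)) {
    g <- genes[gi, ]
    n_ex <- rint(1L, cfg$exons_per_transcript)
    ex_len <- 3L * rint(n_ex, cfg$exon_codons)
    introns <- if (n_ex > 1L) rint(n_ex - 1L, cfg$intron_length) else integer(0)
    cds_len <- sum(ex_len)
    cds <- random_cds(cds_len %/% 3L)
    # genomic layout of the primary transcript within the gene span
    gap <- rint(1L, c(300L, 800L))
    start0 <- chrom_len[[g$chrom]] + gap
    ex_start <- start0 + c(0L, cumsum(ex_len[-n_ex] + introns))
    ex_end <- ex_start + ex_len
    span_len <- ex_end[n_ex] - start0
    # transcription-order chunks of the CDS mapped onto genomic exons; on
    # the minus strand transcription exon j occupies genomic exon n-j+1, so
    # the chunk lengths must follow transcription order
    tr_len <- if (g$strand == "+") ex_len else rev(ex_len)
    bounds <- c(0L, cumsum(tr_len))
    chunks <- substring(cds, bounds[-length(bounds)] + 1L, bounds[-1L])
    span <- paste(sample(c("A", "C", "G", "T"), span_len, replace = TRUE),
                  collapse = "")
    for (e in seq_len(n_ex)) {
      tr_idx <- if (g$strand == "+") e else n_ex + 1L - e
      piece <- if (g$strand == "+") chunks[tr_idx] else revcomp_chr(chunks[tr_idx])
      substr(span, ex_start[e] - start0 + 1L, ex_end[e] - start0) <- piece
    }
    chrom_seq[[g$chrom]] <- c(chrom_seq[[g$chrom]],
                              paste(sample(c("A", "C", "G", "T"), gap,
                                           replace = TRUE), collapse = ""),
                              span)
    chrom_len[[g$chrom]] <- ex_end[n_ex]

    # isoforms: primary + exon-skipping variants (codon-aligned, frame-safe)
    n_tx <- rint(1L, cfg$transcripts_per_gene)
    iso <- list(seq_len(n_ex))
    if (n_tx > 1L && n_ex >= 3L) {
      internal <- seq.int(2L, n_ex - 1L)
      skip <- sample(internal, min(n_tx - 1L, length(internal)))
      for (s in skip) iso[[length(iso) + 1L]] <- setdiff(seq_len(n_ex), s)
    }
    for (ti in seq_along(iso)) {
      keep <- iso[[ti]]
      tid <- sprintf("%s.t%d", g$gene_id, ti)
      es <- ex_start[keep]; ee <- ex_end[keep]
      # exonFrames: cumulative coding length before each exon, transcription order
      tr_order <- if (g$strand == "+") seq_along(keep) else rev(seq_along(keep))
      lens <- (ee - es)[order(tr_order)]
      fr_tr <- (c(0L, cumsum(lens))[seq_along(lens)]) %% 3L
      frames <- fr_tr[tr_order]
      gp_rows <- c(gp_rows, paste(
        tid, g$chrom, g$strand, es[1L], ee[length(ee)], es[1L], ee[length(ee)],
        length(keep),
        paste0(paste(es, collapse = ","), ","),
        paste0(paste(ee, collapse = ","), ","),
        0L, g$gene_id, "cmpl", "cmpl",
        paste0(paste(frames, collapse = ","), ","),
        sep = "\t"))
      tx_meta[[length(tx_meta) + 1L]] <- data.frame(
        transcript_id = tid, gene_id = g$gene_id, cds_len = sum(ee - es),
        stringsAsFactors = FALSE)
    }
    # conservation over exon bases, gene-level mean + per-base noise,
    # with a sprinkle of unscored gaps
    pos <- unlist(mapply(function(a, b) seq.int(a, b - 1L), ex_start, ex_end,
                         SIMPLIFY = FALSE), use.names = FALSE)
    keep_pos <- stats::runif(length(pos)) > 0.05
    pos <- pos[keep_pos]
    phy <- g$cons_level + stats::rnorm(length(pos), sd = 0.8)
    pha <- stats::plogis(1.2 * (g$cons_level - 1.5) +
                           stats::rnorm(length(pos), sd = 1))
    cons_rows[[length(cons_rows) + 1L]] <- data.frame(
      chrom = g$chrom, pos0 = pos, phyloP = round(phy, 4),
      phastCons = round(pha, 4), stringsAsFactors = FALSE)
  }

  paths <- list(
    fasta = file.path(out_dir, "genome.fa"),
    genepred = file.path(out_dir, "transcripts.genepred"),
    phyloP = file.path(out_dir, "phyloP.tsv"),
    phastCons = file.path(out_dir, "phastCons.tsv"),
    resources = out_dir,
    gene_truth = file.path(out_dir, "gene_truth.tsv"))

  seqs <- Biostrings::DNAStringSet(vapply(chrom_seq, paste, "", collapse = ""))
  seqs <- seqs[Biostrings::width(seqs) > 0L]
  Biostrings::writeXStringSet(seqs, paths$fasta)
  writeLines(gp_rows, paths$genepred)
  cons <- data.table::rbindlist(cons_rows)
  data.table::fwrite(cons[, c("chrom", "pos0", "phyloP")], paths$phyloP,
                     sep = "\t", col.names = FALSE)
  data.table::fwrite(cons[, c("chrom", "pos0", "phastCons")], paths$phastCons,
                     sep = "\t", col.names = FALSE)

  tx_meta <- as.data.frame(data.table::rbindlist(tx_meta))
  # expected LoF reflects target size (length), not intolerance: intolerance
  # surfaces through the dearth of observed benign stopgains
  tx_meta$exp_lof <- round(tx_meta$cds_len / 100 *
                             exp(stats::rnorm(nrow(tx_meta), sd = 0.15)), 3)
  keep_lof <- stats::runif(ng) > cfg$frac_explof_missing
  lof_tx <- tx_meta[tx_meta$gene_id %in% genes$gene_id[keep_lof],
                    c("transcript_id", "gene_id", "exp_lof")]
  data.table::fwrite(lof_tx,
                     file.path(out_dir, "expected_lof_by_transcript.tsv"),
                     sep = "\t")
  lof_gene <- stats::aggregate(exp_lof ~ gene_id, tx_meta, max)
  data.table::fwrite(lof_gene[lof_gene$gene_id %in% genes$gene_id[keep_lof], ],
                     file.path(out_dir, "expected_lof_by_gene.tsv"), sep = "\t")
  rvis <- data.frame(gene_id = genes$gene_id,
                     rvis = round((0.5 - genes$u) * 4 +
                                    stats::rnorm(ng, sd = 0.5), 3))
  rvis$rvis_percentile <- round(100 * rank(rvis$rvis) / ng, 2)
  rvis <- rvis[stats::runif(ng) > cfg$frac_rvis_missing, ]
  data.table::fwrite(rvis, file.path(out_dir, "rvis.tsv"), sep = "\t")
  omim <- data.frame(
    gene_id = genes$gene_id,
    recessive = stats::rbinom(ng, 1L, 0.1 + 0.6 * genes$recessive),
    dominant = stats::rbinom(ng, 1L, 0.15 + 0.5 * genes$u * (1 - genes$recessive)))
  data.table::fwrite(omim, file.path(out_dir, "omim.tsv"), sep = "\t")
  data.table::fwrite(genes, paths$gene_truth, sep = "\t")

  invisible(list(paths = paths, gene_params = genes))
}

# All single-base substitutions that create a stop codon, per transcript.
enumerate_stopgain_sites <- function(gms) {
  out <- vector("list", 0L)
  for (tid in names(gms$transcripts)) {
    tx <- gms$transcripts[[tid]]
    if (!tx$coding || !tx$cds_complete) next
    seq <- transcript_cds_seq(gms, tid)
    nc <- tx$cds_len %/% 3L
    starts <- 3L * (seq_len(nc) - 1L)
    cods <- substring(seq, starts + 1L, starts + 3L)
    for (w in 0:2) {
      refb <- substring(cods, w + 1L, w + 1L)
      for (alt in c("A", "C", "G", "T")) {
        newc <- cods
        substr(newc, w + 1L, w + 1L) <- alt
        hit <- newc %in% STOP_CODONS & !(cods %in% STOP_CODONS) & refb != alt
        if (!any(hit)) next
        off <- starts[hit] + w
        gpos0 <- tx$cds_pos[off + 1L]
        flip <- tx$strand == "-"
        out[[length(out) + 1L]] <- data.frame(
          transcript_id = tid, gene_id = tx$gene_id, chrom = tx$chrom,
          pos = gpos0 + 1L,
          ref = if (flip) comp_base(refb[hit]) else refb[hit],
          alt = if (flip) comp_base(rep(alt, sum(hit))) else rep(alt, sum(hit)),
          cds_offset = off, cds_len = tx$cds_len,
          new_stop_codon = newc[hit], stringsAsFactors = FALSE)
      }
    }
  }
  sites <- as.data.frame(data.table::rbindlist(out))
  sites[!duplicated(paste(sites$chrom, sites$pos, sites$ref, sites$alt)), ]
}

#' Generate labelled stopgain variants over a synthetic genome
#'
#' Samples genuine stopgain sites (every emitted variant creates a stop in
#' at least one transcript by construction), assigns zygosity, and draws the
#' pathogenicity label from `Bernoulli(plogis(b0 + sum(w_i m_i)))` where the
#' mechanisms `m_i` are the variant's truncation location, NMD status,
#' stop-codon identity, reinitiation opportunity, gene intolerance,
#' zygosity(x recessive gene) and downstream phyloP. Writes `variants.vcf`
#' (with GT and AF), `labels.tsv` and `ground_truth.tsv` under `out_dir`.
#'
#' @param cfg A [sim_config()].
#' @param genome Return value of [simulate_genome()] (or a list with
#'   `$paths`).
#' @param out_dir Output directory (defaults to the genome directory).
#' @return Invisible list with `labels` (the labelled table), `ground_truth`
#'   and file `paths`.
#' @export
simulate_variants <- function(cfg, genome, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  paths <- genome$paths
  out_dir <- out_dir %||% dirname(paths$fasta)
  gms <- load_annotations(paths$genepred, paths$fasta)
  phyloP <- read_conservation(paths$phyloP, "phyloP")
  gene_params <- genome$gene_params
  with_seed(cfg$seed + 7L,
            simulate_variants_impl(cfg, gms, phyloP, gene_params, out_dir))
}

simulate_variants_impl <- function(cfg, gms, phyloP, gene_params, out_dir) {
  sites <- enumerate_stopgain_sites(gms)
  if (nrow(sites) < cfg$n_variants)
    stop("only ", nrow(sites), " distinct stopgain sites available; ",
         "reduce n_variants or enlarge the genome")
  pick <- sites[sort(sample.int(nrow(sites), cfg$n_variants)), ]
  rownames(pick) <- NULL
  n <- nrow(pick)
  gp <- gene_params[match(pick$gene_id, gene_params$gene_id), ]

  # per-variant mechanism ingredients (first/primary transcript)
  rel_loc <- pick$cds_offset / pick$cds_len
  nmd <- numeric(n); datg <- rep(NA_real_, n); down_phy <- rep(NA_real_, n)
  for (tid in unique(pick$transcript_id)) {
    sel <- which(pick$transcript_id == tid)
    tx <- gms$transcripts[[tid]]
    off <- pick$cds_offset[sel]
    last_exon <- max(tx$exon_of_cds)
    jo <- if (last_exon > min(tx$exon_of_cds))
      min(which(tx$exon_of_cds == last_exon)) - 1L else NA_integer_
    nmd[sel] <- as.numeric(!is.na(jo) & (jo - off) > 50)
    atg <- tx_atg_starts(gms, tid)
    if (length(atg)) {
      ni <- findInterval(off, atg) + 1L
      datg[sel] <- ifelse(ni <= length(atg),
                          atg[pmin(ni, length(atg))] - off, NA_real_)
    }
    v <- track_values(phyloP, tx$chrom, tx$cds_pos)
    cs <- c(0, cumsum(ifelse(is.na(v), 0, v)))
    cn <- c(0, cumsum(!is.na(v)))
    b <- 3L * (off %/% 3L)
    s <- cs[tx$cds_len + 1L] - cs[b + 1L]
    m <- cn[tx$cds_len + 1L] - cn[b + 1L]
    down_phy[sel] <- ifelse(m > 0, s / m, NA_real_)
  }

  zyg <- ifelse(stats::runif(n) < cfg$p_hom, "hom", "het")
  x_hom <- which(chrom_class(pick$chrom) == "X" & zyg == "hom")
  zyg[x_hom[stats::runif(length(x_hom)) < 0.5]] <- "hemi"

  m_loc <- (0.5 - rel_loc) * 2
  m_nmd <- (nmd - 0.5) * 2
  m_stop <- ifelse(pick$new_stop_codon == "TGA", -1, 0.5)
  m_reinit <- ifelse(pick$cds_offset < 100 & !is.na(datg) & datg < 200, -1, 0)
  m_oe <- (gp$u - 0.5) * 2
  m_zyg <- gp$recessive * ifelse(zyg %in% c("hom", "hemi"), 1, -1)
  m_cons <- ifelse(is.na(down_phy), 0, (down_phy - 1.75) / 1.25)
  logit <- stats::qlogis(cfg$class_prior) +
    cfg$w_location * m_loc + cfg$w_nmd * m_nmd + cfg$w_stop_codon * m_stop +
    cfg$w_reinit * m_reinit + cfg$w_oe * m_oe + cfg$w_zygosity * m_zyg +
    cfg$w_conservation * m_cons
  label01 <- stats::rbinom(n, 1L, stats::plogis(logit))
  flip <- stats::runif(n) < cfg$label_noise
  label01[flip] <- 1L - label01[flip]
  label <- ifelse(label01 == 1L, "pathogenic", "benign")

  af <- ifelse(label01 == 1L, 10^stats::runif(n, -6, -3),
               10^stats::runif(n, -5, -2.05))
  common <- stats::runif(n) < cfg$af_common_fraction
  af[common] <- stats::runif(sum(common), 0.011, 0.1)

  out <- data.frame(chrom = pick$chrom, pos = pick$pos, ref = pick$ref,
                    alt = pick$alt, zygosity = zyg, label = label,
                    af = signif(af, 4), source = "synthetic",
                    stringsAsFactors = FALSE)
  mech <- data.frame(logit = logit, m_location = m_loc, m_nmd = m_nmd,
                     m_stop = m_stop, m_reinit = m_reinit, m_oe = m_oe,
                     m_zygosity = m_zyg, m_conservation = m_cons,
                     true_zygosity = zyg, stringsAsFactors = FALSE)

  # benign heterozygous twins of recessive homozygous pathogenic variants:
  # healthy carriers exist, so the same site is benign as a heterozygote
  twin_pool <- which(label01 == 1L & zyg %in% c("hom", "hemi") &
                       gp$recessive == 1L & !common)
  twins <- twin_pool[stats::runif(length(twin_pool)) < cfg$het_twin_fraction]
  if (length(twins)) {
    tw <- out[twins, ]
    tw$zygosity <- "het"
    tw$label <- "benign"
    tw$af <- signif(10^stats::runif(length(twins), -5, -2.5), 4)
    out <- rbind(out, tw)
    tw_mech <- mech[twins, ]
    tw_mech$true_zygosity <- "het"
    tw_mech$m_zygosity <- -1
    tw_mech$logit <- NA_real_  # twin labels are deterministic, not sampled
    mech <- rbind(mech, tw_mech)
  }

  # mask zygosity for a fraction of pathogenic records (clinical databases
  # omit it; the imputation heuristic fills the gap at featurization time)
  hide <- out$label == "pathogenic" &
    stats::runif(nrow(out)) < cfg$hidden_zygosity_fraction
  out$zygosity[hide] <- "unknown"

  ord <- order(out$chrom, out$pos, out$ref, out$alt, out$zygosity)
  out <- out[ord, , drop = FALSE]
  mech <- mech[ord, , drop = FALSE]
  hide <- hide[ord]
  rownames(out) <- rownames(mech) <- NULL
  truth <- cbind(out, mech)

  paths <- list(vcf = file.path(out_dir, "variants.vcf"),
                labels = file.path(out_dir, "labels.tsv"),
                ground_truth = file.path(out_dir, "ground_truth.tsv"),
                exclusion = file.path(out_dir, "external_overlap.tsv"))
  write_sim_vcf(out, ifelse(hide, "unknown", mech$true_zygosity), paths$vcf,
                names(gms$genome))
  write_labeled_tsv(out, paths$labels)
  data.table::fwrite(truth, paths$ground_truth, sep = "\t")
  excl <- out[stats::runif(nrow(out)) < cfg$exclusion_fraction,
              c("chrom", "pos", "ref", "alt")]
  excl <- excl[!duplicated(variant_key4(excl)), ]
  data.table::fwrite(excl, paths$exclusion, sep = "\t")
  invisible(list(labels = out, ground_truth = truth, paths = paths))
}

write_sim_vcf <- function(df, zyg, path, contigs) {
  gt <- ifelse(zyg == "hom", "1/1",
        ifelse(zyg == "het", "0/1",
        ifelse(zyg == "hemi", "1", "./.")))
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("##contig=<ID=", contigs, ">"),
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "sample1", sep = "\t"))
  body <- paste(df$chrom, df$pos, ".", df$ref, df$alt, ".", "PASS",
                paste0("AF=", df$af), "GT", gt, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' One-call synthetic cohort
#'
#' [simulate_genome()] followed by [simulate_variants()] into one directory.
#' @param cfg A [sim_config()].
#' @param out_dir Output directory.
#' @export
simulate_cohort <- function(cfg, out_dir) {
  genome <- simulate_genome(cfg, out_dir)
  variants <- simulate_variants(cfg, genome, out_dir)
  invisible(list(genome = genome, variants = variants,
                 paths = c(genome$paths, variants$paths)))
}
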