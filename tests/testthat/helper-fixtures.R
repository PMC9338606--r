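# Fixture builders shared across test files. Everything is generated in
# code: hand-laid genomes for coordinate oracles, simulated cohorts (cached
# per session) for pipeline-scale checks.

# Write a genome + genePred from explicit specs and load it.
# txs: list of lists with tid, gene, chrom, strand, exon_starts, exon_ends,
# cds_start, cds_end. chrom_seqs: named character vector.
make_gms <- function(txs, chrom_seqs, dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("gms")
    dir.create(dir)
  }
  fa <- file.path(dir, "genome.fa")
  gp <- file.path(dir, "tx.genepred")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(chrom_seqs), fa)
  lines <- vapply(txs, function(t) {
    paste(t$tid, t$chrom, t$strand,
          t$exon_starts[1], t$exon_ends[length(t$exon_ends)],
          t$cds_start, t$cds_end, length(t$exon_starts),
          paste0(paste(t$exon_starts, collapse = ","), ","),
          paste0(paste(t$exon_ends, collapse = ","), ","),
          0, t$gene, "cmpl", "cmpl",
          paste0(paste(rep(-1, length(t$exon_starts)), collapse = ","), ","),
          sep = "\t")
  }, "")
  writeLines(lines, gp)
  load_annotations(gp, fa)
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# Random CDS of n_codons with no internal stop, ATG start, stop end.
rand_cds <- function(n_codons) {
  sense <- stopgainr:::SENSE_CODONS
  paste0("ATG", paste(sample(sense, n_codons - 2, replace = TRUE),
                      collapse = ""), sample(c("TAA", "TAG", "TGA"), 1))
}

# A small multi-isoform fixture genome used throughout:
#  GENEA/chr1/+ : 3 exons (codon-aligned), isoform t1 = all, t2 skips exon 2
#  GENEB/chr1/- : 2 exons on the minus strand
#  GENEC/chrX/+ : single exon
fixture_gms <- function(seed = 42) {
  withr::with_seed(seed, {
    cdsA <- rand_cds(60)   # 180 bp over exons 60/60/60
    cdsB <- rand_cds(40)   # 120 bp over exons 60/60
    cdsC <- rand_cds(33)   # 99 bp single exon
    chr1 <- rand_dna(1200)
    # GENEA at 100: exons [100,160) [260,320) [420,480)
    substr(chr1, 101, 160) <- substr(cdsA, 1, 60)
    substr(chr1, 261, 320) <- substr(cdsA, 61, 120)
    substr(chr1, 421, 480) <- substr(cdsA, 121, 180)
    # GENEB at 600 (minus strand): exons [600,660) [740,800)
    # transcription right-to-left: exon [740,800) carries CDS chunk 1
    rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    substr(chr1, 741, 800) <- rc(substr(cdsB, 1, 60))
    substr(chr1, 601, 660) <- rc(substr(cdsB, 61, 120))
    chrX <- rand_dna(400)
    substr(chrX, 51, 149) <- cdsC
    txs <- list(
      list(tid = "A.t1", gene = "GENEA", chrom = "chr1", strand = "+",
           exon_starts = c(100, 260, 420), exon_ends = c(160, 320, 480),
           cds_start = 100, cds_end = 480),
      list(tid = "A.t2", gene = "GENEA", chrom = "chr1", strand = "+",
           exon_starts = c(100, 420), exon_ends = c(160, 480),
           cds_start = 100, cds_end = 480),
      list(tid = "B.t1", gene = "GENEB", chrom = "chr1", strand = "-",
           exon_starts = c(600, 740), exon_ends = c(660, 800),
           cds_start = 600, cds_end = 800),
      list(tid = "C.t1", gene = "GENEC", chrom = "chrX", strand = "+",
           exon_starts = c(50), exon_ends = c(149),
           cds_start = 50, cds_end = 149))
    gms <- make_gms(txs, c(chr1 = chr1, chrX = chrX))
    list(gms = gms, cdsA = cdsA, cdsB = cdsB, cdsC = cdsC)
  })
}

# Constant-value conservation tracks covering given gms CDS bases.
constant_tracks <- function(gms, value_phyloP = 2, value_phastCons = 0.5) {
  pos <- list()
  for (tx in gms$transcripts) {
    pos[[tx$transcript_id]] <- data.frame(chrom = tx$chrom, pos0 = tx$cds_pos)
  }
  pos <- unique(do.call(rbind, pos))
  list(phyloP = new_conservation_track(pos$chrom, pos$pos0,
                                       rep(value_phyloP, nrow(pos)), "phyloP"),
       phastCons = new_conservation_track(pos$chrom, pos$pos0,
                                          rep(value_phastCons, nrow(pos)),
                                          "phastCons"))
}

# Empty-ish training context for featurization tests that do not exercise
# training-derived tallies.
blank_ctx <- function(gms, resources = NULL) {
  dummy <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      zygosity = character(0), label = character(0),
                      stringsAsFactors = FALSE)
  build_training_context(dummy, gms, resources)
}

# Brute-force translation oracle: does this SNV create a premature stop in
# this transcript's CDS? Returns the mutant codon or NULL.
oracle_stopgain <- function(gms, tx, gpos1, ref, alt) {
  seq <- transcript_cds_seq(gms, tx$transcript_id)
  i <- match(gpos1 - 1L, tx$cds_pos)
  if (is.na(i)) return(NULL)
  base_ref <- if (tx$strand == "+") ref else chartr("ACGT", "TGCA", ref)
  base_alt <- if (tx$strand == "+") alt else chartr("ACGT", "TGCA", alt)
  if (substr(seq, i, i) != base_ref) return(NULL)
  mut <- seq
  substr(mut, i, i) <- base_alt
  aa_ref <- as.character(Biostrings::translate(Biostrings::DNAString(seq)))
  aa_mut <- as.character(Biostrings::translate(Biostrings::DNAString(mut)))
  n <- nchar(aa_mut)
  codon_i <- (i - 1) %/% 3 + 1
  # premature stop exactly at the variant codon, reference codon not a stop
  if (codon_i < n && substr(aa_mut, codon_i, codon_i) == "*" &&
      substr(aa_ref, codon_i, codon_i) != "*") {
    substr(mut, 3 * codon_i - 2, 3 * codon_i)
  } else NULL
}

# Session-cached default cohorts for the expensive end-to-end checks.
.cohort_cache <- new.env(parent = emptyenv())
acceptance_cohort <- function(seed) {
  key <- paste0("seed", seed)
  if (is.null(.cohort_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("cohort_", seed))
    if (!dir.exists(dir)) cmd_simulate(dir, seed = seed)
    cmd_build_dataset(dir, file.path(dir, "ds"), seed = seed)
    .cohort_cache[[key]] <- list(dir = dir, ds = file.path(dir, "ds"))
  }
  .cohort_cache[[key]]
}
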