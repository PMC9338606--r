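test_that("annotation loading builds valid transcript and gene models", {
  # single-exon identity case
  gms1 <- make_gms(list(list(tid = "t1", gene = "g1", chrom = "c", strand = "+",
                             exon_starts = 0, exon_ends = 300,
                             cds_start = 0, cds_end = 300)),
                   c(c = rand_dna(300)))
  tx <- gms1$transcripts[["t1"]]
  expect_equal(tx$cds_len, 300L)
  expect_true(tx$cds_complete)
  expect_equal(tx$cds_pos, 0:299)

  # two transcripts sharing a gene id collapse into one gene model
  fx <- fixture_gms()
  expect_length(fx$gms$genes, 3L)
  expect_setequal(fx$gms$genes[["GENEA"]]$transcript_ids, c("A.t1", "A.t2"))
  expect_equal(fx$gms$genes[["GENEC"]]$chrom_class, "X")

  # CDS length not a multiple of 3 -> flagged incomplete, with a warning
  expect_warning(
    gms3 <- make_gms(list(list(tid = "bad", gene = "g", chrom = "c",
                               strand = "+", exon_starts = 0, exon_ends = 301,
                               cds_start = 0, cds_end = 301)),
                     c(c = rand_dna(301))),
    "incomplete")
  expect_false(gms3$transcripts[["bad"]]$cds_complete)
})

test_that("genomic/CDS coordinate mapping is strand-aware and bijective", {
  gms <- make_gms(list(
    list(tid = "p", gene = "gp", chrom = "c", strand = "+",
         exon_starts = 100, exon_ends = 202, cds_start = 100, cds_end = 202),
    list(tid = "m", gene = "gm", chrom = "c", strand = "-",
         exon_starts = 300, exon_ends = 402, cds_start = 300, cds_end = 402),
    list(tid = "sp", gene = "gs", chrom = "c", strand = "+",
         exon_starts = c(500, 600), exon_ends = c(550, 652),
         cds_start = 500, cds_end = 652)),
    c(c = rand_dna(700)))
  expect_equal(genomic_to_cds(gms$transcripts[["p"]], 100), 0L)
  expect_equal(genomic_to_cds(gms$transcripts[["m"]], 401), 0L)
  # two exons [500,550)+[600,652): genomic 600 is spliced offset 50
  expect_equal(genomic_to_cds(gms$transcripts[["sp"]], 600), 50L)
  # brute-force walk over the spliced CDS agrees everywhere
  tx <- gms$transcripts[["sp"]]
  walk <- c(500:549, 600:651)
  for (k in seq_along(walk))
    expect_equal(genomic_to_cds(tx, walk[k]), k - 1L)
  # intronic -> NA; outside span -> error
  expect_true(is.na(genomic_to_cds(tx, 575)))
  expect_error(genomic_to_cds(tx, 10), "outside span")

  # bijection over every CDS base of every fixture transcript (< 1 kb each)
  fx <- fixture_gms()
  for (tx in fx$gms$transcripts) {
    offs <- vapply(tx$cds_pos, function(g) genomic_to_cds(tx, g), 1L)
    expect_identical(offs, seq_len(tx$cds_len) - 1L)
    expect_identical(cds_to_genomic(tx, offs), tx$cds_pos)
  }
})

test_that("codon_at reads codons on the coding strand", {
  seq <- paste0("ATGCAGTAA")
  gms <- make_gms(list(list(tid = "t", gene = "g", chrom = "c", strand = "+",
                            exon_starts = 0, exon_ends = 9,
                            cds_start = 0, cds_end = 9)),
                  c(c = seq))
  expect_equal(codon_at(gms, "t", 4), list(codon = "CAG", within = 1L,
                                           flagged = FALSE))
  expect_equal(codon_at(gms, "t", 0)$codon, "ATG")

  # minus strand: genomic "TTACTGCAT" left-to-right reads ATGCAGTAA in
  # transcription order (reverse-complement oracle)
  gmsm <- make_gms(list(list(tid = "t", gene = "g", chrom = "c", strand = "-",
                             exon_starts = 0, exon_ends = 9,
                             cds_start = 0, cds_end = 9)),
                   c(c = "TTACTGCAT"))
  expect_equal(codon_at(gmsm, "t", 0)$codon, "ATG")
  expect_equal(transcript_cds_seq(gmsm, "t"), "ATGCAGTAA")
})

test_that("strand symmetry: reversing strand + reverse-complementing the reference preserves codons", {
  withr::with_seed(7, {
    cds <- rand_cds(30)  # 90 bp
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    gp <- make_gms(list(list(tid = "t", gene = "g", chrom = "c", strand = "+",
                             exon_starts = 10, exon_ends = 100,
                             cds_start = 10, cds_end = 100)),
                   c(c = paste0(rand_dna(10), cds, rand_dna(10))))
    gm <- make_gms(list(list(tid = "t", gene = "g", chrom = "c", strand = "-",
                             exon_starts = 10, exon_ends = 100,
                             cds_start = 10, cds_end = 100)),
                   c(c = paste0(rand_dna(10), rc, rand_dna(10))))
    for (off in c(0L, 1L, 2L, 44L, 89L))
      expect_equal(codon_at(gp, "t", off), codon_at(gm, "t", off))
  })
})

test_that("regional conservation means honour region definitions and missingness", {
  fx <- fixture_gms()
  gms <- fx$gms
  tx <- gms$transcripts[["A.t1"]]

  # constant track -> every region mean equals the constant
  tr <- constant_tracks(gms)$phyloP
  for (region in c("upstream", "downstream", "overlapped_exon")) {
    if (region == "upstream") next  # offset 0 has an empty upstream
    expect_equal(region_mean_conservation(tr, tx, region, 90L), 2)
  }
  expect_equal(region_mean_conservation(tr, tx, "upstream", 90L), 2)
  expect_true(is.na(region_mean_conservation(tr, tx, "upstream", 0L)))

  # split track: 1.0 over the first half, 3.0 over the second; variant at
  # the codon-aligned midpoint
  half <- tx$cds_len / 2
  vals <- c(rep(1, half), rep(3, half))
  tr2 <- new_conservation_track(rep(tx$chrom, tx$cds_len), tx$cds_pos, vals)
  expect_equal(region_mean_conservation(tr2, tx, "upstream", half), 1)
  expect_equal(region_mean_conservation(tr2, tx, "downstream", half), 3)

  # sparse track with gaps: mean over present bases equals brute force
  withr::with_seed(11, {
    keep <- runif(tx$cds_len) > 0.4
    sc <- rnorm(sum(keep))
    tr3 <- new_conservation_track(rep(tx$chrom, sum(keep)),
                                  tx$cds_pos[keep], sc)
    for (off in c(3L, 60L, 121L)) {
      b <- 3L * (off %/% 3L)
      up_pos <- tx$cds_pos[seq_len(b)]
      down_pos <- tx$cds_pos[(b + 1):tx$cds_len]
      brute <- function(pos) {
        v <- sc[match(pos, tx$cds_pos[keep])]
        if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
      }
      expect_equal(region_mean_conservation(tr3, tx, "upstream", off),
                   brute(up_pos))
      expect_equal(region_mean_conservation(tr3, tx, "downstream", off),
                   brute(down_pos))
      # upstream + downstream partition the CDS
      expect_equal(length(up_pos) + length(down_pos), tx$cds_len)
    }
  })

  # queries outside the track are missing, never zero
  expect_true(is.na(track_values(tr, "chrZ", 5L)))
  expect_true(all(is.na(track_values(tr, tx$chrom, c(-5L, 10000000L)))))
})

test_that("GTF input builds the same models as GenePred", {
  fx <- fixture_gms()
  gtf <- tempfile(fileext = ".gtf")
  rows <- character(0)
  for (tx in fx$gms$transcripts) {
    gi <- seq_len(tx$n_exons)
    for (e in gi) {
      attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                       tx$gene_id, tx$transcript_id)
      rows <- c(rows,
                paste(tx$chrom, "test", "exon", tx$exon_starts[e] + 1L,
                      tx$exon_ends[e], ".", tx$strand, ".", attrs, sep = "\t"),
                paste(tx$chrom, "test", "CDS", tx$exon_starts[e] + 1L,
                      tx$exon_ends[e], ".", tx$strand, "0", attrs, sep = "\t"))
    }
  }
  writeLines(rows, gtf)
  fa <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(fx$gms$genome, fa)
  gms2 <- load_annotations(gtf, fa, format = "gtf")
  expect_setequal(names(gms2$transcripts), names(fx$gms$transcripts))
  for (tid in names(fx$gms$transcripts)) {
    expect_identical(gms2$transcripts[[tid]]$cds_pos,
                     fx$gms$transcripts[[tid]]$cds_pos)
    expect_equal(transcript_cds_seq(gms2, tid),
                 transcript_cds_seq(fx$gms, tid))
  }
})

test_that("bigWig conservation round-trips through rtracklayer", {
  withr::with_seed(3, {
    pos <- sort(sample(0:999, 200))
    sc <- round(rnorm(200), 3)
  })
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos + 1L, width = 1L),
                               score = sc)
  GenomeInfoDb::seqlengths(gr) <- c(chr1 = 1000L)
  bw <- tempfile(fileext = ".bw")
  rtracklayer::export.bw(gr, bw)
  trk <- read_conservation(bw, "phyloP")
  expect_equal(track_values(trk, "chr1", pos), sc, tolerance = 1e-6)
  expect_true(is.na(track_values(trk, "chr1", setdiff(0:999, pos)[1])))
})
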