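# Feature-library unit tests. The fixture genome (fixture_gms) has a
# 3-exon/2-isoform plus-strand gene, a 2-exon minus-strand gene and a
# single-exon chrX gene; stopgain sites are picked from the enumerated pool.

fixture_sites <- function(gms, n = 10, seed = 2) {
  sites <- stopgainr:::enumerate_stopgain_sites(gms)
  withr::with_seed(seed, sites[sample(nrow(sites), n), ])
}

test_that("zygosity imputation follows the benign-heterozygote heuristic exactly", {
  fx <- fixture_gms()
  train <- data.frame(chrom = "chr1", pos = c(101, 102), ref = "A",
                      alt = "T", zygosity = c("het", "hom"),
                      label = c("benign", "benign"), stringsAsFactors = FALSE)
  # (loci are synthetic, not genuine stopgains: the het index is built from
  # the raw records, so consequence warnings are irrelevant here)
  ctx <- suppressWarnings(build_training_context(train, fx$gms))
  # benign het exists at the locus -> predicted homozygous
  expect_equal(impute_zygosity("chr1", 101, "A", "T", ctx), 1)
  # benign record exists but is hom, or locus absent -> heterozygous
  expect_equal(impute_zygosity("chr1", 102, "A", "T", ctx), 0)
  expect_equal(impute_zygosity("chr1", 999, "A", "T", ctx), 0)
  # vectorised
  expect_equal(impute_zygosity(c("chr1", "chr1"), c(101, 999), c("A", "A"),
                               c("T", "T"), ctx), c(1, 0))
})

test_that("oe, monoclass and splice-out features follow their definitions", {
  fx <- fixture_gms()
  gms <- fx$gms
  sites <- stopgainr:::enumerate_stopgain_sites(gms)
  a_sites <- sites[sites$gene_id == "GENEA", ]
  # 3 benign stopgains on GENEA, 1 pathogenic elsewhere
  train <- data.frame(chrom = a_sites$chrom[1:3], pos = a_sites$pos[1:3],
                      ref = a_sites$ref[1:3], alt = a_sites$alt[1:3],
                      zygosity = "het", label = "benign",
                      stringsAsFactors = FALSE)
  res <- list(exp_lof_tx = c(A.t1 = 10), exp_lof_gene = c(GENEA = 8))
  ctx <- build_training_context(train, gms, res)
  expect_equal(oe_feature("A.t1", "GENEA", ctx), 0.3)   # 3 / 10
  expect_equal(oe_feature("A.t2", "GENEA", ctx), 3 / 8) # gene-level fallback
  expect_true(is.na(oe_feature("B.t1", "GENEB", ctx)))  # no expectation
  # zero observed benign with an expectation present -> 0
  res2 <- list(exp_lof_tx = c(B.t1 = 5))
  ctx2 <- build_training_context(train, gms, res2)
  expect_equal(oe_feature("B.t1", "GENEB", ctx2), 0)

  # monoclass: pathogenic-only transcript/exon flags
  b_sites <- sites[sites$gene_id == "GENEB", ]
  train2 <- data.frame(
    chrom = c(b_sites$chrom[1:2], a_sites$chrom[1:3]),
    pos = c(b_sites$pos[1:2], a_sites$pos[1:3]),
    ref = c(b_sites$ref[1:2], a_sites$ref[1:3]),
    alt = c(b_sites$alt[1:2], a_sites$alt[1:3]),
    zygosity = "het",
    label = c("pathogenic", "pathogenic", "benign", "benign", "pathogenic"),
    stringsAsFactors = FALSE)
  ctx3 <- build_training_context(train2, gms)
  mcB <- monoclass_flags("B.t1", 1L, ctx3)
  expect_equal(mcB$tx_flag, 1)              # 2 pathogenic, 0 benign
  mcA <- monoclass_flags("A.t1", 1L, ctx3)
  expect_equal(mcA$tx_flag, 0)              # pathogenic AND benign present
  expect_equal(monoclass_flags("C.t1", 1L, ctx3)$tx_flag, 0)  # unseen

  # splice-out: GENEA's exon 2 is absent from isoform t2
  tx1 <- gms$transcripts[["A.t1"]]
  exon2_pos <- tx1$cds_pos[tx1$exon_of_cds == 2][1] + 1L
  exon1_pos <- tx1$cds_pos[tx1$exon_of_cds == 1][1] + 1L
  expect_equal(can_be_spliced_out(gms, "GENEA", exon2_pos), 1)
  expect_equal(can_be_spliced_out(gms, "GENEA", exon1_pos), 0)
  expect_equal(can_be_spliced_out(gms, "GENEB", gms$transcripts[["B.t1"]]$cds_pos[5] + 1L), 0)
})

test_that("location, NMD, stop-codon and reinitiation features compute correctly", {
  fx <- fixture_gms()
  gms <- fx$gms
  tx <- gms$transcripts[["A.t1"]]  # 3 exons x 60 bp, CDS 180

  loc <- location_features(tx, 90L)   # middle exon, codon-aligned midpoint
  expect_equal(loc$dist_cds_start, 90L)
  expect_equal(loc$dist_cds_end, 89L)
  expect_equal(loc$relative_cds_location, 0.5)
  expect_equal(loc$exon_number, 2L)
  expect_equal(loc$n_transcript_exons, 3L)
  expect_equal(loc$dist_exon_start, 30L)
  expect_equal(loc$dist_exon_end, 29L)
  expect_equal(loc$exon_length, 60L)
  expect_equal(loc$relative_exon_location, 0.5)
  loc0 <- location_features(tx, 0L)
  expect_equal(loc0$dist_cds_start, 0L)
  expect_equal(loc0$relative_cds_location, 0)

  # NMD: junction at 50 coding bases into a hypothetical, test the rule
  expect_equal(nmd_features(60)$nmd_flag, 1)   # > 50 bp upstream
  expect_equal(nmd_features(50)$nmd_flag, 0)   # strict >
  f <- nmd_features(-10)                        # downstream of junction
  expect_equal(f$nmd_flag, 0)
  expect_equal(f$dist_last_junction, -10)
  expect_equal(nmd_features(NA)$nmd_flag, 0)   # single-exon: no junction

  # the fixture's own junction: last junction of A.t1 sits 120 bases in
  ann <- annotate_stopgains(data.frame(
    chrom = "chr1", pos = tx$cds_pos[91] + 1L,
    ref = substr(fx$cdsA, 91, 91), alt = "X", stringsAsFactors = FALSE), gms)
  # (alt X is invalid; just recompute directly)
  expect_equal(min(which(tx$exon_of_cds == 3)) - 1L, 120L)

  oh <- stop_codon_onehot(c("TGA", "TAG", "TAA"))
  expect_equal(oh$stop_TGA, c(1, 0, 0))
  expect_equal(oh$stop_TAG, c(0, 1, 0))
  expect_equal(oh$stop_TAA, c(0, 0, 1))
  expect_error(stop_codon_onehot("TTT"))

  # reinitiation distance: constructed mRNA with known ATG placement
  cds <- paste0("ATGCCC", "TTTTTTT", "ATG", "CCCCCCCCCCCCCCCCC", "TAA")
  cds <- paste0(cds, paste(rep("C", 3 - nchar(cds) %% 3), collapse = ""))
  gms2 <- make_gms(list(list(tid = "t", gene = "g", chrom = "c", strand = "+",
                             exon_starts = 0, exon_ends = nchar(cds),
                             cds_start = 0, cds_end = nchar(cds))),
                   c(c = cds))
  # ATG begins 7 bases after position 6 (0-based 13); variant at offset 6
  expect_equal(dist_next_start_codon(gms2, "t", 6L), 7)
  # the leading ATG is not downstream of offset 6; none after offset 13
  expect_true(is.na(dist_next_start_codon(gms2, "t", 14L)))
  # nearest of several, against a brute-force string scan
  withr::with_seed(8, {
    for (rep in 1:20) {
      cds3 <- rand_cds(40)
      gms3 <- make_gms(list(list(tid = "t", gene = "g", chrom = "c",
                                 strand = "+", exon_starts = 0,
                                 exon_ends = nchar(cds3),
                                 cds_start = 0, cds_end = nchar(cds3))),
                       c(c = cds3))
      off <- sample(nchar(cds3) - 1L, 1)
      brute <- NA_real_
      for (j in (off + 1):(nchar(cds3) - 3)) {
        if (substr(cds3, j + 1, j + 3) == "ATG") { brute <- j - off; break }
      }
      expect_equal(dist_next_start_codon(gms3, "t", off), brute)
    }
  })
})

test_that("featurize averages transcript-varying features and is pure", {
  fx <- fixture_gms()
  gms <- fx$gms
  tracks <- constant_tracks(gms)
  ctx <- blank_ctx(gms)
  sites <- stopgainr:::enumerate_stopgain_sites(gms)

  # a site in GENEA exon 1 hits both isoforms; relative locations average
  tx1 <- gms$transcripts[["A.t1"]]
  ex1 <- sites[sites$transcript_id == "A.t1" &
                 sites$cds_offset < 60 & sites$cds_offset >= 3, ][1, ]
  v <- data.frame(chrom = ex1$chrom, pos = ex1$pos, ref = ex1$ref,
                  alt = ex1$alt, zygosity = "het", stringsAsFactors = FALSE)
  ft <- featurize(v, gms, ctx, tracks)
  expect_identical(names(ft), as.character(feature_schema()))
  off <- ex1$cds_offset
  expect_equal(ft$relative_cds_location, mean(c(off / 180, off / 120)))
  expect_equal(ft$n_transcript_exons, mean(c(3, 2)))
  expect_equal(ft$stop_TAG + ft$stop_TAA + ft$stop_TGA, 1)
  expect_equal(ft$phyloP_downstream, 2)
  expect_equal(ft$phastCons_exon, 0.5)
  expect_equal(ft$is_chrX, 0)
  expect_equal(ft$zygosity, 0)

  # pct_transcripts_nmd: early GENEA site is >50 bp upstream of the last
  # junction in t1 (junction at 120) and t2 (junction at 60)
  expect_equal(ft$pct_transcripts_nmd,
               100 * mean(c((120 - off) > 50, (60 - off) > 50)))

  # single-transcript variant equals its per-transcript values
  b <- sites[sites$gene_id == "GENEB", ][1, ]
  vb <- data.frame(chrom = b$chrom, pos = b$pos, ref = b$ref, alt = b$alt,
                   zygosity = "hom", stringsAsFactors = FALSE)
  fb <- featurize(vb, gms, ctx, tracks)
  txb <- gms$transcripts[["B.t1"]]
  locb <- location_features(txb, b$cds_offset)
  expect_equal(fb$relative_cds_location, locb$relative_cds_location)
  expect_equal(fb$exon_number, locb$exon_number)
  expect_equal(fb$zygosity, 1)
  expect_equal(fb$dist_next_start_codon,
               dist_next_start_codon(gms, "B.t1", b$cds_offset))

  # chrX flag
  cx <- sites[sites$gene_id == "GENEC", ][1, ]
  fcx <- featurize(data.frame(chrom = cx$chrom, pos = cx$pos, ref = cx$ref,
                              alt = cx$alt, zygosity = "hemi",
                              stringsAsFactors = FALSE), gms, ctx, tracks)
  expect_equal(fcx$is_chrX, 1)
  expect_equal(fcx$zygosity, 1)  # hemizygous counts as homozygous
  expect_true(is.na(fcx$dist_last_junction))  # single exon: no junction
  expect_equal(fcx$pct_transcripts_nmd, 0)

  # purity: repeated calls bit-identical
  expect_identical(featurize(v, gms, ctx, tracks), ft)

  # non-stopgain input is an error
  expect_error(featurize(data.frame(chrom = "chr1", pos = 2, ref = "A",
                                    alt = "T", zygosity = "het"),
                         gms, ctx, tracks),
               "not a stopgain")

  # schema round-trips through TSV serialisation
  p <- tempfile(fileext = ".tsv")
  write_features_tsv(rbind(ft, fb), p)
  back <- read_features_tsv(p)
  expect_equal(as.data.frame(back), as.data.frame(rbind(ft, fb)))
})

test_that("training context built with test variants leaks into features (guard)", {
  # recomputing the context with extra (test) variants must change
  # monoclass/oe outputs, i.e. the pipeline would catch accidental leakage
  fx <- fixture_gms()
  gms <- fx$gms
  sites <- stopgainr:::enumerate_stopgain_sites(gms)
  b <- sites[sites$gene_id == "GENEB", ]
  train <- data.frame(chrom = b$chrom[1], pos = b$pos[1], ref = b$ref[1],
                      alt = b$alt[1], zygosity = "het", label = "pathogenic",
                      stringsAsFactors = FALSE)
  test_extra <- data.frame(chrom = b$chrom[2], pos = b$pos[2], ref = b$ref[2],
                           alt = b$alt[2], zygosity = "het", label = "benign",
                           stringsAsFactors = FALSE)
  res <- list(exp_lof_tx = c(B.t1 = 4))
  ctx_clean <- build_training_context(train, gms, res)
  ctx_leaky <- build_training_context(rbind(train, test_extra), gms, res)
  expect_equal(monoclass_flags("B.t1", 1L, ctx_clean)$tx_flag, 1)
  expect_equal(monoclass_flags("B.t1", 1L, ctx_leaky)$tx_flag, 0)
  expect_lt(oe_feature("B.t1", "GENEB", ctx_clean),
            oe_feature("B.t1", "GENEB", ctx_leaky))
})
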