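# Feature extraction for stopgain variants. The schema is fixed and
# versioned; transcript-varying features are averaged (unweighted) over the
# transcripts in which the variant is a called stopgain, gene- and
# variant-level features are computed once. Missing values stay NA end to
# end — the tree learner routes them, they are never imputed to 0.

FEATURE_SCHEMA_VERSION <- "1"

#' The ordered feature schema
#'
#' @return Character vector of feature names in their fixed, versioned order.
#'   `attr(, "version")` carries the schema version.
#' @export
feature_schema <- function() {
  structure(c(
    "zygosity", "oe", "rvis", "rvis_percentile",
    "omim_recessive", "omim_dominant",
    "monoclass_pathogenic_tx", "monoclass_pathogenic_exon",
    "can_be_spliced_out",
    "dist_cds_start", "dist_cds_end", "relative_cds_location",
    "dist_exon_start", "dist_exon_end", "relative_exon_location",
    "exon_length", "exon_number", "n_transcript_exons",
    "is_chrX", "is_chrY",
    "dist_last_junction", "pct_transcripts_nmd",
    "stop_TAG", "stop_TAA", "stop_TGA",
    "dist_next_start_codon",
    "phyloP_upstream", "phyloP_downstream", "phyloP_exon",
    "phastCons_upstream", "phastCons_downstream", "phastCons_exon"),
    version = FEATURE_SCHEMA_VERSION)
}

#' Read gene-level resource tables
#'
#' Expects TSVs in `dir`: `expected_lof_by_transcript.tsv` (`transcript_id`,
#' `gene_id`, `exp_lof`), `expected_lof_by_gene.tsv` (`gene_id`, `exp_lof`),
#' `rvis.tsv` (`gene_id`, `rvis`, `rvis_percentile`), `omim.tsv` (`gene_id`,
#' `recessive`, `dominant`). Any file may be absent; the corresponding
#' features are then missing.
#' @param dir Directory of resource TSVs.
#' @export
read_resource_tables <- function(dir) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) as.data.frame(data.table::fread(p, sep = "\t")) else NULL
  }
  named <- function(df, key, val) {
    if (is.null(df)) return(numeric(0))
    stats::setNames(as.numeric(df[[val]]), as.character(df[[key]]))
  }
  lof_tx <- rd("expected_lof_by_transcript.tsv")
  lof_gene <- rd("expected_lof_by_gene.tsv")
  rvis <- rd("rvis.tsv")
  omim <- rd("omim.tsv")
  list(exp_lof_tx = named(lof_tx, "transcript_id", "exp_lof"),
       exp_lof_gene = named(lof_gene, "gene_id", "exp_lof"),
       rvis = named(rvis, "gene_id", "rvis"),
       rvis_percentile = named(rvis, "gene_id", "rvis_percentile"),
       omim_recessive = named(omim, "gene_id", "recessive"),
       omim_dominant = named(omim, "gene_id", "dominant"))
}

#' Build the training context
#'
#' Tallies that several features depend on, derived exclusively from the
#' training split (passing test variants here would leak labels into the
#' features): the benign heterozygous allele index used by zygosity
#' imputation, per-gene benign stopgain counts (the `oe` numerator),
#' per-transcript and per-exon pathogenic/benign tallies (the monoclass
#' flags), plus the external gene-level resources.
#'
#' @param train Labelled training `data.frame` (chrom, pos, ref, alt,
#'   zygosity, label).
#' @param gms A `gene_model_set`.
#' @param resources Output of [read_resource_tables()] (or an equivalent
#'   list); may be `NULL`.
#' @return A `training_context`.
#' @export
build_training_context <- function(train, gms, resources = NULL) {
  ann <- annotate_stopgains(train, gms)
  lab <- train$label[ann$variant_row]
  k4 <- variant_key4(ann)
  benign_het <- unique(variant_key4(
    train[train$label == "benign" & train$zygosity == "het", , drop = FALSE]))
  count_by <- function(keys) {
    if (!length(keys)) return(integer(0))
    tb <- table(keys)
    stats::setNames(as.integer(tb), names(tb))
  }
  # one count per distinct (4-tuple, transcript): zygosity twins share a site
  ded_tx <- !duplicated(paste(k4, ann$transcript_id, lab))
  tx_path <- count_by(ann$transcript_id[ded_tx & lab == "pathogenic"])
  tx_benign <- count_by(ann$transcript_id[ded_tx & lab == "benign"])
  exon_key <- paste(ann$transcript_id, ann$exon_index, sep = ":")
  ded_ex <- !duplicated(paste(k4, exon_key, lab))
  exon_path <- count_by(exon_key[ded_ex & lab == "pathogenic"])
  exon_benign <- count_by(exon_key[ded_ex & lab == "benign"])
  # distinct benign sites per gene; a pathogenic zygosity twin at the same
  # locus must not mask the benign observation
  ded_gene <- !duplicated(paste(k4, ann$gene_id, lab))
  gene_benign <- count_by(ann$gene_id[ded_gene & lab == "benign"])
  res <- resources %||% list()
  structure(list(
    benign_het_index = benign_het,
    tx_pathogenic = tx_path, tx_benign = tx_benign,
    exon_pathogenic = exon_path, exon_benign = exon_benign,
    gene_benign_stopgains = gene_benign,
    resources = res,
    schema_version = FEATURE_SCHEMA_VERSION,
    n_train = nrow(train)), class = "training_context")
}

#' @export
print.training_context <- function(x, ...) {
  cat(sprintf("<training_context: %d training variant(s), %d benign het loci>\n",
              x$n_train, length(x$benign_het_index)))
  invisible(x)
}

lookup_or_na <- function(tab, key) {
  if (!length(tab)) return(rep(NA_real_, length(key)))
  unname(tab[key])
}

#' Impute zygosity for variants of unknown zygosity
#'
#' Clinical databases often omit zygosity. The heuristic: if the training
#' set's benign index contains a heterozygous allele at the same
#' (chrom, pos, ref, alt) — i.e. healthy carriers exist, so the disease
#' allele must act recessively — predict homozygous (1); otherwise predict
#' heterozygous (0). Known zygosity must be passed through upstream, not
#' through this function.
#'
#' @param chrom,pos,ref,alt Vectors identifying the loci.
#' @param ctx A `training_context`.
#' @return Numeric vector, 1 = hom, 0 = het.
#' @export
impute_zygosity <- function(chrom, pos, ref, alt, ctx) {
  key <- paste(chrom, pos, ref, alt, sep = ":")
  as.numeric(key %in% ctx$benign_het_index)
}

zygosity_feature <- function(variants, ctx) {
  z <- variants$zygosity
  out <- ifelse(z %in% c("hom", "hemi"), 1, ifelse(z == "het", 0, NA))
  unk <- is.na(out)
  if (any(unk))
    out[unk] <- impute_zygosity(variants$chrom[unk], variants$pos[unk],
                                variants$ref[unk], variants$alt[unk], ctx)
  out
}

#' Stopgain observed/expected ratio for a transcript's gene
#'
#' Benign training stopgains along the gene divided by the expected number
#' of loss-of-function variants (per-transcript table with per-gene
#' fallback). Missing or zero expectation yields `NA`.
#' @param tx_id,gene_id Identifiers.
#' @param ctx A `training_context`.
#' @export
oe_feature <- function(tx_id, gene_id, ctx) {
  expd <- lookup_or_na(ctx$resources$exp_lof_tx, tx_id)
  fb <- is.na(expd)
  if (any(fb))
    expd[fb] <- lookup_or_na(ctx$resources$exp_lof_gene, gene_id[fb])
  obs <- lookup_or_na(ctx$gene_benign_stopgains, gene_id)
  obs[is.na(obs)] <- 0
  ifelse(is.na(expd) | expd <= 0, NA_real_, obs / expd)
}

#' Monoclass-pathogenic flags
#'
#' A transcript (resp. exon) is monoclass pathogenic when the training set
#' contains at least one pathogenic variant and no benign variant on it.
#' Unseen transcripts/exons are 0: absence of evidence is not evidence of
#' intolerance.
#' @param tx_id Transcript id(s).
#' @param exon_index 1-based exon index (transcription order).
#' @param ctx A `training_context`.
#' @return List with numeric vectors `tx_flag`, `exon_flag`.
#' @export
monoclass_flags <- function(tx_id, exon_index, ctx) {
  cnt <- function(tab, key) {
    v <- lookup_or_na(tab, key)
    ifelse(is.na(v), 0, v)
  }
  tx_flag <- as.numeric(cnt(ctx$tx_pathogenic, tx_id) >= 1 &
                        cnt(ctx$tx_benign, tx_id) == 0)
  ek <- paste(tx_id, exon_index, sep = ":")
  exon_flag <- as.numeric(cnt(ctx$exon_pathogenic, ek) >= 1 &
                          cnt(ctx$exon_benign, ek) == 0)
  list(tx_flag = tx_flag, exon_flag = exon_flag)
}

#' Can the variant be spliced out?
#'
#' 1 when at least one coding isoform of the gene does not include the
#' variant position in its CDS (the transcript pool offers an escape route).
#' @param gms A `gene_model_set`.
#' @param gene_id Gene identifier.
#' @param pos 1-based genomic position.
#' @export
can_be_spliced_out <- function(gms, gene_id, pos) {
  gene <- gms$genes[[gene_id]]
  if (is.null(gene)) return(NA_real_)
  pos0 <- pos - 1L
  txs <- Filter(function(t) t$coding,
                gms$transcripts[gene$transcript_ids])
  if (!length(txs)) return(NA_real_)
  skipped <- vapply(txs, function(tx) !(pos0 %in% tx$cds_pos), TRUE)
  as.numeric(any(skipped))
}

exon_offset_table <- function(tx) {
  # first/last CDS offset and genomic length per transcription-order exon
  idx <- tx$exon_of_cds
  ex <- sort(unique(idx))
  first <- vapply(ex, function(e) min(which(idx == e)) - 1L, 1L)
  last <- vapply(ex, function(e) max(which(idx == e)) - 1L, 1L)
  gi <- if (tx$strand == "+") ex else tx$n_exons + 1L - ex
  len <- tx$exon_ends[gi] - tx$exon_starts[gi]
  list(exon = ex, first = stats::setNames(first, ex),
       last = stats::setNames(last, ex), length = stats::setNames(len, ex))
}

#' Variant-location features within one transcript
#'
#' Distances in coding nucleotides; relative locations in `[0, 1]`; exon
#' index 1-based in transcription order.
#' @param tx A `transcript_model`.
#' @param cds_offset 0-based CDS offset.
#' @export
location_features <- function(tx, cds_offset) {
  et <- exon_offset_table(tx)
  ex <- tx$exon_of_cds[cds_offset + 1L]
  k <- as.character(ex)
  des <- cds_offset - et$first[[k]]
  list(dist_cds_start = cds_offset,
       dist_cds_end = tx$cds_len - 1L - cds_offset,
       relative_cds_location = cds_offset / tx$cds_len,
       dist_exon_start = des,
       dist_exon_end = et$last[[k]] - cds_offset,
       relative_exon_location = des / et$length[[k]],
       exon_length = et$length[[k]],
       exon_number = ex,
       n_transcript_exons = tx$n_exons)
}

#' NMD features from the junction distance
#'
#' A premature stop more than 50 coding bases upstream of the last exon-exon
#' junction is predicted to trigger nonsense-mediated decay (strict `> 50`).
#' Single-coding-exon transcripts have no junction: distance missing, flag 0.
#' @param dist_last_junction Signed bp (positive = upstream of the junction).
#' @return List with `dist_last_junction`, `nmd_flag`.
#' @export
nmd_features <- function(dist_last_junction) {
  list(dist_last_junction = dist_last_junction,
       nmd_flag = as.numeric(!is.na(dist_last_junction) &
                             dist_last_junction > 50))
}

#' One-hot encoding of the introduced stop codon
#' @param new_stop_codon `"TAG"`, `"TAA"` or `"TGA"`.
#' @export
stop_codon_onehot <- function(new_stop_codon) {
  stopifnot(all(new_stop_codon %in% STOP_CODONS))
  list(stop_TAG = as.numeric(new_stop_codon == "TAG"),
       stop_TAA = as.numeric(new_stop_codon == "TAA"),
       stop_TGA = as.numeric(new_stop_codon == "TGA"))
}

tx_atg_starts <- function(gms, tx_id) {
  key <- paste0("atg:", tx_id)
  if (!is.null(gms$cache[[key]])) return(gms$cache[[key]])
  seq <- transcript_cds_seq(gms, tx_id)
  m <- gregexpr("ATG", seq, fixed = TRUE)[[1L]]
  starts <- if (m[1L] == -1L) integer(0) else as.integer(m) - 1L  # 0-based
  gms$cache[[key]] <- starts
  starts
}

#' Distance to the next potential downstream start codon
#'
#' Scans the spliced mRNA strictly 3' of the variant for the nearest ATG in
#' any reading frame (translation reinitiation does not preserve the
#' original frame); returns the distance in mRNA bases from the variant to
#' the A, or `NA` when no downstream ATG exists.
#' @param gms A `gene_model_set`.
#' @param tx_id Transcript id.
#' @param cds_offset 0-based CDS offset of the variant.
#' @param in_frame_only Restrict to ATGs in the original reading frame.
#' @export
dist_next_start_codon <- function(gms, tx_id, cds_offset,
                                  in_frame_only = FALSE) {
  starts <- tx_atg_starts(gms, tx_id)
  if (in_frame_only) starts <- starts[starts %% 3L == 0L]
  starts <- starts[starts > cds_offset]
  if (!length(starts)) NA_real_ else as.numeric(starts[1L] - cds_offset)
}

#' Conservation features for one annotation
#'
#' Delegates to [region_mean_conservation()] for each (track, region) pair.
#' @param tx A `transcript_model`.
#' @param cds_offset 0-based offset.
#' @param phyloP,phastCons `conservation_track`s.
#' @export
conservation_features <- function(tx, cds_offset, phyloP, phastCons) {
  out <- list()
  for (nm in c("upstream", "downstream", "exon")) {
    region <- if (nm == "exon") "overlapped_exon" else nm
    out[[paste0("phyloP_", nm)]] <-
      region_mean_conservation(phyloP, tx, region, cds_offset)
    out[[paste0("phastCons_", nm)]] <-
      region_mean_conservation(phastCons, tx, region, cds_offset)
  }
  out
}

# All transcript-varying features for one annotation row (reference
# semantics; featurize() reproduces these vectorised).
per_transcript_features <- function(gms, ctx, tracks, tx_id, gene_id,
                                    cds_offset, new_stop_codon,
                                    dist_last_junction) {
  tx <- gms$transcripts[[tx_id]]
  mc <- monoclass_flags(tx_id, tx$exon_of_cds[cds_offset + 1L], ctx)
  c(list(oe = oe_feature(tx_id, gene_id, ctx),
         monoclass_pathogenic_tx = mc$tx_flag,
         monoclass_pathogenic_exon = mc$exon_flag),
    location_features(tx, cds_offset),
    nmd_features(dist_last_junction),
    stop_codon_onehot(new_stop_codon),
    list(dist_next_start_codon = dist_next_start_codon(gms, tx_id, cds_offset)),
    conservation_features(tx, cds_offset, tracks$phyloP, tracks$phastCons))
}

#' Compute the full feature matrix for stopgain variants
#'
#' Transcript-varying features are averaged (unweighted, missing values
#' excluded) over the transcripts in which each variant is a called
#' stopgain; `pct_transcripts_nmd` is the percentage of those transcripts
#' predicted to trigger NMD; gene-level features are averaged over the
#' distinct genes hit; zygosity and chromosome class are variant-level.
#'
#' @param variants `data.frame` with chrom, pos, ref, alt, zygosity.
#' @param gms A `gene_model_set`.
#' @param ctx A `training_context`.
#' @param tracks List with `phyloP` and `phastCons` `conservation_track`s.
#' @return `data.frame`, one row per input variant, columns exactly
#'   [feature_schema()]; `attr(, "schema_version")` set. Errors if any
#'   variant is not a stopgain in at least one transcript.
#' @export
featurize <- function(variants, gms, ctx, tracks) {
  stopifnot(inherits(ctx, "training_context"),
            all(c("phyloP", "phastCons") %in% names(tracks)))
  ann <- annotate_stopgains(variants, gms)
  missing_rows <- setdiff(seq_len(nrow(variants)), unique(ann$variant_row))
  if (length(missing_rows))
    stop("variant(s) not a stopgain in any coding transcript: row(s) ",
         paste(utils::head(missing_rows, 5L), collapse = ", "))
  per_tx <- vector("list", 0L)
  for (tid in unique(ann$transcript_id)) {
    tx <- gms$transcripts[[tid]]
    sel <- ann$transcript_id == tid
    off <- ann$cds_offset[sel]
    et <- exon_offset_table(tx)
    ex <- tx$exon_of_cds[off + 1L]
    k <- as.character(ex)
    boundary <- 3L * (off %/% 3L)
    # O(1) regional means via cumulative sums over the spliced CDS
    cons <- lapply(tracks, function(trk) {
      v <- track_values(trk, tx$chrom, tx$cds_pos)
      list(s = c(0, cumsum(ifelse(is.na(v), 0, v))),
           n = c(0, cumsum(!is.na(v))))
    })
    reg_mean <- function(cs, from, to) {  # offsets [from, to), 0-based
      s <- cs$s[to + 1L] - cs$s[from + 1L]
      n <- cs$n[to + 1L] - cs$n[from + 1L]
      ifelse(n > 0, s / n, NA_real_)
    }
    exon_means <- lapply(tracks, function(trk) {
      stats::setNames(vapply(et$exon, function(e) {
        gi <- if (tx$strand == "+") e else tx$n_exons + 1L - e
        v <- track_values(trk, tx$chrom,
                          seq.int(tx$exon_starts[gi], tx$exon_ends[gi] - 1L))
        if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
      }, 0), et$exon)
    })
    atg <- tx_atg_starts(gms, tid)
    datg <- if (!length(atg)) rep(NA_real_, sum(sel)) else {
      natg <- findInterval(off, atg) + 1L  # first ATG strictly 3' of offset
      ifelse(natg <= length(atg), atg[pmin(natg, length(atg))] - off, NA_real_)
    }
    mc <- monoclass_flags(rep(tid, sum(sel)), ex, ctx)
    dlj <- ann$dist_last_junction[sel]
    per_tx[[length(per_tx) + 1L]] <- data.frame(
      variant_row = ann$variant_row[sel],
      oe = oe_feature(rep(tid, sum(sel)), rep(tx$gene_id, sum(sel)), ctx),
      monoclass_pathogenic_tx = mc$tx_flag,
      monoclass_pathogenic_exon = mc$exon_flag,
      dist_cds_start = off,
      dist_cds_end = tx$cds_len - 1L - off,
      relative_cds_location = off / tx$cds_len,
      dist_exon_start = off - unname(et$first[k]),
      dist_exon_end = unname(et$last[k]) - off,
      relative_exon_location = (off - unname(et$first[k])) / unname(et$length[k]),
      exon_length = unname(et$length[k]),
      exon_number = ex,
      n_transcript_exons = tx$n_exons,
      dist_last_junction = as.numeric(dlj),
      nmd_flag = as.numeric(!is.na(dlj) & dlj > 50),
      stop_TAG = as.numeric(ann$new_stop_codon[sel] == "TAG"),
      stop_TAA = as.numeric(ann$new_stop_codon[sel] == "TAA"),
      stop_TGA = as.numeric(ann$new_stop_codon[sel] == "TGA"),
      dist_next_start_codon = datg,
      phyloP_upstream = reg_mean(cons$phyloP, 0L, boundary),
      phyloP_downstream = reg_mean(cons$phyloP, boundary, tx$cds_len),
      phyloP_exon = unname(exon_means$phyloP[k]),
      phastCons_upstream = reg_mean(cons$phastCons, 0L, boundary),
      phastCons_downstream = reg_mean(cons$phastCons, boundary, tx$cds_len),
      phastCons_exon = unname(exon_means$phastCons[k]))
  }
  per_tx <- data.table::rbindlist(per_tx)
  agg <- per_tx[, lapply(.SD, function(x) {
    m <- mean(x, na.rm = TRUE)
    if (is.nan(m)) NA_real_ else m
  }), by = "variant_row"]
  pct <- per_tx[, list(pct_transcripts_nmd = 100 * mean(nmd_flag)),
                by = "variant_row"]
  agg <- merge(agg, pct, by = "variant_row")
  data.table::setorder(agg, variant_row)
  stopifnot(identical(agg$variant_row, seq_len(nrow(variants))))

  # gene-level features, averaged over distinct genes hit
  res <- ctx$resources
  gene_feats <- t(vapply(seq_len(nrow(variants)), function(i) {
    gids <- unique(ann$gene_id[ann$variant_row == i])
    avg <- function(tab) {
      v <- lookup_or_na(tab, gids)
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }
    c(rvis = avg(res$rvis),
      rvis_percentile = avg(res$rvis_percentile),
      omim_recessive = avg(res$omim_recessive),
      omim_dominant = avg(res$omim_dominant),
      can_be_spliced_out = max(vapply(gids, function(g)
        can_be_spliced_out(gms, g, variants$pos[i]), 0)))
  }, numeric(5)))

  out <- data.frame(
    zygosity = zygosity_feature(variants, ctx),
    oe = agg$oe, rvis = gene_feats[, "rvis"],
    rvis_percentile = gene_feats[, "rvis_percentile"],
    omim_recessive = gene_feats[, "omim_recessive"],
    omim_dominant = gene_feats[, "omim_dominant"],
    monoclass_pathogenic_tx = agg$monoclass_pathogenic_tx,
    monoclass_pathogenic_exon = agg$monoclass_pathogenic_exon,
    can_be_spliced_out = gene_feats[, "can_be_spliced_out"],
    dist_cds_start = agg$dist_cds_start, dist_cds_end = agg$dist_cds_end,
    relative_cds_location = agg$relative_cds_location,
    dist_exon_start = agg$dist_exon_start, dist_exon_end = agg$dist_exon_end,
    relative_exon_location = agg$relative_exon_location,
    exon_length = agg$exon_length, exon_number = agg$exon_number,
    n_transcript_exons = agg$n_transcript_exons,
    is_chrX = as.numeric(chrom_class(variants$chrom) == "X"),
    is_chrY = as.numeric(chrom_class(variants$chrom) == "Y"),
    dist_last_junction = agg$dist_last_junction,
    pct_transcripts_nmd = agg$pct_transcripts_nmd,
    stop_TAG = agg$stop_TAG, stop_TAA = agg$stop_TAA, stop_TGA = agg$stop_TGA,
    dist_next_start_codon = agg$dist_next_start_codon,
    phyloP_upstream = agg$phyloP_upstream,
    phyloP_downstream = agg$phyloP_downstream,
    phyloP_exon = agg$phyloP_exon,
    phastCons_upstream = agg$phastCons_upstream,
    phastCons_downstream = agg$phastCons_downstream,
    phastCons_exon = agg$phastCons_exon,
    row.names = NULL)
  stopifnot(identical(names(out), as.character(feature_schema())))
  attr(out, "schema_version") <- FEATURE_SCHEMA_VERSION
  out
}

#' Feature table as a numeric matrix
#' @param features Output of [featurize()].
#' @export
features_to_matrix <- function(features) {
  m <- as.matrix(features)
  storage.mode(m) <- "double"
  m
}

#' Write / read a feature matrix TSV (header = schema)
#' @param features Feature `data.frame`; `path` file path.
#' @export
write_features_tsv <- function(features, path) {
  data.table::fwrite(features, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_features_tsv
#' @export
read_features_tsv <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                        na.strings = "NA"))
  df[] <- lapply(df, as.numeric)  # all-NA columns parse as logical
  stopifnot(identical(names(df), as.character(feature_schema())))
  attr(df, "schema_version") <- FEATURE_SCHEMA_VERSION
  df
}
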