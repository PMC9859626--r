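## End-to-end calling: read filters -> SNV candidates (LOD) -> indel and
## complex candidates -> paired cascade -> duplicate-collapsed
## quantification -> filter ledger -> origin -> sorted records.

as_ref_funs <- function(ref, contigs) {
  if (is.function(ref)) return(setNames(rep(list(ref), length(contigs)),
                                        contigs))
  if (is.character(ref)) {
    if (is.null(names(ref)) && length(ref) == 1L && length(contigs) == 1L)
      names(ref) <- contigs
    return(lapply(setNames(names(ref), names(ref)),
                  function(ct) ref_accessor(ref[[ct]])))
  }
  stopifnot(is.list(ref), !is.null(names(ref)))
  ref
}

## unique per-alignment read id (mates and PCR copies get distinct ids)
with_rid <- function(reads) {
  reads <- copy(as.data.table(reads))
  if (!"orig_qname" %in% names(reads)) {
    reads[, orig_qname := qname]
    reads[, qname := paste0(qname, ".", seq_len(.N))]
  }
  reads
}

## when overlapping mates should count once, keep the higher-quality
## observation of each (site, fragment) pair
dedupe_overlapping_mates <- function(obs, reads) {
  if (!"orig_qname" %in% names(reads)) return(obs)
  obs <- copy(obs)
  obs[reads, on = "qname", orig_qname := i.orig_qname]
  setorder(obs, pos, orig_qname, -qual)
  obs <- obs[!duplicated(obs, by = c("pos", "orig_qname"))]
  obs[, orig_qname := NULL]
  setkey(obs, pos)
  obs[]
}

## per-site group statistics for a single-base allele
site_group_stats <- function(base_obs, pos_, alt_, config) {
  at <- base_obs[pos == pos_]
  if (nrow(at) == 0L)
    return(list(support = 0L, depth = 0L, vaf = NA_real_,
                single_strand = FALSE, reps = NULL,
                support_reads = character(0), site_bq = NA_integer_,
                strand_plus = 0L, strand_minus = 0L))
  per_grp <- at[, .(n_alt = sum(allele == alt_), n_tot = .N,
                    strand = strand[1]),
                by = grp]
  per_grp[, frac := n_alt / n_tot]
  supp <- per_grp[frac > config$dup_support_fraction]
  alt_obs <- at[allele == alt_]
  reps <- collapse_site_obs(at)
  list(
    support = nrow(supp),
    depth = nrow(per_grp),
    vaf = 100 * nrow(supp) / nrow(per_grp),
    single_strand = nrow(alt_obs) > 0L &&
      length(unique(alt_obs$strand)) == 1L,
    reps = reps,
    support_reads = unique(alt_obs$qname),
    site_bq = if (nrow(alt_obs)) max(alt_obs$qual) else NA_integer_,
    strand_plus = sum(supp$strand == "+"),
    strand_minus = sum(supp$strand == "-")
  )
}

## normalized per-read indel/complex alleles for every read carrying events
per_read_alleles <- function(reads, obs, ref_fun, config) {
  ev <- extract_indel_events(reads, config)
  empty <- data.table(qname = character(), contig = character(),
                      pos = integer(), ref = character(),
                      alt = character(), vtype = character(),
                      span_start = integer(), span_end = integer(),
                      site_qual = integer())
  if (nrow(ev) == 0L) return(empty)
  base_obs <- obs[allele %chin% c("A", "C", "G", "T")]
  if (nrow(base_obs)) {
    rng <- range(base_obs$pos)
    refvec <- strsplit(ref_fun(rng[1], rng[2] + 1L), "")[[1]]
    mism <- base_obs[allele != refvec[pos - rng[1] + 1L]]
  } else mism <- base_obs
  out <- vector("list", 0L)
  for (rid in unique(ev$qname)) {
    rd <- reads[qname == rid]
    al <- merge_same_read_events(ev[qname == rid],
                                 mism[qname == rid, .(pos, alt = allele)],
                                 rd[1L], ref_fun, config)
    if (nrow(al) == 0L) next
    al[, qname := rid]
    out[[length(out) + 1L]] <- al
  }
  if (length(out) == 0L) return(empty)
  al <- rbindlist(out, use.names = TRUE)
  for (i in seq_len(nrow(al))) {
    nv <- tryCatch(normalize_variant(al$pos[i], al$ref[i], al$alt[i],
                                     ref_fun, check = FALSE),
                   error = function(e) NULL)
    if (is.null(nv)) { set(al, i, "vtype", NA_character_); next }
    set(al, i, "pos", nv$pos); set(al, i, "ref", nv$ref)
    set(al, i, "alt", nv$alt); set(al, i, "vtype", nv$vtype)
  }
  al[!is.na(vtype)]
}

## eligible duplicate groups spanning [s, e) on the reference
spanning_groups <- function(groups, s, e) {
  groups[groups$start <= s & groups$end >= e]
}

indel_requirement_span <- function(pos, ref, vtype) {
  w <- max(nchar(ref), 1L)
  if (vtype == "insertion") w <- w + 1L
  c(pos, pos + w)
}

## evidence for a normalized indel/complex allele in one read set
indel_evidence <- function(alleles, groups, reads, base_obs, key_pos,
                           key_ref, key_alt, key_vtype, config) {
  req <- indel_requirement_span(key_pos, key_ref, key_vtype)
  elig <- spanning_groups(groups, req[1], req[2])
  if (nrow(elig) == 0L)
    return(list(support = 0L, depth = 0L, vaf = NA_real_,
                single_strand = FALSE, obs = NULL,
                support_reads = character(0)))
  hit <- alleles[pos == key_pos & ref == key_ref & alt == key_alt]
  sup_reads <- unique(hit$qname)
  g <- reads[, .(qname, dup_grp, strand)]
  g <- g[dup_grp %in% elig$dup_grp]
  g[, is_alt := qname %chin% sup_reads]
  per_grp <- g[, .(frac = mean(is_alt), n = .N, strand = strand[1]),
               by = dup_grp]
  supp <- per_grp[frac > config$dup_support_fraction]
  ## indicator observations (one per eligible group) for a normal-side LOD
  at <- base_obs[pos == key_pos]
  qmax <- if (nrow(at)) at[, .(q = max(qual)), by = .(grp)] else
    data.table(grp = integer(), q = integer())
  per_grp[qmax, on = c(dup_grp = "grp"), q := i.q]
  per_grp[is.na(q), q := 30L]
  list(
    support = nrow(supp),
    depth = nrow(per_grp),
    vaf = 100 * nrow(supp) / nrow(per_grp),
    single_strand = nrow(supp) > 0L && length(unique(supp$strand)) == 1L,
    obs = data.table(is_alt = per_grp$frac > config$dup_support_fraction,
                     is_ref = !(per_grp$frac > config$dup_support_fraction),
                     qual = per_grp$q),
    support_reads = sup_reads
  )
}

empty_calls <- function() {
  data.table(contig = character(), pos = integer(), ref = character(),
             alt = character(), vtype = character(),
             tumor_support = integer(), tumor_depth = integer(),
             vaf_tumor = numeric(), lod_tumor = numeric(),
             site_bq = integer(), strand_plus = integer(),
             strand_minus = integer(), normal_support = integer(),
             normal_depth = integer(), vaf_normal = numeric(),
             lod_normal = numeric(), fet_p = numeric(),
             path_taken = character(), support_reads = list())
}

call_region <- function(tumor_reads, normal_reads, ref_fun, region,
                        config, pad = NULL) {
  ## pad so every read overlapping the region lies entirely inside the
  ## working window: per-read statistics (mismatch counts, same-read
  ## merging) must not depend on how regions were chunked
  if (is.null(pad)) {
    spans <- c(tumor_reads$end - tumor_reads$pos,
               if (!is.null(normal_reads))
                 normal_reads$end - normal_reads$pos, 0L)
    pad <- max(spans) + 10L
  }
  ext <- list(contig = region$contig,
              start = max(region$start - pad, 0L),
              end = region$end + pad)
  rr <- group_duplicates(with_rid(tumor_reads))
  groups_t <- attr(rr, "groups")
  obs <- build_pileup(rr, ext, config)
  if (!config$count_overlapping_mates)
    obs <- dedupe_overlapping_mates(obs, rr)
  paired <- !is.null(normal_reads)
  if (paired) {
    rn <- group_duplicates(with_rid(normal_reads))
    groups_n <- attr(rn, "groups")
    obs_n <- build_pileup(rn, ext, config)
    if (!config$count_overlapping_mates)
      obs_n <- dedupe_overlapping_mates(obs_n, rn)
    obs_n[rn, on = "qname", grp := i.dup_grp]
    base_obs_n <- obs_n[allele %chin% c("A", "C", "G", "T")]
  }

  ## ---- SNV candidates -----------------------------------------------------
  mm <- read_mismatch_counts(obs, ref_fun)
  hyper <- mm[mm$mismatches >= config$max_mismatches_per_read, qname]
  snv_obs <- obs[!qname %chin% hyper]
  snv_obs[rr, on = "qname", grp := i.dup_grp]
  in_region <- snv_obs[pos >= region$start & pos < region$end]
  base_obs <- in_region[allele %chin% c("A", "C", "G", "T")]
  snv_cand <- empty_calls()
  if (nrow(base_obs)) {
    rng <- range(base_obs$pos)
    refvec <- strsplit(ref_fun(rng[1], rng[2] + 1L), "")[[1]]
    base_obs[, ref := refvec[pos - rng[1] + 1L]]
    site_all <- in_region  # includes indel tokens for depth
    grp_stats <- site_all[, .(n_tot = .N), by = .(pos, grp)]
    alt_cnt <- base_obs[allele != ref,
                        .(n_alt = .N, site_bq = max(qual),
                          support_reads = list(unique(qname))),
                        by = .(pos, allele, ref)]
    if (nrow(alt_cnt)) {
      per_pg <- base_obs[allele != ref, .(n_alt = .N),
                         by = .(pos, grp, allele)]
      per_pg[grp_stats, on = .(pos, grp), n_tot := i.n_tot]
      per_pg[, frac := n_alt / n_tot]
      sup <- per_pg[frac > config$dup_support_fraction,
                    .(support = .N), by = .(pos, allele)]
      depth_tab <- grp_stats[, .(depth = .N), by = pos]
      cand <- merge(alt_cnt, sup, by = c("pos", "allele"), all.x = TRUE)
      cand[is.na(support), support := 0L]
      cand[depth_tab, on = "pos", depth := i.depth]
      cand <- cand[support >= 1L & n_alt >= 2L]
      if (nrow(cand)) {
        cand[, f_hat := support / depth]
        ## duplicate-collapsed representatives once per site
        reps <- collapse_site_obs(site_all[pos %in% unique(cand$pos)])
        lodv <- numeric(nrow(cand))
        for (i in seq_len(nrow(cand))) {
          rp <- reps[pos == cand$pos[i]]
          lodv[i] <- lod_from_indicators(rp$allele == cand$allele[i],
                                         rp$allele == cand$ref[i],
                                         rp$rep_qual, cand$f_hat[i])
        }
        cand[, lod := lodv]
        cand <- cand[lod >= config$lod_threshold]
        if (nrow(cand)) {
          strands <- per_pg[frac > config$dup_support_fraction]
          strands[rr[, .(dup_grp, strand)][!duplicated(dup_grp)],
                  on = c(grp = "dup_grp"), strand := i.strand]
          sp <- strands[, .(p = sum(strand == "+"), m = sum(strand == "-")),
                        by = .(pos, allele)]
          cand[sp, on = c("pos", "allele"), `:=`(strand_plus = i.p,
                                                 strand_minus = i.m)]
          snv_cand <- data.table(
            contig = region$contig, pos = cand$pos, ref = cand$ref,
            alt = cand$allele, vtype = "SNV",
            tumor_support = cand$support, tumor_depth = cand$depth,
            vaf_tumor = 100 * cand$support / cand$depth,
            lod_tumor = cand$lod, site_bq = cand$site_bq,
            strand_plus = cand$strand_plus,
            strand_minus = cand$strand_minus,
            normal_support = NA_integer_, normal_depth = NA_integer_,
            vaf_normal = NA_real_, lod_normal = NA_real_,
            fet_p = NA_real_, path_taken = NA_character_,
            support_reads = cand$support_reads)
        }
      }
    }
  }

  ## ---- indel / complex candidates ----------------------------------------
  alleles <- per_read_alleles(rr, obs, ref_fun, config)
  indel_cand <- empty_calls()
  if (nrow(alleles)) {
    alleles <- alleles[span_start >= region$start & span_start < region$end]
  }
  if (nrow(alleles)) {
    keys <- unique(alleles[, .(contig, pos, ref, alt, vtype)])
    rows <- vector("list", 0L)
    if (paired) alleles_n <- per_read_alleles(rn, obs_n, ref_fun, config)
    for (i in seq_len(nrow(keys))) {
      k <- keys[i]
      evd <- indel_evidence(alleles, groups_t, rr,
                            base_obs = if (nrow(base_obs)) base_obs else
                              data.table(pos = integer(), qual = integer(),
                                         grp = integer()),
                            k$pos, k$ref, k$alt, k$vtype, config)
      if (evd$depth == 0L || evd$support == 0L) next
      sq <- alleles[pos == k$pos & ref == k$ref & alt == k$alt,
                    max(site_qual)]
      rows[[length(rows) + 1L]] <- data.table(
        contig = k$contig, pos = k$pos, ref = k$ref, alt = k$alt,
        vtype = k$vtype, tumor_support = evd$support,
        tumor_depth = evd$depth, vaf_tumor = evd$vaf,
        lod_tumor = NA_real_, site_bq = as.integer(sq),
        strand_plus = sum(rr[qname %chin% evd$support_reads,
                             strand[1], by = dup_grp]$V1 == "+"),
        strand_minus = sum(rr[qname %chin% evd$support_reads,
                              strand[1], by = dup_grp]$V1 == "-"),
        normal_support = NA_integer_, normal_depth = NA_integer_,
        vaf_normal = NA_real_, lod_normal = NA_real_, fet_p = NA_real_,
        path_taken = NA_character_,
        support_reads = list(evd$support_reads))
    }
    if (length(rows)) indel_cand <- rbindlist(rows)
  }

  ## ---- paired cascade -----------------------------------------------------
  if (paired) {
    classify_one <- function(cnd) {
      if (cnd$vtype == "SNV") {
        ev <- site_group_stats(base_obs_n, cnd$pos, cnd$alt, config)
        nobs <- if (is.null(ev$reps)) NULL else
          data.table(is_alt = ev$reps$allele == cnd$alt,
                     is_ref = ev$reps$allele == cnd$ref,
                     qual = ev$reps$rep_qual)
      } else {
        ev <- indel_evidence(alleles_n, groups_n, rn, base_obs_n,
                             cnd$pos, cnd$ref, cnd$alt, cnd$vtype, config)
        nobs <- ev$obs
      }
      nvaf <- if (is.na(ev$vaf)) 0 else ev$vaf
      dec <- classify_paired(cnd$vaf_tumor, cnd$tumor_support,
                             cnd$tumor_depth, nvaf, ev$support, ev$depth,
                             ev$single_strand, nobs, config)
      list(dec = dec, ev = ev)
    }
    annotate <- function(cands) {
      if (nrow(cands) == 0L) return(cands)
      keep <- logical(nrow(cands))
      for (i in seq_len(nrow(cands))) {
        res <- classify_one(cands[i])
        keep[i] <- res$dec$emit
        set(cands, i, "normal_support", as.integer(res$ev$support))
        set(cands, i, "normal_depth", as.integer(res$ev$depth))
        set(cands, i, "vaf_normal",
            if (is.na(res$ev$vaf)) 0 else res$ev$vaf)
        set(cands, i, "lod_normal", res$dec$lod_normal)
        set(cands, i, "fet_p", res$dec$fet_p)
        set(cands, i, "path_taken", res$dec$path_taken)
      }
      cands[keep]
    }
    snv_cand <- annotate(snv_cand)
    indel_cand <- annotate(indel_cand)
  }

  rbindlist(list(snv_cand, indel_cand), use.names = TRUE, fill = TRUE)
}

## drop per-site SNV candidates whose supporting reads mostly carry an
## emitted complex allele spanning the site (the SNV is part of the
## complex, not a separate variant)
suppress_absorbed_snvs <- function(calls, config) {
  snv <- which(calls$vtype == "SNV")
  cx <- which(calls$vtype %in% c("complex", "deletion", "insertion") &
              calls$tumor_support >= config$min_support_reads)
  if (length(snv) == 0L || length(cx) == 0L) return(calls)
  drop <- rep(FALSE, nrow(calls))
  for (i in snv) {
    p <- calls$pos[i]
    sr <- calls$support_reads[[i]]
    for (j in cx) {
      if (calls$contig[j] != calls$contig[i]) next
      if (p >= calls$pos[j] &&
          p < calls$pos[j] + max(nchar(calls$ref[j]), 1L)) {
        ov <- length(intersect(sr, calls$support_reads[[j]]))
        if (length(sr) > 0L && ov >= 0.5 * length(sr)) {
          drop[i] <- TRUE
          break
        }
      }
    }
  }
  calls[!drop]
}

#' Call variants from in-memory reads
#'
#' The full calling cascade on read tables, without file I/O: read-level
#' filters, LOD-scored SNV candidates (with hypermutated-read removal and
#' same-read substitution merging), CIGAR-derived indel and complex
#' candidates (same-read gap/SNV merging), the tumor-normal cascade when
#' `normal_reads` is given, duplicate-collapsed quantification, the filter
#' ledger, and origin classification (tumor-only).
#'
#' @param tumor_reads,normal_reads Read tables ([read_records()]);
#'   `normal_reads = NULL` selects tumor-only mode.
#' @param ref Reference: named character vector of contig sequences, a
#'   single string (one contig), or a named list of accessors.
#' @param regs Region table ([regions()]/[load_regions()]).
#' @param config A [caller_config()].
#' @param population,hotspots Optional site lists ([load_site_table()])
#'   for tumor-only origin classification.
#' @param n_chunks Number of region chunks to process (result is invariant
#'   to this; defaults to `config$threads`).
#' @return A `data.table` of calls (`pos` 0-based; use [write_vcf()] or
#'   [write_report_tsv()] for 1-based output), PASS-only unless
#'   `config$emit_all`.
#' @export
call_from_reads <- function(tumor_reads, normal_reads = NULL, ref, regs,
                            config = caller_config(), population = NULL,
                            hotspots = NULL, n_chunks = NULL) {
  config <- as_config(config)
  regs <- as.data.table(regs)
  ref_funs <- as_ref_funs(ref, unique(regs$contig))
  n_chunks <- n_chunks %||% config$threads
  tumor_reads <- passes_read_filters(as.data.table(tumor_reads), regs,
                                     config)
  if (!is.null(normal_reads))
    normal_reads <- passes_read_filters(as.data.table(normal_reads), regs,
                                        config)
  chunks <- split_regions(regs, n_chunks)
  parts <- vector("list", 0L)
  for (ch in chunks) {
    for (i in seq_len(nrow(ch))) {
      region <- as.list(ch[i])
      rt <- tumor_reads[contig == region$contig & pos < region$end + 500L &
                        end > region$start - 500L]
      rn <- if (is.null(normal_reads)) NULL else
        normal_reads[contig == region$contig & pos < region$end + 500L &
                     end > region$start - 500L]
      parts[[length(parts) + 1L]] <-
        call_region(rt, rn, ref_funs[[region$contig]], region, config)
    }
  }
  calls <- rbindlist(parts, use.names = TRUE, fill = TRUE)
  if (nrow(calls) == 0L) {
    calls <- apply_variant_filters(empty_calls(), config)
    calls[, origin := character()]
    return(calls[])
  }
  calls <- unique(calls, by = c("contig", "pos", "ref", "alt"))
  calls <- suppress_absorbed_snvs(calls, config)
  ## merge adjacent same-read SNV runs into substitution records (done
  ## globally so the result is invariant to region chunking)
  snvish <- calls[vtype %chin% c("SNV", "MNV")]
  rest <- calls[!vtype %chin% c("SNV", "MNV")]
  if (nrow(snvish) > 1L) snvish <- merge_adjacent_snvs(snvish, config)
  calls <- rbindlist(list(snvish, rest), use.names = TRUE, fill = TRUE)
  calls <- apply_variant_filters(calls, config)
  if (is.null(normal_reads)) {
    calls <- classify_origin(calls, population, hotspots, config)
  } else {
    calls[, origin := "somatic"]
  }
  if (!config$emit_all) calls <- calls[filters == ""]
  setorder(calls, contig, pos, alt)
  calls[]
}

#' Run the caller on BAM input
#'
#' File-based front end: reads the tumor (and optional normal) BAM over
#' the BED regions, calls variants, writes a VCF (and optional TSV
#' report), and returns the calls plus a run manifest.
#'
#' @param tumor_bam Coordinate-sorted, indexed tumor BAM.
#' @param normal_bam Optional matched-normal BAM (paired mode).
#' @param bed Target-region BED path.
#' @param fasta Indexed reference FASTA path.
#' @param out_vcf Output VCF path.
#' @param config A [caller_config()].
#' @param population,hotspots Optional site-list paths
#'   ([load_site_table()]).
#' @param report_tsv Optional TSV report path.
#' @return List: `calls` (data.table), `vcf` (path), `manifest`.
#' @export
run_pipeline <- function(tumor_bam, normal_bam = NULL, bed, fasta,
                         out_vcf, config = caller_config(),
                         population = NULL, hotspots = NULL,
                         report_tsv = NULL) {
  config <- as_config(config)
  for (f in c(tumor_bam, normal_bam, bed, fasta))
    if (!file.exists(f)) stop("input not found: ", f)
  regs <- load_regions(bed)
  clen <- contig_lengths_fasta(fasta)
  missing <- setdiff(unique(regs$contig), names(clen))
  if (length(missing)) stop("BED contigs absent from FASTA: ",
                            paste(missing, collapse = ", "))
  ref_funs <- fasta_accessors(fasta, unique(regs$contig))
  tr <- read_alignments(tumor_bam, regs)
  nr <- if (is.null(normal_bam)) NULL else read_alignments(normal_bam, regs)
  pop <- if (is.null(population)) NULL else load_site_table(population)
  hot <- if (is.null(hotspots)) NULL else load_site_table(hotspots)
  calls <- call_from_reads(tr, nr, ref_funs, regs, config,
                           population = pop, hotspots = hot)
  mode <- if (is.null(normal_bam)) "tumor_only" else "paired"
  ord <- order(match(calls$contig, names(clen)), calls$pos, calls$alt)
  calls <- calls[ord]
  write_vcf(calls, out_vcf, mode = mode,
            contigs = clen[names(clen) %in% unique(regs$contig)],
            config = config)
  if (!is.null(report_tsv)) write_report_tsv(calls, report_tsv)
  manifest <- list(
    mode = mode,
    inputs = list(tumor_bam = tumor_bam, normal_bam = normal_bam,
                  bed = bed, fasta = fasta),
    config = unclass(config),
    n_regions = nrow(regs),
    n_calls = nrow(calls),
    calls_per_contig = as.list(table(calls$contig)),
    warnings = character(0)
  )
  list(calls = calls, vcf = out_vcf, manifest = manifest)
}
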