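#' Variant-level filter ledger
#'
#' Appends a failure label for each screening condition a quantified
#' candidate misses: `low_support` (supporting groups below
#' `min_support_reads`), `low_depth`, `low_vaf`, `low_site_quality`, and —
#' when `strand_filter` is on — `strand_bias` for single-strand support
#' where both strands cover the site.  Candidates with a non-empty label
#' set are excluded from the PASS output.
#'
#' @param calls Candidate table with columns `tumor_support`,
#'   `tumor_depth`, `vaf_tumor`, `site_bq` (and `strand_plus`,
#'   `strand_minus` for the strand screen).
#' @param config A [caller_config()].
#' @return The table with a `filters` character column (`""` = PASS,
#'   otherwise `;`-separated labels).
#' @export
apply_variant_filters <- function(calls, config = caller_config()) {
  config <- as_config(config)
  calls <- as.data.table(calls)
  if (nrow(calls) == 0L) { calls[, filters := character()]; return(calls) }
  lab <- function(cond, label) ifelse(!is.na(cond) & cond, label, NA_character_)
  m <- cbind(
    lab(calls$tumor_support < config$min_support_reads, "low_support"),
    lab(calls$tumor_depth < config$min_depth, "low_depth"),
    lab(calls$vaf_tumor < config$min_vaf, "low_vaf"),
    lab(calls$site_bq < config$min_base_quality, "low_site_quality"),
    if (config$strand_filter)
      lab(calls$strand_plus == 0L | calls$strand_minus == 0L, "strand_bias")
    else NA_character_
  )
  calls[, filters := apply(m, 1L, function(r)
    paste(sort(r[!is.na(r)]), collapse = ";"))]
  calls[]
}

#' Classify call origin against population and hotspot site lists
#'
#' In tumor-only mode, emitted variants are annotated from user-supplied
#' site lists: a variant with population allele frequency at or above
#' `germline_popaf_threshold` (1%) is `germline`; one present in a somatic
#' hotspot list is `somatic`; present in both sources, `both`; otherwise
#' `unknown`.  Paired-mode output is somatic by construction.
#'
#' @param calls Normalized candidate table (`contig`, `pos` 0-based,
#'   `ref`, `alt`).
#' @param population Population AF table ([load_site_table()]) or `NULL`.
#' @param hotspots Hotspot site table or `NULL`.
#' @param config A [caller_config()].
#' @return The table with an `origin` column.
#' @export
classify_origin <- function(calls, population = NULL, hotspots = NULL,
                            config = caller_config()) {
  config <- as_config(config)
  calls <- as.data.table(calls)
  if (nrow(calls) == 0L) { calls[, origin := character()]; return(calls) }
  key <- function(dt) paste(dt$contig, dt$pos, dt$ref, dt$alt, sep = ":")
  k <- key(calls)
  germ <- rep(FALSE, nrow(calls))
  if (!is.null(population) && nrow(population)) {
    pop <- as.data.table(population)
    hit <- match(k, key(pop))
    germ <- !is.na(hit) & pop$af[pmax(hit, 1L)] >= config$germline_popaf_threshold
  }
  som <- rep(FALSE, nrow(calls))
  if (!is.null(hotspots) && nrow(hotspots))
    som <- k %in% key(as.data.table(hotspots))
  calls[, origin := fifelse(germ & som, "both",
                     fifelse(germ, "germline",
                      fifelse(som, "somatic", "unknown")))]
  calls[]
}

#' Load a population-AF or hotspot site list
#'
#' Accepts a tab-separated table (`chrom`, `pos` 1-based, `ref`, `alt`,
#' and optionally `af` in percent) or a VCF (AF INFO tag, read through
#' VariantAnnotation when installed).  Returns a `data.table` keyed like
#' the caller's normalized candidates (`contig`, `pos` 0-based, `ref`,
#' `alt`, `af`).
#'
#' @param path File path (`.tsv`/`.txt` or `.vcf`).
#' @return A `data.table` with columns `contig`, `pos`, `ref`, `alt`, `af`.
#' @export
load_site_table <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE))
      stop("reading VCF site lists requires the VariantAnnotation package")
    v <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(v)
    af <- VariantAnnotation::info(v)$AF
    af <- if (is.null(af)) rep(NA_real_, length(rr)) else
      vapply(as.list(af), function(x)
        if (length(x)) as.numeric(x[[1]]) * 100 else NA_real_, numeric(1))
    dt <- data.table(
      contig = as.character(GenomicRanges::seqnames(rr)),
      pos = GenomicRanges::start(rr) - 1L,
      ref = as.character(rr$REF),
      alt = vapply(rr$ALT, function(a) as.character(a)[1], character(1)),
      af = af)
  } else {
    dt <- fread(path)
    nm <- tolower(names(dt))
    setnames(dt, names(dt), nm)
    if (!all(c("chrom", "pos", "ref", "alt") %in% nm))
      stop("site table needs columns chrom, pos, ref, alt (got: ",
           paste(nm, collapse = ", "), ")")
    dt <- data.table(contig = as.character(dt$chrom),
                     pos = as.integer(dt$pos) - 1L,
                     ref = toupper(dt$ref), alt = toupper(dt$alt),
                     af = if ("af" %in% nm) as.numeric(dt$af) else NA_real_)
  }
  dt[]
}
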