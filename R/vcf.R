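#' Write calls to VCF 4.2
#'
#' Emits one record per call with INFO keys `TYPE`, `DP` (collapsed tumor
#' depth), `AD` (collapsed ref,alt), `AF` (fraction), `SB` (supporting
#' strand counts), `TLOD`, and in paired mode `NLOD`, `NDP`, `NAD`,
#' `FETP`; tumor-only records carry `ORIGIN`.  Substitution and complex
#' variants are written as block substitutions (e.g. `REF=GG ALT=A`)
#' without an extra anchor base; pure insertions/deletions are anchored
#' per VCF convention (anchoring happens during normalization).  Byte
#' output is deterministic for fixed input.
#'
#' @param calls Sorted, normalized call table (0-based `pos` internally;
#'   written 1-based).
#' @param path Output path.
#' @param mode `"tumor_only"` or `"paired"`.
#' @param contigs Named integer vector of contig lengths for the header.
#' @param config A [caller_config()] (filter descriptions in the header).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, mode = c("tumor_only", "paired"),
                      contigs = NULL, config = caller_config()) {
  mode <- match.arg(mode)
  config <- as_config(config)
  calls <- as.data.table(calls)
  if (nrow(calls) > 1L) {
    ord <- order(match(calls$contig, names(contigs) %||% unique(calls$contig)),
                 calls$pos, calls$alt)
    if (!identical(ord, seq_len(nrow(calls))))
      stop("calls must be sorted before writing")
  }
  fmt <- function(x, digits = 4) {
    ifelse(is.na(x), ".", trimws(formatC(x, digits = digits, format = "g")))
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=tumorvar",
    sprintf("##tumorvarMode=%s", if (mode == "paired") "SomVar" else "SigVar"),
    if (!is.null(contigs))
      sprintf("##contig=<ID=%s,length=%d>", names(contigs),
              as.integer(contigs)),
    "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"Variant type: SNV, MNV, insertion, deletion or complex\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Duplicate-collapsed tumor depth\">",
    "##INFO=<ID=AD,Number=2,Type=Integer,Description=\"Duplicate-collapsed tumor reference,alternate support\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Tumor variant allele fraction\">",
    "##INFO=<ID=SB,Number=2,Type=Integer,Description=\"Supporting reads on plus,minus strand\">",
    "##INFO=<ID=TLOD,Number=1,Type=Float,Description=\"Tumor Bayesian-classifier log10 odds\">",
    if (mode == "paired") c(
      "##INFO=<ID=NDP,Number=1,Type=Integer,Description=\"Duplicate-collapsed normal depth\">",
      "##INFO=<ID=NAD,Number=2,Type=Integer,Description=\"Duplicate-collapsed normal reference,alternate support\">",
      "##INFO=<ID=NLOD,Number=1,Type=Float,Description=\"Normal-sample log10 odds (when computed)\">",
      "##INFO=<ID=FETP,Number=1,Type=Float,Description=\"Fisher exact test p-value (when computed)\">"),
    if (mode == "tumor_only")
      "##INFO=<ID=ORIGIN,Number=1,Type=String,Description=\"germline, somatic, both or unknown from site lists\">",
    "##FILTER=<ID=low_support,Description=\"Collapsed supporting reads below threshold\">",
    "##FILTER=<ID=low_depth,Description=\"Collapsed depth below threshold\">",
    "##FILTER=<ID=low_vaf,Description=\"Variant allele frequency below threshold\">",
    "##FILTER=<ID=low_site_quality,Description=\"Site base quality below threshold\">",
    "##FILTER=<ID=strand_bias,Description=\"Support restricted to one strand\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  lines <- hdr
  if (nrow(calls)) {
    info <- vapply(seq_len(nrow(calls)), function(i) {
      x <- calls[i]
      parts <- c(
        sprintf("TYPE=%s", x$vtype),
        sprintf("DP=%d", x$tumor_depth),
        sprintf("AD=%d,%d", x$tumor_depth - x$tumor_support,
                x$tumor_support),
        sprintf("AF=%s", fmt(x$vaf_tumor / 100)),
        sprintf("SB=%d,%d", x$strand_plus, x$strand_minus),
        sprintf("TLOD=%s", fmt(x$lod_tumor))
      )
      if (mode == "paired") {
        parts <- c(parts,
          sprintf("NDP=%d", x$normal_depth),
          sprintf("NAD=%d,%d", x$normal_depth - x$normal_support,
                  x$normal_support),
          if (!is.na(x$lod_normal)) sprintf("NLOD=%s", fmt(x$lod_normal)),
          if (!is.na(x$fet_p)) sprintf("FETP=%s", fmt(x$fet_p)))
      } else {
        parts <- c(parts, sprintf("ORIGIN=%s", x$origin %||% "unknown"))
      }
      paste(parts, collapse = ";")
    }, character(1))
    flt <- calls$filters
    flt[is.na(flt) | flt == ""] <- "PASS"
    qual <- fmt(calls$site_bq, digits = 3)
    lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t%s\t%s\t%s",
                              calls$contig, calls$pos + 1L, calls$ref,
                              calls$alt, qual, flt, info))
  }
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a Table-style TSV report
#'
#' Columns `Chr`, `Start`, `End` (1-based inclusive span of the reference
#' allele), `Ref`, `Var`, `Type`, `VAF` (percent).
#'
#' @param calls Normalized call table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(calls, path) {
  calls <- as.data.table(calls)
  out <- data.table(
    Chr = calls$contig,
    Start = calls$pos + 1L,
    End = calls$pos + pmax(nchar(calls$ref), 1L),
    Ref = ifelse(calls$ref == "", "-", calls$ref),
    Var = ifelse(calls$alt == "", "-", calls$alt),
    Type = calls$vtype,
    VAF = sprintf("%.2f", calls$vaf_tumor)
  )
  fwrite(out, path, sep = "\t")
  invisible(path)
}
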