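# Writers keep a "# key=value" comment header (seed provenance) and are
# deterministic: fixed column order, no timestamps, LF endings.
write_tsv_seeded <- function(df, path, seed = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(paste0("# seed=", seed), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    body <- do.call(paste, c(lapply(df, function(x) {
      if (is.numeric(x) && !is.integer(x)) format(x, digits = 15, trim = TRUE,
                                                  scientific = FALSE)
      else as.character(x)
    }), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

.required_mut_cols <- c("sample", "chrom", "pos", "ref", "alt",
                        "ref_count", "alt_count")

#' Read a somatic mutation table (TSV or VCF)
#'
#' TSV input must carry columns `sample`, `chrom`, `pos` (1-based, VCF
#' convention), `ref`, `alt`, `ref_count`, `alt_count` and optionally `label`;
#' lines starting with `#` are ignored. VCF input (detected by file
#' extension) is parsed with the vcfR package and read counts are taken from
#' the first sample's `AD` field. Malformed rows are dropped with per-row
#' diagnostics (line numbers); the read is fatal only when no valid row
#' remains. Duplicate (`chrom`, `pos`, `alt`) rows are rejected.
#'
#' @param path Input file path.
#' @return Validated mutation data frame.
#' @export
read_mutations <- function(path) {
  if (!file.exists(path)) stop("mutation file not found: ", path)
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
    return(read_mutations_vcf(path))
  raw <- utils::read.delim(path, comment.char = "#", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!nrow(raw)) stop("empty mutation file: ", path)
  missing_cols <- setdiff(.required_mut_cols, names(raw))
  if (length(missing_cols))
    stop("mutation table missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!"label" %in% names(raw)) raw$label <- ""
  pos <- suppressWarnings(as.numeric(raw$pos))
  rc <- suppressWarnings(as.numeric(raw$ref_count))
  ac <- suppressWarnings(as.numeric(raw$alt_count))
  bad <- is.na(pos) | pos < 1 | pos != floor(pos) |
         is.na(rc) | rc < 0 | is.na(ac) | ac < 0 | (rc + ac) <= 0
  if (any(bad)) {
    warning("dropping ", sum(bad), " malformed mutation row(s) at line(s): ",
            paste(utils::head(which(bad) + 1L, 20), collapse = ", "))
  }
  out <- raw[!bad, , drop = FALSE]
  if (!nrow(out)) stop("no valid mutation rows in ", path)
  out$pos <- as.integer(pos[!bad])
  out$ref_count <- as.integer(rc[!bad])
  out$alt_count <- as.integer(ac[!bad])
  key <- paste(out$chrom, out$pos, out$alt)
  if (anyDuplicated(key)) {
    warning("rejecting ", sum(duplicated(key)),
            " duplicate (chrom,pos,alt) row(s)")
    out <- out[!duplicated(key), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

read_mutations_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF input requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(ad) || !ncol(ad)) stop("VCF has no per-sample AD field")
  counts <- strsplit(ad[, 1], ",", fixed = TRUE)
  rc <- suppressWarnings(as.integer(vapply(counts, `[`, character(1), 1)))
  ac <- suppressWarnings(as.integer(vapply(counts, function(x)
    if (length(x) >= 2) x[2] else NA_character_, character(1))))
  out <- data.frame(sample = colnames(ad)[1],
                    chrom = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]),
                    ref = fix[, "REF"], alt = fix[, "ALT"],
                    ref_count = rc, alt_count = ac, label = "",
                    stringsAsFactors = FALSE)
  bad <- is.na(out$ref_count) | is.na(out$alt_count) |
         (out$ref_count + out$alt_count) <= 0
  if (any(bad))
    warning("dropping ", sum(bad), " VCF record(s) without usable AD")
  out <- out[!bad, , drop = FALSE]
  if (!nrow(out)) stop("no usable records in ", path)
  key <- paste(out$chrom, out$pos, out$alt)
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a copy-number segment table
#'
#' BED-like TSV, 0-based half-open, with columns `chrom`, `start`, `end`,
#' `major_cn`, `minor_cn`, `clonal_fraction` (the output contract of an
#' allele-specific caller such as Battenberg) and an optional `label`.
#' Rows with `start >= end`, negative copy numbers or a clonal fraction
#' outside \[0, 1\] are dropped with diagnostics.
#'
#' @param path Input file path.
#' @return Validated segment data frame.
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) stop("segment file not found: ", path)
  raw <- utils::read.delim(path, comment.char = "#", header = TRUE,
                           stringsAsFactors = FALSE, colClasses = "character")
  need <- c("chrom", "start", "end", "major_cn", "minor_cn", "clonal_fraction")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("segment table missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!nrow(raw)) stop("empty segment file: ", path)
  num <- lapply(raw[need[-1]], function(x) suppressWarnings(as.numeric(x)))
  bad <- is.na(num$start) | is.na(num$end) | num$start >= num$end |
         is.na(num$major_cn) | num$major_cn < 0 |
         is.na(num$minor_cn) | num$minor_cn < 0 |
         is.na(num$clonal_fraction) |
         num$clonal_fraction < 0 | num$clonal_fraction > 1
  if (any(bad))
    warning("dropping ", sum(bad), " malformed segment row(s) at line(s): ",
            paste(utils::head(which(bad) + 1L, 20), collapse = ", "))
  out <- raw[!bad, , drop = FALSE]
  if (!nrow(out)) stop("no valid segment rows in ", path)
  out$start <- as.numeric(num$start[!bad])
  out$end <- as.numeric(num$end[!bad])
  out$major_cn <- as.integer(num$major_cn[!bad])
  out$minor_cn <- as.integer(num$minor_cn[!bad])
  out$clonal_fraction <- num$clonal_fraction[!bad]
  rownames(out) <- NULL
  out
}
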