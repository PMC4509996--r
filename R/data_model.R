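# Domain types and file I/O. All tables are plain TSV, '#' starts a comment
# line, coordinates are 0-based half-open (BED convention).

#' Construct a genome description
#'
#' Holds chromosome lengths, the name of the X chromosome (for male
#' hemizygosity) and the assembly-gap intervals that CNV calls must avoid.
#' Chromosome Y is not modelled: analyses cover autosomes and X only.
#'
#' @param chrom_lengths named numeric vector, chromosome -> length in bp.
#' @param sex_chrom name of the X chromosome (default `"chrX"`); may be
#'   absent from `chrom_lengths` for autosome-only genomes.
#' @param gaps data.frame chrom/start/end of assembly gaps (may be empty).
#' @return object of class `cnv_genome`.
#' @export
genome <- function(chrom_lengths, sex_chrom = "chrX",
                   gaps = data.frame(chrom = character(), start = numeric(),
                                     end = numeric())) {
  stopifnot(is.numeric(chrom_lengths), length(names(chrom_lengths)) ==
              length(chrom_lengths), all(chrom_lengths > 0))
  if (nrow(gaps)) {
    iv_validate(gaps, "gaps")
    if (!all(gaps$chrom %in% names(chrom_lengths)))
      stop("gap on chromosome absent from genome", call. = FALSE)
  }
  structure(list(chrom_lengths = chrom_lengths, sex_chrom = sex_chrom,
                 gaps = gaps[c("chrom", "start", "end")]),
            class = "cnv_genome")
}

#' @export
print.cnv_genome <- function(x, ...) {
  cat(sprintf("<cnv_genome> %d chromosomes, %.1f Mb, %d gaps (X: %s)\n",
              length(x$chrom_lengths), sum(x$chrom_lengths) / 1e6,
              nrow(x$gaps), x$sex_chrom))
  invisible(x)
}

# -- readers -----------------------------------------------------------------

read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

split_fields <- function(lines) strsplit(lines, "\t", fixed = TRUE)

is_number <- function(x) !is.na(suppressWarnings(as.numeric(x)))

#' Read per-individual CNV calls
#'
#' Expects TSV columns chrom, start, end, call_type, cn (header optional,
#' detected by a non-numeric second field). `call_type` must be
#' "duplication" or "deletion"; `cn` is the estimated diploid copy number.
#'
#' @param path file path.
#' @param sample_id sample identifier to attach to every call.
#' @return data.frame of class `cnv_calls` with columns chrom, start, end,
#'   call_type, cn, sample_id, in file order.
#' @export
read_cnv_calls <- function(path, sample_id) {
  tl <- read_tsv_lines(path)
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      call_type = character(), cn = numeric(),
                      sample_id = character(), stringsAsFactors = FALSE)
  class(empty) <- c("cnv_calls", "data.frame")
  if (length(tl$lines) == 0) return(empty)
  f <- split_fields(tl$lines)
  if (!is_number(f[[1]][2])) { # header row
    f <- f[-1]; tl$lineno <- tl$lineno[-1]
    if (length(f) == 0) return(empty)
  }
  parse_err <- function(i, msg)
    stop(sprintf("parse error at line %d of %s: %s", tl$lineno[i], path, msg),
         call. = FALSE)
  for (i in seq_along(f)) {
    r <- f[[i]]
    if (length(r) < 5) parse_err(i, "expected 5 tab-separated fields")
    if (!is_number(r[2]) || !is_number(r[3]))
      parse_err(i, "non-numeric coordinates")
    s <- as.numeric(r[2]); e <- as.numeric(r[3])
    if (s < 0) parse_err(i, "negative start coordinate")
    if (e <= s) parse_err(i, "end must exceed start")
    if (!r[4] %in% c("duplication", "deletion"))
      parse_err(i, sprintf("unknown call type '%s'", r[4]))
    if (!is_number(r[5]) || as.numeric(r[5]) < 0)
      parse_err(i, "cn must be a nonnegative real")
  }
  m <- do.call(rbind, f)
  out <- data.frame(chrom = m[, 1], start = as.numeric(m[, 2]),
                    end = as.numeric(m[, 3]), call_type = m[, 4],
                    cn = as.numeric(m[, 5]), sample_id = sample_id,
                    stringsAsFactors = FALSE)
  class(out) <- c("cnv_calls", "data.frame")
  out
}

#' Read a BED3 interval file (genes, SDs, gaps)
#'
#' @param path file path; TSV chrom/start/end (+ optional 4th name column),
#'   header optional.
#' @param name_col if `TRUE`, a 4th column is read as `gene_id`.
#' @return data.frame chrom/start/end (+ gene_id).
#' @export
read_bed <- function(path, name_col = FALSE) {
  tl <- read_tsv_lines(path)
  cols <- if (name_col) {
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               gene_id = character(), stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               stringsAsFactors = FALSE)
  }
  if (length(tl$lines) == 0) return(cols)
  f <- split_fields(tl$lines)
  if (!is_number(f[[1]][2])) f <- f[-1]
  if (length(f) == 0) return(cols)
  m <- do.call(rbind, lapply(f, function(r) r[seq_len(if (name_col) 4 else 3)]))
  out <- data.frame(chrom = m[, 1], start = as.numeric(m[, 2]),
                    end = as.numeric(m[, 3]), stringsAsFactors = FALSE)
  if (name_col) out$gene_id <- m[, 4]
  iv_validate(out, path)
  if (name_col && anyDuplicated(out$gene_id))
    stop("duplicated gene_id in ", path, call. = FALSE)
  out
}

#' Read a chrom.sizes table
#' @param path two-column TSV (chrom, length), no header required.
#' @return named numeric vector.
#' @export
read_chrom_sizes <- function(path) {
  tl <- read_tsv_lines(path)
  f <- split_fields(tl$lines)
  if (length(f) && !is_number(f[[1]][2])) f <- f[-1]
  len <- vapply(f, function(r) as.numeric(r[2]), numeric(1))
  names(len) <- vapply(f, `[`, character(1), 1)
  len
}

#' Read a sample sheet
#'
#' @param path TSV with columns sample_id, population, sex
#'   (sex in \{male, female\}).
#' @return data.frame of class `sample_sheet`.
#' @export
read_sample_sheet <- function(path) {
  tl <- read_tsv_lines(path)
  f <- split_fields(tl$lines)
  if (length(f) && f[[1]][1] == "sample_id") f <- f[-1]
  m <- do.call(rbind, f)
  sheet <- data.frame(sample_id = m[, 1], population = m[, 2], sex = m[, 3],
                      stringsAsFactors = FALSE)
  sample_sheet(sheet)
}

#' Construct/validate a sample sheet
#' @param x data.frame with sample_id, population, sex columns.
#' @return the validated data.frame, classed `sample_sheet`.
#' @export
sample_sheet <- function(x) {
  stopifnot(all(c("sample_id", "population", "sex") %in% names(x)))
  if (anyDuplicated(x$sample_id)) stop("duplicated sample_id", call. = FALSE)
  if (!all(x$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'", call. = FALSE)
  class(x) <- unique(c("sample_sheet", class(x)))
  x
}

#' Retain only large segmental duplications
#'
#' @param sds data.frame chrom/start/end.
#' @param min_length keep SDs strictly longer than this (default 10 kb).
#' @return filtered data.frame.
#' @export
filter_sds <- function(sds, min_length = 10000) {
  sds[iv_length(sds) > min_length, , drop = FALSE]
}

# -- writer ------------------------------------------------------------------

#' Write a result table as TSV
#'
#' Deterministic output: fixed column order (as supplied), rows sorted by
#' (chrom, start) when those columns exist, header always written, no
#' quoting. Numeric columns are written with full precision so files
#' round-trip exactly.
#'
#' @param records data.frame (possibly empty: header-only output).
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  if (all(c("chrom", "start") %in% names(records)) && nrow(records) > 1) {
    records <- records[iv_order(transform(records,
                                          end = if ("end" %in% names(records))
                                            end else start)), , drop = FALSE]
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(names(records), collapse = "\t"), con)
  if (nrow(records)) {
    cols <- lapply(records, function(col) {
      if (is.numeric(col)) format(col, digits = 15, trim = TRUE,
                                  scientific = FALSE) else as.character(col)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

# -- call-level filter -------------------------------------------------------

#' Filter CNV calls by length and assembly-gap overlap
#'
#' Keeps calls with length >= `min_len` (boundary length kept) and zero bp of
#' overlap with any annotated gap; any overlap of >= 1 bp removes a call.
#' Input row order is preserved and retained calls are unmodified.
#'
#' @param calls `cnv_calls` data.frame.
#' @param genome a [genome()] object; every call chromosome must be present.
#' @param min_len minimum call length in bp (default 1000).
#' @return filtered `cnv_calls` data.frame.
#' @export
filter_calls <- function(calls, genome, min_len = 1000) {
  stopifnot(inherits(genome, "cnv_genome"))
  if (nrow(calls) == 0) return(calls)
  missing_chr <- setdiff(unique(calls$chrom), names(genome$chrom_lengths))
  if (length(missing_chr))
    stop("calls on chromosome absent from genome: ",
         paste(missing_chr, collapse = ", "), call. = FALSE)
  keep <- iv_length(calls) >= min_len & !iv_overlaps_any(calls, genome$gaps)
  calls[keep, , drop = FALSE]
}

#' Baseline (expected) copy number for a sample on a chromosome
#'
#' 2 on autosomes and on X in females; 1 on X in males (hemizygosity).
#'
#' @param chrom chromosome name(s).
#' @param sex `"male"` or `"female"` (scalar).
#' @param sex_chrom name of the X chromosome.
#' @return numeric vector of baselines (1 or 2), one per chromosome.
#' @export
cn_baseline <- function(chrom, sex, sex_chrom = "chrX") {
  stopifnot(sex %in% c("male", "female"))
  ifelse(chrom == sex_chrom & sex == "male", 1, 2)
}
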