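## I/O for every external format the pipeline touches.
##
## Coordinate convention: 0-based half-open (BED) everywhere internally.
## Any 1-based source must be converted at the reader; nothing downstream
## ever sees raw text.

#' Construct a validated set of genomic intervals
#'
#' Intervals are plain data frames in BED convention: `start` is 0-based
#' inclusive, `end` is 0-based exclusive. `summit`, when present, is the
#' offset of the signal maximum from `start`; when absent it defaults to the
#' interval midpoint, because consensus intervals produced by intersecting
#' two peak callers have no native summit while downstream analyses
#' (motif flanks, TSS distances) are summit-centered.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors, 0-based half-open.
#' @param strand Strand, one of `"+"`, `"-"`, `"."` (default).
#' @param summit Optional integer offset from `start`, in `[0, end - start)`.
#'   `NA` entries fall back to the midpoint rule.
#' @return A `data.frame` with class `genomic_intervals` and columns
#'   `chrom`, `start`, `end`, `strand`, `summit`.
#' @examples
#' genomic_intervals("chr1", 100, 250)
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".", summit = NA_integer_) {
  n <- length(start)
  start <- as.numeric(start); end <- as.numeric(end)
  chrom <- rep_len(as.character(chrom), max(n, length(chrom)))
  strand <- rep_len(as.character(strand), n)
  summit <- rep_len(as.numeric(summit), n)
  if (length(end) != n || length(chrom) != n)
    hif_stop("chrom, start and end must have equal length", "hif_validation_error")
  if (any(!is.finite(start)) || any(!is.finite(end)))
    hif_stop("non-numeric interval coordinates", "hif_validation_error")
  if (any(start < 0))
    hif_stop("interval start must be >= 0", "hif_validation_error")
  bad <- which(end <= start)
  if (length(bad))
    hif_stop(sprintf("interval end <= start at row %d (%s:%g-%g)",
                     bad[1], chrom[bad[1]], start[bad[1]], end[bad[1]]),
             "hif_validation_error")
  if (!all(strand %in% c("+", "-", ".")))
    hif_stop("strand must be one of '+', '-', '.'", "hif_validation_error")
  mid <- floor((start + end) / 2) - start
  summit <- ifelse(is.na(summit), mid, summit)
  if (any(summit < 0 | summit >= end - start))
    hif_stop("summit offset outside [0, width)", "hif_validation_error")
  structure(
    data.frame(chrom = as.character(chrom), start = start, end = end,
               strand = strand, summit = summit, stringsAsFactors = FALSE),
    class = c("genomic_intervals", "data.frame")
  )
}

#' Absolute summit coordinates of intervals
#' @param x A `genomic_intervals` object.
#' @return Numeric vector of 0-based summit positions (`start + summit`).
#' @export
interval_summits <- function(x) x$start + x$summit

#' Read a BED or narrowPeak file as genomic intervals
#'
#' BED3+ with 0-based half-open coordinates, preserved verbatim. When a
#' line has ten fields and the tenth is a nonnegative number (narrowPeak
#' dialect) it is taken as the summit offset from `start`; `-1` means
#' "no summit" and falls back to the midpoint rule.
#'
#' @param path Path to a tab-separated BED/narrowPeak file.
#' @return A `genomic_intervals` data frame in file order.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) hif_stop(paste0("no such file: ", path), "hif_io_error")
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
  if (!length(lines))
    return(genomic_intervals(character(), numeric(), numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    hif_stop(sprintf("BED line %d has %d field(s); need >= 3",
                     which(nf < 3)[1], nf[which(nf < 3)[1]]), "hif_parse_error")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end   <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    hif_stop(sprintf("non-numeric coordinate at line %d",
                     which(is.na(start) | is.na(end))[1]), "hif_parse_error")
  strand <- rep(".", length(lines))
  if (all(nf >= 6)) {
    s6 <- vapply(fields, `[[`, "", 6L)
    strand[s6 %in% c("+", "-")] <- s6[s6 %in% c("+", "-")]
  }
  summit <- rep(NA_real_, length(lines))
  np <- nf == 10
  if (any(np)) {
    s10 <- suppressWarnings(as.numeric(vapply(fields[np], `[[`, "", 10L)))
    s10[!is.na(s10) & s10 < 0] <- NA  # -1 = summit not called
    summit[np] <- s10
  }
  tryCatch(
    genomic_intervals(chrom, start, end, strand, summit),
    hifbind_error = function(e)
      hif_stop(paste0("invalid interval in ", path, ": ", conditionMessage(e)),
               "hif_validation_error")
  )
}

#' Write genomic intervals as BED
#'
#' Emits BED6 plus a 0-based summit offset column when any summit differs
#' from the midpoint default, so that `read_bed(write_bed(x))` round-trips.
#' @param x A `genomic_intervals` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot(inherits(x, "genomic_intervals"))
  if (nrow(x) == 0) { writeLines(character(), path); return(invisible(path)) }
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s\t.\t.\t.\t%d",
                   x$chrom, as.integer(x$start), as.integer(x$end),
                   sprintf("region_%d", seq_len(nrow(x))), x$strand,
                   as.integer(x$summit))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a validated gene annotation table
#'
#' @param id Gene identifiers (unique).
#' @param chrom Chromosome names.
#' @param tss 0-based transcription start site positions.
#' @param strand `"+"` or `"-"`.
#' @param gene_class One of `"protein_coding"`, `"lncRNA"`, `"antisense"`,
#'   `"other"` (the closed vocabulary used for nearest-gene class breakdowns).
#' @return A `data.frame` with class `gene_annotation`.
#' @export
gene_annotation <- function(id, chrom, tss, strand, gene_class) {
  classes <- c("protein_coding", "lncRNA", "antisense", "other")
  tss <- as.numeric(tss)
  if (anyDuplicated(id)) hif_stop("duplicate gene ids", "hif_validation_error")
  if (any(tss < 0)) hif_stop("tss must be >= 0", "hif_validation_error")
  if (!all(strand %in% c("+", "-")))
    hif_stop("gene strand must be '+' or '-'", "hif_validation_error")
  if (!all(gene_class %in% classes))
    hif_stop(paste0("gene_class outside closed vocabulary {",
                    paste(classes, collapse = ", "), "}"), "hif_validation_error")
  structure(
    data.frame(id = as.character(id), chrom = as.character(chrom), tss = tss,
               strand = as.character(strand), gene_class = as.character(gene_class),
               stringsAsFactors = FALSE),
    class = c("gene_annotation", "data.frame")
  )
}

#' Read a JASPAR flat-text position frequency matrix
#'
#' Parses the 2009-era JASPAR core flat format: a `>ID name` header followed
#' by four rows of counts, optionally prefixed with the base letter and
#' optionally bracketed (`A [ 3 10 ... ]`). Row order is normalized to
#' A, C, G, T regardless of file order.
#'
#' @param path Path to the flat-text file (may contain several records).
#' @param motif_id Identifier of the record to extract.
#' @return Numeric 4 x L count matrix with rownames `A,C,G,T` and attribute
#'   `motif_id`.
#' @export
read_jaspar_pwm <- function(path, motif_id) {
  if (!file.exists(path)) hif_stop(paste0("no such file: ", path), "hif_io_error")
  lines <- readLines(path)
  heads <- grep("^>", lines)
  if (!length(heads)) hif_stop("no JASPAR records in file", "hif_parse_error")
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[heads])
  hit <- which(ids == motif_id)
  if (!length(hit))
    hif_stop(sprintf("motif '%s' not found (available: %s)",
                     motif_id, paste(ids, collapse = ", ")), "hif_lookup_error")
  from <- heads[hit[1]] + 1L
  to <- if (hit[1] < length(heads)) heads[hit[1] + 1L] - 1L else length(lines)
  body <- lines[from:to]
  body <- body[nzchar(trimws(body))]
  if (length(body) != 4L)
    hif_stop(sprintf("motif '%s' has %d base rows; need 4", motif_id, length(body)),
             "hif_parse_error")
  parse_row <- function(ln) {
    base <- NA_character_
    m <- regmatches(ln, regexec("^\\s*([ACGTacgt])\\b", ln))[[1]]
    if (length(m) == 2) { base <- toupper(m[2]); ln <- sub("^\\s*[ACGTacgt]", "", ln) }
    ln <- gsub("[][]", " ", ln)
    vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
    if (anyNA(vals)) hif_stop("non-numeric count in PWM row", "hif_parse_error")
    list(base = base, counts = vals)
  }
  rows <- lapply(body, parse_row)
  lens <- vapply(rows, function(r) length(r$counts), 1L)
  if (length(unique(lens)) != 1L)
    hif_stop(sprintf("motif '%s': rows of unequal length (%s)",
                     motif_id, paste(lens, collapse = ",")), "hif_parse_error")
  bases <- vapply(rows, `[[`, "", "base")
  mat <- do.call(rbind, lapply(rows, `[[`, "counts"))
  if (!anyNA(bases) && setequal(bases, c("A", "C", "G", "T"))) {
    mat <- mat[match(c("A", "C", "G", "T"), bases), , drop = FALSE]
  }
  if (any(mat < 0)) hif_stop("negative PWM counts", "hif_validation_error")
  rownames(mat) <- c("A", "C", "G", "T")
  attr(mat, "motif_id") <- motif_id
  mat
}

#' Read a typed, schema-checked delimited table
#'
#' Thin wrapper over [utils::read.delim()] that enforces required columns
#' and column types up front so downstream modules only ever see validated
#' frames. Missing values stay `NA`; they are never imputed here.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param schema Named character vector mapping required column names to
#'   types (`"character"`, `"numeric"`, `"integer"`, `"logical"`).
#' @return A `data.frame` with at least the schema columns, coerced.
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) hif_stop(paste0("no such file: ", path), "hif_io_error")
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  missing <- setdiff(names(schema), names(df))
  if (length(missing))
    hif_stop(paste0("missing required column(s): ", paste(missing, collapse = ", ")),
             "hif_schema_error")
  for (col in names(schema)) {
    df[[col]] <- switch(schema[[col]],
      character = as.character(df[[col]]),
      numeric = as.numeric(df[[col]]),
      integer = as.integer(df[[col]]),
      logical = as.logical(df[[col]]),
      hif_stop(paste0("unknown schema type: ", schema[[col]]), "hif_schema_error")
    )
  }
  df
}

#' Read a clinical table into patient records
#'
#' Expects columns `id`, `age`, `stage`, `metastasis`, `vital_status`
#' (`"deceased"`/`"alive"`), `time` (follow-up days) and `event`
#' (death observed, 0/1). Rows with missing values in any required field are
#' excluded and counted in a log message rather than silently imputed.
#'
#' @param path Path to a tab-separated clinical table.
#' @return A `data.frame` of complete patient records.
#' @export
read_clinical <- function(path) {
  df <- read_table(path, c(id = "character", age = "numeric", stage = "integer",
                           metastasis = "logical", vital_status = "character",
                           time = "numeric", event = "logical"))
  ok <- complete.cases(df[c("age", "stage", "metastasis", "vital_status",
                            "time", "event")])
  if (any(!ok))
    hif_log("excluded %d patient(s) with missing clinical data", sum(!ok))
  df <- df[ok, , drop = FALSE]
  if (any(df$time <= 0)) hif_stop("follow-up time must be > 0", "hif_validation_error")
  if (!all(df$stage %in% 1:4)) hif_stop("stage must be in 1..4", "hif_validation_error")
  df$deceased <- df$vital_status == "deceased"
  if (any(df$event & !df$deceased))
    hif_stop("event = TRUE requires vital_status 'deceased'", "hif_validation_error")
  df
}

#' Read sequences from a FASTA file
#' @param path Path to an (uncompressed) FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(ss)), names(ss))
}

#' Write named sequences to a FASTA file
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
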