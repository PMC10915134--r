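# Readers/writers for the plain-text formats the pipeline consumes: GMT gene
# sets, TSV/GCT expression matrices, clinical tables with a column-mapping
# schema, MAF mutation tables, and the score table TSV.

STAGE_LEVELS <- c("Healthy", "MGUS", "SMM", "NDMM", "RRMM")

#' Read gene signatures from a GMT file
#'
#' One signature per line: name, description (discarded), then gene symbols,
#' tab-separated. Gene symbols are matched case-sensitively after whitespace
#' trimming; no alias resolution is attempted.
#'
#' @param path path to a GMT file.
#' @return named list of \linkS4class{GeneSignature} objects (empty list for
#'   an empty file).
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' writeLines("PlasmaB\tdesc\tSDC1\tXBP1", f)
#' readGMT(f)
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(list())
  sigs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop(sprintf("malformed GMT line %d: fewer than 3 tab-separated fields", i))
    sigs[[i]] <- GeneSignature(fields[[1L]], fields[-(1:2)])
  }
  nms <- vapply(sigs, function(s) s@name, character(1))
  if (anyDuplicated(nms))
    stop("duplicate signature names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(sigs) <- nms
  sigs
}

#' Read an expression matrix (TSV or GCT v1.2)
#'
#' TSV: header row of sample identifiers, first column gene identifiers.
#' GCT: the standard v1.2 layout ("#1.2" line, dimensions line, NAME and
#' Description columns). Values are log-scale expression. Duplicate gene rows
#' are collapsed by the per-sample maximum (a common microarray probe
#' convention) with a message.
#'
#' @param path path to the file.
#' @param format "tsv" or "gct".
#' @return numeric matrix, genes x samples, with unique dimnames.
#' @export
readExpression <- function(path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "gct") {
    header <- readLines(path, n = 2L)
    if (length(header) < 2L || trimws(header[[1L]]) != "#1.2")
      stop("not a GCT v1.2 file: first line must be '#1.2'")
    dims <- as.integer(strsplit(header[[2L]], "\t")[[1L]][1:2])
    df <- read.delim(path, skip = 2L, check.names = FALSE,
                     stringsAsFactors = FALSE)
    if (nrow(df) != dims[1L] || ncol(df) - 2L != dims[2L])
      stop(sprintf("GCT declared dims %d x %d but file has %d x %d",
                   dims[1L], dims[2L], nrow(df), ncol(df) - 2L))
    genes <- trimws(as.character(df[[1L]]))
    vals <- df[, -(1:2), drop = FALSE]
  } else {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    genes <- trimws(as.character(df[[1L]]))
    vals <- df[, -1L, drop = FALSE]
  }
  samples <- colnames(vals)
  if (anyDuplicated(samples))
    stop("duplicate sample identifiers: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1L]
      stop(sprintf("non-numeric value at gene row %d, sample '%s'",
                   bad, samples[j]))
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  if (anyDuplicated(genes)) {
    message(sprintf("collapsing %d duplicate gene row(s) by per-sample maximum",
                    sum(duplicated(genes))))
    m <- do.call(rbind, lapply(split(seq_along(genes), genes), function(idx) {
      apply(m[idx, , drop = FALSE], 2L, max)
    }))
    m <- m[unique(genes), , drop = FALSE]
  }
  validateExpression(m)
  m
}

# invariant checks shared by readers and generators
validateExpression <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("expression must be a numeric matrix")
  if (nrow(m) < 2L || ncol(m) < 1L)
    stop("expression matrix needs >= 2 genes and >= 1 sample")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix must carry gene and sample identifiers")
  if (anyDuplicated(rownames(m))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(m))) stop("duplicate sample identifiers")
  if (!all(is.finite(m))) stop("expression values must all be finite")
  invisible(m)
}

#' Read a clinical table
#'
#' Reads a delimited clinical file and maps its columns onto the fields the
#' pipeline understands via a schema (a named list or a YAML file:
#' \code{field: column_name}). Recognised fields: sample_id, os_time,
#' os_event, efs_time, efs_event, age, sex, race, b2m, albumin, ldh, ldh_uln,
#' stage_label, iss, r_iss, r2_iss, subtype_label, progressed, and any number
#' of logical cytogenetic flags (del17p, t_4_14, t_14_16, t_11_14, t_8_14,
#' gain1q, ...). Unmapped columns are preserved untouched. Missing numeric
#' values are permitted; each downstream analysis applies its own
#' complete-case policy.
#'
#' @param path delimited text file with a header row.
#' @param schema named list mapping field -> column name, or path to a YAML
#'   file with that mapping. \code{NULL} means columns are already named by
#'   field.
#' @return data.frame with validated fields; \code{stage_label} becomes an
#'   ordered factor Healthy < MGUS < SMM < NDMM < RRMM.
#' @export
readClinical <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (is.character(schema) && length(schema) == 1L)
    schema <- yaml::read_yaml(schema)
  if (!is.null(schema)) {
    for (field in names(schema)) {
      col <- schema[[field]]
      if (!col %in% colnames(df))
        stop(sprintf("schema maps field '%s' to missing column '%s'",
                     field, col))
      colnames(df)[colnames(df) == col] <- field
    }
  }
  validateClinical(df)
}

validateClinical <- function(df) {
  if (!"sample_id" %in% colnames(df)) stop("clinical table needs 'sample_id'")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id values")
  for (ev in intersect(c("os_event", "efs_event", "progressed"), colnames(df))) {
    v <- df[[ev]]
    if (!all(is.na(v) | v %in% c(0, 1)))
      stop(sprintf("'%s' must be 0/1", ev))
  }
  for (tm in intersect(c("os_time", "efs_time"), colnames(df))) {
    v <- df[[tm]]
    if (!all(is.na(v) | v >= 0)) stop(sprintf("'%s' must be non-negative", tm))
  }
  if ("stage_label" %in% colnames(df)) {
    v <- as.character(df$stage_label)
    bad <- setdiff(unique(v[!is.na(v)]), STAGE_LEVELS)
    if (length(bad))
      stop("unknown stage_label value(s): ", paste(bad, collapse = ", "))
    df$stage_label <- factor(v, levels = STAGE_LEVELS, ordered = TRUE)
  }
  df
}

#' Read somatic mutations from a MAF-dialect file
#'
#' Requires at least the Hugo_Symbol, Tumor_Sample_Barcode and
#' Variant_Classification columns; comment lines starting with '#' are
#' skipped. Repeated (sample, gene, classification) records are kept —
#' multiple hits are real.
#'
#' @param path tab-delimited MAF(-subset) file.
#' @return data.frame with columns \code{sample_id}, \code{gene},
#'   \code{variant_classification}.
#' @export
readMAF <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  required <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  missing <- setdiff(required, colnames(df))
  if (length(missing))
    stop("MAF file missing required column(s): ",
         paste(missing, collapse = ", "))
  data.frame(sample_id = as.character(df$Tumor_Sample_Barcode),
             gene = trimws(as.character(df$Hugo_Symbol)),
             variant_classification = as.character(df$Variant_Classification),
             stringsAsFactors = FALSE)
}

#' Write / read a signature score table
#'
#' TSV with samples as rows, one column per signature z-score plus a PBM
#' column when a plasma signature was designated. Values survive a
#' write-then-read round trip to 1e-9.
#'
#' @param scores a \linkS4class{SignatureScores}.
#' @param path output path.
#' @return \code{writeScores}: the path, invisibly. \code{readScores}: a
#'   \linkS4class{SignatureScores} rebuilt from the file.
#' @export
writeScores <- function(scores, path) {
  stopifnot(is(scores, "SignatureScores"))
  m <- scores@scores
  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty score table")
  out <- data.frame(sample_id = rownames(m),
                    signif(m, 15L), check.names = FALSE)
  if (length(scores@plasmaSignature))
    out$PBM <- signif(scores@pbm, 15L)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeScores
#' @param plasmaSignature name of the plasma signature column, needed to
#'   reconstruct the PBM designation when reading; \code{NULL} if the file
#'   has no PBM column.
#' @export
readScores <- function(path, plasmaSignature = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  rn <- df$sample_id
  hasPBM <- "PBM" %in% colnames(df)
  m <- as.matrix(df[, setdiff(colnames(df), c("sample_id", "PBM")),
                    drop = FALSE])
  rownames(m) <- rn
  if (hasPBM) {
    if (is.null(plasmaSignature)) {
      # the PBM column is the sign-flipped plasma z-score: identify it
      dev <- vapply(seq_len(ncol(m)),
                    function(j) max(abs(-m[, j] - df$PBM)), 0)
      if (min(dev) > 1e-6)
        stop("cannot identify the plasma signature column; pass plasmaSignature")
      plasmaSignature <- colnames(m)[which.min(dev)]
    }
    new("SignatureScores", scores = m, pbm = df$PBM,
        plasmaSignature = plasmaSignature)
  } else {
    new("SignatureScores", scores = m, pbm = numeric(),
        plasmaSignature = character())
  }
}
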