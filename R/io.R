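# Readers and writers for the pipeline's external formats. Canonical tabular
# dialect: tab-delimited UTF-8 with a header row; missing beta values are
# empty fields, never sentinel numbers. BED is 0-based half-open; the
# manifest's probe positions are 1-based (array-annotation convention).
# Conversion between conventions happens only at these boundaries.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path, required = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = "", fileEncoding = "UTF-8")
  if (!is.null(required)) {
    miss <- setdiff(required, names(df))
    if (length(miss) > 0)
      stop(sprintf("%s: missing required column(s): %s", basename(path),
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read / write an array manifest
#'
#' TSV with columns probe_id, seq_id, position (1-based), strand,
#' design_type, gene, feature, island_relation. Identifiers must be unique
#' and categorical fields must come from their closed vocabularies.
#'
#' @param path file path.
#' @param manifest manifest data.frame.
#' @return the manifest data.frame (readers) or the path, invisibly (writers).
#' @export
read_manifest <- function(path) {
  m <- read_tsv(path, required = c("probe_id", "seq_id", "position", "strand",
                                   "design_type", "gene", "feature",
                                   "island_relation"))
  validate_manifest(m)
  m
}

#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  write_tsv(manifest, path)
}

validate_manifest <- function(m) {
  if (anyDuplicated(m$probe_id))
    stop("manifest: duplicate probe_id", call. = FALSE)
  if (any(m$position < 1))
    stop("manifest: positions must be >= 1", call. = FALSE)
  check_vocab(m$strand, c("+", "-"), "strand")
  check_vocab(m$design_type, c("I", "II"), "design_type")
  check_vocab(m$feature, c("promoter", "5'UTR", "exon", "intron", "3'UTR",
                           "intergenic"), "feature")
  check_vocab(m$island_relation, c("island", "shore", "shelf", "open_sea"),
              "island_relation")
  invisible(m)
}

check_vocab <- function(x, vocab, field) {
  bad <- !is.na(x) & !(x %in% vocab)
  if (any(bad))
    stop(sprintf("invalid %s value(s): %s", field,
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
}

#' Read / write a beta matrix
#'
#' Probes x samples methylation fractions in `[0,1]`; first column
#' `probe_id`, remaining columns one per sample. Masked (missing) cells are
#' empty fields on disk and `NA` in memory. Out-of-range values are rejected
#' with the offending cells named.
#'
#' @param path file path.
#' @param betas numeric matrix with probe rownames and sample colnames.
#' @export
read_beta_matrix <- function(path) {
  df <- read_tsv(path, required = "probe_id")
  if (anyDuplicated(df$probe_id))
    stop("beta matrix: duplicate probe_id", call. = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "probe_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$probe_id
  validate_beta_matrix(m)
  m
}

#' @rdname read_beta_matrix
#' @export
write_beta_matrix <- function(betas, path) {
  validate_beta_matrix(betas)
  df <- data.frame(probe_id = rownames(betas), betas, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

validate_beta_matrix <- function(m) {
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    cells <- apply(utils::head(bad, 5), 1, function(ij)
      sprintf("[%s, %s]=%g", rownames(m)[ij[1]], colnames(m)[ij[2]],
              m[ij[1], ij[2]]))
    stop("beta matrix: values outside [0,1] at ",
         paste(cells, collapse = ", "), call. = FALSE)
  }
  invisible(m)
}

#' Read / write a signal set
#'
#' Three TSVs sharing a basename: `<base>_M.tsv`, `<base>_U.tsv` (probes x
#' samples intensities, first column probe_id) and `<base>_neg.tsv`
#' (negative-control probes x samples).
#'
#' @param base path prefix.
#' @param signals object of class `signal_set`.
#' @export
read_signal_set <- function(base) {
  rd <- function(suffix, id_col) {
    df <- read_tsv(paste0(base, suffix), required = id_col)
    m <- as.matrix(df[, setdiff(names(df), id_col), drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- df[[id_col]]
    m
  }
  M <- rd("_M.tsv", "probe_id")
  U <- rd("_U.tsv", "probe_id")
  neg <- rd("_neg.tsv", "control_id")
  if (!identical(dim(M), dim(U)) || !identical(colnames(M), colnames(U)))
    stop("signal set: M and U matrices misaligned", call. = FALSE)
  if (any(M < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE))
    stop("signal set: negative intensities", call. = FALSE)
  structure(list(M = M, U = U, negatives = neg, sample_ids = colnames(M)),
            class = "signal_set")
}

#' @rdname read_signal_set
#' @export
write_signal_set <- function(signals, base) {
  stopifnot(inherits(signals, "signal_set"))
  wr <- function(m, suffix, id_col) {
    df <- data.frame(id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[1] <- id_col
    write_tsv(df, paste0(base, suffix))
  }
  wr(signals$M, "_M.tsv", "probe_id")
  wr(signals$U, "_U.tsv", "probe_id")
  wr(signals$negatives, "_neg.tsv", "control_id")
  invisible(base)
}

#' Read / write a sample sheet
#'
#' @param path file path.
#' @param sheet sample-sheet data.frame (`sample_id`, `group` in
#'   NC/UC/POS, clinical fields).
#' @export
read_sample_sheet <- function(path) {
  s <- read_tsv(path, required = c("sample_id", "group"))
  if (anyDuplicated(s$sample_id))
    stop("sample sheet: duplicate sample_id", call. = FALSE)
  check_vocab(s$group, c("NC", "UC", "POS"), "group")
  s
}

#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path) {
  if (anyDuplicated(sheet$sample_id))
    stop("sample sheet: duplicate sample_id", call. = FALSE)
  write_tsv(sheet, path)
}

#' Read / write a qPCR Ct table
#' @param path file path.
#' @param ct data.frame with sample_id, target, replicate, ct.
#' @export
read_ct_table <- function(path) {
  ct <- read_tsv(path, required = c("sample_id", "target", "replicate", "ct"))
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0))
    stop("ct table: Ct values must be positive", call. = FALSE)
  ct
}

#' @rdname read_ct_table
#' @export
write_ct_table <- function(ct, path) write_tsv(ct, path)

#' Read / write a bisulfite clone matrix
#' @param path file path.
#' @param m binary clones x CpG matrix.
#' @export
read_clone_matrix <- function(path) {
  df <- read_tsv(path, required = "clone_id")
  m <- as.matrix(df[, setdiff(names(df), "clone_id"), drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$clone_id
  if (!all(m %in% c(0L, 1L)))
    stop("clone matrix: entries must be 0/1", call. = FALSE)
  m
}

#' @rdname read_clone_matrix
#' @export
write_clone_matrix <- function(m, path) {
  df <- data.frame(clone_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read GMT gene sets
#'
#' Standard GMT: one set per line, `term <TAB> description <TAB> gene ...`.
#' Lines with fewer than three fields are rejected with their line numbers.
#'
#' @param path GMT file path.
#' @return named list of character vectors; descriptions in
#'   `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0)
    stop("GMT: line(s) with fewer than 3 fields: ",
         paste(short, collapse = ", "), call. = FALSE)
  terms <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(terms)) stop("GMT: duplicate terms", call. = FALSE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- terms
  attr(sets, "description") <- vapply(fields, `[[`, character(1), 2L)
  sets
}

#' Write GMT gene sets
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read / write BED intervals (0-based half-open)
#'
#' Three-column headerless BED plus an optional name column.
#'
#' @param path file path.
#' @param intervals data.frame with seq_id, start, end (0-based half-open)
#'   and optionally name.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED: need at least 3 columns", call. = FALSE)
  names(df)[1:3] <- c("seq_id", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  if (any(df$end <= df$start))
    stop("BED: end must exceed start", call. = FALSE)
  df[, seq_len(min(ncol(df), 4)), drop = FALSE]
}

#' @rdname read_bed
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("seq_id", "start", "end", "name"), names(intervals))
  utils::write.table(intervals[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write FASTA sequences
#'
#' Backed by Biostrings; sequences are parsed case-insensitively with `N`
#' allowed and returned as plain uppercase character vectors. Output is
#' wrapped at 60 columns.
#'
#' @param path file path.
#' @param sequences named character vector of DNA sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(toupper(sequences))
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read / write gene models
#'
#' TSV with gene, seq_id, strand, tss (0-based), exons encoded as
#' `"start-end,start-end"` in 0-based half-open coordinates.
#'
#' @param path file path.
#' @param gene_models data.frame as from [simulate_annotation()].
#' @export
read_gene_models <- function(path) {
  g <- read_tsv(path, required = c("gene", "seq_id", "strand", "tss", "exons"))
  if (anyDuplicated(g$gene)) stop("gene models: duplicate gene", call. = FALSE)
  check_vocab(g$strand, c("+", "-"), "strand")
  g
}

#' @rdname read_gene_models
#' @export
write_gene_models <- function(gene_models, path) write_tsv(gene_models, path)
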