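#' Construct an expression matrix with detection calls
#'
#' Container for probeset-level intensities on the linear (MAS5-like) scale
#' together with per-cell present/absent/marginal detection calls. All
#' intensities must be strictly positive; log2 transforms happen inside
#' downstream computations, never at I/O time.
#'
#' @param intensity numeric matrix, probesets x samples, all values > 0, with
#'   unique rownames (probeset ids) and colnames (sample ids).
#' @param calls character matrix of identical dimension with entries in
#'   \code{c("P", "A", "M")}.
#' @return An object of class \code{expr_matrix}: a list with elements
#'   \code{intensity} and \code{calls}.
#' @export
expr_matrix <- function(intensity, calls) {
  if (!is.matrix(intensity) || !is.numeric(intensity))
    stop("'intensity' must be a numeric matrix")
  if (is.null(rownames(intensity)) || is.null(colnames(intensity)))
    stop("'intensity' must have probeset rownames and sample colnames")
  if (anyDuplicated(rownames(intensity)))
    stop("duplicate probeset ids")
  if (anyDuplicated(colnames(intensity)))
    stop("duplicate sample ids")
  bad <- which(!is.finite(intensity) | intensity <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "nonpositive or non-finite intensity at probeset '%s', sample '%s'",
      rownames(intensity)[bad[1, 1]], colnames(intensity)[bad[1, 2]]
    ))
  }
  if (!identical(dim(intensity), dim(calls)))
    stop("'intensity' and 'calls' must have identical dimensions")
  calls <- matrix(as.character(calls), nrow(intensity),
                  dimnames = dimnames(intensity))
  if (!all(calls %in% c("P", "A", "M")))
    stop("detection calls must be one of 'P', 'A', 'M'")
  structure(list(intensity = intensity, calls = calls), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d probesets x %d samples (%.1f%% present calls)\n",
              nrow(x$intensity), ncol(x$intensity),
              100 * mean(x$calls == "P")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$intensity)

#' Read a TSV intensity matrix and its companion call matrix
#'
#' The intensity file is tab-separated with a header row of sample ids and a
#' first column of probeset ids. Calls come either from a companion file of
#' the same shape (argument \code{call_path}) or, if \code{call_path} is
#' \code{NULL}, every cell is treated as present.
#'
#' @param path path to the intensity TSV.
#' @param call_path optional path to the call TSV (same shape, entries P/A/M).
#' @return An [expr_matrix()].
#' @export
read_intensity_matrix <- function(path, call_path = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  intensity <- as.matrix(tab)
  storage.mode(intensity) <- "double"
  if (is.null(call_path)) {
    calls <- matrix("P", nrow(intensity), ncol(intensity),
                    dimnames = dimnames(intensity))
  } else {
    ctab <- utils::read.delim(call_path, check.names = FALSE, row.names = 1,
                              colClasses = "character")
    calls <- as.matrix(ctab)
    if (!identical(rownames(calls), rownames(intensity)) ||
        !identical(colnames(calls), colnames(intensity)))
      stop("call matrix ids do not match intensity matrix ids")
  }
  x <- expr_matrix(intensity, calls)
  message(sprintf("read %d probesets x %d samples from %s",
                  nrow(intensity), ncol(intensity), basename(path)))
  x
}

#' Write an expression matrix (and calls) to TSV
#'
#' @param x an [expr_matrix()].
#' @param path output path for intensities.
#' @param call_path optional output path for the call matrix.
#' @param digits significant digits used for serialization (default 10, the
#'   declared round-trip precision of the format).
#' @return Invisibly, the paths written.
#' @export
write_intensity_matrix <- function(x, path, call_path = NULL, digits = 10) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(probeset_id = rownames(x$intensity),
                   signif(x$intensity, digits),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(call_path)) {
    cdf <- data.frame(probeset_id = rownames(x$calls), x$calls,
                      check.names = FALSE)
    utils::write.table(cdf, call_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(path, call_path))
}

.TREATMENTS <- c("noHS", "HS", "HS_NBQX")
.TISSUES <- c("hippocampus", "cortex")
.TIMES_H <- c(1, 6, 12, 48, 168)

#' Read and validate a sample design table
#'
#' Expects columns \code{sample_id}, \code{tissue} (hippocampus/cortex),
#' \code{treatment} (noHS/HS/HS_NBQX), \code{time_h} (1/6/12/48/168) and
#' \code{replicate}; optional seizure phenotype columns \code{seizure_count}
#' and \code{latency_s}.
#'
#' @param path CSV or TSV path (delimiter sniffed from the header line).
#' @return A validated \code{data.frame} of class \code{sample_design}.
#' @export
read_design_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  validate_design(df)
}

#' Validate a sample design data.frame
#'
#' @param df data.frame with the columns described in [read_design_table()].
#' @return The validated data.frame, classed \code{sample_design}.
#' @export
validate_design <- function(df) {
  need <- c("sample_id", "tissue", "treatment", "time_h", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("design table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in design table")
  if (!all(df$tissue %in% .TISSUES))
    stop("unknown tissue level(s): ",
         paste(unique(setdiff(df$tissue, .TISSUES)), collapse = ", "))
  if (!all(df$treatment %in% .TREATMENTS))
    stop("unknown treatment level(s): ",
         paste(unique(setdiff(df$treatment, .TREATMENTS)), collapse = ", "))
  if (!all(df$time_h %in% .TIMES_H))
    stop("unknown time_h level(s): ",
         paste(unique(setdiff(df$time_h, .TIMES_H)), collapse = ", "))
  if (!all(df$replicate == round(df$replicate)) || any(df$replicate < 1))
    stop("replicate must be a positive integer")
  if (anyDuplicated(df[, c("tissue", "treatment", "time_h", "replicate")]))
    stop("duplicate (tissue, treatment, time_h, replicate) combination")
  class(df) <- c("sample_design", "data.frame")
  df
}

#' Write a design table to TSV
#' @param design a \code{sample_design} data.frame.
#' @param path output path.
#' @export
write_design_table <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a probeset-to-gene annotation table
#'
#' Two-column TSV (\code{probeset_id}, \code{gene_symbol}); the mapping is
#' many-to-many and unmapped probesets are simply absent from the table.
#'
#' @param path TSV path.
#' @return data.frame with columns \code{probeset_id} and \code{gene_symbol}.
#' @export
read_probe_gene_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probeset_id", "gene_symbol") %in% names(df)))
    stop("annotation table needs columns probeset_id, gene_symbol")
  if (anyDuplicated(df[, c("probeset_id", "gene_symbol")]))
    stop("duplicate (probeset_id, gene_symbol) pairs in annotation")
  df
}

#' Write a probeset-to-gene annotation table
#' @param map data.frame with columns \code{probeset_id}, \code{gene_symbol}.
#' @param path output path.
#' @export
write_probe_gene_map <- function(map, path) {
  utils::write.table(map[, c("probeset_id", "gene_symbol")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a signed gene set
#'
#' A gene set names \code{k_u} positive regulatees (genes the pathway
#' up-regulates) and \code{k_d} negative regulatees. The two lists must be
#' disjoint and jointly non-empty.
#'
#' @param name set name.
#' @param up_genes character vector of positive regulatees.
#' @param down_genes character vector of negative regulatees.
#' @param source source collection label (default \code{"user"}).
#' @return A \code{gene_set} object.
#' @export
gene_set <- function(name, up_genes, down_genes = character(), source = "user") {
  up_genes <- unique(as.character(up_genes))
  down_genes <- unique(as.character(down_genes))
  if (length(intersect(up_genes, down_genes)) > 0)
    stop(sprintf("gene set '%s': member(s) listed with both signs: %s", name,
                 paste(intersect(up_genes, down_genes), collapse = ", ")))
  if (length(up_genes) + length(down_genes) < 1)
    stop(sprintf("gene set '%s' is empty", name))
  structure(list(name = name, source = source,
                 up_genes = up_genes, down_genes = down_genes),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s' [%s]: k_u = %d, k_d = %d\n", x$name, x$source,
              length(x$up_genes), length(x$down_genes)))
  invisible(x)
}

#' Read signed gene sets in the GMT dialect
#'
#' Standard GMT has no sign channel, so members may carry a \code{"+"} or
#' \code{"-"} suffix marking them as positive or negative regulatees;
#' unsuffixed members default to positive. Duplicate members within a set are
#' deduplicated with a warning; a member listed with both signs rejects that
#' set with a message and the set is skipped.
#'
#' @param path GMT file path.
#' @param source source collection label attached to every set (default the
#'   file base name).
#' @return A list of [gene_set()] objects (a gene-set collection).
#' @export
read_signed_gene_sets <- function(path, source = NULL) {
  if (is.null(source))
    source <- sub("\\.gmt$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  n_dups <- 0L
  keep <- logical(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      warning(sprintf("GMT line %d has no members; skipped", i))
      next
    }
    name <- fields[1]
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    sign <- ifelse(grepl("-$", members), "-",
                   ifelse(grepl("\\+$", members), "+", "+"))
    gene <- sub("[+-]$", "", members)
    dup <- duplicated(paste(gene, sign))
    if (any(dup)) {
      n_dups <- n_dups + sum(dup)
      gene <- gene[!dup]; sign <- sign[!dup]
    }
    both <- intersect(gene[sign == "+"], gene[sign == "-"])
    if (length(both) > 0) {
      message(sprintf("gene set '%s' rejected: member(s) with both signs: %s",
                      name, paste(both, collapse = ", ")))
      next
    }
    sets[[i]] <- gene_set(name, gene[sign == "+"], gene[sign == "-"], source)
    keep[i] <- TRUE
  }
  if (n_dups > 0)
    warning(sprintf("deduplicated %d duplicate member(s) across sets", n_dups))
  sets[keep]
}

#' Write signed gene sets in the GMT dialect
#' @param collection list of [gene_set()] objects.
#' @param path output path.
#' @export
write_signed_gene_sets <- function(collection, path) {
  lines <- vapply(collection, function(s) {
    paste(c(s$name, s$source,
            paste0(s$up_genes, "+"),
            if (length(s$down_genes)) paste0(s$down_genes, "-")),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write pipeline result tables to a directory
#'
#' Serializes stage outputs as TSV with deterministic column order and fixed
#' precision. Enrichment tables carry the columns \code{name, source, ku, kd,
#' d_updown, p_value, fdr, c_left, c_right, selected}.
#'
#' @param results named list of data.frames (names become file stems).
#' @param out_dir output directory, created if needed.
#' @param digits significant digits for numeric columns (default 6).
#' @return Invisibly, the paths written.
#' @export
write_results_tables <- function(results, out_dir, digits = 6) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  paths <- character(0)
  for (nm in names(results)) {
    df <- as.data.frame(results[[nm]])
    df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) signif(v, digits))
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
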