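#' Construct a validated expression count matrix
#'
#' The canonical expression container is a plain integer matrix with genes in
#' rows and samples in columns, both axes named. Counts must be nonnegative
#' integers; values within `tol` of an integer (e.g. `3.0` read from text)
#' are rounded, anything else is rejected.
#'
#' @param counts numeric matrix, genes in rows, samples in columns, with
#'   row and column names.
#' @param tol numeric tolerance for integrality.
#' @return an integer-mode matrix with validated dimnames.
#' @export
expression_matrix <- function(counts, tol = 1e-8) {
  check(is.matrix(counts), "counts must be a matrix")
  check(!is.null(rownames(counts)) && !is.null(colnames(counts)),
        "counts must have gene (row) and sample (column) names")
  dup_g <- rownames(counts)[duplicated(rownames(counts))]
  check(length(dup_g) == 0L, "duplicate gene id: %s", dup_g[1L])
  dup_s <- colnames(counts)[duplicated(colnames(counts))]
  check(length(dup_s) == 0L, "duplicate sample id: %s", dup_s[1L])
  bad <- which(!is.finite(counts) | counts < 0 |
                 abs(counts - round(counts)) > tol, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "invalid count %s at gene '%s', sample '%s' (must be a nonnegative integer)",
      format(counts[bad[1L, , drop = FALSE]]),
      rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]]),
      call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Construct an allele-specific copy-number profile
#'
#' Holds per gene/sample major (`A`) and minor (`B`) absolute allele copy
#' numbers as two integer matrices on identical axes. `NA` marks a
#' (gene, sample) pair with no covering segment; such pairs are excluded
#' from model fits, never imputed. The convention `A >= B >= 0` is enforced:
#' with `fix_swapped = TRUE` violating pairs are swapped (with a warning
#' reporting how many), otherwise they are an error.
#'
#' @param major,minor integer matrices, genes in rows, samples in columns.
#' @param fix_swapped swap entries where `major < minor` instead of erroring.
#' @return an object of class `CopyNumberProfile` with elements `major`,
#'   `minor` (integer matrices, `NA` = missing).
#' @export
copy_number_profile <- function(major, minor, fix_swapped = FALSE) {
  check(is.matrix(major) && is.matrix(minor), "major/minor must be matrices")
  check(identical(dim(major), dim(minor)) &&
          identical(dimnames(major), dimnames(minor)),
        "major and minor must share dimensions and dimnames")
  check(!is.null(rownames(major)) && !is.null(colnames(major)),
        "copy-number matrices must have gene and sample names")
  check(!anyDuplicated(rownames(major)) && !anyDuplicated(colnames(major)),
        "duplicate gene or sample ids in copy-number profile")
  for (m in list(major, minor)) {
    ok <- is.na(m) | (is.finite(m) & m >= 0 & abs(m - round(m)) <= 1e-8)
    check(all(ok), "copy numbers must be nonnegative integers or NA")
  }
  check(identical(is.na(major), is.na(minor)),
        "major and minor must be missing for the same (gene, sample) pairs")
  storage.mode(major) <- "integer"
  storage.mode(minor) <- "integer"
  swapped <- which(!is.na(major) & major < minor)
  if (length(swapped) > 0L) {
    if (!fix_swapped) {
      stop(sprintf("%d (gene, sample) pairs have major < minor; see fix_swapped",
                   length(swapped)), call. = FALSE)
    }
    warning(sprintf("swapped major/minor in %d (gene, sample) pairs to enforce A >= B",
                    length(swapped)), call. = FALSE)
    tmp <- major[swapped]
    major[swapped] <- minor[swapped]
    minor[swapped] <- tmp
  }
  structure(list(major = major, minor = minor), class = "CopyNumberProfile")
}

#' @export
print.CopyNumberProfile <- function(x, ...) {
  cat(sprintf("CopyNumberProfile: %d genes x %d samples (%d missing pairs)\n",
              nrow(x$major), ncol(x$major), sum(is.na(x$major))))
  invisible(x)
}

#' @export
dim.CopyNumberProfile <- function(x) dim(x$major)

#' Read a gene x sample count matrix from TSV
#'
#' Expects a tab-delimited file with a header row of sample ids and gene ids
#' in the first column (genes in rows, the package's canonical orientation).
#' Lines starting with `#` are treated as comments. Cells must be
#' nonnegative integers; `3.0` is accepted as 3, `3.5` is rejected.
#'
#' @param path file path.
#' @return validated integer matrix (see [expression_matrix()]).
#' @export
read_counts <- function(path) {
  check(file.exists(path), "file not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  check(ncol(df) >= 2L, "counts file needs a gene-id column plus samples")
  genes <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  expression_matrix(m)
}

#' Write a count matrix to TSV (genes in rows)
#'
#' @param counts matrix from [expression_matrix()].
#' @param path output path.
#' @param comment optional provenance line(s) written as leading `# ` comments.
#' @export
write_counts <- function(counts, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(c("gene_id", colnames(counts)), collapse = "\t"), con)
  utils::write.table(counts, con, sep = "\t", quote = FALSE,
                     col.names = FALSE, row.names = TRUE)
  invisible(path)
}

#' Read gene-level allele-specific copy numbers
#'
#' Two encodings are supported: a long TSV with columns `gene_id`,
#' `sample_id`, `major`, `minor`; or a pair of wide gene x sample matrices
#' (major and minor) given as two paths. Pairs violating `major >= minor`
#' are swapped with a warning; absent (gene, sample) combinations in the
#' long format become missing (`NA`).
#'
#' @param path long-format TSV, or the major matrix if `minor_path` is given.
#' @param minor_path optional path to the minor-allele matrix (wide encoding).
#' @return a [copy_number_profile()].
#' @export
read_gene_cn <- function(path, minor_path = NULL) {
  check(file.exists(path), "file not found: %s", path)
  if (!is.null(minor_path)) {
    rd <- function(p) {
      df <- utils::read.delim(p, check.names = FALSE, comment.char = "#",
                              stringsAsFactors = FALSE)
      m <- as.matrix(df[, -1L, drop = FALSE])
      storage.mode(m) <- "double"
      rownames(m) <- as.character(df[[1L]])
      m
    }
    return(copy_number_profile(rd(path), rd(minor_path), fix_swapped = TRUE))
  }
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "sample_id", "major", "minor")
  miss <- setdiff(need, names(df))
  check(length(miss) == 0L, "missing column(s) in %s: %s", path,
        paste(miss, collapse = ", "))
  check(all(is.na(df$major) | df$major >= 0) &&
          all(is.na(df$minor) | df$minor >= 0),
        "negative copy numbers in %s", path)
  genes <- unique(as.character(df$gene_id))
  samples <- unique(as.character(df$sample_id))
  shape <- function(v) {
    m <- matrix(NA_real_, length(genes), length(samples),
                dimnames = list(genes, samples))
    m[cbind(match(df$gene_id, genes), match(df$sample_id, samples))] <- v
    m
  }
  copy_number_profile(shape(df$major), shape(df$minor), fix_swapped = TRUE)
}

#' Write a copy-number profile as long TSV
#'
#' Missing (gene, sample) pairs are omitted from the output.
#'
#' @param cn a [copy_number_profile()].
#' @param path output path.
#' @param comment optional provenance comment line(s).
#' @export
write_gene_cn <- function(cn, path, comment = NULL) {
  idx <- which(!is.na(cn$major), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  df <- data.frame(gene_id = rownames(cn$major)[idx[, 1L]],
                   sample_id = colnames(cn$major)[idx[, 2L]],
                   major = cn$major[idx], minor = cn$minor[idx])
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one pathway per line, tab-separated fields
#' `name  description  gene1  gene2 ...`. Duplicate genes within a line are
#' kept once (with a warning); a line with fewer than three fields is an
#' error naming the line number.
#'
#' @param path GMT file path.
#' @return named list of character vectors (pathway id -> gene ids).
#' @export
read_gmt <- function(path) {
  check(file.exists(path), "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty GMT file: ", path, call. = FALSE)
    return(structure(list(), names = character(0)))
  }
  out <- vector("list", length(lines))
  nms <- character(length(lines))
  ndup <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    check(length(f) >= 3L, "GMT line %d has fewer than 3 fields", i)
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      ndup <- ndup + 1L
      genes <- unique(genes)
    }
    check(length(genes) >= 1L, "GMT line %d has no genes", i)
    nms[i] <- f[1L]
    out[[i]] <- genes
  }
  if (ndup > 0L) {
    warning(sprintf("deduplicated genes within %d GMT line(s)", ndup),
            call. = FALSE)
  }
  check(!anyDuplicated(nms), "duplicate pathway name in %s", path)
  names(out) <- nms
  out
}

#' Write gene sets to a GMT file
#'
#' @param pathways named list of character vectors.
#' @param path output path.
#' @param description description field (recycled).
#' @export
write_gmt <- function(pathways, path, description = "na") {
  lines <- vapply(seq_along(pathways), function(i) {
    paste(c(names(pathways)[i], description, pathways[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read allele-specific copy-number segments
#'
#' SEG-like TSV with header columns `sample_id`, `chrom`, `start`, `end`,
#' `major`, `minor`; coordinates are 0-based half-open (BED convention).
#'
#' @param path file path.
#' @return data.frame of segments.
#' @export
read_segments <- function(path) {
  check(file.exists(path), "file not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "chrom", "start", "end", "major", "minor")
  miss <- setdiff(need, names(df))
  check(length(miss) == 0L, "missing column(s) in %s: %s", path,
        paste(miss, collapse = ", "))
  check(all(df$start < df$end), "segment with start >= end in %s", path)
  check(all(df$major >= df$minor & df$minor >= 0),
        "segment with major < minor or negative CN in %s", path)
  df[need]
}

#' Read a gene annotation table
#'
#' TSV with header columns `gene_id`, `chrom`, `start`, `end`; coordinates
#' 0-based half-open (BED convention).
#'
#' @param path file path.
#' @return data.frame with one row per gene.
#' @export
read_gene_annotation <- function(path) {
  check(file.exists(path), "file not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end")
  miss <- setdiff(need, names(df))
  check(length(miss) == 0L, "missing column(s) in %s: %s", path,
        paste(miss, collapse = ", "))
  check(all(df$start < df$end), "gene with start >= end in %s", path)
  check(!anyDuplicated(df$gene_id), "duplicate gene_id in %s", path)
  df[need]
}

#' Read binary sample group labels
#'
#' TSV with header columns `sample_id`, `group`; exactly two distinct group
#' labels must be present.
#'
#' @param path file path.
#' @return named character vector (sample id -> label).
#' @export
read_groups <- function(path) {
  check(file.exists(path), "file not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  miss <- setdiff(c("sample_id", "group"), names(df))
  check(length(miss) == 0L, "missing column(s) in %s: %s", path,
        paste(miss, collapse = ", "))
  g <- as.character(df$group)
  names(g) <- as.character(df$sample_id)
  check(!anyDuplicated(names(g)), "duplicate sample_id in %s", path)
  check(length(unique(g)) == 2L, "expected exactly 2 group labels, got %d",
        length(unique(g)))
  g
}

#' Align an expression matrix and a copy-number profile
#'
#' Restricts both objects to the intersection of their gene and sample ids,
#' in a common order, reporting how many ids were dropped from each side.
#' Idempotent: aligning already-aligned inputs is the identity.
#'
#' @param expr count matrix ([expression_matrix()]).
#' @param cn a [copy_number_profile()].
#' @return list with elements `expr` and `cn` on identical axes.
#' @export
align <- function(expr, cn) {
  genes <- intersect(rownames(expr), rownames(cn$major))
  samples <- intersect(colnames(expr), colnames(cn$major))
  check(length(genes) > 0L, "no genes in common between expression and CN")
  check(length(samples) > 0L, "no samples in common between expression and CN")
  dropped <- c(expr_genes = nrow(expr) - length(genes),
               cn_genes = nrow(cn$major) - length(genes),
               expr_samples = ncol(expr) - length(samples),
               cn_samples = ncol(cn$major) - length(samples))
  if (any(dropped > 0L)) {
    message(sprintf(
      "align: dropped %d/%d genes and %d/%d samples (expr/cn)",
      dropped[["expr_genes"]], dropped[["cn_genes"]],
      dropped[["expr_samples"]], dropped[["cn_samples"]]))
  }
  list(expr = expr[genes, samples, drop = FALSE],
       cn = copy_number_profile(cn$major[genes, samples, drop = FALSE],
                                cn$minor[genes, samples, drop = FALSE]))
}
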