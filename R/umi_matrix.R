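#' Construct a UMI count matrix object
#'
#' `umi_matrix` is the central container of the package: a sparse cells x
#' genes matrix of non-negative integer UMI counts together with unique cell
#' barcodes, a gene table (id, symbol) and a per-cell donor label.
#'
#' @param counts A matrix or sparse Matrix, cells in rows, genes in columns,
#'   non-negative integers.
#' @param barcodes Character vector of unique cell identifiers (defaults to
#'   rownames of `counts`).
#' @param genes A data.frame with columns `gene_id` and `symbol`, or a
#'   character vector of gene ids (then also used as symbols).
#' @param donor Per-cell donor label, recycled if length 1.
#'
#' @return An object of class `umi_matrix` with elements `counts`
#'   (a `dgCMatrix`), `barcodes`, `genes` and `donor`.
#' @export
umi_matrix <- function(counts, barcodes = rownames(counts), genes = colnames(counts),
                       donor = "donor1") {
  if (is.matrix(counts)) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(barcodes)) stop("barcodes are required")
  if (is.character(genes)) genes <- data.frame(gene_id = genes, symbol = genes,
                                               stringsAsFactors = FALSE)
  if (is.null(genes$symbol)) genes$symbol <- genes$gene_id
  barcodes <- as.character(barcodes)
  donor <- rep_len(as.character(donor), length(barcodes))
  rownames(counts) <- barcodes
  colnames(counts) <- genes$gene_id
  obj <- structure(list(counts = counts, barcodes = barcodes,
                        genes = genes, donor = donor),
                   class = "umi_matrix")
  validate_umi_matrix(obj)
}

validate_umi_matrix <- function(x) {
  stopifnot(inherits(x, "umi_matrix"))
  cnt <- x$counts
  if (nrow(cnt) != length(x$barcodes))
    stop("counts rows (", nrow(cnt), ") do not match number of barcodes (",
         length(x$barcodes), ")")
  if (ncol(cnt) != nrow(x$genes))
    stop("counts columns (", ncol(cnt), ") do not match number of genes (",
         nrow(x$genes), ")")
  if (length(x$donor) != length(x$barcodes))
    stop("donor labels do not match number of cells")
  if (anyDuplicated(x$barcodes)) stop("duplicate barcodes")
  if (anyDuplicated(x$genes$gene_id)) stop("duplicate gene ids")
  v <- cnt@x
  if (length(v)) {
    if (any(v < 0)) stop("negative counts are not allowed")
    if (any(v != round(v))) stop("non-integer counts are not allowed")
  }
  x
}

#' @export
print.umi_matrix <- function(x, ...) {
  cat("umi_matrix:", nrow(x$counts), "cells x", ncol(x$counts), "genes;",
      length(unique(x$donor)), "donor(s);",
      format(sum(x$counts), big.mark = ","), "total UMIs\n")
  invisible(x)
}

#' @export
dim.umi_matrix <- function(x) dim(x$counts)

#' Subset a UMI matrix by cells and/or genes
#'
#' @param um A `umi_matrix`.
#' @param cells,genes Logical, integer or character index into cells / genes;
#'   `NULL` keeps all.
#' @return A `umi_matrix` restricted to the selected cells and genes.
#' @export
subset_umi <- function(um, cells = NULL, genes = NULL) {
  ci <- if (is.null(cells)) seq_along(um$barcodes) else cells
  if (is.character(ci)) ci <- match(ci, um$barcodes)
  gi <- if (is.null(genes)) seq_len(nrow(um$genes)) else genes
  if (is.character(gi)) gi <- match(gi, um$genes$gene_id)
  umi_matrix(um$counts[ci, gi, drop = FALSE],
             barcodes = um$barcodes[ci],
             genes = um$genes[gi, , drop = FALSE],
             donor = um$donor[ci])
}

find_tenx_file <- function(directory, stems) {
  for (stem in stems) for (suf in c("", ".gz")) {
    f <- file.path(directory, paste0(stem, suf))
    if (file.exists(f)) return(f)
  }
  NULL
}

read_id_table <- function(path) {
  lines <- readLines(path)   # file() auto-detects gzip on read
  lines <- lines[nzchar(lines)]
  do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
}

#' Read a 10x-style Matrix Market triplet directory
#'
#' Reads `matrix.mtx`, `barcodes.tsv` and `features.tsv` (or `genes.tsv`),
#' gzipped or plain. On-disk orientation (the 10x convention is genes x
#' cells) is auto-detected by matching the header dimensions against the
#' identifier file lengths; the returned matrix is always cells x genes.
#' Features files with a single column use the symbol as gene id.
#'
#' @param directory Path to the matrix directory.
#' @param donor Donor label applied to every cell (default: directory name).
#' @return A [umi_matrix()].
#' @export
read_mtx_triplet <- function(directory, donor = basename(normalizePath(directory))) {
  mtx_f <- find_tenx_file(directory, "matrix.mtx")
  bc_f  <- find_tenx_file(directory, "barcodes.tsv")
  ft_f  <- find_tenx_file(directory, c("features.tsv", "genes.tsv"))
  if (is.null(mtx_f) || is.null(bc_f) || is.null(ft_f))
    stop("directory ", directory,
         " must contain matrix.mtx, barcodes.tsv and features.tsv (optionally gzipped)")
  m <- tryCatch({
    # readMM opens and closes an unopened connection itself
    Matrix::readMM(if (grepl("\\.gz$", mtx_f)) gzfile(mtx_f) else mtx_f)
  }, error = function(e) stop("malformed Matrix Market file ", mtx_f, ": ",
                              conditionMessage(e)))
  v <- m@x
  if (length(v) && any(v < 0))
    stop("negative entry in ", mtx_f)
  if (length(v) && any(v != round(v)))
    stop("non-integer entry in ", mtx_f)

  bc <- read_id_table(bc_f)[, 1]
  ft <- read_id_table(ft_f)
  genes <- if (ncol(ft) >= 2) {
    data.frame(gene_id = ft[, 1], symbol = ft[, 2], stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = ft[, 1], symbol = ft[, 1], stringsAsFactors = FALSE)
  }

  nb <- length(bc); ng <- nrow(genes)
  if (nrow(m) == ng && ncol(m) == nb) {
    m <- Matrix::t(m)                       # 10x genes x cells convention
  } else if (!(nrow(m) == nb && ncol(m) == ng)) {
    stop("matrix dimensions ", nrow(m), " x ", ncol(m),
         " match neither barcodes (", nb, ") x features (", ng,
         ") nor the transposed convention")
  }
  umi_matrix(m, barcodes = bc, genes = genes, donor = donor)
}

#' Write a UMI matrix as a 10x-style triplet directory
#'
#' Writes `matrix.mtx` in the on-disk genes x cells convention plus
#' `barcodes.tsv` and `features.tsv` (id, symbol).
#'
#' @param um A `umi_matrix`.
#' @param directory Output directory (created if absent).
#' @param gzip Write gzipped files.
#' @return `directory`, invisibly.
#' @export
write_mtx_triplet <- function(um, directory, gzip = FALSE) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  suf <- if (gzip) ".gz" else ""
  mtx_plain <- file.path(directory, "matrix.mtx")
  Matrix::writeMM(Matrix::t(um$counts), mtx_plain)
  if (gzip) {
    lines <- readLines(mtx_plain)
    con <- gzfile(paste0(mtx_plain, suf), "w")
    writeLines(lines, con); close(con)
    unlink(mtx_plain)
  }
  write_one <- function(lines, stem) {
    path <- file.path(directory, paste0(stem, suf))
    con <- if (gzip) gzfile(path, "w") else file(path, "w")
    writeLines(lines, con); close(con)
  }
  write_one(um$barcodes, "barcodes.tsv")
  write_one(paste(um$genes$gene_id, um$genes$symbol, sep = "\t"), "features.tsv")
  invisible(directory)
}

#' Merge per-donor UMI matrices into one annotated matrix
#'
#' Row-concatenates the matrices over their shared gene universe (genes are
#' intersected with a warning when the universes differ) and suffixes each
#' barcode with its donor label to keep cell identifiers unique.
#'
#' @param matrices List of `umi_matrix` objects.
#' @param donor_labels Character vector, one label per matrix.
#' @return A single `umi_matrix` covering all cells.
#' @export
merge_donors <- function(matrices, donor_labels = NULL) {
  stopifnot(length(matrices) >= 1)
  if (is.null(donor_labels))
    donor_labels <- vapply(matrices, function(m) m$donor[1], character(1))
  stopifnot(length(donor_labels) == length(matrices))
  if (length(matrices) == 1) {
    m <- matrices[[1]]
    m$donor <- rep_len(donor_labels[1], length(m$barcodes))
    return(validate_umi_matrix(m))
  }
  shared <- Reduce(intersect, lapply(matrices, function(m) m$genes$gene_id))
  if (length(shared) == 0) stop("no shared genes across matrices")
  n_union <- length(unique(unlist(lapply(matrices, function(m) m$genes$gene_id))))
  if (n_union > length(shared))
    warning("gene universes differ; merging over ", length(shared),
            " shared genes (union had ", n_union, ")")
  parts <- mapply(function(m, lab) {
    s <- subset_umi(m, genes = shared)
    s$barcodes <- paste0(s$barcodes, "-", lab)
    s$donor <- rep_len(lab, length(s$barcodes))
    rownames(s$counts) <- s$barcodes
    s
  }, matrices, donor_labels, SIMPLIFY = FALSE)
  bc <- unlist(lapply(parts, `[[`, "barcodes"))
  if (anyDuplicated(bc)) stop("duplicate suffixed barcodes after merge")
  umi_matrix(do.call(rbind, lapply(parts, `[[`, "counts")),
             barcodes = bc,
             genes = parts[[1]]$genes,
             donor = unlist(lapply(parts, `[[`, "donor")))
}
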