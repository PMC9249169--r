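# Readers, writers, QC filters, size factors and window aggregation.
# Formats: expression as dense TSV/CSV (cells x features, first column
# cell_id) or MatrixMarket (.mtx with <path>.rows / <path>.cols sidecars);
# epigenome as long TSV (feature_id, cell_id, met_reads, total_reads);
# factors as TSV (cell_id, size_factor).

read_expression_matrix <- function(path) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    rows <- readLines(paste0(path, ".rows"))
    cols <- readLines(paste0(path, ".cols"))
    if (nrow(m) != length(rows) || ncol(m) != length(cols))
      stop("MatrixMarket dimensions do not match the .rows/.cols sidecars")
    dimnames(m) <- list(rows, cols)
    return(m)
  }
  dt <- data.table::fread(path, header = TRUE)
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- as.character(dt[[1]])
  storage.mode(m) <- "numeric"
  if (anyNA(m)) {
    bad <- which(rowSums(is.na(m)) > 0)[1]
    stop(sprintf("malformed expression row at line %d of %s", bad + 1L, path))
  }
  m
}

#' Read a paired two-layer dataset from disk
#'
#' Inner-joins the expression matrix (cells x features) with the
#' long-format epigenome table on (feature, cell). Cells present in the
#' expression matrix but absent from the epigenome table get coverage 0
#' (missing, not evidence of zero); features present in only one layer
#' are dropped. Optional cell scaling factors default to 1.
#'
#' @param expression_path dense TSV/CSV (first column `cell_id`) or
#'   MatrixMarket `.mtx` with `.rows`/`.cols` sidecar name files.
#' @param epigenome_path long TSV with columns `feature_id`, `cell_id`,
#'   `met_reads`, `total_reads`.
#' @param factors_path optional TSV with columns `cell_id`, `size_factor`.
#' @return List of [feature_data], one per shared feature, with a
#'   `cells` attribute giving the cell ordering.
#' @export
read_dataset <- function(expression_path, epigenome_path, factors_path = NULL) {
  expr <- read_expression_matrix(expression_path)
  meth <- data.table::fread(epigenome_path, header = TRUE)
  need <- c("feature_id", "cell_id", "met_reads", "total_reads")
  if (!all(need %in% names(meth)))
    stop("epigenome table must have columns: ", paste(need, collapse = ", "))
  meth <- as.data.frame(meth)
  meth$met_reads <- suppressWarnings(as.numeric(meth$met_reads))
  meth$total_reads <- suppressWarnings(as.numeric(meth$total_reads))
  bad <- which(!is.finite(meth$met_reads) | !is.finite(meth$total_reads))
  if (length(bad))
    stop(sprintf("malformed epigenome row at line %d of %s", bad[1] + 1L, epigenome_path))
  over <- which(meth$met_reads > meth$total_reads)
  if (length(over))
    stop("met_reads exceeds total_reads at rows: ",
         paste(utils::head(over, 10), collapse = ", "))

  cells <- rownames(expr)
  if (!length(intersect(cells, unique(meth$cell_id))))
    stop("no overlapping cells between the expression and epigenome layers")
  features <- intersect(colnames(expr), unique(meth$feature_id))
  if (!length(features)) stop("no overlapping features between layers")

  s <- rep(1, length(cells))
  if (!is.null(factors_path)) {
    fac <- data.table::fread(factors_path, header = TRUE)
    if (!all(c("cell_id", "size_factor") %in% names(fac)))
      stop("factors file must have columns cell_id, size_factor")
    idx <- match(cells, fac$cell_id)
    if (anyNA(idx)) stop("size factors missing for some expression cells")
    s <- as.numeric(fac$size_factor[idx])
  }

  cell_pos <- seq_along(cells); names(cell_pos) <- cells
  out <- lapply(features, function(f) {
    rows <- meth[meth$feature_id == f & meth$cell_id %in% cells, ]
    y2 <- n <- rep(0, length(cells))
    if (nrow(rows)) {
      i <- cell_pos[rows$cell_id]
      y2[i] <- rows$met_reads
      n[i] <- rows$total_reads
    }
    feature_data(f, expr[, f], y2, n, s)
  })
  attr(out, "cells") <- cells
  out
}

#' Write a dataset to disk in the formats [read_dataset()] consumes
#'
#' @param dataset an `slc_dataset` or list of [feature_data].
#' @param dir output directory (created if needed). Writes
#'   `expression.tsv`, `methylation.tsv`, `factors.tsv` and, when ground
#'   truth is available, `truth.tsv`.
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  features <- dataset_features(dataset)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  I <- length(features[[1]]$y1)
  cells <- sprintf("cell_%04d", seq_len(I))
  expr <- vapply(features, `[[`, numeric(I), "y1")
  colnames(expr) <- vapply(features, `[[`, character(1), "feature_id")
  utils::write.table(data.frame(cell_id = cells, expr, check.names = FALSE),
                     file.path(dir, "expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  meth <- do.call(rbind, lapply(features, function(fd) {
    keep <- fd$n > 0
    if (!any(keep)) return(NULL)
    data.frame(feature_id = fd$feature_id, cell_id = cells[keep],
               met_reads = fd$y2[keep], total_reads = fd$n[keep],
               stringsAsFactors = FALSE)
  }))
  utils::write.table(meth, file.path(dir, "methylation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(cell_id = cells, size_factor = features[[1]]$s),
                     file.path(dir, "factors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (inherits(dataset, "slc_dataset") && !is.null(dataset$truth))
    utils::write.table(dataset$truth, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Quality-control filter
#'
#' Drops features with zero variance in either layer (expression counts,
#' or methylation rate over covered cells) and features whose fraction of
#' expression zeros exceeds `max_zero_frac`. For sparse count data in
#' both layers (10X-style accessibility), `check_layer2_zeros = TRUE`
#' additionally applies the zero-fraction rule to the second layer.
#'
#' @param dataset an `slc_dataset` or list of [feature_data].
#' @param max_zero_frac maximum tolerated fraction of zeros (default 0.80).
#' @param check_layer2_zeros also apply the zero rule to layer 2 counts.
#' @return The filtered dataset with a `drop_log` attribute
#'   (data.frame of dropped feature ids and reasons). Errors if nothing
#'   survives. Idempotent.
#' @export
qc_filter <- function(dataset, max_zero_frac = 0.80, check_layer2_zeros = FALSE) {
  features <- dataset_features(dataset)
  reason <- vapply(features, function(fd) {
    if (var(fd$y1) == 0) return("zero_variance_expression")
    covered <- fd$n > 0
    if (sum(covered) < 2L) return("zero_variance_epigenome")
    if (var(fd$y2[covered] / fd$n[covered]) == 0) return("zero_variance_epigenome")
    if (mean(fd$y1 == 0) > max_zero_frac) return("zero_fraction_expression")
    if (check_layer2_zeros && mean(fd$y2 == 0) > max_zero_frac)
      return("zero_fraction_epigenome")
    ""
  }, character(1))
  keep <- reason == ""
  if (!any(keep)) stop("all features removed by QC")
  drop_log <- data.frame(
    feature_id = vapply(features[!keep], `[[`, character(1), "feature_id"),
    reason = reason[!keep], stringsAsFactors = FALSE)
  out <- if (inherits(dataset, "slc_dataset")) {
    truth <- dataset$truth
    if (!is.null(truth)) truth <- truth[keep, , drop = FALSE]
    structure(list(features = features[keep], truth = truth,
                   config = dataset$config), class = "slc_dataset")
  } else {
    features[keep]
  }
  attr(out, "drop_log") <- drop_log
  out
}

read_annotation <- function(annotation) {
  if (is.character(annotation) && length(annotation) == 1L) {
    if (grepl("\\.(gtf|gff3?|gff)$", annotation, ignore.case = TRUE)) {
      gr <- rtracklayer::import(annotation)
      md <- S4Vectors::mcols(gr)
      if ("type" %in% names(md) && any(md$type == "gene")) gr <- gr[md$type == "gene"]
      id <- if ("gene_id" %in% names(S4Vectors::mcols(gr))) S4Vectors::mcols(gr)$gene_id
            else as.character(seq_along(gr))
      return(data.frame(gene_id = id,
                        chrom = as.character(GenomicRanges::seqnames(gr)),
                        start = GenomicRanges::start(gr),
                        end = GenomicRanges::end(gr),
                        strand = as.character(GenomicRanges::strand(gr)),
                        stringsAsFactors = FALSE))
    }
    if (grepl("\\.bed$", annotation, ignore.case = TRUE)) {
      bed <- data.table::fread(annotation, header = FALSE)
      if (ncol(bed) < 4L) stop("BED annotation needs at least 4 columns (name in column 4)")
      return(data.frame(gene_id = as.character(bed[[4]]),
                        chrom = as.character(bed[[1]]),
                        start = bed[[2]] + 1L,  # BED is 0-based half-open
                        end = bed[[3]],
                        strand = if (ncol(bed) >= 6L) as.character(bed[[6]]) else "*",
                        stringsAsFactors = FALSE))
    }
    annotation <- data.table::fread(annotation, header = TRUE)
  }
  annotation <- as.data.frame(annotation)
  need <- c("gene_id", "chrom", "start", "end")
  if (!all(need %in% names(annotation)))
    stop("annotation must provide columns: ", paste(need, collapse = ", "))
  if (is.null(annotation$strand)) annotation$strand <- "*"
  annotation
}

#' Aggregate site-level epigenome counts into gene windows
#'
#' Sums methylated (or open) and total counts over all sites falling
#' within a window around each gene's anchor, per cell. For
#' `anchor = "promoter"` the window is centred on the strand-aware TSS
#' (gene start on `+`, gene end on `-`); for `anchor = "gene_body"` the
#' gene interval is extended by the window on both sides. A site at
#' distance exactly `window_bp` is included. Coordinates are 1-based
#' inclusive; BED annotation files are converted on read.
#'
#' @param sites data.frame or TSV path with columns `chrom`, `pos`
#'   (1-based site position), `cell_id`, `met_reads`, `total_reads`.
#' @param annotation data.frame / TSV with columns `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, or a GTF/BED file path.
#' @param window_bp half-width of the window in base pairs.
#' @param anchor `"promoter"` (TSS-centred) or `"gene_body"`.
#' @return data.frame in the long epigenome format (`feature_id`,
#'   `cell_id`, `met_reads`, `total_reads`).
#' @export
aggregate_windows <- function(sites, annotation, window_bp,
                              anchor = c("promoter", "gene_body")) {
  anchor <- match.arg(anchor)
  if (is.character(sites) && length(sites) == 1L) sites <- data.table::fread(sites)
  sites <- as.data.frame(sites)
  need <- c("chrom", "pos", "cell_id", "met_reads", "total_reads")
  if (!all(need %in% names(sites)))
    stop("site table must provide columns: ", paste(need, collapse = ", "))
  ann <- read_annotation(annotation)

  if (anchor == "promoter") {
    if (any(!ann$strand %in% c("+", "-")))
      stop("promoter anchoring requires strand (+/-) for every gene")
    tss <- ifelse(ann$strand == "+", ann$start, ann$end)
    win_start <- tss - window_bp
    win_end <- tss + window_bp
  } else {
    win_start <- ann$start - window_bp
    win_end <- ann$end + window_bp
  }
  windows <- GenomicRanges::GRanges(
    ann$chrom, IRanges::IRanges(pmax(win_start, 1L), win_end))
  site_gr <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(sites$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(site_gr, windows, ignore.strand = TRUE)
  if (!length(hits)) {
    return(data.frame(feature_id = character(0), cell_id = character(0),
                      met_reads = numeric(0), total_reads = numeric(0)))
  }
  long <- data.frame(
    feature_id = ann$gene_id[S4Vectors::subjectHits(hits)],
    cell_id = sites$cell_id[S4Vectors::queryHits(hits)],
    met_reads = sites$met_reads[S4Vectors::queryHits(hits)],
    total_reads = sites$total_reads[S4Vectors::queryHits(hits)],
    stringsAsFactors = FALSE)
  agg <- stats::aggregate(cbind(met_reads, total_reads) ~ feature_id + cell_id,
                          data = long, FUN = sum)
  agg[order(agg$feature_id, agg$cell_id), , drop = FALSE]
}

#' Estimate cell scaling factors from an expression matrix
#'
#' Local substitutes for an external normalisation tool; user-supplied
#' factors always take precedence in the model. `libsize` uses total
#' counts per cell; `median_ratio` uses the median ratio to the
#' per-gene geometric mean (computed over genes expressed in every
#' cell). Factors are normalised to mean 1.
#'
#' @param expression_matrix numeric matrix, cells in rows, genes in
#'   columns.
#' @param method `"libsize"` or `"median_ratio"`.
#' @return Positive numeric vector of per-cell factors, mean 1.
#' @export
estimate_size_factors <- function(expression_matrix,
                                  method = c("libsize", "median_ratio")) {
  method <- match.arg(method)
  m <- as.matrix(expression_matrix)
  if (!length(m)) stop("empty expression matrix")
  if (method == "libsize") {
    totals <- rowSums(m)
    if (any(totals <= 0)) {
      warning("cells with zero total counts; their factors floored at epsilon")
      totals[totals <= 0] <- 1e-8
    }
    f <- totals / mean(totals)
  } else {
    if (any(rowSums(m) <= 0)) stop("a cell with zero total counts cannot be normalised by median ratio")
    loggeo <- colMeans(log(m))
    usable <- is.finite(loggeo)
    if (!any(usable)) stop("no gene is expressed in every cell; median-ratio factors undefined")
    f <- apply(m, 1, function(row) {
      median(exp(log(row[usable]) - loggeo[usable]))
    })
    if (any(!is.finite(f) | f <= 0)) stop("median-ratio factors undefined for some cells")
  }
  f / mean(f)
}
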