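# Reading, normalizing and assembling multi-slice ST data.
#
# A slice is a set of spots with raw counts (spots x genes), 2-D coordinates
# and a platform tag; a dataset is an ordered collection of slices sharing a
# common gene panel, with a global spot index running over slices in order.

PLATFORMS <- c("ST", "Visium", "SlideSeqV2")

#' Construct a single-slice container
#'
#' Low-level constructor used by [load_slice()] and the simulator. `counts`
#' and/or `expr` are spots-by-genes matrices whose rownames are spot barcodes
#' and colnames are gene identifiers; `coords` is a numeric matrix of 2-D
#' positions in platform units, row-aligned with the expression rows.
#'
#' @param counts integer matrix or sparse Matrix of non-negative counts, or
#'   `NULL` for pre-normalized (e.g. simulated) data.
#' @param coords numeric matrix with two columns (x, y).
#' @param platform one of `"ST"`, `"Visium"`, `"SlideSeqV2"`.
#' @param batch_id character scalar naming the slice/batch.
#' @param expr optional numeric matrix of normalized log expression.
#' @return an object of class `slice_data`.
#' @export
slice_data <- function(counts = NULL, coords, platform, batch_id,
                       expr = NULL) {
  platform <- match.arg(platform, PLATFORMS)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 2L) stop("coords must have exactly 2 columns")
  if (anyDuplicated(coords) > 0L)
    warning("duplicate coordinates within slice '", batch_id, "'")
  ref <- if (!is.null(counts)) counts else expr
  if (is.null(ref)) stop("one of counts or expr must be supplied")
  if (nrow(ref) != nrow(coords))
    stop("expression and coordinate row counts differ")
  if (!is.null(counts) && any(counts < 0))
    stop("counts must be non-negative")
  structure(
    list(counts = counts, expr = expr, coords = coords,
         platform = platform, batch_id = as.character(batch_id)),
    class = "slice_data"
  )
}

#' @export
print.slice_data <- function(x, ...) {
  n <- nrow(x$coords)
  p <- if (!is.null(x$expr)) ncol(x$expr) else ncol(x$counts)
  cat(sprintf("<slice_data '%s'> %d spots x %d genes [%s]%s\n",
              x$batch_id, n, p, x$platform,
              if (is.null(x$expr)) " (raw counts)" else " (normalized)"))
  invisible(x)
}

n_spots <- function(slice) nrow(slice$coords)

read_mtx_triplet <- function(counts_path) {
  # Accept either the directory holding the triplet or the matrix file itself.
  dir <- if (dir.exists(counts_path)) counts_path else dirname(counts_path)
  find1 <- function(stems) {
    for (s in stems) for (ext in c("", ".gz")) {
      f <- file.path(dir, paste0(s, ext))
      if (file.exists(f)) return(f)
    }
    stop("missing ", stems[1], " next to ", counts_path, call. = FALSE)
  }
  mtx <- find1(c("matrix.mtx"))
  bc  <- find1(c("barcodes.tsv"))
  ft  <- find1(c("features.tsv", "genes.tsv"))
  m <- Matrix::readMM(mtx)                         # genes x cells (10x layout)
  barcodes <- read.delim(bc, header = FALSE)[[1]]
  feats <- read.delim(ft, header = FALSE)
  genes <- if (ncol(feats) >= 2L) feats[[2]] else feats[[1]]
  if (nrow(m) != length(genes) || ncol(m) != length(barcodes))
    stop("MTX dimensions do not match barcodes/features files")
  m <- Matrix::t(m)                                # spots x genes
  rownames(m) <- as.character(barcodes)
  colnames(m) <- make.unique(as.character(genes))
  m
}

read_dense_counts <- function(path) {
  df <- read.csv(path, header = TRUE, check.names = FALSE,
                 stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

read_coords <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("barcode", first, ignore.case = TRUE)
  df <- read.csv(path, header = has_header, stringsAsFactors = FALSE)
  if (!has_header && ncol(df) == 6L) {
    # legacy 10x tissue_positions_list.csv:
    # barcode,in_tissue,array_row,array_col,pxl_row,pxl_col
    names(df) <- c("barcode", "in_tissue", "array_row", "array_col",
                   "pxl_row", "pxl_col")
  }
  nms <- tolower(names(df))
  if (all(c("pxl_row", "pxl_col") %in% nms) ||
      all(c("pxl_row_in_fullres", "pxl_col_in_fullres") %in% nms)) {
    if ("in_tissue" %in% nms) df <- df[df[[which(nms == "in_tissue")]] == 1, ]
    xy <- df[, grep("^pxl_", nms)[1:2]]
    co <- cbind(x = xy[[2]], y = xy[[1]])       # col ~ x, row ~ y
  } else if (ncol(df) >= 3L) {
    co <- as.matrix(df[, 2:3])
    colnames(co) <- c("x", "y")
  } else {
    stop("coordinate file must have a barcode column plus two numeric columns")
  }
  storage.mode(co) <- "double"
  rownames(co) <- as.character(df[[1]])
  co
}

#' Load one slice from disk
#'
#' Reads a counts matrix (10x MTX triplet or dense CSV with a header whose
#' first column holds spot barcodes) together with spot coordinates
#' (`barcode,x,y` CSV or a 10x tissue-positions file) and row-aligns the two
#' by exact, case-sensitive barcode match. Spots present in only one of the
#' files are dropped with a message.
#'
#' @param counts_path path to `matrix.mtx[.gz]`, its directory, or a dense
#'   CSV counts file.
#' @param coords_path path to the coordinates file.
#' @inheritParams slice_data
#' @param verbose emit alignment messages?
#' @return a [slice_data] object.
#' @export
load_slice <- function(counts_path, coords_path, platform,
                       batch_id = basename(counts_path), verbose = TRUE) {
  for (f in c(counts_path, coords_path)) {
    if (!file.exists(f)) stop("cannot read input file: ", f, call. = FALSE)
  }
  counts <- if (dir.exists(counts_path) ||
                grepl("\\.mtx(\\.gz)?$", counts_path)) {
    read_mtx_triplet(counts_path)
  } else {
    read_dense_counts(counts_path)
  }
  coords <- read_coords(coords_path)
  shared <- intersect(rownames(counts), rownames(coords))
  if (length(shared) == 0L)
    stop("no overlapping spot barcodes between counts and coordinates",
         call. = FALSE)
  dropped <- (nrow(counts) - length(shared)) + (nrow(coords) - length(shared))
  if (dropped > 0L)
    msg_log("load_slice: dropped ", dropped,
            " spot record(s) absent from the other file", verbose = verbose)
  slice_data(counts = counts[shared, , drop = FALSE],
             coords = coords[shared, , drop = FALSE],
             platform = platform, batch_id = batch_id)
}

#' Library-size normalization and log transform
#'
#' Computes `expr[i, j] = log(1 + scale * counts[i, j] / libsize_i)` where
#' `libsize_i` is the spot's total count. Spots with zero library size are
#' removed (with a message).
#'
#' @param slice a [slice_data] with raw counts.
#' @param scale target library size, default `1e4`.
#' @param verbose emit messages about removed spots?
#' @return the slice with `expr` filled in.
#' @export
normalize_log <- function(slice, scale = 1e4, verbose = TRUE) {
  stopifnot(inherits(slice, "slice_data"))
  if (is.null(slice$counts)) stop("slice has no counts to normalize")
  if (scale <= 0) stop("scale must be positive")
  counts <- as.matrix(slice$counts)
  lib <- rowSums(counts)
  if (all(lib == 0)) stop("all spots have zero library size", call. = FALSE)
  keep <- lib > 0
  if (any(!keep))
    msg_log("normalize_log: removed ", sum(!keep),
            " spot(s) with zero library size in '", slice$batch_id, "'",
            verbose = verbose)
  counts <- counts[keep, , drop = FALSE]
  expr <- log1p(scale * counts / rowSums(counts))
  slice_data(counts = counts, coords = slice$coords[keep, , drop = FALSE],
             platform = slice$platform, batch_id = slice$batch_id,
             expr = expr)
}

#' Assemble slices into a multi-slice dataset
#'
#' Restricts every slice to the strict intersection of the gene panels (the
#' loading matrix is shared across batches, so a common panel is required),
#' orders genes identically, and assigns global spot indices running over
#' slices in the given order.
#'
#' @param slices list of [slice_data] objects, each normalized.
#' @return an object of class `st_dataset` with fields `slices`, `genes`,
#'   `spots` (a tibble with barcode, batch, x, y and the global index) and
#'   `n_total`.
#' @export
assemble_dataset <- function(slices) {
  stopifnot(length(slices) >= 1L, all(vapply(slices, inherits, TRUE,
                                             "slice_data")))
  ids <- vapply(slices, function(s) s$batch_id, "")
  if (anyDuplicated(ids)) stop("batch ids must be unique")
  panels <- lapply(slices, function(s) colnames(s$expr %||% s$counts))
  genes <- Reduce(intersect, panels)
  if (length(genes) == 0L) stop("slices share no genes")
  slices <- lapply(slices, function(s) {
    s$expr <- if (!is.null(s$expr)) s$expr[, genes, drop = FALSE]
    s$counts <- if (!is.null(s$counts)) s$counts[, genes, drop = FALSE]
    s
  })
  names(slices) <- ids
  ns <- vapply(slices, n_spots, 1L)
  spots <- dplyr::bind_rows(lapply(slices, function(s) {
    tibble(barcode = rownames(s$coords) %||%
             paste0(s$batch_id, "_", seq_len(n_spots(s))),
           batch = s$batch_id,
           x = s$coords[, 1], y = s$coords[, 2])
  }))
  spots$index <- seq_len(nrow(spots))
  structure(
    list(slices = slices, genes = genes, spots = spots,
         n_total = sum(ns), centered = FALSE, center = NULL),
    class = "st_dataset"
  )
}

#' @export
print.st_dataset <- function(x, ...) {
  cat(sprintf("<st_dataset> %d slices, %d spots, %d shared genes%s\n",
              length(x$slices), x$n_total, length(x$genes),
              if (x$centered) " (centered)" else ""))
  for (s in x$slices) print(s)
  invisible(x)
}

#' Stacked expression matrix of a dataset
#'
#' @param dataset an `st_dataset`.
#' @return dense numeric matrix, `n_total` spots by `p` genes, slices stacked
#'   in order.
#' @export
expr_matrix <- function(dataset) {
  do.call(rbind, lapply(dataset$slices, function(s) {
    if (is.null(s$expr)) stop("slice '", s$batch_id, "' is not normalized")
    as.matrix(s$expr)
  }))
}

#' @noRd
batch_index <- function(dataset) {
  rep(seq_along(dataset$slices),
      vapply(dataset$slices, n_spots, 1L))
}

#' Rank genes by variability across slices
#'
#' Scores each gene per slice by standardized dispersion (variance/mean of the
#' de-logged normalized expression, z-scored within 20 mean bins), then
#' aggregates by the median of per-slice ranks. Deterministic; ties broken by
#' gene-panel order.
#'
#' @param dataset an assembled, normalized `st_dataset`.
#' @param n_genes number of genes to keep (default 2000).
#' @return character vector of selected gene identifiers, best first.
#' @export
select_hvgs <- function(dataset, n_genes = 2000) {
  stopifnot(inherits(dataset, "st_dataset"))
  p <- length(dataset$genes)
  if (n_genes > p)
    stop("n_genes (", n_genes, ") exceeds the shared panel size (", p, ")")
  ranks <- vapply(dataset$slices, function(s) {
    e <- expm1(as.matrix(s$expr))
    mu <- colMeans(e)
    v <- apply(e, 2, var)
    disp <- ifelse(mu > 0, v / mu, 0)
    ldisp <- log1p(disp)
    bins <- cut(rank(mu, ties.method = "first"),
                breaks = min(20L, max(1L, floor(p / 2))), labels = FALSE)
    z <- ldisp
    for (b in unique(bins)) {
      i <- bins == b
      s_ <- sd(ldisp[i])
      z[i] <- if (isTRUE(s_ > 0)) (ldisp[i] - mean(ldisp[i])) / s_ else 0
    }
    rank(-z, ties.method = "first")
  }, numeric(p))
  med <- apply(as.matrix(ranks), 1, median)
  dataset$genes[order(med, seq_len(p))][seq_len(n_genes)]
}

#' Restrict a dataset to a gene subset
#'
#' @param dataset an `st_dataset`.
#' @param genes character vector; must be a subset of the shared panel.
#' @return the restricted dataset.
#' @export
filter_genes <- function(dataset, genes) {
  missing <- setdiff(genes, dataset$genes)
  if (length(missing) > 0L)
    stop("genes not in the shared panel: ", paste(head(missing, 5),
                                                  collapse = ", "))
  dataset$slices <- lapply(dataset$slices, function(s) {
    s$expr <- if (!is.null(s$expr)) s$expr[, genes, drop = FALSE]
    s$counts <- if (!is.null(s$counts)) s$counts[, genes, drop = FALSE]
    s
  })
  dataset$genes <- genes
  dataset$centered <- FALSE
  dataset$center <- NULL
  dataset
}

#' Center each gene over all spots of all slices
#'
#' Subtracts from each gene its mean over the pooled dataset, so the factor
#' model needs no global intercept (the cluster-mean prior is centered at
#' zero). The centering vector is stored for the inverse transform.
#'
#' @param dataset an `st_dataset` with normalized expression.
#' @return the centered dataset (idempotent).
#' @export
center_genes <- function(dataset) {
  Y <- expr_matrix(dataset)
  mu <- colMeans(Y)
  dataset$slices <- lapply(dataset$slices, function(s) {
    s$expr <- sweep(as.matrix(s$expr), 2, mu, "-")
    s
  })
  prev <- dataset$center %||% rep(0, length(mu))
  dataset$center <- prev + mu
  dataset$centered <- TRUE
  dataset
}

#' Undo gene centering
#'
#' @param dataset a centered `st_dataset`.
#' @return dataset with the stored gene means added back.
#' @export
uncenter_genes <- function(dataset) {
  if (!isTRUE(dataset$centered) || is.null(dataset$center)) return(dataset)
  mu <- dataset$center
  dataset$slices <- lapply(dataset$slices, function(s) {
    s$expr <- sweep(as.matrix(s$expr), 2, mu, "+")
    s
  })
  dataset$center <- NULL
  dataset$centered <- FALSE
  dataset
}

#' Write an assembled dataset to an open-format bundle
#'
#' Writes `genes.tsv`, a per-spot table `spots.csv`
#' (`barcode,batch,platform,x,y`), one dense `expr_<batch>.csv` per slice and,
#' when raw counts are present, a 10x-style MTX triplet per slice under
#' `counts_<batch>/`.
#'
#' @param dataset an `st_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(dataset$genes, file.path(dir, "genes.tsv"))
  spots <- dataset$spots
  spots$platform <- rep(vapply(dataset$slices, function(s) s$platform, ""),
                        vapply(dataset$slices, n_spots, 1L))
  write.csv(spots[, c("barcode", "batch", "platform", "x", "y")],
            file.path(dir, "spots.csv"), row.names = FALSE)
  for (s in dataset$slices) {
    if (!is.null(s$expr)) {
      df <- data.frame(barcode = rownames(s$expr), as.data.frame(s$expr),
                       check.names = FALSE)
      write.csv(df, file.path(dir, paste0("expr_", s$batch_id, ".csv")),
                row.names = FALSE)
    }
    if (!is.null(s$counts)) {
      cdir <- file.path(dir, paste0("counts_", s$batch_id))
      dir.create(cdir, showWarnings = FALSE)
      Matrix::writeMM(as(as(Matrix::t(as(s$counts, "CsparseMatrix")),
                            "generalMatrix"), "CsparseMatrix"),
                      file.path(cdir, "matrix.mtx"))
      writeLines(rownames(s$counts), file.path(cdir, "barcodes.tsv"))
      writeLines(paste(colnames(s$counts), colnames(s$counts), "Gene Expression",
                       sep = "\t"), file.path(cdir, "features.tsv"))
    }
  }
  invisible(dir)
}

#' Read a dataset bundle written by [write_dataset()]
#'
#' @param dir bundle directory.
#' @return an `st_dataset`.
#' @export
read_dataset <- function(dir) {
  genes <- readLines(file.path(dir, "genes.tsv"))
  spots <- read.csv(file.path(dir, "spots.csv"), stringsAsFactors = FALSE)
  slices <- lapply(split(spots, factor(spots$batch,
                                       levels = unique(spots$batch))),
                   function(sp) {
    b <- sp$batch[1]
    efile <- file.path(dir, paste0("expr_", b, ".csv"))
    expr <- NULL
    if (file.exists(efile)) {
      df <- read.csv(efile, check.names = FALSE, stringsAsFactors = FALSE)
      expr <- as.matrix(df[, -1, drop = FALSE])
      rownames(expr) <- df[[1]]
      expr <- expr[match(sp$barcode, rownames(expr)), genes, drop = FALSE]
    }
    cdir <- file.path(dir, paste0("counts_", b))
    counts <- NULL
    if (dir.exists(cdir)) {
      counts <- read_mtx_triplet(cdir)[sp$barcode, genes, drop = FALSE]
    }
    co <- cbind(x = sp$x, y = sp$y)
    rownames(co) <- sp$barcode
    slice_data(counts = counts, coords = co, platform = sp$platform[1],
               batch_id = b, expr = expr)
  })
  assemble_dataset(slices[unique(spots$batch)])
}
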