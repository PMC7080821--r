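#' Read an expression matrix from disk
#'
#' Dense CSV/TSV (header row = gene IDs, first column = cell IDs) or
#' MatrixMarket coordinate format (`matrix.mtx` with `barcodes.tsv` and
#' `features.tsv`/`genes.tsv` sidecars in the same directory, 10x dialect:
#' genes in rows, cells in columns — transposed on read). The internal
#' orientation is always cells in rows.
#'
#' @param path File path (`.mtx` file for the MatrixMarket dialect).
#' @param dialect `"csv"`, `"tsv"`, or `"mtx"`; guessed from the extension
#'   when omitted.
#' @param genes_in_rows For dense files: the file stores genes in rows and
#'   cells in columns, so transpose on read. Ignored for MTX (always
#'   genes-in-rows).
#' @param scale Declared transformation state of the values.
#' @return An `expr_matrix`.
#' @export
read_matrix <- function(path, dialect = NULL, genes_in_rows = FALSE,
                        scale = c("counts", "tpm", "log", "standardized")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (is.null(dialect)) {
    dialect <- switch(tolower(tools::file_ext(path)),
                      csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
                      stop("cannot guess dialect from extension of ", path))
  }
  dialect <- match.arg(dialect, c("csv", "tsv", "mtx"))
  if (dialect == "mtx") {
    dir <- dirname(path)
    bc <- file.path(dir, "barcodes.tsv")
    ft_candidates <- file.path(dir, c("features.tsv", "genes.tsv"))
    ft <- ft_candidates[file.exists(ft_candidates)][1]
    if (!file.exists(bc) || is.na(ft))
      stop("MTX input needs barcodes.tsv and features.tsv/genes.tsv next to ",
           path)
    mm <- as.matrix(Matrix::readMM(path))
    barcodes <- data.table::fread(bc, header = FALSE)[[1]]
    feats <- data.table::fread(ft, header = FALSE)[[1]]
    if (nrow(mm) != length(feats))
      stop("MTX has ", nrow(mm), " rows but ", length(feats), " features")
    if (ncol(mm) != length(barcodes))
      stop("MTX has ", ncol(mm), " columns but ", length(barcodes),
           " barcodes")
    return(expression_matrix(t(mm), barcodes, feats, scale = scale))
  }
  sep <- if (dialect == "csv") "," else "\t"
  hdr <- strsplit(readLines(path, n = 1), sep, fixed = TRUE)[[1]][-1]
  if (anyDuplicated(hdr))
    stop("duplicate gene IDs in header of ", path, ": ",
         hdr[duplicated(hdr)][1])
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          data.table = FALSE)
  if (ncol(dt) < 2) stop("malformed table in ", path, ": fewer than 2 columns")
  ids <- as.character(dt[[1]])
  vals <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric entries in ", path)
  rownames(vals) <- ids
  if (genes_in_rows) vals <- t(vals)
  expression_matrix(vals, scale = scale)
}

#' Write an expression matrix to disk
#'
#' Inverse of [read_matrix()], in the same dialects. Dense output keeps
#' cells in rows unless `genes_in_rows = TRUE`; MTX output writes the 10x
#' triple (`.mtx` + `barcodes.tsv` + `features.tsv`, genes in rows).
#'
#' @param m `expr_matrix`.
#' @param path Output path (`.mtx` file name for the MTX dialect).
#' @param dialect `"csv"`, `"tsv"`, or `"mtx"`; guessed from the extension
#'   when omitted.
#' @param genes_in_rows Transpose dense output.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, dialect = NULL, genes_in_rows = FALSE) {
  stopifnot(inherits(m, "expr_matrix"))
  if (is.null(dialect)) {
    dialect <- switch(tolower(tools::file_ext(path)),
                      csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
                      stop("cannot guess dialect from extension of ", path))
  }
  dialect <- match.arg(dialect, c("csv", "tsv", "mtx"))
  if (dialect == "mtx") {
    dir <- dirname(path)
    Matrix::writeMM(Matrix::Matrix(t(m$values), sparse = TRUE), path)
    writeLines(m$cell_ids, file.path(dir, "barcodes.tsv"))
    writeLines(m$gene_ids, file.path(dir, "features.tsv"))
    return(invisible(path))
  }
  vals <- if (genes_in_rows) t(m$values) else m$values
  df <- data.frame(id = rownames(vals), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- if (genes_in_rows) "gene_id" else "cell_id"
  data.table::fwrite(df, path, sep = if (dialect == "csv") "," else "\t")
  invisible(path)
}

#' Save / load a fitted model
#'
#' Serializes the full model (config, all parameter arrays, gene IDs, loss
#' trace) to a single archive file; the round trip is exact.
#'
#' @param model A `fitted_ca`.
#' @param path Archive file path.
#' @return `path` invisibly; `load_model` returns the `fitted_ca`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "fitted_ca"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model archive not found: ", path)
  model <- readRDS(path)
  if (!inherits(model, "fitted_ca")) stop(path, " is not a saved model")
  model
}

#' Write pseudo-time results
#'
#' `write_pseudotime` emits a CSV with `cell_id`, `pseudotime`, and one
#' column per linear component. `write_phenotype_cls` emits the continuous
#' one-phenotype CLS dialect (a `#numeric` header block followed by the
#' values) consumed by external gene-set enrichment tools.
#'
#' @param pt A `pseudotime_result`.
#' @param path Output file.
#' @param digits Significant digits for the CSV (full precision is kept in
#'   the model archive).
#' @return `path`, invisibly.
#' @export
write_pseudotime <- function(pt, path, digits = 6) {
  stopifnot(inherits(pt, "pseudotime_result"))
  df <- data.frame(cell_id = pt$cell_ids,
                   pseudotime = signif(unname(pt$circular), digits),
                   stringsAsFactors = FALSE)
  if (ncol(pt$linear) > 0) {
    lin <- signif(pt$linear, digits)
    colnames(lin) <- sprintf("linear_%d", seq_len(ncol(lin)))
    df <- cbind(df, lin)
  }
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_pseudotime
#' @export
write_phenotype_cls <- function(pt, path, digits = 6) {
  stopifnot(inherits(pt, "pseudotime_result"))
  writeLines(c("#numeric", "#pseudotime",
               paste(signif(unname(pt$circular), digits), collapse = " ")),
             path)
  invisible(path)
}

#' Write a machine-readable provenance record
#'
#' JSON sidecar recording the seed, configuration, package and R versions,
#' and MD5 checksums of the input files, so any output can be traced back
#' to the exact run that produced it.
#'
#' @param path Output JSON file.
#' @param seed Integer seed of the run.
#' @param config Arbitrary configuration list (coerced to JSON).
#' @param inputs Character vector of input file paths to checksum.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, seed = NULL, config = NULL,
                             inputs = character(0)) {
  rec <- list(
    package = "scperiodic",
    version = as.character(utils::packageVersion("scperiodic")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    inputs = if (length(inputs))
      lapply(stats::setNames(inputs, inputs),
             function(f) unname(tools::md5sum(f)))
    else NULL)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
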