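#' Read a cell-by-feature matrix
#'
#' Supported formats: delimited text (\code{tsv}, \code{csv}; header row =
#' feature ids, optional first column = cell ids), dense binary \code{npy}
#' (NumPy v1.0 layout, with optional plain-text id sidecars
#' \code{<path>.rows} / \code{<path>.cols}), and Matrix Market coordinate
#' \code{mtx} (same sidecar convention). Missing ids are generated. Sparse
#' input is densified by [modality_matrix()].
#'
#' @param path file to read.
#' @param format one of \code{"auto"} (from the extension), \code{"tsv"},
#'   \code{"csv"}, \code{"npy"}, \code{"mtx"}.
#' @param transpose flip to cells-in-rows when the file stores features in
#'   rows.
#' @return a [modality_matrix()].
#' @export
read_matrix <- function(path, format = c("auto", "tsv", "csv", "npy", "mtx"),
                        transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, tsv = "tsv", txt = "tsv", tab = "tsv", csv = "csv",
                     npy = "npy", mtx = "mtx",
                     stop(sprintf("cannot infer format from extension '.%s'", ext)))
  }
  out <- switch(format,
                tsv = .read_delim_matrix(path, "\t"),
                csv = .read_delim_matrix(path, ","),
                npy = .read_npy_matrix(path),
                mtx = .read_mtx_matrix(path))
  modality_matrix(out$values, out$cell_ids, out$feature_ids,
                  transpose = transpose)
}

.read_delim_matrix <- function(path, sep) {
  df <- tryCatch(
    utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE, comment.char = "",
                      quote = "\""),
    error = function(e) stop(sprintf("format error in %s: %s", path,
                                     conditionMessage(e)), call. = FALSE)
  )
  cell_ids <- NULL
  if (ncol(df) >= 2L && !is.numeric(df[[1L]])) {
    cell_ids <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
  }
  bad <- which(!vapply(df, is.numeric, TRUE))
  if (length(bad)) {
    col <- bad[1L]
    row <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1L]
    stop(sprintf("format error in %s: non-numeric entry in column '%s' (data line %s)",
                 path, names(df)[col], ifelse(is.na(row), "?", row)), call. = FALSE)
  }
  list(values = as.matrix(df), cell_ids = cell_ids, feature_ids = colnames(df))
}

.read_sidecar <- function(path, suffix, n) {
  f <- paste0(path, suffix)
  if (!file.exists(f)) return(NULL)
  ids <- readLines(f)
  if (length(ids) != n) {
    stop(sprintf("format error: %s has %d ids, expected %d", f, length(ids), n))
  }
  ids
}

.read_mtx_matrix <- function(path) {
  m <- as.matrix(Matrix::readMM(path))
  list(values = m,
       cell_ids = .read_sidecar(path, ".rows", nrow(m)),
       feature_ids = .read_sidecar(path, ".cols", ncol(m)))
}

.read_npy_matrix <- function(path) {
  m <- read_npy(path)
  if (is.null(dim(m))) m <- matrix(m, ncol = 1L)
  list(values = m,
       cell_ids = .read_sidecar(path, ".rows", nrow(m)),
       feature_ids = .read_sidecar(path, ".cols", ncol(m)))
}

# --- minimal NPY v1.0 reader/writer -------------------------------------------
# Dense 1-D/2-D arrays; dtypes <f8, <f4, <i4, <i8; C or Fortran order.
# No R package in the dependency set reads .npy, so the 60 lines live here.

#' Read a dense NumPy .npy array
#'
#' Minimal reader for the v1.x layout: little-endian float32/float64/int32/
#' int64, 1- or 2-dimensional, C or Fortran order.
#'
#' @param path file to read.
#' @return numeric vector or matrix.
#' @export
read_npy <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  if (!identical(magic, as.raw(c(0x93, charToRaw("NUMPY"))))) {
    stop(sprintf("format error: %s is not an NPY file", path))
  }
  ver <- readBin(con, "raw", 2L)
  hlen <- if (as.integer(ver[1L]) >= 2L) {
    readBin(con, "integer", 1L, size = 4L, endian = "little")
  } else {
    readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = "little")
  }
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr'\\s*:\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order'\\s*:\\s*True", header)
  shape_s <- sub(".*'shape'\\s*:\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_s), ",")[[1]])
  shape <- shape[!is.na(shape)]
  n <- prod(shape)
  vals <- switch(descr,
    "<f8" = readBin(con, "double", n, size = 8L, endian = "little"),
    "<f4" = readBin(con, "double", n, size = 4L, endian = "little"),
    "<i4" = readBin(con, "integer", n, size = 4L, endian = "little"),
    "<i8" = {
      raw8 <- matrix(as.integer(readBin(con, "raw", n * 8L)), nrow = 8L)
      w <- 2^(8 * (0:7))
      # two's complement: negatives via the complement so intermediates stay
      # small enough to be exact in doubles (values beyond 2^53 lose precision)
      pos <- colSums(raw8 * w)
      neg <- -(colSums((255L - raw8) * w) + 1)
      ifelse(raw8[8L, ] >= 128L, neg, pos)
    },
    stop(sprintf("format error: unsupported NPY dtype '%s'", descr)))
  vals <- as.double(vals)
  if (length(shape) == 1L) return(vals)
  if (length(shape) != 2L) stop("format error: only 1-D and 2-D NPY supported")
  if (fortran) matrix(vals, shape[1L], shape[2L])
  else t(matrix(vals, shape[2L], shape[1L]))
}

#' Write a dense NumPy .npy array
#'
#' Writes a numeric vector or matrix as little-endian float64, C order,
#' NPY format v1.0.
#'
#' @param x numeric vector or matrix.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_npy <- function(x, path) {
  if (is.matrix(x)) {
    shape <- sprintf("(%d, %d)", nrow(x), ncol(x))
    vals <- as.double(t(x))     # C order
  } else {
    shape <- sprintf("(%d,)", length(x))
    vals <- as.double(x)
  }
  header <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': %s, }",
                    shape)
  # total preamble (10 bytes) + header padded to a multiple of 16, '\n'-terminated
  pad <- 16L - ((10L + nchar(header) + 1L) %% 16L)
  if (pad == 16L) pad <- 0L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(nchar(header), con, size = 2L, endian = "little")
  writeBin(charToRaw(header), con)
  writeBin(vals, con, size = 8L, endian = "little")
  invisible(path)
}

#' Write a cell-by-feature matrix
#'
#' Inverse of [read_matrix()]: TSV/CSV with a \code{cell_id} first column and
#' feature ids in the header; NPY or MTX with \code{.rows}/\code{.cols} id
#' sidecars.
#'
#' @param x a [modality_matrix()] or numeric matrix.
#' @param path output file.
#' @param format \code{"tsv"}, \code{"csv"}, \code{"npy"} or \code{"mtx"}.
#' @return invisibly, \code{path}.
#' @export
write_matrix <- function(x, path, format = c("tsv", "csv", "npy", "mtx")) {
  format <- match.arg(format)
  if (!inherits(x, "modality_matrix")) x <- modality_matrix(as_modality_values(x))
  if (format %in% c("tsv", "csv")) {
    df <- data.frame(cell_id = x$cell_ids, x$values, check.names = FALSE)
    colnames(df) <- c("cell_id", x$feature_ids)
    utils::write.table(df, path, sep = ifelse(format == "tsv", "\t", ","),
                       quote = FALSE, row.names = FALSE)
  } else {
    if (format == "npy") {
      write_npy(x$values, path)
    } else {
      Matrix::writeMM(methods::as(Matrix::Matrix(x$values, sparse = TRUE),
                                  "generalMatrix"), path)
    }
    writeLines(x$cell_ids, paste0(path, ".rows"))
    writeLines(x$feature_ids, paste0(path, ".cols"))
  }
  invisible(path)
}

# --- run configuration ---------------------------------------------------------

#' Write / read a flat key=value run configuration
#'
#' One \code{key=value} pair per line; values are deparsed so that numbers,
#' logicals and strings round-trip exactly.
#'
#' @param config named list of scalar settings.
#' @param path file.
#' @return \code{write_run_config}: invisibly, \code{path};
#'   \code{read_run_config}: the named list.
#' @export
write_run_config <- function(config, path) {
  stopifnot(!is.null(names(config)), all(nzchar(names(config))))
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    s <- if (is.character(v)) v
    else if (is.logical(v)) ifelse(v, "TRUE", "FALSE")
    else format(v, digits = 17, scientific = FALSE, trim = TRUE)
    sprintf("%s=%s", k, s)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  out <- list()
  for (p in kv) {
    v <- p[2L]
    parsed <- if (v %in% c("TRUE", "FALSE")) as.logical(v)
    else if (grepl("^-?[0-9.]+(e[+-]?[0-9]+)?$", v)) as.numeric(v)
    else v
    out[[trimws(p[1L])]] <- parsed
  }
  out
}

#' Write the artifacts of a fitted alignment
#'
#' Writes, under \code{outdir}: \code{embedding_x.tsv} and
#' \code{embedding_y.tsv} (cell ids + latent coordinates),
#' \code{params_x.tsv} / \code{params_y.tsv}, \code{trace.tsv}
#' (iteration, loss components, total, foscttm), and \code{config.txt}
#' (the resolved hyperparameters). Re-reading an embedding with
#' [read_matrix()] reproduces the values to float precision.
#'
#' @param fit a fitted [mmdma()] object.
#' @param outdir output directory (created if needed).
#' @return invisibly, the vector of paths written.
#' @export
write_results <- function(fit, outdir) {
  stopifnot(inherits(fit, "mmdma"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dims <- sprintf("dim_%02d", seq_len(ncol(fit$embedding_x)))
  paths <- character(0)
  wemb <- function(emb, ids, name) {
    mm <- modality_matrix(emb, cell_ids = ids, feature_ids = dims)
    p <- file.path(outdir, name)
    write_matrix(mm, p, "tsv")
    p
  }
  paths <- c(paths, wemb(fit$embedding_x, fit$cell_ids_x, "embedding_x.tsv"))
  paths <- c(paths, wemb(fit$embedding_y, fit$cell_ids_y, "embedding_y.tsv"))
  for (side in c("x", "y")) {
    p <- file.path(outdir, sprintf("params_%s.tsv", side))
    utils::write.table(fit[[paste0("params_", side)]], p, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = dims)
    paths <- c(paths, p)
  }
  tp <- file.path(outdir, "trace.tsv")
  utils::write.table(fit$trace, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, tp)
  hp <- fit$hp_used
  cfg <- list(mode = hp$mode, d = hp$d, lambda1 = hp$lambda1,
              lambda2 = hp$lambda2,
              sigma = if (is.numeric(hp$sigma)) hp$sigma else hp$sigma,
              sigma_used = fit$sigma_used, n_iter = hp$n_iter,
              learning_rate = hp$learning_rate, seed = hp$seed,
              streaming = hp$streaming, block_size = hp$block_size,
              eval_interval = hp$eval_interval)
  cp <- file.path(outdir, "config.txt")
  write_run_config(cfg, cp)
  invisible(c(paths, cp))
}
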