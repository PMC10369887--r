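# Readers/writers for the text interchange formats and full-precision model
# serialization (JSON manifest + %.17g TSV arrays, which round-trips doubles
# bit-identically).

#' Read a cell-state (or any cells-by-features) matrix
#'
#' TSV/CSV: header row, first column holds cell ids. MTX: Matrix-market
#' triplets with a sidecar id file (one id per line); set `transpose = TRUE`
#' when the triplets are stored features-by-cells.
#'
#' @param path input file.
#' @param format `"tsv"`, `"csv"` or `"mtx"`; default guessed from the
#'   extension.
#' @param ids path to the row-id file (MTX only).
#' @param transpose transpose an MTX matrix after reading.
#' @return numeric matrix with cell ids as row names.
#' @export
read_state_matrix <- function(path, format = NULL, ids = NULL,
                              transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- format %||% tolower(tools::file_ext(path))
  if (format %in% c("tsv", "csv")) {
    df <- read.table(path, header = TRUE, sep = if (format == "tsv") "\t" else ",",
                     check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
      stop(sprintf("non-numeric values in column '%s'", names(df[-1])[bad]))
    }
    if (anyNA(m)) {
      w <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop(sprintf("missing value at row %d, column %d", w[1], w[2]))
    }
    rownames(m) <- as.character(df[[1]])
    return(m)
  }
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    if (transpose) m <- t(m)
    if (!is.null(ids)) {
      id <- readLines(ids)
      if (length(id) != nrow(m))
        stop(sprintf("id file has %d entries but the matrix has %d rows",
                     length(id), nrow(m)))
      rownames(m) <- id
    }
    return(m)
  }
  stop("unsupported format: ", format)
}

#' Write a matrix as TSV with a leading cell_id column
#'
#' @param m matrix with row names.
#' @param path output file.
#' @param digits significant digits (default 17, lossless for doubles).
#' @export
write_state_matrix <- function(m, path, digits = 17) {
  df <- data.frame(cell_id = rownames(m) %||% seq_len(nrow(m)),
                   formatC(m, format = "g", digits = digits),
                   check.names = FALSE)
  colnames(df) <- c("cell_id", colnames(m) %||% paste0("dim_", seq_len(ncol(m))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

fmt_full <- function(x) formatC(x, format = "g", digits = 17)

write_array_tsv <- function(x, path) {
  x <- as.matrix(x)
  write.table(fmt_full(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
}

read_array_tsv <- function(path) {
  as.matrix(read.table(path, sep = "\t", header = FALSE,
                       colClasses = "numeric"))
}

#' Serialize and restore fitted density models
#'
#' Writes a directory holding a JSON manifest (scalars, configuration,
#' package version) and TSV arrays at 17 significant digits, so that
#' `read_cell_density()` restores a model whose predictions are bit-identical.
#' Works for both `cell_density` and `cell_density_time` fits.
#'
#' @param object a fitted model.
#' @param dir output directory (created if needed).
#' @export
write_cell_density <- function(object, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  is_time <- inherits(object, "cell_density_time")
  manifest <- list(
    package = "celldensity",
    version = as.character(utils::packageVersion("celldensity")),
    class = class(object),
    mean = fmt_full(object$mean),
    length_scale = fmt_full(object$kernel$length_scale),
    variance = fmt_full(object$kernel$variance),
    density_dim = object$density_dim, mode = object$mode,
    n = object$n, dim = object$dim, seed = object$seed,
    jitter = fmt_full(object$jitter))
  if (is_time) {
    manifest$time_length_scale <- fmt_full(object$time_kernel$length_scale)
    manifest$time_range <- fmt_full(object$time_range)
    write_array_tsv(object$landmark_times, file.path(dir, "landmark_times.tsv"))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  write_array_tsv(object$landmarks, file.path(dir, "landmarks.tsv"))
  write_array_tsv(cbind(object$latent, object$weights),
                  file.path(dir, "coefficients.tsv"))
  invisible(dir)
}

#' @rdname write_cell_density
#' @export
read_cell_density <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  if (!identical(manifest$package, "celldensity"))
    stop("not a celldensity model directory")
  co <- read_array_tsv(file.path(dir, "coefficients.tsv"))
  object <- list(
    mean = as.numeric(manifest$mean),
    kernel = list(type = "matern52",
                  length_scale = as.numeric(manifest$length_scale),
                  variance = as.numeric(manifest$variance)),
    landmarks = read_array_tsv(file.path(dir, "landmarks.tsv")),
    latent = co[, 1], weights = co[, 2],
    density_dim = manifest$density_dim, mode = manifest$mode,
    n = manifest$n, dim = manifest$dim, seed = manifest$seed,
    jitter = as.numeric(manifest$jitter))
  if ("cell_density_time" %in% manifest$class) {
    object$time_kernel <- list(type = "matern52",
                               length_scale = as.numeric(manifest$time_length_scale))
    object$landmark_times <- drop(read_array_tsv(file.path(dir, "landmark_times.tsv")))
    object$time_range <- as.numeric(manifest$time_range)
  }
  class(object) <- manifest$class
  object
}
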