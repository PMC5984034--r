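# All on-disk vertex indices are 0-based (the convention of most surface
# tooling); in-memory indices are 1-based R indices.  Conversion happens
# only here.

.ext_of <- function(path) tolower(tools::file_ext(path))

.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out[is.infinite(x) & x > 0] <- "Inf"
  out[is.infinite(x) & x < 0] <- "-Inf"
  out
}

#' Read a numeric matrix with optional tract sidecar
#'
#' Supports dense tab-separated text (`.tsv`/`.txt`, header row = column
#' names) and MatrixMarket sparse exchange format (`.mtx`).  For `.mtx`, a
#' sidecar file listing tract names (one per line) provides column labels;
#' by default `<path>.tracts.txt` is used if present, otherwise anonymous
#' labels are assigned with a warning.
#'
#' @param path Input file.
#' @param tracts_path Optional sidecar file of column (tract) names.
#' @param nonnegative If `TRUE` (default), any negative entry is an error
#'   (count/probability matrices cannot be negative).
#' @param sidecar If `TRUE` (default), look for a `<path>.tracts.txt`
#'   sidecar when reading `.mtx` and warn if absent; set `FALSE` for
#'   matrices whose columns are not tracts (e.g. brain locations).
#' @return Numeric matrix (dense) with column names where available.
#' @export
read_matrix <- function(path, tracts_path = NULL, nonnegative = TRUE,
                        sidecar = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- .ext_of(path)
  if (ext == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    if (is.null(tracts_path) && sidecar) {
      cand <- paste0(path, ".tracts.txt")
      if (file.exists(cand)) tracts_path <- cand
    }
    if (!is.null(tracts_path)) {
      nm <- readLines(tracts_path)
      if (length(nm) != ncol(m))
        stop("sidecar ", tracts_path, " lists ", length(nm),
             " names but matrix has ", ncol(m), " columns")
      colnames(m) <- nm
    } else {
      if (sidecar)
        warning("no tract sidecar found for ", path,
                "; using anonymous labels")
      colnames(m) <- paste0("col", seq_len(ncol(m)))
    }
  } else {
    df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
    m <- as.matrix(df)
    if (!is.numeric(m)) stop("malformed matrix file ", path,
                             ": non-numeric entries")
    storage.mode(m) <- "double"
  }
  if (nonnegative && any(m < 0, na.rm = TRUE))
    stop("negative entry in count matrix ", path)
  m
}

#' Write a numeric matrix
#'
#' Dense TSV with a header row for `.tsv`/`.txt`; MatrixMarket format for
#' `.mtx` (column names go to the `<path>.tracts.txt` sidecar).
#'
#' @param m Numeric matrix (dense or sparse `Matrix`).
#' @param path Output file; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  ext <- .ext_of(path)
  if (ext == "mtx") {
    nm <- colnames(m)
    Matrix::writeMM(methods::as(Matrix::Matrix(as.matrix(m), sparse = TRUE),
                                "CsparseMatrix"), path)
    if (!is.null(nm)) writeLines(nm, paste0(path, ".tracts.txt"))
  } else {
    dm <- as.matrix(m)
    if (is.null(colnames(dm))) colnames(dm) <- paste0("col", seq_len(ncol(dm)))
    write.table(dm, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a tract-name file into a tract set
#'
#' One tract name per line, in blueprint column order.
#'
#' @param path Text file of tract names.
#' @return A [tract_set()].
#' @export
read_tract_set <- function(path) {
  nm <- readLines(path)
  nm <- nm[nzchar(trimws(nm))]
  tract_set(trimws(nm))
}

#' Read / write a surface scalar map as one-column text
#'
#' One value per vertex per line; masked vertices are written as `NA` and
#' read back as masked.
#'
#' @param path Input/output text file.
#' @param expected_length Optional vertex count to validate against.
#' @param name,units Metadata for the returned map.
#' @return [surface_scalar_map()] (read) or `path` invisibly (write).
#' @export
read_surface_scalar <- function(path, expected_length = NULL, name = "",
                                units = "") {
  v <- suppressWarnings(as.numeric(readLines(path)))
  if (!is.null(expected_length) && length(v) != expected_length)
    stop("scalar map ", path, " has ", length(v),
         " vertices; expected ", expected_length)
  surface_scalar_map(v, name = if (nzchar(name)) name
                     else tools::file_path_sans_ext(basename(path)),
                     units = units)
}

#' @rdname read_surface_scalar
#' @param map A `surface_scalar_map`.
#' @export
write_surface_scalar <- function(map, path) {
  writeLines(.fmt_num(map$values), path)
  invisible(path)
}

#' Read / write a region atlas as labeled text
#'
#' Either one label per line, or two tab-separated columns
#' `(vertex, label)` with 0-based vertex indices.  An optional name table
#' maps labels to region names (two tab-separated columns: label, name).
#'
#' @param path Label file.
#' @param names_path Optional label-to-name table.
#' @param species Species label for the atlas.
#' @param expected_length Optional vertex count to validate against.
#' @return A [region_atlas()] (read) or `path` invisibly (write).
#' @export
read_region_atlas <- function(path, names_path = NULL, species = "",
                              expected_length = NULL) {
  df <- read.table(path, header = FALSE, sep = "\t")
  if (ncol(df) == 1L) {
    labels <- as.integer(df[[1L]])
  } else {
    vert <- as.integer(df[[1L]]) + 1L  # 0-based on disk
    labels <- integer(max(vert))
    labels[vert] <- as.integer(df[[2L]])
  }
  if (!is.null(expected_length) && length(labels) != expected_length)
    stop("atlas ", path, " covers ", length(labels),
         " vertices; expected ", expected_length)
  names_tab <- if (!is.null(names_path))
    read.table(names_path, header = FALSE, sep = "\t",
               colClasses = c("integer", "character"))
  region_atlas(labels, names = names_tab, species = species)
}

#' @rdname read_region_atlas
#' @param atlas A `region_atlas`.
#' @export
write_region_atlas <- function(atlas, path, names_path = NULL) {
  write.table(
    data.frame(vertex = seq_along(atlas$labels) - 1L, label = atlas$labels),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(names_path))
    write.table(
      data.frame(label = base::names(atlas$names), name = atlas$names),
      names_path, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
  invisible(path)
}

#' Read / write a connectivity blueprint
#'
#' The blueprint matrix is stored as TSV (vertices x tracts, header row =
#' tract names; masked vertices as `NA` rows) with a JSON sidecar
#' `<path>.meta.json` recording species, subject, hemisphere tags and the
#' epsilon floor used at construction.
#'
#' @param path Blueprint TSV file.
#' @return A `connectivity_blueprint` (read) or `path` invisibly (write).
#' @export
read_blueprint <- function(path) {
  m <- read_matrix(path, nonnegative = FALSE)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path)
          else list()
  hemi <- if (!is.null(meta$hemisphere)) unlist(meta$hemisphere) else NULL
  tracts <- tract_set(colnames(m), hemisphere = hemi)
  mask <- stats::complete.cases(m)
  m[!mask, ] <- 0
  connectivity_blueprint(
    m, tracts, vertex_mask = mask,
    species = if (!is.null(meta$species)) meta$species else "",
    subject = if (!is.null(meta$subject)) meta$subject else "",
    epsilon = 0)  # values on disk are already floored/normalized
}

#' @rdname read_blueprint
#' @param bp A `connectivity_blueprint`.
#' @export
write_blueprint <- function(bp, path) {
  out <- apply(bp$matrix, 2L, .fmt_num)
  colnames(out) <- bp$tracts$names
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(species = bp$species, subject = bp$subject,
         hemisphere = bp$tracts$hemisphere, epsilon = bp$epsilon,
         n_vertices = nrow(bp$matrix)),
    paste0(path, ".meta.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(path)
}

#' Read / write a divergence matrix as TSV
#'
#' Values only, one row per source vertex; masked vertices appear as
#' all-`NA` rows/columns and are reconstructed as masks on read.  TSV is
#' intended for modest sizes: writing refuses matrices beyond 5000 x 5000.
#'
#' @param path TSV file.
#' @return A `divergence_matrix` (read) or `path` invisibly (write).
#' @export
read_divergence <- function(path) {
  v <- as.matrix(read.table(path, header = FALSE, sep = "\t"))
  dimnames(v) <- NULL
  row_mask <- rowSums(!is.na(v)) > 0
  col_mask <- colSums(!is.na(v)) > 0
  structure(list(values = v, row_mask = row_mask, col_mask = col_mask,
                 units = "bits"),
            class = "divergence_matrix")
}

#' @rdname read_divergence
#' @param D A `divergence_matrix`.
#' @export
write_divergence <- function(D, path) {
  if (nrow(D$values) > 5000L || ncol(D$values) > 5000L)
    stop("divergence matrix ", nrow(D$values), "x", ncol(D$values),
         " exceeds the 5000x5000 TSV guard; compute on submatrices instead")
  out <- apply(D$values, 2L, .fmt_num)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
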