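#' Read a single-cell dataset from an h5ad file
#'
#' Loads an AnnData h5ad file (the interchange format used by scanpy and the
#' CellxGene / Single Cell Portal repositories) into an [expr_dataset()].
#' Because the co-expression statistic is defined on raw counts, the reader
#' prefers an explicitly raw matrix over a processed main matrix: it takes, in
#' order, a layer named `"counts"`, the `raw/X` slot, then the main `X`
#' matrix, selecting the first that exists and holds integral values. If no
#' stored matrix is integral the file is rejected with an error naming the
#' matrices present.
#'
#' Dense and CSR/CSC sparse encodings are supported, as are string, numeric,
#' boolean and categorical `obs` columns.
#'
#' @param path Path to an `.h5ad` file.
#' @param layer Optional explicit source: `"X"`, `"raw"`, or the name of an
#'   entry under `layers/`. Overrides the priority rule; the chosen matrix
#'   must still be integral.
#'
#' @return An [expr_dataset()] with raw counts and the full `obs` table.
#' @export
read_h5ad <- function(path, layer = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  contents <- rhdf5::h5ls(path)
  entries <- file.path(contents$group, contents$name)
  entries <- sub("^/+", "/", entries)
  has <- function(e) e %in% entries

  layer_names <- contents$name[contents$group == "/layers"]
  candidates <- if (is.null(layer)) {
    c(if ("counts" %in% layer_names) "layers/counts",
      if (has("/raw")) "raw/X",
      if (has("/X")) "X")
  } else if (layer %in% c("X", "raw")) {
    if (layer == "raw") "raw/X" else "X"
  } else {
    if (!layer %in% layer_names) {
      abort(sprintf("Layer '%s' not found; layers present: %s.", layer,
                    if (length(layer_names)) paste(layer_names, collapse = ", ") else "none"))
    }
    paste0("layers/", layer)
  }
  if (!length(candidates)) abort("No expression matrix found in the h5ad file.")

  n_obs <- length(read_h5ad_index(path, "obs"))
  chosen <- NULL
  for (cand in candidates) {
    m <- read_h5ad_matrix(path, cand, n_obs)
    if (length(m@x) == 0 || is_wholenumber(m@x)) {
      chosen <- cand
      break
    }
  }
  if (is.null(chosen)) {
    abort(sprintf(
      "No integer-valued count matrix found (checked: %s). Raw counts are required.",
      paste(candidates, collapse = ", ")
    ))
  }

  var_group <- if (chosen == "raw/X") "raw/var" else "var"
  genes <- read_h5ad_index(path, var_group)
  cells <- read_h5ad_index(path, "obs")
  dimnames(m) <- list(cells, genes)
  obs <- read_h5ad_dataframe(path, "obs", index_name = "cell_id")
  expr_dataset(m, obs)
}

# Read X / raw/X / layers/<name> as a cells x genes dgCMatrix.
read_h5ad_matrix <- function(path, name, n_obs) {
  attrs <- rhdf5::h5readAttributes(path, name)
  enc <- as.character(attrs[["encoding-type"]] %||% "")
  obj <- rhdf5::h5read(path, name, compoundAsDataFrame = FALSE)
  if (is.list(obj) && all(c("data", "indices", "indptr") %in% names(obj))) {
    shape <- as.numeric(attrs[["shape"]]) # [n_obs, n_var]
    if (enc == "" ) enc <- if (length(obj$indptr) - 1 == shape[1]) "csr_matrix" else "csc_matrix"
    x <- as.numeric(obj$data)
    i <- as.numeric(obj$indices)
    p <- as.numeric(obj$indptr)
    if (enc == "csr_matrix") {
      # CSR of (cells x genes) is CSC of the transpose
      m <- Matrix::sparseMatrix(i = i + 1, p = p, x = x,
                                dims = c(shape[2], shape[1]))
      Matrix::t(m)
    } else {
      Matrix::sparseMatrix(i = i + 1, p = p, x = x, dims = c(shape[1], shape[2]))
    }
  } else {
    m <- as.matrix(obj)
    # rhdf5 returns HDF5 row-major data transposed; orient cells x genes
    if (nrow(m) != n_obs && ncol(m) == n_obs) m <- t(m)
    methods::as(methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                        "dMatrix"), "generalMatrix"),
                "CsparseMatrix")
  }
}

read_h5ad_index <- function(path, group) {
  attrs <- rhdf5::h5readAttributes(path, group)
  idx <- as.character(attrs[["_index"]] %||% "_index")
  as.character(rhdf5::h5read(path, paste0(group, "/", idx)))
}

read_h5ad_dataframe <- function(path, group, index_name) {
  attrs <- rhdf5::h5readAttributes(path, group)
  idx <- as.character(attrs[["_index"]] %||% "_index")
  cols <- as.character(attrs[["column-order"]] %||% character(0))
  out <- tibble::tibble(!!index_name := as.character(
    rhdf5::h5read(path, paste0(group, "/", idx))
  ))
  for (cn in cols) {
    out[[cn]] <- read_h5ad_column(path, paste0(group, "/", cn))
  }
  out
}

read_h5ad_column <- function(path, name) {
  attrs <- rhdf5::h5readAttributes(path, name)
  enc <- as.character(attrs[["encoding-type"]] %||% "")
  val <- rhdf5::h5read(path, name, compoundAsDataFrame = FALSE)
  if (enc == "categorical" || (is.list(val) && all(c("categories", "codes") %in% names(val)))) {
    codes <- as.integer(val$codes)
    codes[codes < 0] <- NA_integer_ # -1 encodes missing
    return(as.character(val$categories)[codes + 1])
  }
  if (enc == "nullable-boolean" && is.list(val)) {
    v <- as.logical(val$values)
    v[!as.logical(val$mask)] <- NA
    return(v)
  }
  if (is.raw(val)) val <- as.logical(val)
  if (is.array(val)) val <- as.vector(val)
  if (is.character(val)) as.character(val) else val
}

#' Write a dataset to an h5ad file
#'
#' Writes an [expr_dataset()] as an AnnData-compatible h5ad file: counts as a
#' CSR sparse `X`, `obs` as a dataframe group, `var` holding the gene index
#' plus any supplied per-gene columns. Files written this way load in
#' scanpy/anndata and round-trip through [read_h5ad()].
#'
#' @param ds An [expr_dataset()].
#' @param path Output path (conventionally `.h5ad`).
#' @param var Optional per-gene metadata: a data frame with a `gene` column
#'   matching `gene_ids(ds)` (e.g. chromosome and start from an annotation).
#'
#' @return `path`, invisibly.
#' @export
write_h5ad <- function(ds, path, var = NULL) {
  stopifnot(inherits(ds, "expr_dataset"))
  if (file.exists(path)) file.remove(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createFile(path)

  tm <- Matrix::t(ds$counts) # CSC of transpose == CSR of counts
  rhdf5::h5createGroup(path, "X")
  rhdf5::h5write(as.numeric(tm@x), path, "X/data")
  rhdf5::h5write(as.integer(tm@i), path, "X/indices")
  rhdf5::h5write(as.integer(tm@p), path, "X/indptr")

  obs_cols <- ds$obs[setdiff(names(ds$obs), "cell_id")]
  rhdf5::h5createGroup(path, "obs")
  rhdf5::h5write(ds$obs$cell_id, path, "obs/cell_id")
  for (cn in names(obs_cols)) {
    v <- obs_cols[[cn]]
    if (is.factor(v)) v <- as.character(v)
    if (is.logical(v)) v <- as.integer(v)
    rhdf5::h5write(v, path, paste0("obs/", cn))
  }

  var_cols <- list()
  if (!is.null(var)) {
    var <- as.data.frame(var)
    stopifnot("gene" %in% names(var))
    var <- var[match(gene_ids(ds), var$gene), , drop = FALSE]
    var_cols <- as.list(var[setdiff(names(var), "gene")])
  }
  rhdf5::h5createGroup(path, "var")
  rhdf5::h5write(gene_ids(ds), path, "var/gene_id")
  for (cn in names(var_cols)) {
    v <- var_cols[[cn]]
    if (is.factor(v)) v <- as.character(v)
    rhdf5::h5write(v, path, paste0("var/", cn))
  }

  fid <- rhdf5::H5Fopen(path)
  on.exit(try(rhdf5::H5Fclose(fid), silent = TRUE), add = TRUE, after = FALSE)
  h5ad_attr(fid, "encoding-type", "anndata")
  h5ad_attr(fid, "encoding-version", "0.1.0")
  gid <- rhdf5::H5Gopen(fid, "X")
  h5ad_attr(gid, "encoding-type", "csr_matrix")
  h5ad_attr(gid, "encoding-version", "0.1.0")
  rhdf5::h5writeAttribute(dim(ds$counts), gid, "shape")
  rhdf5::H5Gclose(gid)
  h5ad_df_attrs(fid, "obs", "cell_id", obs_cols)
  h5ad_df_attrs(fid, "var", "gene_id", var_cols)
  rhdf5::H5Fclose(fid)
  rhdf5::h5closeAll()
  invisible(path)
}

h5ad_attr <- function(obj, name, value) {
  rhdf5::h5writeAttribute(value, obj, name,
                          variableLengthString = TRUE, asScalar = TRUE)
}

# Dataframe-group bookkeeping attributes. rhdf5's high-level writer cannot
# create a zero-length string attribute, so an empty column-order falls back
# to the low-level H5A API.
h5ad_df_attrs <- function(fid, group, index_name, cols) {
  gid <- rhdf5::H5Gopen(fid, group)
  h5ad_attr(gid, "encoding-type", "dataframe")
  h5ad_attr(gid, "encoding-version", "0.2.0")
  h5ad_attr(gid, "_index", index_name)
  col_names <- as.character(names(cols))
  if (length(col_names)) {
    rhdf5::h5writeAttribute(col_names, gid, "column-order",
                            variableLengthString = TRUE)
  } else {
    sid <- rhdf5::H5Screate_simple(0L)
    tid <- rhdf5::H5Tcopy("H5T_C_S1")
    rhdf5::H5Tset_size(tid, 8L)
    rhdf5::H5Tset_cset(tid, "UTF-8")
    aid <- rhdf5::H5Acreate(gid, "column-order", tid, sid)
    rhdf5::H5Aclose(aid)
    rhdf5::H5Sclose(sid)
  }
  rhdf5::H5Gclose(gid)
  for (cn in c(index_name, col_names)) {
    did <- rhdf5::H5Dopen(fid, paste0(group, "/", cn))
    enc <- if (cn == index_name) "string-array" else {
      if (is.character(cols[[cn]]) || is.factor(cols[[cn]])) "string-array" else "array"
    }
    h5ad_attr(did, "encoding-type", enc)
    h5ad_attr(did, "encoding-version", "0.2.0")
    rhdf5::H5Dclose(did)
  }
}
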