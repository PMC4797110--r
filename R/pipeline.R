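## descriptor-computation counter, used to verify batch caching
.protshape_state <- new.env(parent = emptyenv())
.protshape_state$descriptor_count <- 0L

descriptor_count <- function(reset = FALSE) {
  out <- .protshape_state$descriptor_count
  if (reset) .protshape_state$descriptor_count <- 0L
  out
}

as_mesh <- function(x) {
  if (inherits(x, "trimesh")) return(x)
  if (is.character(x) && length(x) == 1L)
    return(orient_outward(clean_mesh(read_mesh(x))))
  stop("expected a trimesh or a file path, got ", class(x)[1L])
}

## stable small hash of a model name, used to offset per-model seeds so a
## batch is reproducible and adding a model does not change the others
name_seed_offset <- function(name) {
  h <- 0
  for (cp in utf8ToInt(name)) h <- (h * 31 + cp) %% 1000003
  as.integer(h)
}

descriptor_for <- function(mesh, sgf_cfg, cfg, umbilic_tol,
                           per_model_seed = TRUE) {
  if (per_model_seed) {
    cfg$seed <- as.integer((cfg$seed + name_seed_offset(mesh$name)) %%
                             .Machine$integer.max)
  }
  .protshape_state$descriptor_count <- .protshape_state$descriptor_count + 1L
  compute_descriptor(mesh, sgf_cfg, cfg, umbilic_tol)
}

#' Similarity of two protein surface meshes
#'
#' Computes the feature-matrix descriptor of each mesh and returns the
#' matrix grey relation degree between them. A mesh compared with itself
#' scores exactly 1.
#'
#' @param mesh_a,mesh_b [trimesh] objects or file paths (paths are read,
#'   cleaned and oriented).
#' @param sgf_cfg an [sgf_config()].
#' @param cfg a [descriptor_config()]; `cfg$seed` is offset per model
#'   name so batch results are stable under library growth.
#' @param umbilic_tol passed to [shape_index()].
#' @return scalar similarity `eta` in `(0, 1]`.
#' @export
compare_meshes <- function(mesh_a, mesh_b, sgf_cfg = sgf_config(),
                           cfg = descriptor_config(), umbilic_tol = 0.25) {
  a <- as_mesh(mesh_a)
  b <- as_mesh(mesh_b)
  da <- descriptor_for(a, sgf_cfg, cfg, umbilic_tol)
  db <- descriptor_for(b, sgf_cfg, cfg, umbilic_tol)
  grey_relation(da$M, db$M)$eta
}

#' All-versus-all similarity matrix for a set of meshes
#'
#' Each descriptor is computed exactly once; the diagonal is set to
#' exactly 1.
#'
#' @param meshes list of [trimesh] objects and/or file paths, or a
#'   directory containing OFF/PLY/OBJ files.
#' @param labels model names; default the mesh names.
#' @param sgf_cfg,cfg,umbilic_tol as in [compare_meshes()].
#' @return object of class `similarity_matrix`: a symmetric numeric
#'   matrix of `eta` values with unit diagonal and label dimnames.
#' @export
similarity_matrix <- function(meshes, labels = NULL,
                              sgf_cfg = sgf_config(),
                              cfg = descriptor_config(),
                              umbilic_tol = 0.25) {
  if (is.character(meshes) && length(meshes) == 1L && dir.exists(meshes)) {
    meshes <- list.files(meshes, pattern = "\\.(off|ply|obj)$",
                         ignore.case = TRUE, full.names = TRUE)
    meshes <- as.list(sort(meshes))
  }
  if (!is.list(meshes)) meshes <- as.list(meshes)
  if (length(meshes) < 2L) stop("need at least 2 meshes")
  ms <- lapply(meshes, as_mesh)
  if (is.null(labels)) labels <- vapply(ms, function(m) m$name, "")
  if (anyDuplicated(labels))
    labels <- make.unique(labels)
  descs <- lapply(ms, descriptor_for, sgf_cfg = sgf_cfg, cfg = cfg,
                  umbilic_tol = umbilic_tol)
  N <- length(descs)
  S <- diag(1, N)
  for (i in seq_len(N - 1L))
    for (j in (i + 1L):N) {
      eta <- grey_relation(descs[[i]]$M, descs[[j]]$M)$eta
      S[i, j] <- eta
      S[j, i] <- eta
    }
  dimnames(S) <- list(labels, labels)
  class(S) <- c("similarity_matrix", "matrix")
  S
}

#' @export
print.similarity_matrix <- function(x, digits = 4L, ...) {
  cat("similarity_matrix (grey relation degrees):\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Rank a mesh library by similarity to a query
#'
#' @param query a [trimesh] or path.
#' @param library list of [trimesh]/paths or a directory (as in
#'   [similarity_matrix()]).
#' @param labels optional library labels.
#' @param sgf_cfg,cfg,umbilic_tol as in [compare_meshes()].
#' @return data.frame with columns `label`, `eta`, sorted by descending
#'   `eta`, ties broken by label.
#' @export
rank_query <- function(query, library, labels = NULL,
                       sgf_cfg = sgf_config(), cfg = descriptor_config(),
                       umbilic_tol = 0.25) {
  if (is.character(library) && length(library) == 1L &&
      dir.exists(library)) {
    library <- as.list(sort(list.files(library,
                                       pattern = "\\.(off|ply|obj)$",
                                       ignore.case = TRUE,
                                       full.names = TRUE)))
  }
  if (!is.list(library)) library <- as.list(library)
  if (length(library) == 0L) stop("empty mesh library")
  q <- as_mesh(query)
  ms <- lapply(library, as_mesh)
  if (is.null(labels)) labels <- vapply(ms, function(m) m$name, "")
  dq <- descriptor_for(q, sgf_cfg, cfg, umbilic_tol)
  etas <- vapply(ms, function(m) {
    d <- descriptor_for(m, sgf_cfg, cfg, umbilic_tol)
    grey_relation(dq$M, d$M)$eta
  }, 0)
  ord <- order(-etas, labels, method = "radix")
  data.frame(label = labels[ord], eta = etas[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Average-linkage (UPGMA) clustering of a similarity matrix
#'
#' Clusters on the dissimilarity `d = 1 - eta` with
#' `stats::hclust(method = "average")`; merge heights are non-decreasing.
#'
#' @param S a `similarity_matrix` (or any symmetric similarity matrix
#'   with unit diagonal and labels).
#' @return an `hclust` object.
#' @export
average_linkage <- function(S) {
  S <- unclass(S)
  if (nrow(S) < 2L) stop("need at least 2 labels to cluster")
  stats::hclust(stats::as.dist(1 - S), method = "average")
}

#' Serialize an hclust tree to Newick with branch lengths
#'
#' Branch lengths follow the ultrametric merge heights (each leaf sits at
#' height 0; edge lengths are height differences).
#'
#' @param hc an `hclust`, e.g. from [average_linkage()].
#' @param path optional output file; when `NULL` the Newick string is
#'   returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Write a similarity matrix to CSV
#'
#' Values are rounded to 4 decimals, matching the conventional table
#' display; use [write_descriptor()] JSON for full precision.
#'
#' @param S a `similarity_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_similarity_csv <- function(S, path) {
  m <- round(unclass(S), 4L)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}
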