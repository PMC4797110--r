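#' Read a triangle mesh from OFF, PLY or OBJ
#'
#' Polygonal faces with more than three sides are fan-triangulated from
#' their first vertex. OBJ indices are 1-based on disk, OFF and PLY are
#' 0-based; all are converted to this package's 1-based convention. No
#' cleaning or orientation is applied; see [clean_mesh()] and
#' [orient_outward()].
#'
#' @param path file path.
#' @param format one of `"auto"`, `"off"`, `"ply"`, `"obj"`; `"auto"`
#'   dispatches on the file extension, falling back to content sniffing.
#' @param name model label; defaults to the file base name.
#' @return a [trimesh].
#' @export
read_mesh <- function(path, format = c("auto", "off", "ply", "obj"),
                      name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read mesh: no such file '", path, "'")
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", basename(path)))
    format <- if (ext %in% c("off", "ply", "obj")) ext else {
      head_bytes <- readBin(path, "raw", 16L)
      head_txt <- toupper(rawToChar(head_bytes[head_bytes != as.raw(0)]))
      if (startsWith(head_txt, "OFF")) "off"
      else if (startsWith(head_txt, "PLY")) "ply"
      else stop("cannot auto-detect mesh format of '", path, "'")
    }
  }
  switch(format,
         off = read_off(path, name),
         ply = read_ply(path, name),
         obj = read_obj(path, name))
}

#' Write a triangle mesh to OFF, PLY (ASCII) or OBJ
#'
#' @param mesh a [trimesh]; must have at least one vertex.
#' @param path output file path.
#' @param format one of `"auto"` (from extension), `"off"`, `"ply"`,
#'   `"obj"`.
#' @param digits significant digits for coordinates.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "off", "ply", "obj"),
                       digits = 17L) {
  format <- match.arg(format)
  validate_trimesh(mesh)
  if (nrow(mesh$vertices) == 0L)
    stop("refusing to write an empty mesh (0 vertices)")
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", basename(path)))
    if (!ext %in% c("off", "ply", "obj"))
      stop("cannot infer mesh format from extension '.", ext, "'")
    format <- ext
  }
  vtxt <- apply(format(mesh$vertices, digits = digits, trim = TRUE,
                       scientific = FALSE), 1L, paste, collapse = " ")
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  lines <- switch(format,
    off = c("OFF",
            paste(nv, nf, 0L),
            vtxt,
            paste(3L, mesh$faces[, 1L] - 1L, mesh$faces[, 2L] - 1L,
                  mesh$faces[, 3L] - 1L)),
    ply = c("ply", "format ascii 1.0",
            paste("element vertex", nv),
            "property double x", "property double y", "property double z",
            paste("element face", nf),
            "property list uchar int vertex_indices",
            "end_header",
            vtxt,
            paste(3L, mesh$faces[, 1L] - 1L, mesh$faces[, 2L] - 1L,
                  mesh$faces[, 3L] - 1L)),
    obj = c(paste("# protshape OBJ:", mesh$name),
            paste("v", vtxt),
            paste("f", mesh$faces[, 1L], mesh$faces[, 2L],
                  mesh$faces[, 3L])))
  con <- file(path, "wb")  # binary: stable newlines across platforms
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

read_text_tokens <- function(lines) {
  ## drop comments and blank lines, split on whitespace
  lines <- sub("#.*$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  lines
}

fan_triangulate <- function(poly_list, line_no, path) {
  ## poly_list: list of integer vectors (1-based); returns m x 3 matrix
  out <- vector("list", length(poly_list))
  for (i in seq_along(poly_list)) {
    p <- poly_list[[i]]
    k <- length(p)
    if (k < 3L)
      stop("parse error in '", path, "' at line ", line_no[i],
           ": face with ", k, " vertices")
    out[[i]] <- cbind(p[1L], p[2:(k - 1L)], p[3:k])
  }
  do.call(rbind, out)
}

read_off <- function(path, name) {
  raw_lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw_lines)
  lines <- trimws(sub("#.*$", "", raw_lines[keep]))
  lineno <- which(keep)
  if (length(lines) == 0L) stop("parse error in '", path, "': empty OFF file")
  first <- lines[1L]
  if (!grepl("^OFF", first, ignore.case = FALSE))
    stop("parse error in '", path, "' at line ", lineno[1L],
         ": missing OFF header")
  rest <- trimws(sub("^OFF", "", first))
  if (nzchar(rest)) {          # counts on the header line
    cnt_line <- rest; body_at <- 2L
  } else {
    if (length(lines) < 2L) stop("parse error in '", path, "': missing counts")
    cnt_line <- lines[2L]; body_at <- 3L
  }
  counts <- suppressWarnings(as.numeric(strsplit(cnt_line, "\\s+")[[1L]]))
  if (length(counts) < 2L || anyNA(counts))
    stop("parse error in '", path, "': bad OFF count line '", cnt_line, "'")
  nv <- as.integer(counts[1L]); nf <- as.integer(counts[2L])
  body <- lines[seq.int(body_at, length.out = length(lines) - body_at + 1L)]
  bodyno <- lineno[seq.int(body_at, length.out = length(body))]
  if (length(body) < nv)
    stop("parse error in '", path, "': header promises ", nv,
         " vertices but body has ", length(body), " records")
  vtok <- strsplit(body[seq_len(nv)], "\\s+")
  if (any(lengths(vtok) < 3L))
    stop("parse error in '", path, "' at line ",
         bodyno[which(lengths(vtok) < 3L)[1L]], ": bad vertex record")
  verts <- t(vapply(vtok, function(t) as.numeric(t[1:3]), numeric(3L)))
  if (anyNA(verts))
    stop("parse error in '", path, "': non-numeric vertex coordinate")
  frecs <- body[nv + seq_len(min(nf, max(0L, length(body) - nv)))]
  if (length(frecs) < nf)
    stop("parse error in '", path, "': header promises ", nf,
         " faces but body has ", length(frecs))
  fno <- bodyno[nv + seq_along(frecs)]
  polys <- vector("list", nf)
  for (i in seq_len(nf)) {
    t <- suppressWarnings(as.numeric(strsplit(frecs[i], "\\s+")[[1L]]))
    if (anyNA(t) || length(t) < 1L || t[1L] < 3 || length(t) < 1 + t[1L])
      stop("parse error in '", path, "' at line ", fno[i],
           ": bad face record '", frecs[i], "'")
    polys[[i]] <- as.integer(t[2:(1 + t[1L])]) + 1L
  }
  faces <- if (nf > 0L) fan_triangulate(polys, fno, path)
           else matrix(integer(0), 0L, 3L)
  trimesh(verts, faces, name)
}

read_obj <- function(path, name) {
  lines <- readLines(path, warn = FALSE)
  vsel <- grepl("^v\\s", lines)
  fsel <- grepl("^f\\s", lines)
  vtok <- strsplit(trimws(sub("^v", "", lines[vsel])), "\\s+")
  if (any(lengths(vtok) < 3L))
    stop("parse error in '", path, "' at line ",
         which(vsel)[which(lengths(vtok) < 3L)[1L]], ": bad vertex record")
  verts <- if (length(vtok)) t(vapply(vtok, function(t)
    as.numeric(t[1:3]), numeric(3L))) else matrix(numeric(0), 0L, 3L)
  if (anyNA(verts)) stop("parse error in '", path, "': bad vertex coordinate")
  fno <- which(fsel)
  ftok <- strsplit(trimws(sub("^f", "", lines[fsel])), "\\s+")
  polys <- vector("list", length(ftok))
  for (i in seq_along(ftok)) {
    idx <- suppressWarnings(as.integer(sub("/.*$", "", ftok[[i]])))
    if (anyNA(idx) || any(idx < 1L))
      stop("parse error in '", path, "' at line ", fno[i],
           ": bad face record (only positive 1-based indices supported)")
    polys[[i]] <- idx
  }
  faces <- if (length(polys)) fan_triangulate(polys, fno, path)
           else matrix(integer(0), 0L, 3L)
  trimesh(verts, faces, name)
}

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_bin <- function(con, type, n = 1L) {
  switch(type,
    char = , int8 = readBin(con, "integer", n, size = 1L, signed = TRUE,
                            endian = "little"),
    uchar = , uint8 = readBin(con, "integer", n, size = 1L, signed = FALSE,
                              endian = "little"),
    short = , int16 = readBin(con, "integer", n, size = 2L, signed = TRUE,
                              endian = "little"),
    ushort = , uint16 = readBin(con, "integer", n, size = 2L, signed = FALSE,
                                endian = "little"),
    int = , int32 = , uint = , uint32 =
      readBin(con, "integer", n, size = 4L, endian = "little"),
    float = , float32 = readBin(con, "double", n, size = 4L,
                                endian = "little"),
    double = , float64 = readBin(con, "double", n, size = 8L,
                                 endian = "little"),
    stop("unsupported PLY property type '", type, "'"))
}

read_ply <- function(path, name) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, 1L)
  if (!identical(trimws(magic), "ply"))
    stop("parse error in '", path, "': missing 'ply' magic")
  fmt <- NULL
  elements <- list()   # list of list(name, count, props=list(name,type,list_count_type))
  cur <- NULL
  repeat {
    ln <- readLines(con, 1L)
    if (length(ln) == 0L) stop("parse error in '", path, "': truncated header")
    tok <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(tok) == 0L || tok[1L] == "comment") next
    if (tok[1L] == "format") {
      fmt <- tok[2L]
      if (!fmt %in% c("ascii", "binary_little_endian"))
        stop("unsupported PLY format '", fmt, "' in '", path, "'")
    } else if (tok[1L] == "element") {
      cur <- length(elements) + 1L
      elements[[cur]] <- list(name = tok[2L],
                              count = as.integer(tok[3L]), props = list())
    } else if (tok[1L] == "property") {
      if (is.null(cur)) stop("parse error in '", path, "': property before element")
      p <- if (tok[2L] == "list")
        list(name = tok[5L], type = tok[4L], count_type = tok[3L])
      else list(name = tok[3L], type = tok[2L], count_type = NULL)
      elements[[cur]]$props <- c(elements[[cur]]$props, list(p))
    } else if (tok[1L] == "end_header") break
  }
  if (is.null(fmt)) stop("parse error in '", path, "': no format line")
  verts <- NULL
  polys <- NULL
  if (fmt == "ascii") {
    body <- readLines(con)
    body <- body[nzchar(trimws(body))]
    at <- 0L
    for (el in elements) {
      if (el$count > length(body) - at)
        stop("parse error in '", path, "': element '", el$name,
             "' promises ", el$count, " records, body has fewer")
      rec <- body[at + seq_len(el$count)]
      at <- at + el$count
      if (el$name == "vertex") {
        pn <- vapply(el$props, `[[`, "", "name")
        xyz <- match(c("x", "y", "z"), pn)
        if (anyNA(xyz)) stop("PLY vertex element lacks x/y/z in '", path, "'")
        tokl <- strsplit(trimws(rec), "\\s+")
        verts <- t(vapply(tokl, function(t) as.numeric(t[xyz]), numeric(3L)))
      } else if (el$name == "face") {
        polys <- lapply(strsplit(trimws(rec), "\\s+"), function(t) {
          t <- as.numeric(t)
          as.integer(t[2:(1 + t[1L])]) + 1L
        })
      }
    }
  } else {
    for (el in elements) {
      is_list <- vapply(el$props, function(p) !is.null(p$count_type), logical(1L))
      if (el$name == "vertex") {
        pn <- vapply(el$props, `[[`, "", "name")
        if (any(is_list)) stop("list property on PLY vertex unsupported")
        types <- vapply(el$props, `[[`, "", "type")
        cols <- matrix(0, el$count, length(el$props))
        for (i in seq_len(el$count))
          for (j in seq_along(el$props))
            cols[i, j] <- ply_read_bin(con, types[j])
        xyz <- match(c("x", "y", "z"), pn)
        if (anyNA(xyz)) stop("PLY vertex element lacks x/y/z in '", path, "'")
        verts <- cols[, xyz, drop = FALSE]
      } else if (el$name == "face") {
        polys <- vector("list", el$count)
        p <- el$props[[1L]]
        if (length(el$props) != 1L || is.null(p$count_type))
          stop("unsupported PLY face layout in '", path, "'")
        for (i in seq_len(el$count)) {
          k <- ply_read_bin(con, p$count_type)
          polys[[i]] <- as.integer(ply_read_bin(con, p$type, k)) + 1L
        }
      } else {
        types <- vapply(el$props, `[[`, "", "type")
        for (i in seq_len(el$count))
          for (j in seq_along(el$props)) {
            if (!is.null(el$props[[j]]$count_type)) {
              k <- ply_read_bin(con, el$props[[j]]$count_type)
              ply_read_bin(con, types[j], k)
            } else ply_read_bin(con, types[j])
          }
      }
    }
  }
  if (is.null(verts)) stop("parse error in '", path, "': no vertex element")
  if (is.null(polys)) polys <- list()
  faces <- if (length(polys))
    fan_triangulate(polys, seq_along(polys), path)
  else matrix(integer(0), 0L, 3L)
  trimesh(verts, faces, name)
}

#' Clean a triangle mesh
#'
#' Merges duplicate vertices (within `merge_tol`), drops zero-area and
#' duplicate faces, and drops unreferenced vertices. Removal counts are
#' reported via `message()` when anything changes. Idempotent.
#'
#' @param mesh a [trimesh].
#' @param merge_tol merge distance; default `1e-8` times the bounding-box
#'   diagonal (scale-free duplicate detection).
#' @param verbose emit a message describing removals.
#' @return a cleaned [trimesh].
#' @export
clean_mesh <- function(mesh, merge_tol = NULL, verbose = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces
  if (is.null(merge_tol)) merge_tol <- 1e-8 * bbox_diagonal(mesh)
  n0 <- nrow(v); m0 <- nrow(f)
  ## vertex merge by snapping to a grid of pitch merge_tol
  if (merge_tol > 0 && n0 > 0L) {
    key <- apply(round(sweep(v, 2L, apply(v, 2L, min)) / merge_tol), 1L,
                 paste, collapse = ",")
  } else {
    key <- apply(v, 1L, paste, collapse = ",")
  }
  first <- !duplicated(key)
  remap <- match(key, key[first])
  v <- v[first, , drop = FALSE]
  if (nrow(f) > 0L) {
    f <- matrix(remap[f], ncol = 3L)
    ## degenerate (repeated-index) faces
    keep <- f[, 1L] != f[, 2L] & f[, 2L] != f[, 3L] & f[, 1L] != f[, 3L]
    f <- f[keep, , drop = FALSE]
    ## zero-area slivers
    if (nrow(f) > 0L) {
      ar <- face_normals_areas(list(vertices = v, faces = f))$area
      scale2 <- max(bbox_diagonal(list(vertices = v, faces = f))^2, 1e-300)
      f <- f[ar > 1e-14 * scale2, , drop = FALSE]
    }
    ## duplicate faces (same vertex set)
    if (nrow(f) > 0L) {
      fs <- t(apply(f, 1L, sort))
      f <- f[!duplicated(fs), , drop = FALSE]
    }
  }
  ## unreferenced vertices
  used <- sort(unique(as.vector(f)))
  if (length(used) < nrow(v) && nrow(f) > 0L) {
    v <- v[used, , drop = FALSE]
    f <- matrix(match(f, used), ncol = 3L)
  } else if (nrow(f) == 0L) {
    used <- integer(0)
  }
  out <- trimesh(v, f, mesh$name)
  if (verbose && (nrow(v) != n0 || nrow(f) != m0))
    message(sprintf("clean_mesh: %d -> %d vertices, %d -> %d faces",
                    n0, nrow(v), m0, nrow(f)))
  out
}

#' Orient a mesh consistently and outward
#'
#' Face windings are made consistent by breadth-first propagation over the
#' face-adjacency graph of each connected component; each closed component
#' is then globally flipped, if needed, so its signed volume is positive
#' (outward-facing winding). Open components receive a consistent winding
#' and a warning that outwardness is undefined. Idempotent.
#'
#' @param mesh a [trimesh] with manifold edges.
#' @return an oriented [trimesh].
#' @export
orient_outward <- function(mesh) {
  f <- mesh$faces
  nf <- nrow(f)
  if (nf == 0L) return(mesh)
  e <- mesh_edges(mesh)
  ## face adjacency via interior edges
  int <- which(!is.na(e$f2))
  adj_src <- c(e$f1[int], e$f2[int])
  adj_dst <- c(e$f2[int], e$f1[int])
  adj_same <- c(e$same_dir[int], e$same_dir[int])
  ord <- order(adj_src, method = "radix")
  fac <- factor(adj_src[ord], levels = seq_len(nf))
  nb <- split(adj_dst[ord], fac)
  nb_same <- split(adj_same[ord], fac)
  flip <- rep(NA, nf)
  comp <- rep(NA_integer_, nf)
  ncomp <- 0L
  for (start in seq_len(nf)) {
    if (!is.na(flip[start])) next
    ncomp <- ncomp + 1L
    flip[start] <- FALSE
    comp[start] <- ncomp
    queue <- integer(nf)
    queue[1L] <- start
    qh <- 1L
    qt <- 1L
    while (qh <= qt) {
      cur <- queue[qh]
      qh <- qh + 1L
      ns <- nb[[cur]]
      ss <- nb_same[[cur]]
      for (k in seq_along(ns)) {
        nxt <- ns[k]
        ## consistent orientation: shared edge traversed in opposite
        ## directions, i.e. need flip[nxt] == xor(flip[cur], same_dir)
        want <- xor(flip[cur], ss[k])
        if (is.na(flip[nxt])) {
          flip[nxt] <- want
          comp[nxt] <- ncomp
          qt <- qt + 1L
          queue[qt] <- nxt
        } else if (flip[nxt] != want) {
          stop("non-orientable surface: component ", ncomp,
               " admits no consistent face winding")
        }
      }
    }
  }
  f[flip, ] <- f[flip, c(1L, 3L, 2L), drop = FALSE]
  ## per-component outward flip for closed components
  bnd_face <- unique(e$f1[is.na(e$f2)])
  open_comp <- unique(comp[bnd_face])
  for (ci in seq_len(ncomp)) {
    sel <- comp == ci
    if (ci %in% open_comp) {
      warning("component ", ci, " is open; outward orientation undefined")
      next
    }
    sub <- list(vertices = mesh$vertices, faces = f[sel, , drop = FALSE])
    if (signed_volume(sub) < 0)
      f[sel, ] <- f[sel, c(1L, 3L, 2L), drop = FALSE]
  }
  trimesh(mesh$vertices, f, mesh$name)
}
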