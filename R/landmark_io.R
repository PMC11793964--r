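# Landmark data containers and file I/O.
#
# Conventions: landmark indices are 1-based everywhere a user sees them;
# coordinates are stored as k x 3 matrices (one configuration) or k x 3 x n
# arrays (a dataset); units are an opaque label (default "mm").

#' Single landmark configuration
#'
#' A named set of k ordered 3D points for one specimen.
#'
#' @param specimen_id character scalar identifier.
#' @param coords numeric k x 3 matrix of landmark coordinates.
#' @param landmark_names optional character vector of k labels; defaults to
#'   `L1..Lk`.
#' @return An object of class `landmark_config` with elements `specimen_id`,
#'   `coords` and `landmark_names`.
#' @export
landmark_config <- function(specimen_id, coords, landmark_names = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L)
    stop("coords must have 3 columns (x, y, z), got ", ncol(coords))
  k <- nrow(coords)
  if (k < 4L)
    stop("configuration '", specimen_id, "' has ", k, " landmarks; at least 4 required")
  bad <- which(!is.finite(coords), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-finite coordinate for specimen '", specimen_id,
         "' at landmark ", bad[1L, 1L])
  if (is.null(landmark_names)) landmark_names <- paste0("L", seq_len(k))
  if (length(landmark_names) != k)
    stop("landmark_names length ", length(landmark_names), " != k = ", k)
  storage.mode(coords) <- "double"
  dimnames(coords) <- list(landmark_names, c("x", "y", "z"))
  structure(list(specimen_id = as.character(specimen_id), coords = coords,
                 landmark_names = as.character(landmark_names)),
            class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat("<landmark_config> specimen:", x$specimen_id,
      "| k =", nrow(x$coords), "landmarks\n")
  invisible(x)
}

#' Bilateral symmetry map
#'
#' Describes the object-symmetry structure of a landmark scheme: which
#' landmarks form left/right pairs, which lie on the midline, and across
#' which coordinate plane the structure is (approximately) mirrored.
#'
#' @param pairs two-column integer matrix (or data.frame) of (left, right)
#'   landmark indices, 1-based.
#' @param midline integer vector of unpaired (midline) landmark indices.
#' @param plane axis normal to the reflection plane: `"x"` (the default,
#'   i.e. the yz-plane), `"y"` or `"z"`.
#' @return An object of class `symmetry_map`.
#' @export
symmetry_map <- function(pairs, midline = integer(0), plane = c("x", "y", "z")) {
  plane <- match.arg(plane)
  pairs <- as.matrix(pairs)
  if (length(pairs) == 0L) pairs <- matrix(integer(0), 0L, 2L)
  if (ncol(pairs) != 2L) stop("pairs must have two columns (left, right)")
  storage.mode(pairs) <- "integer"
  midline <- as.integer(midline)
  idx <- c(pairs[, 1L], pairs[, 2L], midline)
  if (anyDuplicated(idx))
    stop("symmetry map re-uses landmark index ", idx[duplicated(idx)][1L])
  colnames(pairs) <- c("left", "right")
  structure(list(pairs = pairs, midline = midline, plane = plane),
            class = "symmetry_map")
}

#' Validate a symmetry map against a landmark count
#'
#' Checks that pair and midline indices exactly partition `1..k`.
#'
#' @param map a [symmetry_map()].
#' @param k number of landmarks in the scheme.
#' @return `map`, invisibly; errors otherwise.
#' @export
validate_symmetry_map <- function(map, k) {
  stopifnot(inherits(map, "symmetry_map"))
  idx <- sort(c(map$pairs[, 1L], map$pairs[, 2L], map$midline))
  if (any(idx < 1L) || any(idx > k))
    stop("symmetry map index out of range 1..", k, ": ",
         idx[idx < 1L | idx > k][1L])
  if (length(idx) != k || !all(idx == seq_len(k)))
    stop("symmetry map does not partition landmarks 1..", k,
         " (missing: ", paste(setdiff(seq_len(k), idx), collapse = ","), ")")
  invisible(map)
}

#' Landmark dataset
#'
#' n configurations sharing one landmark scheme, with optional design factors
#' (lineage, period) and an optional symmetry map.
#'
#' @param configs list of [landmark_config()] objects sharing k and landmark
#'   order.
#' @param lineage,period optional factors (or character vectors), one value
#'   per configuration.
#' @param symmetry optional [symmetry_map()].
#' @param units coordinate unit label; not interpreted.
#' @return An object of class `landmark_dataset` with elements `coords`
#'   (k x 3 x n array), `specimen_id`, `landmark_names`, `lineage`, `period`,
#'   `symmetry`, `units`.
#' @export
landmark_dataset <- function(configs, lineage = NULL, period = NULL,
                             symmetry = NULL, units = "mm") {
  if (length(configs) < 2L) stop("a landmark dataset needs n >= 2 specimens")
  k <- nrow(configs[[1L]]$coords)
  nms <- configs[[1L]]$landmark_names
  ids <- vapply(configs, function(cf) cf$specimen_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicated specimen_id: ", ids[duplicated(ids)][1L])
  for (cf in configs) {
    if (nrow(cf$coords) != k)
      stop("specimen '", cf$specimen_id, "' has ", nrow(cf$coords),
           " landmarks, expected ", k)
    if (!identical(cf$landmark_names, nms))
      stop("specimen '", cf$specimen_id, "' has a different landmark order")
  }
  coords <- array(NA_real_, dim = c(k, 3L, length(configs)),
                  dimnames = list(nms, c("x", "y", "z"), ids))
  for (i in seq_along(configs)) coords[, , i] <- configs[[i]]$coords
  if (!is.null(symmetry)) validate_symmetry_map(symmetry, k)
  as_fac <- function(f, what) {
    if (is.null(f)) return(NULL)
    if (length(f) != length(configs))
      stop(what, " must have one value per specimen")
    factor(f)
  }
  structure(list(coords = coords, specimen_id = ids, landmark_names = nms,
                 lineage = as_fac(lineage, "lineage"),
                 period = as_fac(period, "period"),
                 symmetry = symmetry, units = units),
            class = "landmark_dataset")
}

#' @export
print.landmark_dataset <- function(x, ...) {
  cat("<landmark_dataset> n =", dim(x$coords)[3L], "specimens, k =",
      dim(x$coords)[1L], "landmarks [", x$units, "]\n")
  if (!is.null(x$lineage) && !is.null(x$period)) {
    cat("  lineage x period counts:\n")
    print(table(x$lineage, x$period))
  }
  if (!is.null(x$symmetry))
    cat("  symmetry:", nrow(x$symmetry$pairs), "pairs,",
        length(x$symmetry$midline), "midline, plane", x$symmetry$plane, "\n")
  invisible(x)
}

#' Number of specimens / landmarks
#' @param x a `landmark_dataset`.
#' @return integer count.
#' @export
n_specimens <- function(x) dim(x$coords)[3L]

#' @rdname n_specimens
#' @export
n_landmarks <- function(x) dim(x$coords)[1L]

#' Subset a landmark dataset by specimen
#'
#' @param x a `landmark_dataset`.
#' @param keep logical or integer index over specimens.
#' @return A `landmark_dataset` with the selected specimens; factor levels
#'   are dropped.
#' @export
subset_dataset <- function(x, keep) {
  ids <- x$specimen_id[keep]
  if (length(ids) < 2L) stop("subset must retain at least 2 specimens")
  structure(list(coords = x$coords[, , keep, drop = FALSE],
                 specimen_id = ids, landmark_names = x$landmark_names,
                 lineage = if (!is.null(x$lineage)) droplevels(x$lineage[keep]),
                 period = if (!is.null(x$period)) droplevels(x$period[keep]),
                 symmetry = x$symmetry, units = x$units),
            class = "landmark_dataset")
}

num_fmt <- function(x) formatC(x, digits = 17, format = "g")

parse_num <- function(x, specimen, landmark) {
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v)))
    stop("non-numeric coordinate for specimen '", specimen,
         "' at landmark ", landmark)
  v
}

#' Read landmark coordinates from CSV
#'
#' Two dialects are supported. `wide`: one row per specimen; first column is
#' the specimen id, remaining columns come in x/y/z triplets named
#' `x<label>`, `y<label>`, `z<label>` (e.g. `x1,y1,z1,...`). `long`: columns
#' `specimen_id`, `landmark`, `x`, `y`, `z`, one row per landmark. Landmark
#' order is taken from the header (wide) or from the first specimen (long).
#' Files are comma-separated with `.` decimal and a mandatory header.
#'
#' @param path file path.
#' @param schema `"wide"` or `"long"`.
#' @return A `landmark_dataset` fragment (no metadata factors, no symmetry).
#' @export
read_landmarks_csv <- function(path, schema = c("wide", "long")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (schema == "wide") read_landmarks_wide(df) else read_landmarks_long(df)
}

read_landmarks_wide <- function(df) {
  if (ncol(df) < 2L) stop("wide CSV needs an id column plus coordinates")
  ids <- df[[1L]]
  cn <- colnames(df)[-1L]
  m <- regmatches(cn, regexec("^([xyz])[._]?(.*)$", cn))
  ax <- vapply(m, function(g) if (length(g)) g[2L] else NA_character_, "")
  lab <- vapply(m, function(g) if (length(g)) g[3L] else NA_character_, "")
  if (any(is.na(ax)))
    stop("wide CSV coordinate columns must be named x<label>,y<label>,z<label>; bad column: ",
         cn[is.na(ax)][1L])
  labs <- unique(lab)
  configs <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    co <- matrix(NA_real_, length(labs), 3L)
    for (j in seq_along(labs)) {
      for (a in 1:3) {
        col <- which(ax == c("x", "y", "z")[a] & lab == labs[j])
        if (length(col) != 1L)
          stop("missing or duplicated coordinate column for landmark ", j,
               " (", c("x", "y", "z")[a], labs[j], ")")
        val <- df[i, col + 1L]
        if (is.na(val) || !nzchar(val))
          stop("missing coordinate for specimen '", ids[i],
               "' at landmark ", j)
        co[j, a] <- parse_num(val, ids[i], j)
      }
    }
    configs[[i]] <- landmark_config(ids[i], co, labs)
  }
  landmark_dataset(configs)
}

read_landmarks_long <- function(df) {
  need <- c("specimen_id", "landmark", "x", "y", "z")
  if (!all(need %in% colnames(df)))
    stop("long CSV needs columns: ", paste(need, collapse = ", "))
  ids <- unique(df$specimen_id)
  first <- df[df$specimen_id == ids[1L], , drop = FALSE]
  labs <- first$landmark
  if (anyDuplicated(labs))
    stop("duplicated landmark '", labs[duplicated(labs)][1L],
         "' for specimen '", ids[1L], "'")
  configs <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    rows <- df[df$specimen_id == ids[i], , drop = FALSE]
    miss <- setdiff(labs, rows$landmark)
    if (length(miss) > 0L || nrow(rows) != length(labs))
      stop("specimen '", ids[i], "' is missing landmark ",
           if (length(miss)) which(labs == miss[1L]) else "(extra rows present)")
    ord <- match(labs, rows$landmark)
    co <- cbind(parse_num(rows$x[ord], ids[i], "x"),
                parse_num(rows$y[ord], ids[i], "y"),
                parse_num(rows$z[ord], ids[i], "z"))
    configs[[i]] <- landmark_config(ids[i], co, labs)
  }
  landmark_dataset(configs)
}

#' Write landmark coordinates to CSV
#'
#' Inverse of [read_landmarks_csv()]; coordinates are written with 17
#' significant digits so a write/read round trip is lossless to well below
#' 1e-12.
#'
#' @param x a `landmark_dataset` (or `landmark_config` for a 1-specimen wide
#'   file).
#' @param path output file path.
#' @param schema `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_landmarks_csv <- function(x, path, schema = c("wide", "long")) {
  schema <- match.arg(schema)
  k <- dim(x$coords)[1L]; n <- dim(x$coords)[3L]
  labs <- x$landmark_names
  if (schema == "wide") {
    hdr <- c("specimen_id",
             as.vector(t(outer(labs, c("x", "y", "z"),
                               function(l, a) paste0(a, l)))))
    lines <- vapply(seq_len(n), function(i) {
      paste(c(x$specimen_id[i], num_fmt(as.vector(t(x$coords[, , i])))),
            collapse = ",")
    }, character(1))
    writeLines(c(paste(hdr, collapse = ","), lines), path)
  } else {
    lines <- unlist(lapply(seq_len(n), function(i) {
      vapply(seq_len(k), function(j)
        paste(c(x$specimen_id[i], labs[j], num_fmt(x$coords[j, , i])),
              collapse = ","), character(1))
    }))
    writeLines(c("specimen_id,landmark,x,y,z", lines), path)
  }
  invisible(path)
}

#' Read a TPS landmark file
#'
#' Parses records of the form `LM3=<k>` followed by k lines of three numbers,
#' with optional `ID=` and `SCALE=` lines; `SCALE=` is applied
#' multiplicatively to the record's coordinates.
#'
#' @param path file path.
#' @return A `landmark_dataset` fragment.
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM3=", lines)
  if (length(starts) == 0L) stop("no LM3= records found in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  configs <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:ends[r]]
    k <- as.integer(sub("^LM3=", "", block[1L]))
    coord_lines <- block[-1L][!grepl("^[A-Za-z]+=", block[-1L])]
    if (length(coord_lines) != k)
      stop("record ", r, ": LM3=", k, " but ", length(coord_lines),
           " coordinate lines found")
    co <- t(vapply(coord_lines, function(l) {
      v <- suppressWarnings(as.numeric(strsplit(l, "[ \t]+")[[1L]]))
      if (length(v) != 3L || any(is.na(v)))
        stop("record ", r, ": malformed coordinate line '", l, "'")
      v
    }, numeric(3), USE.NAMES = FALSE))
    id_line <- grep("^ID=", block, value = TRUE)
    id <- if (length(id_line)) sub("^ID=", "", id_line[1L]) else paste0("spec", r)
    sc_line <- grep("^SCALE=", block, value = TRUE)
    if (length(sc_line)) co <- co * as.numeric(sub("^SCALE=", "", sc_line[1L]))
    configs[[r]] <- landmark_config(id, co)
  }
  landmark_dataset(configs)
}

#' Write a TPS landmark file
#'
#' @param x a `landmark_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(x, path) {
  k <- dim(x$coords)[1L]; n <- dim(x$coords)[3L]
  out <- character(0)
  for (i in seq_len(n)) {
    rows <- apply(x$coords[, , i], 1L, function(p) paste(num_fmt(p), collapse = " "))
    out <- c(out, paste0("LM3=", k), rows, paste0("ID=", x$specimen_id[i]))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a plain-text pts landmark export
#'
#' One specimen per file: lines of `name x y z` following optional header
#' lines (a header line is any line whose first token is not followed by
#' three numbers, e.g. a bare point count). Names containing spaces must be
#' double-quoted.
#'
#' @param path file path.
#' @param specimen_id id for the resulting configuration; defaults to the
#'   file name without extension.
#' @return A `landmark_config`.
#' @export
read_pts <- function(path, specimen_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(specimen_id))
    specimen_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  names <- character(0); co <- NULL
  for (l in lines) {
    toks <- scan(text = l, what = "character", quiet = TRUE)
    if (length(toks) < 4L) next                      # header / count line
    v <- suppressWarnings(as.numeric(toks[(length(toks) - 2L):length(toks)]))
    if (any(is.na(v))) next                          # header line
    nm <- paste(toks[seq_len(length(toks) - 3L)], collapse = " ")
    names <- c(names, nm)
    co <- rbind(co, v)
  }
  if (is.null(co) || nrow(co) < 4L)
    stop("pts file '", path, "' contains fewer than 4 points")
  landmark_config(specimen_id, co, names)
}

#' Write a plain-text pts landmark export
#'
#' @param config a `landmark_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pts <- function(config, path) {
  nm <- config$landmark_names
  quoted <- ifelse(grepl("[ \t]", nm), paste0('"', nm, '"'), nm)
  rows <- vapply(seq_along(nm), function(j)
    paste(c(quoted[j], num_fmt(config$coords[j, ])), collapse = " "),
    character(1))
  writeLines(c(length(nm), rows), path)
  invisible(path)
}

#' Read a symmetry-pair table from CSV
#'
#' Columns `left` and `right` hold 1-based landmark indices of bilateral
#' pairs; rows with an empty/NA `right` declare midline landmarks. Landmarks
#' appearing in no row are treated as midline.
#'
#' @param path file path.
#' @param k number of landmarks in the scheme.
#' @param plane reflection plane axis, as in [symmetry_map()].
#' @return A validated `symmetry_map`.
#' @export
read_symmetry_csv <- function(path, k, plane = "x") {
  df <- utils::read.csv(path)
  if (!all(c("left", "right") %in% colnames(df)))
    stop("symmetry CSV needs columns 'left' and 'right'")
  mid_rows <- is.na(df$right)
  pairs <- cbind(as.integer(df$left[!mid_rows]), as.integer(df$right[!mid_rows]))
  explicit_mid <- as.integer(df$left[mid_rows])
  midline <- sort(unique(c(explicit_mid,
                           setdiff(seq_len(k), c(pairs, explicit_mid)))))
  validate_symmetry_map(symmetry_map(pairs, midline, plane), k)
}

#' Assemble a full dataset from coordinates, metadata and symmetry tables
#'
#' Joins a coordinate fragment with a specimen metadata table (columns
#' `specimen_id`, `lineage`, `period`) and a symmetry map. Specimens without
#' a metadata row are dropped with a warning; metadata rows without a
#' coordinate configuration are ignored (the dataset is sized by the
#' coordinates). Row order of the metadata table never affects the result.
#'
#' @param coords a `landmark_dataset` fragment (e.g. from
#'   [read_landmarks_csv()]).
#' @param metadata data.frame with columns `specimen_id`, `lineage`,
#'   `period`, or a path to such a CSV.
#' @param symmetry a `symmetry_map`, a path to a symmetry CSV, or `NULL`.
#' @param lineage_levels,period_levels allowed factor levels; values outside
#'   these are an error.
#' @return A `landmark_dataset` with factors and symmetry attached.
#' @export
assemble_dataset <- function(coords, metadata, symmetry = NULL,
                             lineage_levels = c("DE", "DL", "wild"),
                             period_levels = c("historic", "modern")) {
  stopifnot(inherits(coords, "landmark_dataset"))
  if (is.character(metadata)) metadata <- utils::read.csv(metadata)
  need <- c("specimen_id", "lineage", "period")
  if (!all(need %in% colnames(metadata)))
    stop("metadata needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(metadata$specimen_id))
    stop("duplicated specimen_id in metadata: ",
         metadata$specimen_id[duplicated(metadata$specimen_id)][1L])
  k <- dim(coords$coords)[1L]
  if (is.character(symmetry)) symmetry <- read_symmetry_csv(symmetry, k)
  if (!is.null(symmetry)) validate_symmetry_map(symmetry, k)

  hit <- match(coords$specimen_id, metadata$specimen_id)
  if (all(is.na(hit)))
    stop("no specimen ids shared between coordinates and metadata")
  if (anyNA(hit)) {
    dropped <- coords$specimen_id[is.na(hit)]
    warning("dropping ", length(dropped),
            " specimen(s) without metadata: ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ...")
  }
  keep <- which(!is.na(hit))
  md <- metadata[hit[keep], , drop = FALSE]
  bad_lin <- setdiff(unique(as.character(md$lineage)), lineage_levels)
  if (length(bad_lin))
    stop("unknown lineage level: ", bad_lin[1L])
  bad_per <- setdiff(unique(as.character(md$period)), period_levels)
  if (length(bad_per))
    stop("unknown period level: ", bad_per[1L])

  structure(list(coords = coords$coords[, , keep, drop = FALSE],
                 specimen_id = coords$specimen_id[keep],
                 landmark_names = coords$landmark_names,
                 lineage = factor(md$lineage, levels = lineage_levels),
                 period = factor(md$period, levels = period_levels),
                 symmetry = symmetry, units = coords$units),
            class = "landmark_dataset")
}
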